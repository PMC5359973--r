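#' Event weights for duplication-loss parsimony
#'
#' The default weights are 1.5 for a duplication, 0.0 for a conditional
#' duplication (one whose existence depends on how a species-tree polytomy is
#' resolved) and 1.0 for a loss.
#'
#' @param dup,cond,loss Non-negative event weights.
#' @return A list of class `recon_params`.
#' @export
recon_params <- function(dup = 1.5, cond = 0.0, loss = 1.0) {
  stopifnot(dup >= 0, cond >= 0, loss >= 0)
  structure(list(dup = dup, cond = cond, loss = loss),
            class = "recon_params")
}

## ---- LCA mapping ------------------------------------------------------------

#' Map gene-tree nodes to species-tree nodes (LCA mapping)
#'
#' Each gene leaf maps to its species; each internal gene node maps to the
#' last common ancestor, in the species tree, of its children's images.
#'
#' @param gene_tree A rooted binary gene tree.
#' @param species_tree A rooted species tree (polytomies allowed).
#' @param leaf_map Named character vector from [build_leaf_map()].
#' @return An integer vector over gene-tree nodes holding species node ids.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_map) {
  if (!gene_tree$rooted)
    stop("gene tree is unrooted; root it first (see root_balance)")
  if (!gt_is_binary(gene_tree))
    stop("gene tree must be binary for reconciliation")
  sp_leaf_id <- stats::setNames(gt_leaves(species_tree),
                                gt_leaf_labels(species_tree))
  depth <- gt_depths(species_tree)
  M <- integer(gt_nnode(gene_tree))
  for (v in gt_postorder(gene_tree)) {
    kids <- gene_tree$children[[v]]
    if (!length(kids)) {
      sp <- leaf_map[[gene_tree$label[v]]]
      if (is.null(sp) || is.na(sp)) stop("leaf not in map: ",
                                         gene_tree$label[v])
      M[v] <- sp_leaf_id[[sp]]
    } else {
      m <- M[kids[1L]]
      for (k in kids[-1L]) m <- gt_lca2(species_tree, depth, m, M[k])
      M[v] <- m
    }
  }
  M
}

## hit set: which children of species node s contain leaf images of the gene
## subtree rooted at v (only called when M[v] is at or below s)
.hit_set <- function(v, s, gene_tree, species_tree, M, depth) {
  if (M[v] != s) {
    ## M[v] strictly below s: walk up to the child of s on its path
    x <- M[v]
    while (!identical(species_tree$parent[x], s) &&
           !is.na(species_tree$parent[x])) x <- species_tree$parent[x]
    return(x)
  }
  unique(unlist(lapply(gene_tree$children[[v]], .hit_set,
                       s = s, gene_tree = gene_tree,
                       species_tree = species_tree, M = M, depth = depth)))
}

#' Classify gene-tree nodes as speciation, duplication or conditional
#' duplication
#'
#' At binary-resolved species nodes a gene node is a duplication when it maps
#' to the same species node as one of its children. At a species polytomy the
#' classification follows the resolution semantics: a node is a (required)
#' duplication when it is a duplication in every binary resolution of the
#' polytomy, which holds exactly when the sets of polytomy-child subtrees hit
#' by its two gene-child clades intersect; it is a conditional duplication
#' when they are disjoint but at least one clade spans two or more
#' polytomy-child subtrees (a duplication in some, not all, resolutions);
#' otherwise it is a speciation.
#'
#' @param mapping Result of [lca_map()].
#' @inheritParams lca_map
#' @return Character vector over gene nodes: `"leaf"`, `"speciation"`,
#'   `"duplication"` or `"conditional_duplication"`.
#' @export
classify_events <- function(mapping, gene_tree, species_tree) {
  depth <- gt_depths(species_tree)
  ev <- rep("leaf", gt_nnode(gene_tree))
  for (v in gt_internal(gene_tree)) {
    kids <- gene_tree$children[[v]]
    s <- mapping[v]
    nsch <- length(species_tree$children[[s]])
    if (nsch <= 2L) {
      ev[v] <- if (any(mapping[kids] == s)) "duplication" else "speciation"
    } else {
      h1 <- .hit_set(kids[1L], s, gene_tree, species_tree, mapping, depth)
      h2 <- .hit_set(kids[2L], s, gene_tree, species_tree, mapping, depth)
      ev[v] <- if (length(intersect(h1, h2))) "duplication"
      else if (max(length(h1), length(h2)) >= 2L) "conditional_duplication"
      else "speciation"
    }
  }
  ev
}

#' Count reconstructible losses per species node
#'
#' For every gene-tree edge (u, v) with k species-tree edges on the path from
#' the image of u down to the image of v, k - 1 losses are implied when u is
#' a speciation and k when u is a (conditional) duplication. Each loss is
#' attributed to the off-path sibling node where the lineage disappeared;
#' when the path node is a polytomy (several off-path siblings) the loss is
#' attributed to the polytomous node itself. No losses are imputed above the
#' image of the gene root.
#'
#' @param mapping,events Results of [lca_map()] and [classify_events()].
#' @inheritParams lca_map
#' @return Integer vector of loss counts over species-tree nodes.
#' @export
count_losses <- function(mapping, events, gene_tree, species_tree) {
  depth <- gt_depths(species_tree)
  losses <- integer(gt_nnode(species_tree))
  for (u in gt_internal(gene_tree)) {
    is_dup <- events[u] != "speciation"
    for (v in gene_tree$children[[u]]) {
      ## path M(u) = x0, x1, ..., xk = M(v), walking v's image upwards
      path <- mapping[v]
      x <- mapping[v]
      while (x != mapping[u]) {
        x <- species_tree$parent[x]
        path <- c(x, path)
      }
      k <- length(path) - 1L
      if (k == 0L) next
      from <- if (is_dup) 1L else 2L  # index into path of first losing node
      if (from > k) next
      for (i in from:k) {
        at <- path[i]                 # node where the lineage passed
        sib <- setdiff(species_tree$children[[at]], path[i + 1L])
        target <- if (length(sib) == 1L) sib else at
        losses[target] <- losses[target] + 1L
      }
    }
  }
  losses
}

#' Lower and upper bounds of inferred duplications
#'
#' The lower bound is the oldest species node in which the duplication was
#' already present (its LCA image); the upper bound is the youngest species
#' node in which it was not yet present (the parent of the image), absent for
#' duplications at the species root.
#'
#' @inheritParams count_losses
#' @return A data frame with columns `gene_node`, `lower`, `upper` (species
#'   node ids; `upper` is `NA` at the species root).
#' @export
duplication_bounds <- function(mapping, events, species_tree) {
  idx <- which(events == "duplication")
  data.frame(gene_node = idx,
             lower = mapping[idx],
             upper = species_tree$parent[mapping[idx]])
}

## ---- full reconciliation ----------------------------------------------------

#' Reconcile a gene tree with a species tree
#'
#' Weighted duplication-loss parsimony reconciliation via the LCA mapping:
#' maps every gene node into the species tree, classifies internal nodes as
#' speciation, duplication or conditional duplication (the latter only at
#' species-tree polytomies), tabulates reconstructible losses per species
#' node, and reports duplication bounds and the total weighted cost
#' `w_dup * duplications + w_cond * conditionals + w_loss * losses`.
#' Conditional duplications carry the (default zero) conditional weight and
#' are excluded from downstream event tables.
#'
#' @inheritParams lca_map
#' @param params Event weights from [recon_params()].
#' @return An object of class `reconciliation`: a list with elements
#'   `mapping`, `events`, `losses` (named by species node), `dup_bounds`
#'   (data frame with species node labels), `n_dup`, `n_cond`, `n_loss`,
#'   `cost`, plus the inputs (`gene_tree`, `species_tree`, `leaf_map`,
#'   `params`).
#' @examples
#' g <- parse_newick("((A.1,B.1),A.2);")
#' s <- parse_newick("(A,B);")
#' r <- reconcile(g, s, build_leaf_map(g, s))
#' r$cost   # 1 duplication + 1 loss = 2.5
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map,
                      params = recon_params()) {
  stopifnot(inherits(params, "recon_params"))
  species_tree <- label_internal_nodes(species_tree)
  M <- lca_map(gene_tree, species_tree, leaf_map)
  ev <- classify_events(M, gene_tree, species_tree)
  losses <- count_losses(M, ev, gene_tree, species_tree)
  bounds <- duplication_bounds(M, ev, species_tree)
  n_dup <- sum(ev == "duplication")
  n_cond <- sum(ev == "conditional_duplication")
  n_loss <- sum(losses)
  cost <- params$dup * n_dup + params$cond * n_cond + params$loss * n_loss
  bounds_lab <- data.frame(
    gene_node = bounds$gene_node,
    lower = species_tree$label[bounds$lower],
    upper = ifelse(is.na(bounds$upper), NA_character_,
                   species_tree$label[bounds$upper]),
    stringsAsFactors = FALSE)
  structure(list(
    gene_tree = gene_tree, species_tree = species_tree, leaf_map = leaf_map,
    params = params, mapping = M, events = ev,
    losses = stats::setNames(losses, species_tree$label),
    dup_bounds = bounds_lab,
    n_dup = n_dup, n_cond = n_cond, n_loss = n_loss, cost = cost
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Duplication-loss reconciliation\n")
  cat(sprintf("  gene leaves: %d   species leaves: %d\n",
              length(gt_leaves(x$gene_tree)),
              length(gt_leaves(x$species_tree))))
  cat(sprintf("  duplications: %d   conditional: %d   losses: %d\n",
              x$n_dup, x$n_cond, x$n_loss))
  cat(sprintf("  weighted cost: %g  (dup %g, cond %g, loss %g)\n",
              x$cost, x$params$dup, x$params$cond, x$params$loss))
  invisible(x)
}

#' @export
summary.reconciliation <- function(object, ...) {
  loss_tab <- object$losses[object$losses > 0]
  out <- list(
    n_dup = object$n_dup, n_cond = object$n_cond, n_loss = object$n_loss,
    cost = object$cost,
    duplications = object$dup_bounds,
    losses = data.frame(species_node = names(loss_tab),
                        losses = as.integer(loss_tab),
                        row.names = NULL, stringsAsFactors = FALSE))
  class(out) <- "summary.reconciliation"
  out
}

#' @export
print.summary.reconciliation <- function(x, ...) {
  cat(sprintf("Reconciliation: %d duplications, %d conditional, %d losses, cost %g\n",
              x$n_dup, x$n_cond, x$n_loss, x$cost))
  if (nrow(x$duplications)) {
    cat("Duplication bounds (lower = oldest species with the duplication):\n")
    print(x$duplications, row.names = FALSE)
  }
  if (nrow(x$losses)) {
    cat("Losses per species node:\n")
    print(x$losses, row.names = FALSE)
  }
  invisible(x)
}
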