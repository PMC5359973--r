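## LCA mapping without the binarity requirement (used while gene-tree
## polytomies are being resolved)
gt_lca_map_any <- function(gene_tree, species_tree, leaf_map) {
  sp_leaf_id <- stats::setNames(gt_leaves(species_tree),
                                gt_leaf_labels(species_tree))
  depth <- gt_depths(species_tree)
  M <- integer(gt_nnode(gene_tree))
  for (v in gt_postorder(gene_tree)) {
    kids <- gene_tree$children[[v]]
    if (!length(kids)) {
      M[v] <- sp_leaf_id[[leaf_map[[gene_tree$label[v]]]]]
    } else {
      m <- M[kids[1L]]
      for (k in kids[-1L]) m <- gt_lca2(species_tree, depth, m, M[k])
      M[v] <- m
    }
  }
  M
}

#' Root an unrooted tree by branch-sum balance
#'
#' Places the root on the edge, and at the point along it, that minimises the
#' absolute difference between the sums of all branch lengths in the two
#' subtrees of the root (each sum including the root-adjacent partial edge).
#' This is the branch-balance variant of midpoint rooting. Supports are
#' re-homed to the edges they describe; the two root-adjacent edges share the
#' support of the split edge.
#'
#' @param tree An unrooted tree with branch lengths on every edge (a rooted
#'   binary tree is first unrooted).
#' @return A rooted binary tree (when the input was fully resolved).
#' @export
root_balance <- function(tree) {
  if (tree$rooted && length(tree$children[[tree$root]]) == 2L)
    tree <- unroot_tree(tree)
  nonroot <- setdiff(seq_len(gt_nnode(tree)), tree$root)
  if (anyNA(tree$length[nonroot]))
    stop("branch-balance rooting requires branch lengths on every edge")
  tot <- sum(tree$length[nonroot])
  ## subtree length sums (including the node's own edge)
  ssub <- numeric(gt_nnode(tree))
  for (v in gt_postorder(tree))
    ssub[v] <- sum(tree$length[v], ssub[tree$children[[v]]], na.rm = TRUE)
  best <- NULL
  for (v in gt_preorder(tree)) {
    if (v == tree$root) next
    L <- tree$length[v]
    c_left <- ssub[v] - L           # strictly inside v's subtree
    c_right <- tot - ssub[v]        # strictly on the other side
    t_star <- min(max((c_right + L - c_left) / 2, 0), L)
    diff <- abs(c_left - c_right - L + 2 * t_star)
    if (is.null(best) || diff < best$diff - 1e-12) {
      best <- list(v = v, t = t_star, diff = diff)
    }
  }
  .reroot_on_edge(tree, best$v, best$t)
}

## re-root `tree` on the edge above node v, at distance t from v
.reroot_on_edge <- function(tree, v, t) {
  n <- gt_nnode(tree)
  p <- tree$parent[v]
  ## undirected edge list: one per non-root node
  ea <- tree$parent[-tree$root]; eb <- setdiff(seq_len(n), tree$root)
  el <- tree$length[eb]; es <- tree$support[eb]
  keep <- eb != v
  ea <- ea[keep]; el2 <- el[keep]; es2 <- es[keep]; eb2 <- eb[keep]
  R <- n + 1L
  ea <- c(ea, R, R); eb2 <- c(eb2, v, p)
  el2 <- c(el2, t, tree$length[v] - t)
  es2 <- c(es2, tree$support[v], tree$support[v])
  ## orient away from R by BFS
  parent <- rep(NA_integer_, R)
  length_ <- rep(NA_real_, R)
  support <- rep(NA_real_, R)
  children <- rep(list(integer(0)), R)
  label <- c(tree$label, NA_character_)
  adj <- vector("list", R)
  for (i in seq_along(ea)) {
    adj[[ea[i]]] <- c(adj[[ea[i]]], list(c(eb2[i], i)))
    adj[[eb2[i]]] <- c(adj[[eb2[i]]], list(c(ea[i], i)))
  }
  visited <- logical(R)
  queue <- R; visited[R] <- TRUE
  while (length(queue)) {
    a <- queue[1L]; queue <- queue[-1L]
    for (e in adj[[a]]) {
      b <- e[1L]
      if (visited[b]) next
      visited[b] <- TRUE
      parent[b] <- a
      children[[a]] <- c(children[[a]], b)
      length_[b] <- el2[e[2L]]
      support[b] <- es2[e[2L]]
      queue <- c(queue, b)
    }
  }
  gt_validate(gt_new(parent, children, label, length_, support, rooted = TRUE))
}

#' Contract weakly supported internal edges
#'
#' Every internal edge whose bootstrap support is below the cutoff (strict
#' inequality: support equal to the cutoff is kept) is contracted, producing
#' polytomies; edges with missing support are treated as weak.
#'
#' @param tree A rooted gene tree with supports on internal edges.
#' @param cutoff Support threshold (default 90).
#' @return The tree with weak edges contracted.
#' @export
collapse_weak_edges <- function(tree, cutoff = 90) {
  weak <- integer(0)
  n_missing <- 0L
  for (v in gt_postorder(tree)) {
    if (v == tree$root || length(tree$children[[v]]) == 0L) next
    s <- tree$support[v]
    if (is.na(s)) n_missing <- n_missing + 1L
    if (is.na(s) || s < cutoff) {
      weak <- c(weak, v)
      p <- tree$parent[v]
      at <- match(v, tree$children[[p]])
      kids <- tree$children[[v]]
      tree$children[[p]] <- append(tree$children[[p]][-at], kids, after = at - 1L)
      tree$parent[kids] <- p
      tree$children[[v]] <- integer(0)
    }
  }
  if (n_missing > 0L)
    message(n_missing, " internal edge(s) without support treated as weak")
  if (length(weak)) tree <- gt_drop_nodes(tree, weak)
  tree
}

## ---- polytomy resolution by minimum reconciliation cost ---------------------

## all rooted binary tree shapes over k labelled units, as nested lists of
## unit indices; (2k-3)!! shapes, generated by leaf insertion
.enumerate_local_trees <- function(k) {
  trees <- list(1L)
  for (j in 2:k) {
    nxt <- list()
    insert <- function(tr) {
      res <- list(list(tr, j))
      if (is.list(tr)) {
        for (l in insert(tr[[1L]])) res <- c(res, list(list(l, tr[[2L]])))
        for (r in insert(tr[[2L]])) res <- c(res, list(list(tr[[1L]], r)))
      }
      res
    }
    for (tr in trees) nxt <- c(nxt, insert(tr))
    trees <- nxt
  }
  trees
}

#' Resolve gene-tree polytomies at minimum reconciliation cost
#'
#' Each polytomy is replaced by the binary arrangement of its child subtrees
#' that minimises the weighted duplication-loss reconciliation cost. Because
#' the LCA image of a polytomy is invariant under its resolution, each
#' polytomy can be optimised independently and the result is a global
#' optimum over all joint resolutions. Resolution is exact (full enumeration
#' of the (2k-3)!! local topologies) for polytomies of degree at most
#' `d_max`; beyond that a species-guided greedy join is used and a warning
#' is emitted.
#'
#' @param poly_tree A rooted gene tree, possibly with polytomies (typically
#'   from [collapse_weak_edges()]).
#' @inheritParams lca_map
#' @param params Event weights from [recon_params()].
#' @param d_max Largest polytomy degree resolved exactly (default 8).
#' @return A binary gene tree with reconciliation cost no larger than that of
#'   any binary tree obtainable by resolving the polytomies.
#' @export
resolve_min_cost <- function(poly_tree, species_tree, leaf_map,
                             params = recon_params(), d_max = 8) {
  tree <- poly_tree
  depth <- gt_depths(species_tree)
  repeat {
    polys <- which(lengths(tree$children) > 2L)
    if (!length(polys)) break
    ## deepest-first: resolve a polytomy none of whose descendants is one
    d <- gt_depths(tree)
    v <- polys[which.max(d[polys])]
    M <- gt_lca_map_any(tree, species_tree, leaf_map)
    units <- tree$children[[v]]
    k <- length(units)
    if (k <= d_max) {
      shapes <- .enumerate_local_trees(k)
      costs <- vapply(shapes, function(sh)
        .local_cost(sh, units, tree, species_tree, leaf_map, M, depth, params),
        0)
      sh <- shapes[[which.min(costs)]]
    } else {
      warning("polytomy of degree ", k, " exceeds d_max = ", d_max,
              "; using greedy species-guided resolution (may be non-optimal)")
      sh <- .greedy_shape(units, M, species_tree, depth)
    }
    tree <- .apply_local_shape(tree, v, units, sh)
  }
  tree
}

## hit set of a gene subtree (or resolved group) w.r.t. species polytomy s
.unit_hits <- function(u, s, tree, species_tree, M, depth) {
  .hit_set(u, s, tree, species_tree, M, depth)
}

## cost of the edges/events introduced by one local shape (nested list of
## unit indices); everything outside the shape is invariant
.local_cost <- function(shape, units, tree, species_tree, leaf_map, M,
                        depth, params) {
  cost <- 0
  eval_node <- function(nd) {
    ## returns list(img, hits_cache_fun, is_dup_parent marker cost added)
    if (!is.list(nd)) {
      u <- units[nd]
      return(list(img = M[u], node = u, units = nd))
    }
    a <- eval_node(nd[[1L]]); b <- eval_node(nd[[2L]])
    s <- gt_lca2(species_tree, depth, a$img, b$img)
    nsch <- length(species_tree$children[[s]])
    if (nsch <= 2L) {
      ev <- if (a$img == s || b$img == s) "duplication" else "speciation"
    } else {
      h1 <- .group_hits(nd[[1L]], units, s, tree, species_tree, M, depth)
      h2 <- .group_hits(nd[[2L]], units, s, tree, species_tree, M, depth)
      ev <- if (length(intersect(h1, h2))) "duplication"
      else if (max(length(h1), length(h2)) >= 2L) "conditional_duplication"
      else "speciation"
    }
    w <- switch(ev, duplication = params$dup,
                conditional_duplication = params$cond, speciation = 0)
    extra <- if (ev == "speciation") -1L else 0L
    k1 <- depth[a$img] - depth[s]
    k2 <- depth[b$img] - depth[s]
    cost <<- cost + w +
      params$loss * (max(k1 + extra, 0L) + max(k2 + extra, 0L))
    list(img = s, units = c(a$units, b$units))
  }
  eval_node(shape)
  cost
}

## hit set of a (possibly grouped) local subtree w.r.t. species node s
.group_hits <- function(nd, units, s, tree, species_tree, M, depth) {
  idx <- unlist(nd)
  unique(unlist(lapply(units[idx], .hit_set, s = s, gene_tree = tree,
                       species_tree = species_tree, M = M, depth = depth)))
}

## greedy species-guided resolution: repeatedly join the pair of groups whose
## joint LCA image is deepest (ties: first pair in index order)
.greedy_shape <- function(units, M, species_tree, depth) {
  groups <- as.list(seq_along(units))
  imgs <- M[units]
  while (length(groups) > 1L) {
    best <- NULL
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        l <- gt_lca2(species_tree, depth, imgs[i], imgs[j])
        if (is.null(best) || depth[l] > best$d) best <- list(i = i, j = j, d = depth[l], l = l)
      }
    }
    groups[[best$i]] <- list(groups[[best$i]], groups[[best$j]])
    imgs[best$i] <- best$l
    groups <- groups[-best$j]
    imgs <- imgs[-best$j]
  }
  groups[[1L]]
}

## graft a local binary shape in place of polytomy v
.apply_local_shape <- function(tree, v, units, shape) {
  build <- function(nd, par) {
    if (!is.list(nd)) {
      u <- units[nd]
      tree$parent[u] <<- par
      tree$children[[par]] <<- c(tree$children[[par]], u)
      return(invisible(NULL))
    }
    id <- gt_nnode(tree) + 1L
    tree$parent[id] <<- par
    tree$children[[id]] <<- integer(0)
    tree$label[id] <<- NA_character_
    tree$length[id] <<- 0
    tree$support[id] <<- NA_real_
    tree$children[[par]] <<- c(tree$children[[par]], id)
    build(nd[[1L]], id); build(nd[[2L]], id)
  }
  tree$children[[v]] <- integer(0)
  build(shape[[1L]], v); build(shape[[2L]], v)
  tree
}

#' Randomly resolve species-tree polytomies
#'
#' Each polytomy is resolved into a random binary arrangement (new edges get
#' zero length), reproducibly under a seed.
#'
#' @param tree A rooted tree, possibly with polytomies.
#' @param seed Optional integer seed.
#' @return A binary tree.
#' @export
random_resolve <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!gt_has_polytomy(tree)) return(tree)
  phy <- as_phylo(tree)
  phy2 <- ape::multi2di(phy, random = TRUE)
  as_gtree(phy2, supports = "label", rooted = tree$rooted)
}

#' Rearrange a gene tree at weakly supported branches
#'
#' The full rearrangement protocol applied before reconciliation: internal
#' edges with support below `cutoff` are contracted and the resulting
#' polytomies re-resolved at minimum reconciliation cost. When the species
#' tree contains polytomies the default protocol first resolves them
#' randomly (seeded), rearranges against that binary tree, and leaves the
#' final reconciliation against the non-binary species tree to the caller;
#' random rearrangements introduced this way map back to species polytomies
#' and can only yield conditional duplications, which are discarded from the
#' results. The rearranged tree is kept only if its reconciliation cost
#' against the original species tree does not exceed that of the input tree,
#' so rearrangement never hurts parsimony.
#'
#' @inheritParams resolve_min_cost
#' @param gene_tree A rooted binary gene tree with supports.
#' @param cutoff Bootstrap cutoff identifying weak branches (default 90,
#'   strict `<`).
#' @param two_pass Rearrange against a randomly binarised species tree
#'   (default) rather than directly against the non-binary one.
#' @param seed Seed for the random species-tree resolution.
#' @return The rearranged gene tree, with attributes `cost_before`,
#'   `cost_after` and `improved`.
#' @export
rearrange_tree <- function(gene_tree, species_tree, leaf_map,
                           params = recon_params(), cutoff = 90,
                           d_max = 8, two_pass = TRUE, seed = NULL) {
  collapsed <- collapse_weak_edges(gene_tree, cutoff)
  sp_res <- if (two_pass && gt_has_polytomy(species_tree))
    random_resolve(species_tree, seed) else species_tree
  resolved <- resolve_min_cost(collapsed, sp_res, leaf_map, params, d_max)
  cost0 <- reconcile(gene_tree, species_tree, leaf_map, params)$cost
  cost1 <- reconcile(resolved, species_tree, leaf_map, params)$cost
  out <- if (cost1 <= cost0) resolved else gene_tree
  attr(out, "cost_before") <- cost0
  attr(out, "cost_after") <- min(cost0, cost1)
  attr(out, "improved") <- cost1 < cost0
  out
}
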