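#' @importFrom ape read.tree write.tree multi2di rphylo
NULL

## Internal rooted-tree representation ("gtree")
##
## A gtree is a list with parallel vectors indexed by node id (1..N):
##   parent   integer, NA at the root
##   children list of integer vectors (ordered); leaves have integer(0)
##   label    character, NA where absent (leaves always labelled)
##   length   numeric, length of the edge above the node, NA where absent
##   support  numeric in [0, 100], NA where absent (edge above the node)
##   root     integer id of the root
##   rooted   logical flag (an "unrooted" tree is stored with a basal
##            multifurcation and rooted = FALSE)
##
## Polytomies are allowed everywhere; binarity is checked where an operation
## requires it.

gt_new <- function(parent, children, label, length_, support, rooted = TRUE) {
  structure(list(
    parent = as.integer(parent), children = children,
    label = as.character(label), length = as.numeric(length_),
    support = as.numeric(support),
    root = which(is.na(parent))[1L], rooted = isTRUE(rooted)
  ), class = "gtree")
}

gt_nnode <- function(tree) length(tree$parent)

gt_leaves <- function(tree) which(lengths(tree$children) == 0L)

gt_leaf_labels <- function(tree) tree$label[gt_leaves(tree)]

gt_internal <- function(tree) which(lengths(tree$children) > 0L)

gt_is_binary <- function(tree) all(lengths(tree$children) %in% c(0L, 2L))

#' @export
print.gtree <- function(x, ...) {
  cat(sprintf("<gtree> %d leaves, %d nodes, %s\n",
              length(gt_leaves(x)), gt_nnode(x),
              if (x$rooted) "rooted" else "unrooted"))
  invisible(x)
}

## postorder / preorder node sequences (iterative; children before parents)
gt_postorder <- function(tree) {
  rev(gt_preorder(tree))
}

gt_preorder <- function(tree) {
  n <- gt_nnode(tree)
  out <- integer(n); stack <- tree$root; k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; out[k] <- v
    kids <- tree$children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out[seq_len(k)]
}

gt_depths <- function(tree) {
  d <- integer(gt_nnode(tree))
  for (v in gt_preorder(tree)) {
    p <- tree$parent[v]
    d[v] <- if (is.na(p)) 0L else d[p] + 1L
  }
  d
}

## LCA of two nodes by walking up (trees here are small)
gt_lca2 <- function(tree, depth, a, b) {
  while (a != b) {
    if (depth[a] < depth[b]) b <- tree$parent[b] else a <- tree$parent[a]
  }
  a
}

## leaf-label sets per node (list over nodes), postorder fold
gt_clades <- function(tree) {
  cl <- vector("list", gt_nnode(tree))
  for (v in gt_postorder(tree)) {
    kids <- tree$children[[v]]
    cl[[v]] <- if (!length(kids)) tree$label[v] else
      sort(unlist(cl[kids], use.names = FALSE))
  }
  cl
}

gt_validate <- function(tree) {
  stopifnot(inherits(tree, "gtree"))
  if (sum(is.na(tree$parent)) != 1L) stop("tree must have exactly one root")
  lv <- gt_leaves(tree)
  if (anyNA(tree$label[lv])) stop("all leaves must be labelled")
  if (anyDuplicated(tree$label[lv]))
    stop("duplicate leaf labels: ",
         paste(unique(tree$label[lv][duplicated(tree$label[lv])]), collapse = ", "))
  sup <- tree$support[!is.na(tree$support)]
  if (length(sup) && (any(sup < 0) || any(sup > 100)))
    stop("supports must lie in [0, 100]")
  invisible(tree)
}

## ---- conversion to/from ape "phylo" ----------------------------------------

## numeric-looking internal labels
.is_numeric_label <- function(x) {
  !is.na(x) & x != "" & !is.na(suppressWarnings(as.numeric(x)))
}

as_gtree <- function(phy, supports = c("auto", "support", "label"),
                     rooted = TRUE) {
  supports <- match.arg(supports)
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c_ <- phy$edge[i, 2L]
    parent[c_] <- p
    children[[p]] <- c(children[[p]], c_)
  }
  label <- rep(NA_character_, n)
  label[seq_len(ntip)] <- phy$tip.label
  support <- rep(NA_real_, n)
  if (!is.null(phy$node.label)) {
    raw <- phy$node.label
    idx <- ntip + seq_along(raw)
    if (supports == "label") {
      label[idx] <- ifelse(raw == "", NA_character_, raw)
    } else {
      num <- .is_numeric_label(raw)
      if (supports == "support") num <- raw != "" & !is.na(raw)
      support[idx[num]] <- suppressWarnings(as.numeric(raw[num]))
      label[idx[!num]] <- ifelse(raw[!num] == "", NA_character_, raw[!num])
    }
  }
  len <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) {
    len[phy$edge[, 2L]] <- ifelse(is.nan(phy$edge.length), NA_real_,
                                  phy$edge.length)
  }
  gt_validate(gt_new(parent, children, label, len, support, rooted = rooted))
}

as_phylo <- function(tree) {
  n <- gt_nnode(tree)
  lv <- gt_leaves(tree)
  ntip <- length(lv)
  ## renumber: tips 1..ntip in preorder of appearance, internals after
  pre <- gt_preorder(tree)
  newid <- integer(n)
  tipc <- 0L; intc <- ntip
  for (v in pre) {
    if (length(tree$children[[v]]) == 0L) {
      tipc <- tipc + 1L; newid[v] <- tipc
    } else {
      intc <- intc + 1L; newid[v] <- intc
    }
  }
  edge <- matrix(0L, n - 1L, 2L)
  elen <- numeric(n - 1L)
  k <- 0L
  for (v in pre) {
    p <- tree$parent[v]
    if (is.na(p)) next
    k <- k + 1L
    edge[k, ] <- c(newid[p], newid[v])
    elen[k] <- tree$length[v]
  }
  tip.label <- character(ntip)
  tip.label[newid[lv]] <- tree$label[lv]
  node.label <- character(n - ntip)
  for (v in gt_internal(tree)) {
    lab <- if (!is.na(tree$support[v])) format(tree$support[v]) else
      if (!is.na(tree$label[v])) tree$label[v] else ""
    node.label[newid[v] - ntip] <- lab
  }
  phy <- list(edge = edge, Nnode = n - ntip, tip.label = tip.label,
              node.label = node.label)
  if (any(!is.na(elen))) phy$edge.length <- ifelse(is.na(elen), NaN, elen)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

## ---- newick I/O -------------------------------------------------------------

#' Parse a newick string into a tree
#'
#' Reads one rooted or unrooted tree in newick format. Internal node labels
#' that look numeric are interpreted as branch supports by default (the common
#' bootstrap convention); non-numeric labels are kept as node names. Supports
#' are attached to the child node of each internal edge.
#'
#' @param text A newick string (single tree, terminated by ';'), or the path
#'   of a file containing one.
#' @param supports How to interpret internal node labels: `"auto"` (numeric
#'   values become supports, anything else a name), `"support"` or `"label"`
#'   to force one reading.
#' @param rooted Logical; whether to treat the tree as rooted. A basal
#'   trifurcation with `rooted = FALSE` represents an unrooted tree.
#' @return A tree object (internal class `gtree`). Polytomies are preserved.
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:1,C:2);")
#' write_newick(tr)
#' @export
parse_newick <- function(text, supports = c("auto", "support", "label"),
                         rooted = TRUE) {
  supports <- match.arg(supports)
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  text <- paste(text, collapse = "")
  ## structural pre-checks with positions, before handing to the reader
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth > 0L) stop("unbalanced '(': ", depth, " unclosed at end of string")
  if (!grepl(";", text)) stop("newick string lacks terminating ';'")
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse newick string")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  as_gtree(phy, supports = supports, rooted = rooted)
}

#' Write a tree as a newick string
#'
#' Supports are emitted as internal node labels; absent branch lengths are
#' omitted (0-length branches are written as `:0`).
#'
#' @param tree A tree as returned by [parse_newick()].
#' @param file Optional path; when given the string is written there
#'   (UTF-8, LF) and returned invisibly.
#' @param digits Number of significant digits for branch lengths.
#' @return The newick string.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  gt_validate(tree)
  s <- .gt_newick_node(tree, tree$root, digits)
  s <- paste0(s, ";")
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    writeLines(s, con = con, sep = "\n", useBytes = TRUE)
    close(con)
    return(invisible(s))
  }
  s
}

.gt_newick_node <- function(tree, v, digits) {
  kids <- tree$children[[v]]
  lab <- if (length(kids) == 0L) tree$label[v] else {
    if (!is.na(tree$support[v])) format(tree$support[v]) else
      if (!is.na(tree$label[v])) tree$label[v] else ""
  }
  core <- if (length(kids) == 0L) lab else
    paste0("(", paste(vapply(kids, function(k)
      .gt_newick_node(tree, k, digits), ""), collapse = ","), ")", lab)
  if (!is.na(tree$length[v]))
    core <- paste0(core, ":", format(tree$length[v], digits = digits))
  core
}

## ---- leaf -> species mapping ------------------------------------------------

#' Build the gene-leaf to species mapping
#'
#' Either extracts the species label from each gene-leaf label with a
#' delimiter rule (e.g. taxid-prefixed identifiers such as `9606.P1`), or
#' uses an explicit two-column table, which takes precedence when supplied.
#' Gene-leaf labels are never altered; the mapping is a view on them.
#'
#' @param gene_tree,species_tree Trees as returned by [parse_newick()].
#' @param delimiter Field delimiter in gene-leaf labels (fixed string).
#' @param field 1-based index of the field holding the species label.
#' @param table Optional explicit mapping: a two-column data frame
#'   (gene leaf, species leaf) or the path of a headerless TSV.
#' @return A named character vector: names are gene-leaf labels, values the
#'   species-leaf labels. Errors list any leaf whose species is absent from
#'   the species tree.
#' @examples
#' g <- parse_newick("((9606.P1,9606.P2),4932.Q1);")
#' s <- parse_newick("(9606,4932);")
#' build_leaf_map(g, s)
#' @export
build_leaf_map <- function(gene_tree, species_tree, delimiter = ".",
                           field = 1L, table = NULL) {
  gl <- gt_leaf_labels(gene_tree)
  sl <- gt_leaf_labels(species_tree)
  if (!is.null(table)) {
    if (is.character(table) && length(table) == 1L)
      table <- utils::read.table(table, sep = "\t", header = FALSE,
                                 colClasses = "character", quote = "")
    map <- stats::setNames(as.character(table[[2L]]),
                           as.character(table[[1L]]))
    missing_leaves <- setdiff(gl, names(map))
    if (length(missing_leaves))
      stop("leaf map table lacks entries for: ",
           paste(missing_leaves, collapse = ", "))
    map <- map[gl]
  } else {
    sp <- vapply(strsplit(gl, delimiter, fixed = TRUE), function(p) {
      if (length(p) < field) NA_character_ else p[field]
    }, "")
    map <- stats::setNames(sp, gl)
  }
  bad <- names(map)[is.na(map) | !(map %in% sl)]
  if (length(bad))
    stop("gene leaves map to species absent from the species tree: ",
         paste(bad, collapse = ", "))
  map
}

## ---- misc tree utilities ----------------------------------------------------

#' Name unlabelled internal nodes
#'
#' Assigns deterministic names (`prefix` + preorder index) to internal nodes
#' lacking one, so that event and loss tables have stable keys.
#'
#' @param tree A tree.
#' @param prefix Name prefix.
#' @return The tree with all internal nodes labelled.
#' @export
label_internal_nodes <- function(tree, prefix = "n") {
  k <- 0L
  for (v in gt_preorder(tree)) {
    if (length(tree$children[[v]]) == 0L) next
    k <- k + 1L
    if (is.na(tree$label[v])) tree$label[v] <- paste0(prefix, k)
  }
  tree
}

## does the tree contain polytomies?
gt_has_polytomy <- function(tree) any(lengths(tree$children) > 2L)

## drop the root of a rooted binary tree, producing the unrooted form
## (basal trifurcation); the two root edges merge into one, keeping the
## summed length and whichever support is present.
unroot_tree <- function(tree) {
  r <- tree$root
  kids <- tree$children[[r]]
  if (length(kids) != 2L) {
    tree$rooted <- FALSE
    return(tree)
  }
  a <- kids[1L]; b <- kids[2L]
  ## attach b under a if a is internal, else a under b
  if (length(tree$children[[a]]) == 0L && length(tree$children[[b]]) == 0L)
    stop("cannot unroot a two-leaf tree")
  if (length(tree$children[[a]]) == 0L) { tmp <- a; a <- b; b <- tmp }
  ## a becomes the new basal node
  tree$parent[a] <- NA_integer_
  tree$parent[b] <- a
  tree$children[[a]] <- c(tree$children[[a]], b)
  tree$length[b] <- .na_sum(tree$length[a], tree$length[b])
  tree$support[b] <- if (!is.na(tree$support[b])) tree$support[b] else
    tree$support[a]
  tree$length[a] <- NA_real_
  tree$support[a] <- NA_real_
  ## remove the old root node, compacting ids
  gt_drop_nodes(tree, r, new_root = a)
}

.na_sum <- function(a, b) {
  if (is.na(a) && is.na(b)) return(NA_real_)
  sum(c(a, b), na.rm = TRUE)
}

## remove the given nodes (assumed disconnected already) and compact ids
gt_drop_nodes <- function(tree, drop, new_root = NULL) {
  keep <- setdiff(seq_len(gt_nnode(tree)), drop)
  newid <- integer(gt_nnode(tree))
  newid[keep] <- seq_along(keep)
  parent <- tree$parent[keep]
  parent <- ifelse(is.na(parent), NA_integer_, newid[parent])
  children <- lapply(tree$children[keep], function(k) newid[k])
  out <- gt_new(parent, children, tree$label[keep], tree$length[keep],
                tree$support[keep], rooted = tree$rooted)
  out
}

## canonical topology string (sorted children by clade label sets); used for
## deterministic comparisons, ignoring lengths and supports
gt_canonical <- function(tree) {
  rec <- function(v) {
    kids <- tree$children[[v]]
    if (!length(kids)) return(tree$label[v])
    paste0("(", paste(sort(vapply(kids, rec, "")), collapse = ","), ")")
  }
  rec(tree$root)
}

## build a gtree from a nested list structure: leaves are character labels,
## internal nodes are (unnamed) lists of children. Lengths/supports NA.
gt_from_nested <- function(x) {
  parent <- integer(0); children <- list(); label <- character(0)
  add <- function(node, par) {
    id <- length(parent) + 1L
    parent[id] <<- if (is.null(par)) NA_integer_ else par
    children[[id]] <<- integer(0)
    label[id] <<- NA_character_
    if (!is.null(par)) children[[par]] <<- c(children[[par]], id)
    if (is.character(node)) {
      label[id] <<- node
    } else {
      for (ch in node) add(ch, id)
    }
    id
  }
  add(x, NULL)
  gt_new(parent, children, label, rep(NA_real_, length(parent)),
         rep(NA_real_, length(parent)))
}
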