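## Independent oracles used across the test files: naive species-LCA mapping,
## brute-force minimum reconciliation cost by enumeration of all valid
## mappings (and, for polytomous species trees, all binary resolutions), and
## exhaustive generators of tree shapes. These deliberately avoid the
## package's reconciliation code paths.

## ancestor chain (node, parent, ..., root) for every node
oracle_anc_chains <- function(tree) {
  lapply(seq_len(gt_nnode(tree)), function(v) {
    ch <- v
    while (!is.na(tree$parent[v])) {
      v <- tree$parent[v]
      ch <- c(ch, v)
    }
    ch
  })
}

## naive LCA mapping by ancestor-set intersection (quadratic)
oracle_lca_map <- function(gene_tree, species_tree, leaf_map) {
  chains <- oracle_anc_chains(species_tree)
  dep <- gt_depths(species_tree)
  sp_id <- setNames(gt_leaves(species_tree), gt_leaf_labels(species_tree))
  M <- integer(gt_nnode(gene_tree))
  cl <- gt_clades(gene_tree)
  for (v in seq_len(gt_nnode(gene_tree))) {
    sps <- unique(unname(leaf_map[cl[[v]]]))
    common <- Reduce(intersect, chains[sp_id[sps]])
    M[v] <- common[which.max(dep[common])]
  }
  M
}

## brute-force minimum weighted duplication-loss cost over all valid
## mappings of a binary gene tree into a binary species tree: every internal
## gene node may map to any ancestor-or-equal of its LCA image, subject to
## M(parent) being ancestor-or-equal of M(child); events and losses follow
## from the mapping.
oracle_min_cost_binary <- function(gene_tree, species_tree, leaf_map,
                                   w_dup = 1.5, w_loss = 1.0) {
  dep <- gt_depths(species_tree)
  chains <- oracle_anc_chains(species_tree)
  Mlca <- oracle_lca_map(gene_tree, species_tree, leaf_map)
  internal <- intersect(gt_postorder(gene_tree), gt_internal(gene_tree))
  if (!length(internal)) return(0)
  cand <- lapply(internal, function(v) chains[[Mlca[v]]])
  grid <- as.matrix(do.call(expand.grid, cand))
  pos <- setNames(seq_along(internal), internal)
  ## ancestor-or-equal indicator
  n_sp <- gt_nnode(species_tree)
  anc <- matrix(FALSE, n_sp, n_sp)
  for (v in seq_len(n_sp)) anc[chains[[v]], v] <- TRUE
  img <- function(node, row) {
    if (as.character(node) %in% names(pos)) row[pos[[as.character(node)]]]
    else Mlca[node]
  }
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    row <- grid[r, ]
    cost <- 0
    ok <- TRUE
    for (v in internal) {
      mv <- row[pos[[as.character(v)]]]
      kids <- gene_tree$children[[v]]
      mk <- vapply(kids, img, 0L, row = row)
      if (!all(anc[mv, mk])) { ok <- FALSE; break }
      ## v is a speciation only when its children descend through two
      ## different children of M(v); otherwise it is a duplication
      branch_of <- vapply(mk, function(m) {
        ch <- chains[[m]]
        i <- match(mv, ch)
        if (i == 1L) 0L else ch[i - 1L]
      }, 0L)
      dup <- any(mk == mv) || branch_of[1L] == branch_of[2L]
      if (dup) cost <- cost + w_dup
      for (m in mk)
        cost <- cost + w_loss * max(dep[m] - dep[mv] - (!dup), 0)
      if (cost >= best) { ok <- FALSE; break }
    }
    if (ok && cost < best) best <- cost
  }
  best
}

## all rooted binary tree shapes over a set of "unit" objects, by the split
## recursion (first unit always in the left block)
oracle_binary_shapes <- function(units) {
  k <- length(units)
  if (k == 1L) return(list(units[[1L]]))
  out <- list()
  rest <- seq_len(k)[-1L]
  for (sz in 0:(k - 2L)) {
    combos <- if (sz == 0L) list(integer(0)) else
      asplit(combn(rest, sz), 2L)
    for (extra in combos) {
      left_idx <- c(1L, extra)
      right_idx <- setdiff(seq_len(k), left_idx)
      for (L in oracle_binary_shapes(units[left_idx]))
        for (R in oracle_binary_shapes(units[right_idx]))
          out <- c(out, list(list(L, R)))
    }
  }
  out
}

## all binary resolutions of a (possibly polytomous) rooted tree, as nested
## label structures
oracle_resolutions <- function(tree) {
  rec <- function(v) {
    kids <- tree$children[[v]]
    if (!length(kids)) return(list(tree$label[v]))
    kid_res <- lapply(kids, rec)
    ## cartesian product of child resolutions
    combos <- list(list())
    for (kr in kid_res) {
      combos <- unlist(lapply(combos, function(cm)
        lapply(kr, function(x) c(cm, list(x)))), recursive = FALSE)
    }
    out <- list()
    for (cm in combos) out <- c(out, oracle_binary_shapes(cm))
    out
  }
  lapply(rec(tree$root), gt_from_nested)
}

## minimum cost over all valid mappings and all binary resolutions
oracle_min_cost <- function(gene_tree, species_tree, leaf_map,
                            w_dup = 1.5, w_loss = 1.0) {
  min(vapply(oracle_resolutions(species_tree), function(res)
    oracle_min_cost_binary(gene_tree, res, leaf_map, w_dup, w_loss), 0))
}

## per-node duplication status of the LCA reconciliation on a binary
## species tree (independent of the package's classifier)
oracle_lca_dup_flags <- function(gene_tree, species_tree, leaf_map) {
  M <- oracle_lca_map(gene_tree, species_tree, leaf_map)
  vapply(seq_len(gt_nnode(gene_tree)), function(v) {
    kids <- gene_tree$children[[v]]
    length(kids) > 0L && any(M[kids] == M[v])
  }, TRUE)
}

## ---- exhaustive shape generation -------------------------------------------

## canonical string of a nested colored tree
shape_canon <- function(tr) {
  if (is.character(tr)) return(tr)
  a <- shape_canon(tr[[1L]]); b <- shape_canon(tr[[2L]])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

## all distinct rooted binary shapes with n leaves colored from `colors`,
## up to isomorphism, as nested structures (built from smaller canonical
## shapes, so generation is fast)
colored_shapes <- function(n, colors) {
  memo <- vector("list", n)
  memo[[1L]] <- as.list(colors)
  for (m in seq_len(n)[-1L]) {
    seen <- new.env(parent = emptyenv())
    acc <- list()
    for (l in seq_len(m %/% 2)) {
      r <- m - l
      for (L in memo[[l]]) for (R in memo[[r]]) {
        key <- shape_canon(list(L, R))
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          acc <- c(acc, list(list(L, R)))
        }
      }
    }
    memo[[m]] <- acc
  }
  memo[[n]]
}

## recolor a nested shape via a named map
shape_recolor <- function(tr, map) {
  if (is.character(tr)) return(unname(map[tr]))
  list(shape_recolor(tr[[1L]], map), shape_recolor(tr[[2L]], map))
}

## deduplicate shapes under a group of color permutations (list of named
## character vectors): keep one representative per orbit
dedupe_under_group <- function(shapes, group) {
  keys <- vapply(shapes, shape_canon, "")
  names(shapes) <- keys
  kept <- character(0)
  seen <- new.env(parent = emptyenv())
  for (key in keys) {
    if (!is.null(seen[[key]])) next
    orbit <- vapply(group, function(g)
      shape_canon(shape_recolor(shapes[[key]], g)), "")
    for (o in orbit) seen[[o]] <- TRUE
    kept <- c(kept, key)
  }
  shapes[kept]
}

## gene gtree + leaf map from a nested colored shape (leaves get unique
## labels "<color>_<i>")
shape_to_gene <- function(shape) {
  cnt <- new.env(parent = emptyenv())
  relab <- function(tr) {
    if (is.character(tr)) {
      k <- (cnt[[tr]] %||% 0L) + 1L
      cnt[[tr]] <- k
      return(paste0(tr, "_", k))
    }
    list(relab(tr[[1L]]), relab(tr[[2L]]))
  }
  g <- gt_from_nested(relab(shape))
  lm <- setNames(sub("_.*$", "", gt_leaf_labels(g)), gt_leaf_labels(g))
  list(tree = g, map = lm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## the species trees (with label automorphism groups) over which the
## optimality checks enumerate: every rooted tree shape with <= `max_leaves`
## leaves, polytomies included, with one canonical labelling each
species_shape_set <- function(max_leaves = 4) {
  perms <- function(x) {
    if (length(x) <= 1L) return(list(x))
    unlist(lapply(seq_along(x), function(i)
      lapply(perms(x[-i]), function(p) c(x[i], p))), recursive = FALSE)
  }
  as_group <- function(labs, perm_list) {
    lapply(perm_list, function(p) setNames(p, labs))
  }
  sets <- list(
    list(newick = "(A,B);", labs = c("A", "B"),
         group = perms(c("A", "B"))),
    list(newick = "((A,B),C);", labs = c("A", "B", "C"),
         group = list(c("A", "B", "C"), c("B", "A", "C"))),
    list(newick = "(A,B,C);", labs = c("A", "B", "C"),
         group = perms(c("A", "B", "C"))),
    list(newick = "(((A,B),C),D);", labs = c("A", "B", "C", "D"),
         group = list(c("A", "B", "C", "D"), c("B", "A", "C", "D"))),
    list(newick = "((A,B),(C,D));", labs = c("A", "B", "C", "D"),
         group = list(c("A", "B", "C", "D"), c("B", "A", "C", "D"),
                      c("A", "B", "D", "C"), c("B", "A", "D", "C"),
                      c("C", "D", "A", "B"), c("D", "C", "A", "B"),
                      c("C", "D", "B", "A"), c("D", "C", "B", "A"))),
    list(newick = "(A,(B,C,D));", labs = c("A", "B", "C", "D"),
         group = lapply(perms(c("B", "C", "D")), function(p) c("A", p))),
    list(newick = "((A,B),C,D);", labs = c("A", "B", "C", "D"),
         group = list(c("A", "B", "C", "D"), c("B", "A", "C", "D"),
                      c("A", "B", "D", "C"), c("B", "A", "D", "C"))),
    list(newick = "(A,B,C,D);", labs = c("A", "B", "C", "D"),
         group = perms(c("A", "B", "C", "D"))))
  sets <- Filter(function(s) length(s$labs) <= max_leaves, sets)
  lapply(sets, function(s) {
    s$tree <- parse_newick(s$newick, supports = "label")
    s$group <- as_group(s$labs, s$group)
    s
  })
}
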