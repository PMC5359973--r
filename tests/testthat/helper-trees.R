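## Shared fixtures built in code.

## random rooted binary tree with unique leaf labels, unit-ish lengths and
## random supports (uses ape's generator; converted to the package form)
random_gene_tree <- function(n, labels = NULL) {
  phy <- ape::rtree(n)
  if (!is.null(labels)) phy$tip.label <- labels
  phy$node.label <- NULL
  tr <- as_gtree(phy)
  for (v in setdiff(gt_internal(tr), tr$root))
    tr$support[v] <- sample(0:100, 1L)
  tr
}

## congruent one-copy-per-species gene tree for a species tree
congruent_gene_tree <- function(species_tree, copy = 1L) {
  g <- species_tree
  lv <- gt_leaves(g)
  g$label[lv] <- paste0(g$label[lv], ".copy", copy)
  g$label[gt_internal(g)] <- NA_character_
  g
}

## quick builder: newick -> (tree, species, map) with "X.n" leaf naming
recon_case <- function(gene_nwk, species_nwk) {
  g <- parse_newick(gene_nwk)
  s <- parse_newick(species_nwk, supports = "label")
  list(gene = g, species = s, map = build_leaf_map(g, s))
}

## simulation wrappers that redraw the (rare) replicates whose gene family
## outgrows the simulator's lineage cap under x10 episodes
sim_family_safe <- function(st, p, ...) {
  repeat {
    f <- tryCatch(sim_family(st, p, ...), error = function(e) NULL)
    if (!is.null(f)) return(f)
  }
}

sim_pair_safe <- function(st, p) {
  repeat {
    x <- tryCatch(sim_correlated_pair(st, p), error = function(e) NULL)
    if (!is.null(x)) return(x)
  }
}
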