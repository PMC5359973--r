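test_that("LCA mapping matches the naive ancestor-set oracle", {
  ## congruent case
  cs <- recon_case("((A.1,B.1),C.1);", "((A,B),C);")
  M <- lca_map(cs$gene, cs$species, cs$map)
  cl <- gt_clades(cs$species)
  expect_identical(sort(cl[[M[cs$gene$root]]]), c("A", "B", "C"))

  ## within-species duplication maps below the root
  cs2 <- recon_case("((A.1,A.2),B.1);", "(A,B);")
  M2 <- lca_map(cs2$gene, cs2$species, cs2$map)
  inner <- setdiff(gt_internal(cs2$gene), cs2$gene$root)
  expect_identical(gt_clades(cs2$species)[[M2[inner]]], "A")

  ## random gene trees on 5 species vs the quadratic oracle
  set.seed(21)
  sp <- sim_species_tree(5)
  for (i in 1:15) {
    labs <- paste0("s", sample(1:5, 8, replace = TRUE), ".g", 1:8)
    g <- random_gene_tree(8, labels = labs)
    lm <- build_leaf_map(g, sp)
    expect_identical(lca_map(g, sp, lm), oracle_lca_map(g, sp, lm))
  }

  expect_error(lca_map(parse_newick("(A.1,B.1,C.1);"), sp, NULL), "binary")
  u <- parse_newick("(A.1,B.1,(C.1,D.1));", rooted = FALSE)
  expect_error(lca_map(u, sp, NULL), "root")
})

test_that("event classification follows the duplication rules", {
  cs <- recon_case("((A.1,B.1),(A.2,B.2));", "(A,B);")
  r <- reconcile(cs$gene, cs$species, cs$map)
  expect_identical(unname(r$events[cs$gene$root]), "duplication")
  expect_equal(r$n_dup, 1L)
  expect_equal(sum(r$events == "speciation"), 2L)

  cs2 <- recon_case("((A.1,B.1),C.1);", "((A,B),C);")
  expect_equal(reconcile(cs2$gene, cs2$species, cs2$map)$n_dup, 0L)

  ## species polytomy: intersecting hit sets force a required duplication
  cs3 <- recon_case("(((A.1,B.1),C.1),(A.2,D.1));", "(A,B,C,D);")
  r3 <- reconcile(cs3$gene, cs3$species, cs3$map)
  expect_identical(unname(r3$events[cs3$gene$root]), "duplication")
  ## the clade spanning {A,B} vs {C} is a duplication only in some
  ## resolutions: conditional
  expect_equal(r3$n_cond, 1L)
})

test_that("losses are counted and attributed along species paths", {
  cs <- recon_case("(A.1,C.1);", "((A,B),C);")
  r <- reconcile(cs$gene, cs$species, cs$map)
  expect_equal(r$n_loss, 1L)
  expect_equal(unname(r$losses[["B"]]), 1L)

  cs2 <- recon_case("((A.1,B.1),A.2);", "(A,B);")
  r2 <- reconcile(cs2$gene, cs2$species, cs2$map)
  expect_equal(r2$n_dup, 1L)
  expect_equal(unname(r2$losses[["B"]]), 1L)
  expect_equal(r2$cost, 2.5)

  ## loss table values are non-negative and sum to the edge-formula total
  set.seed(31)
  sp <- sim_species_tree(6)
  for (i in 1:10) {
    labs <- paste0("s", sample(1:6, 7, replace = TRUE), ".g", 1:7)
    g <- random_gene_tree(7, labels = labs)
    r <- reconcile(g, sp, build_leaf_map(g, sp))
    expect_true(all(r$losses >= 0))
    expect_equal(sum(r$losses), r$n_loss)
  }
})

test_that("duplication bounds are ancestor-ordered parent/child pairs", {
  cs <- recon_case("((A.1,B.1),(A.2,B.2));", "(A,B);")
  r <- reconcile(cs$gene, cs$species, cs$map)
  expect_equal(nrow(r$dup_bounds), 1L)
  expect_true(is.na(r$dup_bounds$upper))  # duplication at the species root

  cs2 <- recon_case("((A.1,A.2),C.1);", "((A,B),C);")
  r2 <- reconcile(cs2$gene, cs2$species, cs2$map)
  expect_identical(r2$dup_bounds$lower, "A")
  ## upper is the parent of lower
  sp_lab <- r2$species_tree$label
  low_id <- match(r2$dup_bounds$lower, sp_lab)
  up_id <- match(r2$dup_bounds$upper, sp_lab)
  expect_identical(r2$species_tree$parent[low_id], up_id)

  set.seed(41)
  sp <- sim_species_tree(6)
  for (i in 1:10) {
    labs <- paste0("s", sample(1:6, 8, replace = TRUE), ".g", 1:8)
    g <- random_gene_tree(8, labels = labs)
    r <- reconcile(g, sp, build_leaf_map(g, sp))
    if (!nrow(r$dup_bounds)) next
    low <- match(r$dup_bounds$lower, r$species_tree$label)
    up <- ifelse(is.na(r$dup_bounds$upper), NA_integer_,
                 match(r$dup_bounds$upper, r$species_tree$label))
    expect_identical(r$species_tree$parent[low], up)
  }
})

test_that("congruent trees cost zero and cost ignores child order", {
  sp <- parse_newick("((A,B),(C,D));", supports = "label")
  g <- congruent_gene_tree(sp)
  expect_equal(reconcile(g, sp, build_leaf_map(g, sp))$cost, 0)

  ## zero events iff congruent one-copy-per-species
  cs <- recon_case("((A.1,B.1),A.2);", "(A,B);")
  expect_gt(reconcile(cs$gene, cs$species, cs$map)$cost, 0)

  ## permuting children of either tree leaves the cost unchanged
  set.seed(51)
  sp6 <- sim_species_tree(6)
  labs <- paste0("s", sample(1:6, 8, replace = TRUE), ".g", 1:8)
  g <- random_gene_tree(8, labels = labs)
  lm <- build_leaf_map(g, sp6)
  base <- reconcile(g, sp6, lm)$cost
  for (i in 1:5) {
    g2 <- g; sp2 <- sp6
    for (v in gt_internal(g2))
      g2$children[[v]] <- sample(g2$children[[v]])
    for (v in gt_internal(sp2))
      sp2$children[[v]] <- sample(sp2$children[[v]])
    expect_equal(reconcile(g2, sp2, lm)$cost, base)
  }
})

test_that("reconciliation cost equals the exhaustive minimum on small trees", {
  ## spot check here; the exhaustive sweep runs in the acceptance suite
  set.seed(61)
  sets <- species_shape_set(3)
  for (s in sets[!vapply(sets, function(x) gt_has_polytomy(x$tree), TRUE)]) {
    shapes <- unlist(lapply(2:4, colored_shapes, colors = s$labs),
                     recursive = FALSE)
    for (sh in shapes[sample.int(length(shapes), 25)]) {
      gm <- shape_to_gene(sh)
      r <- reconcile(gm$tree, s$tree, gm$map)
      expect_equal(r$cost, oracle_min_cost_binary(gm$tree, s$tree, gm$map))
    }
  }
})
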