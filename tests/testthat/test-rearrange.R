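test_that("branch-balance rooting minimises the subtree length difference", {
  ## symmetric quartet: root lands mid internal edge, both sides sum 2.5
  u <- parse_newick("((A:1,B:1):1,C:1,D:1);", rooted = FALSE)
  r <- root_balance(u)
  kids <- r$children[[r$root]]
  ssub <- numeric(gt_nnode(r))
  for (v in gt_postorder(r))
    ssub[v] <- sum(r$length[v], ssub[r$children[[v]]], na.rm = TRUE)
  expect_equal(sort(ssub[kids]), c(2.5, 2.5))

  ## caterpillar with one long pendant edge: compare to a brute-force scan
  ## over all edges with fine discretisation
  u2 <- parse_newick("(((A:0.4,B:0.7):0.3,C:0.5):0.2,D:6,E:0.9);",
                     rooted = FALSE)
  r2 <- root_balance(u2)
  kids2 <- r2$children[[r2$root]]
  ssub2 <- numeric(gt_nnode(r2))
  for (v in gt_postorder(r2))
    ssub2[v] <- sum(r2$length[v], ssub2[r2$children[[v]]], na.rm = TRUE)
  achieved <- abs(diff(ssub2[kids2]))
  ## scan oracle: for every edge and 1000 interior points, the balance
  ## difference of the bipartition
  tot <- sum(u2$length, na.rm = TRUE)
  clades <- gt_clades(u2)
  ssubu <- numeric(gt_nnode(u2))
  for (v in gt_postorder(u2))
    ssubu[v] <- sum(u2$length[v], ssubu[u2$children[[v]]], na.rm = TRUE)
  best_scan <- Inf
  for (v in setdiff(seq_len(gt_nnode(u2)), u2$root)) {
    L <- u2$length[v]
    for (t in seq(0, L, length.out = 1000)) {
      d <- abs((ssubu[v] - L + t) - (tot - ssubu[v] + L - t))
      best_scan <- min(best_scan, d)
    }
  }
  ## the closed-form optimum is never worse than the discretised scan, and
  ## the scan (grid resolution ~ L/1000) confirms it up to grid error
  expect_lte(achieved, best_scan + 1e-9)
  expect_lt(best_scan - achieved, 0.01)

  ## an already balanced rooted tree is unchanged by unroot + reroot
  b <- parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  expect_identical(gt_canonical(root_balance(b)), gt_canonical(b))

  expect_error(root_balance(parse_newick("(A,B,C);", rooted = FALSE)),
               "branch lengths")
})

test_that("weak-edge collapsing uses a strict cutoff at 90", {
  strong <- parse_newick("(((A,B)100,C)100,D);")
  expect_identical(gt_canonical(collapse_weak_edges(strong)),
                   gt_canonical(strong))

  weak <- parse_newick("(((A,B)89,C)95,D);")
  cw <- collapse_weak_edges(weak)
  expect_equal(max(lengths(cw$children)), 3L)
  expect_equal(sum(lengths(cw$children) > 2L), 1L)

  ## support exactly 90 is kept (the cutoff itself is not weak)
  at90 <- parse_newick("(((A,B)90,C)90,D);")
  expect_identical(gt_canonical(collapse_weak_edges(at90)),
                   gt_canonical(at90))

  ## both internal edges weak in a rooted 4-leaf tree: degree-4 root
  allweak <- parse_newick("(((A,B)10,C)20,D);")
  ca <- collapse_weak_edges(allweak)
  expect_equal(lengths(ca$children)[ca$root], 4L)

  ## missing supports are treated as weak, with a message
  nosup <- parse_newick("(((A,B),C)95,D);")
  expect_message(cn <- collapse_weak_edges(nosup), "without support")
  expect_equal(max(lengths(cn$children)), 3L)
})

test_that("minimum-cost resolution finds the congruent topology", {
  cs <- recon_case("((A.1:1,C.1:1)50:1,B.1:1);", "((A,B),C);")
  expect_equal(reconcile(cs$gene, cs$species, cs$map)$cost, 4.5)
  rearranged <- rearrange_tree(cs$gene, cs$species, cs$map)
  expect_equal(attr(rearranged, "cost_after"), 0)
  expect_true(attr(rearranged, "improved"))
  ## the optimal resolution pairs A with B, congruently with the species tree
  expect_match(gt_canonical(rearranged), "(A.1,B.1)", fixed = TRUE)

  ## no weak edges: output identical to input
  strong <- parse_newick("((A.1:1,C.1:1)99:1,B.1:1);")
  kept <- rearrange_tree(strong, cs$species,
                         build_leaf_map(strong, cs$species))
  expect_identical(gt_canonical(kept), gt_canonical(strong))
})

test_that("exact resolution matches enumeration over all local topologies", {
  ## a degree-5 polytomy: compare against reconciling every resolution
  set.seed(71)
  sp <- sim_species_tree(5)
  labs <- paste0("s", c(1, 2, 3, 4, 5), ".g", 1:5)
  star <- gt_from_nested(as.list(labs))
  lm <- build_leaf_map(star, sp)
  res <- resolve_min_cost(star, sp, lm)
  expect_true(gt_is_binary(res))
  best <- min(vapply(oracle_binary_shapes(as.list(labs)), function(sh)
    reconcile(gt_from_nested(sh), sp, lm)$cost, 0))
  expect_equal(reconcile(res, sp, lm)$cost, best)
})

test_that("rearrangement never hurts and preserves strong clades", {
  set.seed(81)
  st <- sim_species_tree(15)
  p <- sim_params(episode_fraction = 0, rho = 1)
  n_checked <- 0
  while (n_checked < 20) {
    f <- sim_family(st, p)
    if (f$extinct || length(gt_leaves(f$gene_tree)) < 5) next
    g <- add_noise(f$gene_tree, 0.15)
    lm <- build_leaf_map(g, st)
    rt <- suppressMessages(rearrange_tree(g, st, lm))
    expect_lte(attr(rt, "cost_after"), attr(rt, "cost_before"))
    ## clades above the cutoff survive verbatim
    cl_in <- gt_clades(g)
    strong <- which(!is.na(g$support) & g$support >= 90)
    cl_out <- lapply(gt_clades(rt), paste, collapse = "|")
    for (v in strong)
      expect_true(paste(cl_in[[v]], collapse = "|") %in% cl_out)
    n_checked <- n_checked + 1
  }
})

test_that("random species-tree resolution is binary and seeded", {
  poly <- parse_newick("((A,B,C),(D,E),F);", supports = "label")
  r1 <- random_resolve(poly, seed = 3)
  r2 <- random_resolve(poly, seed = 3)
  expect_true(gt_is_binary(r1))
  expect_identical(gt_canonical(r1), gt_canonical(r2))
  expect_setequal(gt_leaf_labels(r1), gt_leaf_labels(poly))
})
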