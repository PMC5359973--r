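test_that("LG pairwise distances behave like a distance", {
  a <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(ml_pairwise_distance(a, a), 0)
  b <- "ACDEFGHIKLMNPQRSTVWF"
  d1 <- ml_pairwise_distance(a, b)
  expect_gt(d1, 0)
  expect_equal(d1, ml_pairwise_distance(b, a))  # time-reversibility
  ## gap columns are skipped; all-gap overlap is undefined
  expect_equal(ml_pairwise_distance("AC-E", "AC-E"), 0)
  expect_warning(d <- ml_pairwise_distance("AA--", "--AA"), "undefined")
  expect_identical(d, Inf)
})

test_that("LG distance recovers the simulating divergence", {
  ## simulate a pair at t = 0.5 under the model's own transition matrix
  set.seed(91)
  n <- 10000L
  d <- dupcoev:::lg_decomposition()
  P <- dupcoev:::lg_prob_matrix(0.5)
  x <- sample.int(20L, n, replace = TRUE, prob = d$pi)
  y <- vapply(x, function(i) sample.int(20L, 1L, prob = P[i, ]), 0L)
  alpha <- dupcoev:::.lg_alphabet
  est <- ml_pairwise_distance(alpha[x], alpha[y])
  expect_lt(abs(est - 0.5), 0.05)
})

test_that("LG distances agree with an independent implementation", {
  set.seed(92)
  alpha <- dupcoev:::.lg_alphabet
  seqs <- c(s1 = paste(sample(alpha, 300, replace = TRUE), collapse = ""),
            s2 = NA, s3 = NA)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(seq_along(v), k)
    v[at] <- sample(alpha, k, replace = TRUE)
    paste(v, collapse = "")
  }
  seqs["s2"] <- mut(seqs["s1"], 60)
  seqs["s3"] <- mut(seqs["s1"], 150)
  D <- ml_distance_matrix(seqs)
  library(phangorn)
  pd <- as.phyDat(t(sapply(strsplit(seqs, ""), identity)),
                  type = "AA")
  Dref <- as.matrix(dist.ml(pd, model = "LG"))
  expect_equal(D[upper.tri(D)], Dref[rownames(D), rownames(D)][upper.tri(D)],
               tolerance = 0.01)
})

test_that("subset selection applies the two quoted steps deterministically", {
  ids <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["A", "B"] <- D["B", "A"] <- 0.1   # unique closest pair
  D["A", "C"] <- D["C", "A"] <- 0.5
  D["A", "D"] <- D["D", "A"] <- 0.6   # totals: A = 1.2, B = 0.8
  D["B", "C"] <- D["C", "B"] <- 0.3
  D["B", "D"] <- D["D", "B"] <- 0.4
  D["C", "D"] <- D["D", "C"] <- 0.9
  expect_setequal(subset_select(D, 3), c("B", "C", "D"))  # A removed first

  ## two identical sequences: one of them goes first
  D2 <- D; D2["C", "D"] <- D2["D", "C"] <- 0
  expect_true(length(setdiff(c("C", "D"), subset_select(D2, 3))) == 1L)

  ## k = |ids| is the identity; k <= 0 errors
  expect_identical(subset_select(D, 4), ids)
  expect_error(subset_select(D, 0), "positive")

  ## order-independence of the retained set
  perm <- c(3, 1, 4, 2)
  Dp <- D[perm, perm]
  expect_setequal(subset_select(Dp, 2), subset_select(D, 2))
  expect_length(subset_select(D, 2), 2L)
})

test_that("column filtering applies gap and conservation thresholds", {
  ## 10 sequences; column 1: 3 gaps (70% non-gap, excluded); column 2:
  ## identical residues (kept); column 3: maximally diverse (low score)
  col1 <- c(rep("-", 3), rep("A", 7))
  col2 <- rep("W", 10)
  col3 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  m <- cbind(col1, col2, col3)
  rownames(m) <- paste0("s", 1:10)
  kept <- filter_columns(m)
  expect_false(1L %in% kept)
  expect_true(2L %in% kept)

  ## two identical gapless sequences: every column kept
  two <- rbind(a = strsplit("WCKDY", "")[[1]],
               b = strsplit("WCKDY", "")[[1]])
  expect_identical(filter_columns(two), 1:5)

  ## monotone in the gap threshold
  k80 <- filter_columns(m, nongap_min = 0.80)
  k60 <- filter_columns(m, nongap_min = 0.60)
  expect_true(all(k80 %in% k60))

  ## pluggable score function
  expect_identical(filter_columns(m, score_fun = function(res) 1),
                   2:3)
})

test_that("hit filtering combines score threshold and motif/triad rules", {
  hits <- data.frame(
    id = paste0("h", 1:10),
    score = c(95, 88, 80, 72, 40, 35, 30, 22, 15, 8),
    length = c(120, 118, 110, 105, 60, 55, 50, 45, 40, 30),
    matched_subsequence = c("MLDHHCWL", "MADHHCYK", "MLDHHCAA", "GADHHCLL",
                            "MLDHYCWL", "MADHHCYK", "AAAAAA", "GADHHCLL",
                            "MLDHHCAA", "DHHC"),
    stringsAsFactors = FALSE)
  ## threshold between the 4th and 5th sorted score keeps exactly 4
  kept <- filter_hits(hits, score_min = 56, motif = "DHHC")
  expect_equal(nrow(kept), 4L)
  ## motif absent removes a high-scoring hit
  expect_false("h5" %in% filter_hits(hits, score_min = 30,
                                     motif = "DHHC")$id)
  ## catalytic-triad style column constraints
  hits$match_columns <- c("1,2,3,4,5,6,7,8", "1,2,3,4,5,6,7,8",
                          "1,2,3,4,5,6,7,8", "1,2,3,4,5,6,7,8",
                          "1,2,3,4,5,6,7,8", "1,2,3,4,5,6,7,8",
                          "1,2,3,4,5,6", "1,2,3,4,5,6,7,8",
                          "2,3,4,5,6,7,8,9", "3,4,5,6")
  tri <- filter_hits(hits, score_min = 0,
                     column_constraints = list(list(column = 5,
                                                    allowed = c("H"))))
  expect_true(all(c("h1", "h9", "h10") %in% tri$id))  # H at profile column 5
  ## residue mismatch at the constrained column fails
  expect_false("h7" %in% tri$id)
  hits2 <- hits; hits2$match_columns <- NULL
  expect_error(filter_hits(hits2, 0,
                           column_constraints = list(list(column = 1,
                                                          allowed = "M"))),
               "match_columns")
  ## helper summarises scores by length decile
  sm <- hit_score_by_length(hits)
  expect_true(all(c("n", "median") %in% names(sm)))
  expect_equal(sum(sm$n), nrow(hits))
})

test_that("FASTA alignments round-trip into the filter functions", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKW-A", ">b", "MKWCA", ">c", "MKWCA"), fa)
  m <- read_alignment(fa)
  expect_equal(dim(m), c(3L, 5L))
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_true(all(c(1L, 2L, 3L, 5L) %in% filter_columns(m, nongap_min = 0.6)))
})
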