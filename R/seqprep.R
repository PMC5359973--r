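#' Read a protein multiple-sequence alignment from FASTA
#'
#' @param path FASTA file of aligned amino-acid sequences (gaps as `-`).
#' @return A character matrix, one row per sequence (rownames are the
#'   sequence ids), one column per alignment column.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  as_alignment_matrix(stats::setNames(as.character(aln), names(aln)))
}

## named character vector of aligned sequences -> character matrix
as_alignment_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("aligned sequences must have equal length")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequence ids must be unique")
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(m) <- ids
  m
}

## ---- pairwise ML distance under LG ------------------------------------------

#' Maximum-likelihood pairwise distance under the LG model
#'
#' Estimates the evolutionary distance t (expected substitutions per site)
#' between two aligned amino-acid sequences by maximising the likelihood
#' `sum over sites of log(pi_x * P(x -> y | t))` under the LG substitution
#' model (published exchangeabilities and frequencies; rate matrix
#' normalised to one expected substitution per site). Columns where either
#' sequence has a gap or a non-standard residue are skipped.
#'
#' @param a,b Aligned sequences (character strings or character vectors of
#'   residues) of equal length.
#' @param max_dist Upper cap on the estimate (default 10 substitutions/site).
#' @param tol Optimiser tolerance (default 1e-6).
#' @return The distance estimate, 0 for identical sequences; `Inf` (with a
#'   warning) when no overlapping non-gap columns exist.
#' @export
ml_pairwise_distance <- function(a, b, max_dist = 10, tol = 1e-6) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% .lg_alphabet & b %in% .lg_alphabet
  if (!any(ok)) {
    warning("no overlapping non-gap columns; distance is undefined (Inf)")
    return(Inf)
  }
  ia <- match(a[ok], .lg_alphabet)
  ib <- match(b[ok], .lg_alphabet)
  N <- matrix(0, 20L, 20L)
  for (i in seq_along(ia)) N[ia[i], ib[i]] <- N[ia[i], ib[i]] + 1
  if (sum(N) == sum(diag(N))) return(0)
  d <- lg_decomposition()
  nll <- function(t) {
    P <- d$U %*% (exp(d$values * t) * d$Uinv)
    P[P < 1e-300] <- 1e-300
    -sum(N * log(d$pi * P))
  }
  opt <- stats::optimize(nll, interval = c(1e-8, max_dist), tol = tol)
  min(opt$minimum, max_dist)
}

#' All pairwise ML distances of an alignment
#'
#' @param aln A character matrix from [read_alignment()], or a named
#'   character vector of aligned sequences.
#' @inheritParams ml_pairwise_distance
#' @return A symmetric distance matrix with zero diagonal.
#' @export
ml_distance_matrix <- function(aln, max_dist = 10, tol = 1e-6) {
  m <- as_alignment_matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- ml_pairwise_distance(m[i, ], m[j, ],
                                                 max_dist = max_dist,
                                                 tol = tol)
    }
  }
  D
}

## ---- distance-based subset selection ----------------------------------------

#' Reduce a sequence set to k representatives by iterated removal
#'
#' Repeats two steps until k sequences remain: the two sequences with the
#' smallest pairwise distance are identified, and of these two, the one with
#' the largest total distance to all other (currently retained) sequences is
#' removed. Ties are broken deterministically: the lexicographically
#' smallest id pair is chosen, and on a total-distance tie the
#' lexicographically larger id is removed.
#'
#' @param D Symmetric distance matrix with id dimnames.
#' @param k Number of sequences to retain (1 <= k <= nrow(D)).
#' @return Character vector of the k retained ids (in the input order of D).
#' @export
subset_select <- function(D, k) {
  ids <- rownames(D)
  if (is.null(ids)) stop("D must have id dimnames")
  if (k <= 0) stop("k must be positive")
  if (k > length(ids)) stop("k exceeds the number of sequences")
  keep <- ids
  while (length(keep) > k) {
    d <- D[keep, keep, drop = FALSE]
    diag(d) <- Inf
    mn <- min(d)
    hit <- which(d == mn, arr.ind = TRUE)
    pairs <- cbind(pmin(keep[hit[, 1L]], keep[hit[, 2L]]),
                   pmax(keep[hit[, 1L]], keep[hit[, 2L]]))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1L], pairs[, 2L])
    p <- pairs[ord[1L], ]
    diag(d) <- 0
    tot <- rowSums(d)[p]
    drop_id <- if (tot[1L] > tot[2L]) p[1L] else if (tot[2L] > tot[1L]) p[2L]
    else max(p)
    keep <- setdiff(keep, drop_id)
  }
  ids[ids %in% keep]
}

## ---- alignment column filtering ---------------------------------------------

## BLOSUM62-derived pairwise similarity rescaled to [0, 1], over the 20
## standard residues
.blosum_sim <- function() {
  if (!is.null(.lg_cache$bsim)) return(.lg_cache$bsim)
  B <- .get_blosum62()[.lg_alphabet, .lg_alphabet]
  sim <- (B - min(B)) / (max(B) - min(B))
  .lg_cache$bsim <- sim
  sim
}

.get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Select alignment columns by gap fraction and conservation
#'
#' A column is kept when its non-gap fraction is at least `nongap_min`
#' (default 0.80) and its conservation score is at least `conservation_min`
#' (default 5e-6). The default conservation score is the mean, over all
#' unordered pairs of non-gap residues in the column, of a BLOSUM62-derived
#' similarity rescaled to [0, 1] (so a column of identical tryptophans
#' scores 1 and the score has a near-zero floor); columns with fewer than
#' two non-gap residues score 0. The score function is pluggable via
#' `score_fun(column_residues)`.
#'
#' @param aln Alignment (character matrix or named character vector).
#' @param nongap_min Minimum non-gap fraction in [0, 1].
#' @param conservation_min Minimum conservation score.
#' @param score_fun Optional replacement conservation score function.
#' @return Sorted integer vector of kept column indices (1-based).
#' @export
filter_columns <- function(aln, nongap_min = 0.80, conservation_min = 5e-6,
                           score_fun = NULL) {
  stopifnot(nongap_min >= 0, nongap_min <= 1)
  m <- as_alignment_matrix(aln)
  if (is.null(score_fun)) {
    sim <- .blosum_sim()
    score_fun <- function(res) {
      res <- res[res %in% .lg_alphabet]
      n <- length(res)
      if (n < 2L) return(0)
      idx <- match(res, .lg_alphabet)
      s <- sim[idx, idx, drop = FALSE]
      (sum(s) - sum(diag(s))) / (n * (n - 1))
    }
  }
  keep <- logical(ncol(m))
  for (cc in seq_len(ncol(m))) {
    col <- m[, cc]
    nongap <- mean(col != "-")
    keep[cc] <- nongap >= nongap_min && score_fun(col) >= conservation_min
  }
  which(keep)
}

## ---- homology-hit filtering -------------------------------------------------

#' Filter domain hits by score and required sequence features
#'
#' Keeps a hit when its score reaches `score_min` and its matched
#' subsequence contains the required motif (a regular expression, e.g. a
#' DHHC-style motif) and/or satisfies per-column residue constraints (e.g. a
#' catalytic triad at fixed profile match columns). The score threshold is
#' supplied by the user; [hit_score_by_length()] summarises the length-score
#' distribution to support choosing it.
#'
#' @param hits Data frame with columns `id`, `score`, `length`,
#'   `matched_subsequence`, and, when column constraints are used,
#'   `match_columns` (comma-separated profile column of each residue of the
#'   matched subsequence).
#' @param score_min Minimum score.
#' @param motif Optional regular expression the matched subsequence must
#'   contain.
#' @param column_constraints Optional list of `list(column =, allowed =)`
#'   entries: the residue at that profile match column must be one of
#'   `allowed`; hits not covering the column fail.
#' @return The kept rows of `hits`.
#' @export
filter_hits <- function(hits, score_min, motif = NULL,
                        column_constraints = NULL) {
  stopifnot(is.data.frame(hits))
  keep <- hits$score >= score_min
  if (!is.null(motif))
    keep <- keep & grepl(motif, hits$matched_subsequence)
  if (!is.null(column_constraints)) {
    if (is.null(hits$match_columns))
      stop("column constraints require a match_columns column in hits")
    cols <- lapply(strsplit(as.character(hits$match_columns), ","),
                   as.integer)
    res <- strsplit(toupper(hits$matched_subsequence), "")
    for (ct in column_constraints) {
      ok <- mapply(function(cl, rs) {
        at <- match(ct$column, cl)
        !is.na(at) && rs[at] %in% toupper(ct$allowed)
      }, cols, res)
      keep <- keep & ok
    }
  }
  hits[keep & !is.na(keep), , drop = FALSE]
}

#' Summarise hit scores by length decile
#'
#' Helper for choosing a score threshold from the length-score distribution.
#'
#' @param hits Data frame with `score` and `length` columns.
#' @return Data frame with one row per length decile: n, length range and
#'   score quartiles.
#' @export
hit_score_by_length <- function(hits) {
  br <- unique(stats::quantile(hits$length, probs = seq(0, 1, 0.1)))
  dec <- cut(hits$length, breaks = br, include.lowest = TRUE)
  do.call(rbind, lapply(split(hits, dec), function(h) {
    data.frame(decile = as.character(dec[match(h$length[1], hits$length)]),
               n = nrow(h),
               min_length = min(h$length), max_length = max(h$length),
               q25 = unname(stats::quantile(h$score, 0.25)),
               median = stats::median(h$score),
               q75 = unname(stats::quantile(h$score, 0.75)),
               stringsAsFactors = FALSE)
  }))
}
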