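#' Wilcoxon rank-sum test for two independent samples
#'
#' Uses midranks for ties. The two-sided p-value is exact (full enumeration
#' of rank assignments) when `n1 + n2 <= exact_max` and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. When every value in both groups is identical the
#' p-value is 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest combined sample size for the exact enumeration
#'   (default 12).
#' @return A list with `statistic` (rank sum of `x`), `p.value` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all_v <- c(x, y)
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])
  if (length(unique(all_v)) == 1L)
    return(list(statistic = W, p.value = 1, method = "degenerate"))
  ties <- anyDuplicated(all_v) > 0L
  if (N <= exact_max && !ties && choose(N, n1) <= 2e6) {
    sums <- utils::combn(N, n1, FUN = function(i) sum(r[i]))
    p_lo <- mean(sums <= W + 1e-9)
    p_hi <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = W, p.value = p, method = "exact"))
  }
  mu <- n1 * (N + 1) / 2
  tt <- table(all_v)
  tie_term <- sum(tt^3 - tt) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)
    return(list(statistic = W, p.value = 1, method = "degenerate"))
  dev <- W - mu
  z <- (dev - 0.5 * sign(dev)) / sqrt(sigma2)
  if (dev == 0) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p.value = p, method = "normal")
}

#' Fisher's exact test for r x c contingency tables
#'
#' For 2 x 2 tables the two-sided p-value is the exact hypergeometric sum of
#' the probabilities of all tables (with the observed margins) no more
#' probable than the observed one. Larger tables use the Freeman-Halton
#' extension: full enumeration of tables with the observed margins when the
#' grand total is at most `enum_max`, otherwise Monte-Carlo sampling of at
#' least `nsim` tables (via [stats::r2dtable()]) with the standard error of
#' the estimate reported.
#'
#' @param tab Matrix of non-negative integer counts; no margin may be empty.
#' @param enum_max Largest grand total for full enumeration of r x c tables
#'   (default 60).
#' @param nsim Number of Monte-Carlo tables (default 1e5).
#' @return A list with `p.value`, `method` (`"hypergeometric"`,
#'   `"enumeration"` or `"monte-carlo"`) and `se` (`NA` unless Monte-Carlo).
#' @export
fisher_exact <- function(tab, enum_max = 60, nsim = 1e5) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("empty row or column margin")
  n <- sum(tab)
  eps <- 1 + 1e-7
  if (all(dim(tab) == c(2L, 2L))) {
    ## hypergeometric over the (1,1) cell
    k_range <- max(0L, rs[1L] - cs[2L]):min(rs[1L], cs[1L])
    dens <- stats::dhyper(k_range, cs[1L], cs[2L], rs[1L])
    p_obs <- stats::dhyper(tab[1L, 1L], cs[1L], cs[2L], rs[1L])
    return(list(p.value = min(1, sum(dens[dens <= p_obs * eps])),
                method = "hypergeometric", se = NA_real_))
  }
  logp <- function(m) {
    sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
      lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  }
  lp_obs <- logp(tab)
  if (n <= enum_max) {
    acc <- 0
    nr <- nrow(tab); nc <- ncol(tab)
    ## enumerate tables with the observed margins, row by row, cell by cell
    fillrow <- function(m, ri) {
      if (ri == nr) {
        last <- cs - colSums(m)
        if (any(last < 0)) return()
        lp <- logp(rbind(m, last))
        if (lp <= lp_obs + log(eps)) acc <<- acc + exp(lp)
        return()
      }
      used <- colSums(m)
      fill <- function(row, ci, left) {
        if (ci == nc) {
          if (left > cs[ci] - used[ci]) return()
          fillrow(rbind(m, c(row, left)), ri + 1L)
          return()
        }
        for (v in 0:min(left, cs[ci] - used[ci]))
          fill(c(row, v), ci + 1L, left - v)
      }
      fill(integer(0), 1L, rs[ri])
    }
    fillrow(matrix(0L, 0L, nc), 1L)
    return(list(p.value = min(1, acc), method = "enumeration",
                se = NA_real_))
  }
  sims <- stats::r2dtable(nsim, rs, cs)
  hit <- vapply(sims, function(m) logp(m) <= lp_obs + log(eps), TRUE)
  p <- (sum(hit) + 1) / (nsim + 1)
  list(p.value = p, method = "monte-carlo",
       se = sqrt(p * (1 - p) / nsim))
}
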