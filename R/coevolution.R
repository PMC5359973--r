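#' Tabulate duplication and loss events per species-tree branch
#'
#' Sums, over all reconciliations of one family, the duplications (attributed
#' to the incoming branch of their lower-bound node) and losses (attributed
#' to the incoming branch of their loss-table node). Conditional duplications
#' are excluded. The species root, which has no incoming branch, keeps a row
#' (flagged) so that events mapped to it are not silently dropped.
#'
#' @param recs A single [reconcile()] result or a list of them (all against
#'   the same species tree).
#' @param species_tree The common species tree; defaults to the one stored in
#'   the first reconciliation.
#' @param family Family identifier stored with the table.
#' @return A data frame of class `branch_events` with one row per species
#'   node: `node`, `is_internal`, `is_root`, `dup`, `loss`,
#'   `net` (= dup - loss).
#' @export
branch_events <- function(recs, species_tree = NULL, family = "family") {
  if (inherits(recs, "reconciliation")) recs <- list(recs)
  stopifnot(length(recs) >= 1L)
  if (is.null(species_tree)) species_tree <- recs[[1L]]$species_tree
  species_tree <- label_internal_nodes(species_tree)
  key <- gt_canonical(species_tree)
  labs <- species_tree$label
  dup <- loss <- stats::setNames(integer(length(labs)), labs)
  for (r in recs) {
    if (!inherits(r, "reconciliation")) stop("expected reconciliation objects")
    if (gt_canonical(r$species_tree) != key)
      stop("reconciliations were made against a different species tree")
    for (lo in r$dup_bounds$lower) dup[lo] <- dup[lo] + 1L
    loss[names(r$losses)] <- loss[names(r$losses)] + as.integer(r$losses)
  }
  is_leaf <- seq_along(labs) %in% gt_leaves(species_tree)
  out <- data.frame(node = labs,
                    is_internal = !is_leaf,
                    is_root = seq_along(labs) == species_tree$root,
                    dup = as.integer(dup), loss = as.integer(loss),
                    net = as.integer(dup) - as.integer(loss),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "family") <- family
  attr(out, "species_key") <- key
  class(out) <- c("branch_events", "data.frame")
  out
}

#' Categorise branches as gain, loss or no change
#'
#' @param net Integer vector of net gains (duplications minus losses).
#' @return Factor with levels `gain`, `loss`, `no_change`.
#' @export
branch_category <- function(net) {
  factor(ifelse(net > 0, "gain", ifelse(net < 0, "loss", "no_change")),
         levels = c("gain", "loss", "no_change"))
}

#' Pearson correlation of copy numbers between two families
#'
#' @param tbl Data frame or matrix of extant gene counts, species in rows,
#'   families in columns.
#' @param famA,famB Column names (or indices) of the two families.
#' @return Pearson r, or `NA` (with a warning) when a family has zero
#'   variance.
#' @export
copy_number_correlation <- function(tbl, famA = 1L, famB = 2L) {
  x <- as.numeric(tbl[[famA]] %||% tbl[, famA])
  y <- as.numeric(tbl[[famB]] %||% tbl[, famB])
  if (length(x) < 3L) stop("need at least 3 species")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in copy numbers; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

`%||%` <- function(a, b) tryCatch(if (is.null(a)) b else a,
                                  error = function(e) b)

#' Test for correlated evolution of two gene families
#'
#' Partitions the internal species-tree branches by the second family's
#' category (gain, loss, no change in net copy number) and compares the
#' first family's net gains between the categories: the headline comparison
#' is gain-group versus loss-group by the Wilcoxon rank-sum test, with all
#' pairwise comparisons reported as secondary; the gain/loss/no-change
#' category co-occurrence of the two families is additionally tested with
#' Fisher's exact test (Freeman-Halton for the 3 x 3 table). Terminal
#' branches and the root are excluded from testing. Branches where family A
#' shows fewer than `min_events` duplications and fewer than `min_events`
#' losses can be filtered out (default 0: no filter).
#'
#' @param tableA,tableB [branch_events()] tables over the same species tree.
#' @param min_events Optional per-branch activity filter on family A.
#' @param exact_max,enum_max,nsim Passed to the statistical kernels.
#' @return An object of class `coevolution_test`: group sizes and medians,
#'   the Wilcoxon comparisons, the category contingency table and its
#'   Fisher p-value, and notes about skipped comparisons.
#' @export
coevolution_test <- function(tableA, tableB, min_events = 0,
                             exact_max = 12, enum_max = 60, nsim = 1e5) {
  if (!identical(attr(tableA, "species_key"), attr(tableB, "species_key")) ||
      !identical(tableA$node, tableB$node))
    stop("branch event tables refer to different species trees")
  use <- tableA$is_internal & !tableA$is_root
  if (min_events > 0)
    use <- use & (tableA$dup >= min_events | tableA$loss >= min_events)
  netA <- tableA$net[use]
  catA <- branch_category(netA)
  catB <- branch_category(tableB$net[use])
  groups <- split(netA, catB)
  sizes <- vapply(groups, length, 0L)
  medians <- vapply(groups, function(g) if (length(g)) stats::median(g)
                    else NA_real_, 0)
  notes <- character(0)
  pair_names <- c("gain_vs_loss", "gain_vs_no_change", "loss_vs_no_change")
  pairs <- list(c("gain", "loss"), c("gain", "no_change"),
                c("loss", "no_change"))
  wil <- stats::setNames(vector("list", 3L), pair_names)
  for (i in seq_along(pairs)) {
    g1 <- groups[[pairs[[i]][1L]]]; g2 <- groups[[pairs[[i]][2L]]]
    if (!length(g1) || !length(g2)) {
      notes <- c(notes, paste0(pair_names[i], ": skipped (empty group)"))
      wil[pair_names[i]] <- list(NULL)
    } else {
      wil[[pair_names[i]]] <- wilcoxon_rank_sum(g1, g2, exact_max = exact_max)
    }
  }
  ctab <- table(famA = catA, famB = catB)
  fis <- NULL
  keep_r <- rowSums(ctab) > 0; keep_c <- colSums(ctab) > 0
  if (sum(keep_r) >= 2L && sum(keep_c) >= 2L) {
    fis <- fisher_exact(ctab[keep_r, keep_c, drop = FALSE],
                        enum_max = enum_max, nsim = nsim)
  } else {
    notes <- c(notes, "fisher: skipped (fewer than 2 non-empty categories)")
  }
  structure(list(
    n_branches = sum(use), group_sizes = sizes, group_medians = medians,
    wilcoxon = wil, headline = wil[["gain_vs_loss"]],
    contingency = ctab, fisher = fis,
    min_events = min_events, notes = notes,
    familyA = attr(tableA, "family"), familyB = attr(tableB, "family")
  ), class = "coevolution_test")
}

#' @export
print.coevolution_test <- function(x, ...) {
  cat(sprintf("Coevolution test: %s vs %s (%d internal branches)\n",
              x$familyA, x$familyB, x$n_branches))
  cat("  branches by", x$familyB, "category:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = "  "), "\n")
  cat("  median net gain of", x$familyA, "per category:",
      paste(sprintf("%s=%g", names(x$group_medians), x$group_medians),
            collapse = "  "), "\n")
  if (!is.null(x$headline))
    cat(sprintf("  Wilcoxon gain vs loss: W = %g, p = %.4g (%s)\n",
                x$headline$statistic, x$headline$p.value, x$headline$method))
  for (nm in setdiff(names(x$wilcoxon), "gain_vs_loss")) {
    w <- x$wilcoxon[[nm]]
    if (!is.null(w))
      cat(sprintf("  Wilcoxon %s: p = %.4g\n", nm, w$p.value))
  }
  if (!is.null(x$fisher))
    cat(sprintf("  Fisher exact (category co-occurrence): p = %.4g (%s)\n",
                x$fisher$p.value, x$fisher$method))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
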