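#' Define a two-group comparison
#'
#' Selects two disjoint sample groups from a sample-sheet column. Each
#' group must contain at least two samples.
#'
#' @param samples A `SampleSheet` (or the `samples` element of a dataset).
#' @param column Name of the grouping column.
#' @param groups Optional character vector of the two labels to compare
#'   (`c(group0, group1)`); defaults to the first two levels in sort order.
#' @return An object of class `GroupComparison` with the group labels and
#'   per-group sample index sets.
#' @export
group_comparison <- function(samples, column, groups = NULL) {
  if (inherits(samples, "MethylationDataset")) samples <- samples$samples
  if (!column %in% names(samples))
    stop_mw("no column '", column, "' in sample sheet")
  lab <- as.character(samples[[column]])
  if (is.null(groups)) {
    groups <- sort(unique(stats::na.omit(lab)))
    if (length(groups) != 2L)
      stop_mw("column '", column, "' has ", length(groups),
              " levels; give 'groups' explicitly")
  }
  if (length(groups) != 2L) stop_mw("exactly two group labels required")
  idx0 <- which(lab == groups[1L])
  idx1 <- which(lab == groups[2L])
  if (length(idx0) < 2L || length(idx1) < 2L)
    stop_mw("each group needs at least 2 samples (got ", length(idx0),
            " and ", length(idx1), ")")
  structure(list(column = column, group0 = groups[1L], group1 = groups[2L],
                 idx0 = idx0, idx1 = idx1),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("GroupComparison on '", x$column, "': ", x$group0, " (n=",
      length(x$idx0), ") vs ", x$group1, " (n=", length(x$idx1), ")\n",
      sep = "")
  invisible(x)
}

# Estimate the empirical-Bayes variance prior (d0, s0^2) by moment matching
# on log sample variances: if s^2 ~ s0^2 * F(df, d0), then
#   E[log s^2]  = log s0^2 + digamma(df/2) - digamma(d0/2)
#                 - log(df/2) + log(d0/2)
#   Var[log s^2] = trigamma(df/2) + trigamma(d0/2),
# so d0 solves trigamma(d0/2) = var(log s^2) - trigamma(df/2) (Newton on
# the trigamma inverse) and s0^2 follows from the mean equation. A
# non-positive trigamma target yields d0 = Inf (all unit variances equal).
fit_variance_prior <- function(s2, df) {
  z <- log(s2[is.finite(log(s2))])
  if (length(z) < 2L) return(list(d0 = 0, s02 = mean(s2)))
  e <- mean(z)
  v <- stats::var(z)
  target <- v - trigamma(df / 2)
  if (!is.finite(target) || target <= 1e-8) {
    d0 <- Inf
    s02 <- exp(e - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s02 <- exp(e - digamma(df / 2) + digamma(d0 / 2) +
                 log(df / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Newton iteration for y = trigamma(x); trigamma is convex decreasing, so
# iterate on x <- x + (trigamma(x) - y) / -trigamma'(x) using the identity
# trigamma'(x) = psigamma(x, 2).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (it in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated two-sample t-test per unit
#'
#' Computes a two-sample (equal-variance) t-statistic for every row of
#' `values` between the two groups of `comparison`. With `prior = TRUE`
#' (the empirical-Bayes framework), per-unit variances are shrunk toward a
#' common prior: `s2_post = (d0 * s02 + dg * s2_g) / (d0 + dg)` with
#' `(d0, s02)` estimated across units by moment matching on log variances,
#' and the statistic is referred to a t distribution with `d0 + dg` degrees
#' of freedom. With `prior = FALSE` (`d0 = 0`) this reduces exactly to the
#' classical Student t-test.
#'
#' @param values Numeric unit x sample matrix.
#' @param comparison A [group_comparison()].
#' @param prior Apply empirical-Bayes variance shrinkage (default `TRUE`).
#' @param missing `"drop"` removes units with any missing value in the
#'   compared samples (count reported in the `"n_dropped"` attribute);
#'   `"error"` refuses them.
#' @param eps Pseudo-count used inside log-quotients (default 0.01).
#' @return A `data.frame` (one row per retained unit) with columns `unit`,
#'   `mean0`, `mean1`, `diff` (= mean1 - mean0), `log_quotient`
#'   (= log2((mean1+eps)/(mean0+eps))), `var0`, `var1`, `var_diff`,
#'   `var_log_ratio`, `statistic`, `p`. Attributes: `d0`, `s02`,
#'   `n_dropped`.
#' @export
moderated_t_table <- function(values, comparison, prior = TRUE,
                              missing = c("drop", "error"), eps = 0.01) {
  missing <- match.arg(missing)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("unit", seq_len(nrow(values)))
  x0 <- values[, comparison$idx0, drop = FALSE]
  x1 <- values[, comparison$idx1, drop = FALSE]
  has_na <- rowSums(is.na(x0)) + rowSums(is.na(x1)) > 0L
  if (any(has_na)) {
    if (missing == "error")
      stop_mw(sum(has_na), " unit(s) have missing values; impute first ",
              "or use missing = 'drop'")
    x0 <- x0[!has_na, , drop = FALSE]
    x1 <- x1[!has_na, , drop = FALSE]
  }
  n0 <- ncol(x0)
  n1 <- ncol(x1)
  dg <- n0 + n1 - 2
  mean0 <- rowMeans(x0)
  mean1 <- rowMeans(x1)
  v0 <- row_vars(x0)
  v1 <- row_vars(x1)
  s2g <- ((n0 - 1) * v0 + (n1 - 1) * v1) / dg
  if (prior) {
    pr <- fit_variance_prior(s2g, dg)
    d0 <- pr$d0
    s2post <- if (is.infinite(d0)) rep(pr$s02, length(s2g)) else
      (d0 * pr$s02 + dg * s2g) / (d0 + dg)
    dftot <- min(d0 + dg, .Machine$double.xmax)
  } else {
    d0 <- 0
    pr <- list(d0 = 0, s02 = NA_real_)
    s2post <- s2g
    dftot <- dg
  }
  se <- sqrt(s2post * (1 / n0 + 1 / n1))
  stat <- (mean1 - mean0) / se
  p <- 2 * stats::pt(-abs(stat), df = dftot)
  zero_var <- se == 0
  if (any(zero_var)) {
    if (!prior)
      warning(sum(zero_var), " unit(s) with zero pooled variance; ",
              "p set to the smallest representable value", call. = FALSE)
    stat[zero_var] <- ifelse((mean1 - mean0)[zero_var] == 0, 0,
                             sign((mean1 - mean0)[zero_var]) * Inf)
    p[zero_var] <- ifelse(stat[zero_var] == 0, 1, .Machine$double.xmin)
  }
  p[p == 0] <- .Machine$double.xmin
  # mean quotients are only meaningful for non-negative scales (betas);
  # negative group means (e.g. deviation inputs) yield NA quietly
  lq <- suppressWarnings(log2((mean1 + eps) / (mean0 + eps)))
  lq[is.nan(lq)] <- NA_real_
  out <- data.frame(
    unit = rownames(x0), mean0 = mean0, mean1 = mean1,
    diff = mean1 - mean0,
    log_quotient = lq,
    var0 = v0, var1 = v1, var_diff = v1 - v0,
    var_log_ratio = log2((v1 + eps) / (v0 + eps)),
    statistic = stat, p = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "d0") <- d0
  attr(out, "s02") <- pr$s02
  attr(out, "n_dropped") <- sum(has_na)
  out
}

#' Differential variability by moderated deviations (diffVar-style)
#'
#' Tests each unit for a group difference in variability: per cell the
#' absolute deviation from its group median, `z = |v - median(group)|`, is
#' computed, and the moderated-t machinery ([moderated_t_table()]) is
#' applied to the deviations. A positive statistic means larger deviations
#' (more variability) in group1. Group variances of the original values and
#' their difference/log-ratio are reported alongside for the worst-rank
#' criteria.
#'
#' @inheritParams moderated_t_table
#' @return A `data.frame` as from [moderated_t_table()], where `mean0`,
#'   `mean1`, `diff`, `statistic`, `p` refer to the group deviations, while
#'   `var0`, `var1`, `var_diff`, `var_log_ratio` describe the original
#'   values.
#' @export
diffvar_table <- function(values, comparison, prior = TRUE,
                          missing = c("drop", "error"), eps = 0.01) {
  missing <- match.arg(missing)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("unit", seq_len(nrow(values)))
  z <- abs_group_deviations(values, comparison)
  res <- moderated_t_table(z, comparison, prior = prior, missing = missing,
                           eps = eps)
  # variance columns describe the original values, not the deviations
  keep <- match(res$unit, rownames(values))
  x0 <- values[keep, comparison$idx0, drop = FALSE]
  x1 <- values[keep, comparison$idx1, drop = FALSE]
  res$var0 <- row_vars(x0)
  res$var1 <- row_vars(x1)
  res$var_diff <- res$var1 - res$var0
  res$var_log_ratio <- log2((res$var1 + eps) / (res$var0 + eps))
  res
}

# |value - group median| per cell, medians taken per unit within group.
abs_group_deviations <- function(values, comparison) {
  z <- values
  for (idx in list(comparison$idx0, comparison$idx1)) {
    med <- apply(values[, idx, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    z[, idx] <- abs(values[, idx, drop = FALSE] - med)
  }
  z
}

#' Differential variability by Bartlett's test (iEVORA-style)
#'
#' Per unit, Bartlett's test for unequal variances between the two groups
#' (k = 2 closed form), Benjamini-Hochberg adjustment to q-values, and the
#' regularization step of the iEVORA scheme: a unit is selected iff its
#' Bartlett q-value is below `q_threshold` and its classical t-test p-value
#' is below `t_threshold`; selected units are ordered by the t-test p-value
#' (reported in `select_rank`).
#'
#' @inheritParams moderated_t_table
#' @param q_threshold Bartlett q-value threshold (default 0.001).
#' @param t_threshold t-test p-value threshold (default 0.05).
#' @return A `data.frame` with columns `unit`, group variance summaries,
#'   `bartlett_stat`, `bartlett_p`, `bartlett_q`, `t_p`, `selected`,
#'   `select_rank` (1 = best selected unit by t-test p, `NA` if not
#'   selected).
#' @export
ievora_table <- function(values, comparison, q_threshold = 0.001,
                         t_threshold = 0.05, missing = c("drop", "error"),
                         eps = 0.01) {
  missing <- match.arg(missing)
  check_number(q_threshold, "q_threshold", 0, 1)
  check_number(t_threshold, "t_threshold", 0, 1)
  base <- moderated_t_table(values, comparison, prior = FALSE,
                            missing = missing, eps = eps)
  n0 <- length(comparison$idx0)
  n1 <- length(comparison$idx1)
  bt <- bartlett_two_groups(base$var0, base$var1, n0, n1)
  q <- stats::p.adjust(bt$p, method = "BH")
  selected <- q < q_threshold & base$p < t_threshold
  sel_rank <- rep(NA_integer_, nrow(base))
  sel_rank[selected] <- rank(base$p[selected], ties.method = "first")
  out <- data.frame(
    unit = base$unit, var0 = base$var0, var1 = base$var1,
    var_diff = base$var_diff, var_log_ratio = base$var_log_ratio,
    bartlett_stat = bt$stat, bartlett_p = bt$p, bartlett_q = q,
    t_p = base$p, selected = selected, select_rank = sel_rank,
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- attr(base, "n_dropped")
  out
}

# Vectorized Bartlett statistic for exactly two groups:
#   stat = ((N-2) ln s_p^2 - sum_i (n_i - 1) ln s_i^2) / C,
#   C = 1 + (1/3) (sum_i 1/(n_i-1) - 1/(N-2)),  stat ~ chisq(1) under H0.
bartlett_two_groups <- function(v0, v1, n0, n1) {
  N <- n0 + n1
  sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (N - 2)
  C <- 1 + (1 / 3) * (1 / (n0 - 1) + 1 / (n1 - 1) - 1 / (N - 2))
  stat <- ((N - 2) * log(sp2) - (n0 - 1) * log(v0) - (n1 - 1) * log(v1)) / C
  # equal variances (including both zero) give a zero statistic by symmetry
  equal <- abs(v0 - v1) < .Machine$double.eps * pmax(v0, v1, 1)
  stat[equal] <- 0
  one_zero <- !equal & (v0 == 0 | v1 == 0)
  stat[one_zero] <- Inf
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[p == 0] <- .Machine$double.xmin
  list(stat = stat, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#' Input p-values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop_mw("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Combine criterion ranks by the worst rank
#'
#' Implements the worst-rank scoring used for differential methylation and
#' differential variability: every unit is ranked separately by each of
#' three criteria — smaller adjusted p-value is better, larger absolute
#' effect is better, larger absolute quotient is better — with ties sharing
#' the minimal rank, and the combined rank of a unit is the worst (maximum)
#' of its three criterion ranks. The returned table is ordered by combined
#' rank (ascending), ties broken by adjusted p-value and then input order.
#' Units with a missing criterion value are ranked last on that criterion
#' (their count is reported in the `"n_missing"` attribute).
#'
#' @param table `data.frame` holding the criterion columns.
#' @param p_col,effect_col,quotient_col Names of the criterion columns
#'   (defaults `"p_adj"`, `"diff"`, `"log_quotient"`).
#' @return `table` augmented with `rank_p`, `rank_effect`, `rank_quotient`,
#'   `combined_rank`, sorted as described.
#' @export
combine_ranks <- function(table, p_col = "p_adj", effect_col = "diff",
                          quotient_col = "log_quotient") {
  for (cn in c(p_col, effect_col, quotient_col))
    if (!cn %in% names(table)) stop_mw("missing criterion column '", cn, "'")
  n <- nrow(table)
  rank_worst_na <- function(x) {
    r <- rep(n, n)                         # missing -> worst rank
    ok <- !is.na(x)
    r[ok] <- rank(x[ok], ties.method = "min")
    as.integer(r)
  }
  n_missing <- sum(is.na(table[[p_col]]) | is.na(table[[effect_col]]) |
                     is.na(table[[quotient_col]]))
  table$rank_p <- rank_worst_na(table[[p_col]])
  table$rank_effect <- rank_worst_na(-abs(table[[effect_col]]))
  table$rank_quotient <- rank_worst_na(-abs(table[[quotient_col]]))
  table$combined_rank <- pmax(table$rank_p, table$rank_effect,
                              table$rank_quotient)
  ord <- order(table$combined_rank, table[[p_col]], seq_len(n))
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  out
}

#' Automatic rank cutoff at a target FDR
#'
#' The number of units selected from a worst-rank-ordered table: the count
#' of units with adjusted p-value below `fdr`. The selected set consists of
#' that many best units by combined rank.
#'
#' @param table A combined-rank table (from [combine_ranks()]) containing a
#'   `p_adj` column.
#' @param fdr FDR level in (0, 1), default 0.05.
#' @return Integer cutoff (possibly 0), with the selected units' `unit`
#'   values in the `"selected"` attribute when a `unit` column exists.
#' @export
auto_rank_cutoff <- function(table, fdr = 0.05) {
  check_number(fdr, "fdr", 0, 1)
  if (nrow(table) == 0L) stop_mw("empty differential table")
  cutoff <- sum(table$p_adj < fdr, na.rm = TRUE)
  ord <- order(table$combined_rank, table$p_adj)
  sel <- utils::head(ord, cutoff)
  out <- cutoff
  if ("unit" %in% names(table)) attr(out, "selected") <- table$unit[sel]
  out
}

#' Differential methylation / variability analysis
#'
#' High-level wrappers producing a full `DifferentialTable`: per-unit group
#' statistics, p-values, BH-adjusted p-values, the three criterion ranks
#' and the combined (worst) rank. `differential_methylation()` tests group
#' mean differences with the moderated t-test and ranks by
#' (adjusted p, |mean difference|, |log2 quotient of means|);
#' `differential_variability()` tests variability with diffVar-style
#' moderated deviations (or iEVORA) and ranks by (adjusted p, difference of
#' group variances, log2 ratio of group variances).
#'
#' @param values Unit x sample matrix (CpG betas or region methylation).
#' @param comparison A [group_comparison()].
#' @param method For variability: `"diffvar"` or `"ievora"`.
#' @param prior Empirical-Bayes shrinkage for the moderated tests.
#' @param ... Passed to the underlying table function.
#' @return A `data.frame` of class `DifferentialTable`, ordered by combined
#'   rank.
#' @export
differential_methylation <- function(values, comparison, prior = TRUE, ...) {
  tab <- moderated_t_table(values, comparison, prior = prior, ...)
  tab$p_adj <- adjust_bh(tab$p)
  out <- combine_ranks(tab, p_col = "p_adj", effect_col = "diff",
                       quotient_col = "log_quotient")
  class(out) <- c("DifferentialTable", "data.frame")
  attr(out, "analysis") <- "methylation"
  out
}

#' @rdname differential_methylation
#' @export
differential_variability <- function(values, comparison,
                                     method = c("diffvar", "ievora"),
                                     prior = TRUE, ...) {
  method <- match.arg(method)
  if (method == "diffvar") {
    tab <- diffvar_table(values, comparison, prior = prior, ...)
    tab$p_adj <- adjust_bh(tab$p)
  } else {
    tab <- ievora_table(values, comparison, ...)
    tab$p <- tab$bartlett_p
    tab$p_adj <- tab$bartlett_q
  }
  out <- combine_ranks(tab, p_col = "p_adj", effect_col = "var_diff",
                       quotient_col = "var_log_ratio")
  class(out) <- c("DifferentialTable", "data.frame")
  attr(out, "analysis") <- paste0("variability_", method)
  out
}

#' Export a differential table as TSV
#'
#' Column order is fixed: unit, group summaries, statistic, p, p_adj,
#' criterion ranks, combined rank.
#'
#' @param table A `DifferentialTable`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_differential_table <- function(table, path) {
  lead <- intersect(c("unit", "mean0", "mean1", "diff", "log_quotient",
                      "var0", "var1", "var_diff", "var_log_ratio",
                      "statistic", "bartlett_stat", "p", "bartlett_p",
                      "t_p", "p_adj", "rank_p", "rank_effect",
                      "rank_quotient", "combined_rank"), names(table))
  out <- table[, c(lead, setdiff(names(table), lead)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
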