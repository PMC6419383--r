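#' Filter CpG sites by annotation and coverage rules
#'
#' Applies the standard preprocessing filters in a fixed order: first the
#' annotation rules (sex-chromosome removal, SNP-overlap removal), then the
#' coverage rule. Under the coverage rule a site is retained iff strictly
#' more than `min_fraction_covered` of the samples have coverage of at
#' least `min_coverage` reads — e.g. the common "at least 5 reads in more
#' than 50% of samples" criterion is `min_coverage = 5`,
#' `min_fraction_covered = 0.5`. For array-derived data (all-missing
#' coverage) the coverage rule is skipped with a notice instead of
#' erroring.
#'
#' @param dataset A `MethylationDataset`.
#' @param remove_sex_chromosomes Drop chrX/chrY sites.
#' @param remove_snp_sites Drop sites flagged `is_snp`.
#' @param min_coverage,min_fraction_covered Coverage rule parameters; both
#'   must be given for the rule to apply. The coverage comparison is
#'   non-strict (`>= min_coverage`), the fraction comparison strict
#'   (`> min_fraction_covered`).
#' @return A list with elements `dataset` (the filtered dataset, site order
#'   preserved) and `report` (a `FilterReport` data frame with per-rule
#'   removed/retained counts in application order).
#' @export
filter_sites <- function(dataset, remove_sex_chromosomes = FALSE,
                         remove_snp_sites = FALSE, min_coverage = NULL,
                         min_fraction_covered = NULL) {
  check_flag(remove_sex_chromosomes, "remove_sex_chromosomes")
  check_flag(remove_snp_sites, "remove_snp_sites")
  if (!is.null(min_fraction_covered))
    check_number(min_fraction_covered, "min_fraction_covered", 0, 1)
  if (!is.null(min_coverage))
    check_number(min_coverage, "min_coverage", 1)
  keep <- rep(TRUE, n_sites(dataset))
  report <- data.frame(rule = "input", removed = 0L,
                       retained = n_sites(dataset),
                       stringsAsFactors = FALSE)
  add_stage <- function(rule, keep_before, keep_after) {
    rbind(report, data.frame(rule = rule,
                             removed = sum(keep_before) - sum(keep_after),
                             retained = sum(keep_after),
                             stringsAsFactors = FALSE))
  }
  if (remove_sex_chromosomes) {
    keep2 <- keep & !is_sex_chromosome(dataset$sites$chrom)
    report <- add_stage("sex_chromosomes", keep, keep2)
    keep <- keep2
  }
  if (remove_snp_sites) {
    keep2 <- keep & !dataset$sites$is_snp
    report <- add_stage("snp_sites", keep, keep2)
    keep <- keep2
  }
  if (!is.null(min_coverage) && !is.null(min_fraction_covered)) {
    if (all(is.na(dataset$coverage))) {
      message("coverage rule skipped: dataset has no coverage information")
      report <- rbind(report, data.frame(rule = "coverage_skipped",
                                         removed = 0L,
                                         retained = sum(keep),
                                         stringsAsFactors = FALSE))
    } else {
      frac <- rowMeans(!is.na(dataset$coverage) &
                         dataset$coverage >= min_coverage)
      keep2 <- keep & (frac > min_fraction_covered)
      report <- add_stage("coverage", keep, keep2)
      keep <- keep2
    }
  }
  class(report) <- c("FilterReport", "data.frame")
  if (!any(keep))
    stop_mw("all sites removed by filtering", data = report)
  list(dataset = subset_dataset(dataset, sites = keep), report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("Site filter report:\n")
  print.data.frame(x)
  invisible(x)
}

#' Mask beta values with insufficient read coverage
#'
#' Cell-level analogue of the site-level coverage filter: beta values whose
#' coverage is below `min_coverage` are set to missing; the coverage matrix
#' itself is unchanged.
#'
#' @param dataset A `MethylationDataset`.
#' @param min_coverage Minimum reads for a call to be kept (>= 1).
#' @return The masked `MethylationDataset`.
#' @export
mask_low_coverage <- function(dataset, min_coverage) {
  check_number(min_coverage, "min_coverage", 1)
  mask <- !is.na(dataset$coverage) & dataset$coverage < min_coverage
  dataset$beta[mask] <- NA_real_
  dataset
}

#' Impute missing methylation values
#'
#' Implements the imputation strategies for incomplete methylation
#' matrices: sample-wise mean/median (column statistics), CpG-wise
#' mean/median (row statistics), random replacement drawn uniformly from
#' the observed values of the same CpG row (explicit seed required), and
#' k-nearest-neighbor imputation over CpG rows. For KNN, the distance
#' between two rows is the Euclidean distance over the columns where both
#' are observed, scaled by `1/sqrt(m)` for `m` shared columns (i.e. a
#' root-mean-square difference); the imputed value is the unweighted mean
#' of the k nearest rows observed in the target column, skipping nearer
#' rows that are missing there.
#'
#' @param x A `MethylationDataset` or a numeric matrix in `[0, 1]`.
#' @param strategy One of `"sample_mean"`, `"sample_median"`, `"cpg_mean"`,
#'   `"cpg_median"`, `"random"`, `"knn"`.
#' @param k Neighbor count for `"knn"` (must be `< nrow`).
#' @param seed Required for `"random"`; ignored otherwise.
#' @return Object of the same type with no missing beta values; observed
#'   cells are untouched.
#' @export
impute_missing <- function(x, strategy = c("cpg_mean", "cpg_median",
                                           "sample_mean", "sample_median",
                                           "random", "knn"),
                           k = 10L, seed = NULL) {
  strategy <- match.arg(strategy)
  if (inherits(x, "MethylationDataset")) {
    x$beta <- impute_matrix(x$beta, strategy, k = k, seed = seed)
    attr(x, "imputed") <- strategy
    return(x)
  }
  impute_matrix(x, strategy, k = k, seed = seed)
}

#' @rdname impute_missing
#' @export
impute_matrix <- function(x, strategy, k = 10L, seed = NULL) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (strategy %in% c("sample_mean", "sample_median")) {
    fun <- if (strategy == "sample_mean") mean else stats::median
    for (j in which(colSums(miss) > 0L)) {
      obs <- x[!miss[, j], j]
      if (length(obs) == 0L)
        stop_mw("column ", colnames(x)[j] %||% j,
                " has no observed values; cannot impute sample-wise")
      x[miss[, j], j] <- fun(obs)
    }
  } else if (strategy %in% c("cpg_mean", "cpg_median", "random")) {
    fun <- if (strategy == "cpg_median") stats::median else mean
    rows <- which(rowSums(miss) > 0L)
    no_obs <- rows[rowSums(!miss[rows, , drop = FALSE]) == 0L]
    if (length(no_obs))
      stop_mw("row ", rownames(x)[no_obs[1L]] %||% no_obs[1L],
              " has no observed values; cannot impute CpG-wise")
    if (strategy == "random") {
      if (is.null(seed))
        stop_mw("random imputation requires an explicit 'seed'")
      x <- with_seed(seed, {
        for (i in rows) {
          obs <- x[i, !miss[i, ]]
          x[i, miss[i, ]] <- sample(obs, sum(miss[i, ]), replace = TRUE)
        }
        x
      })
    } else {
      for (i in rows) x[i, miss[i, ]] <- fun(x[i, !miss[i, ]])
    }
  } else if (strategy == "knn") {
    check_number(k, "k", 1)
    if (k >= nrow(x))
      stop_mw("k (", k, ") must be smaller than the number of rows (",
              nrow(x), ")")
    rows <- which(rowSums(miss) > 0L)
    no_obs <- rows[rowSums(!miss[rows, , drop = FALSE]) == 0L]
    if (length(no_obs))
      stop_mw("row ", rownames(x)[no_obs[1L]] %||% no_obs[1L],
              " has no observed values; cannot impute with knn")
    obs_mat <- !miss
    for (i in rows) {
      d <- knn_row_distances(x, obs_mat, i)
      for (j in which(miss[i, ])) {
        cand <- which(obs_mat[, j] & is.finite(d))
        if (length(cand) == 0L) {
          # no comparable neighbor observed here; fall back to the row mean
          x[i, j] <- mean(x[i, obs_mat[i, ]])
          next
        }
        ord <- cand[order(d[cand])]
        x[i, j] <- mean(x[ord[seq_len(min(k, length(ord)))], j])
      }
    }
  }
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# RMS distance of row i to all rows over pairwise-complete columns;
# Inf where no columns are shared, Inf at i itself.
knn_row_distances <- function(x, obs, i) {
  shared <- obs %*% obs[i, ]                      # m per row
  diff <- x - matrix(x[i, ], nrow(x), ncol(x), byrow = TRUE)
  diff[!obs | !matrix(obs[i, ], nrow(x), ncol(x), byrow = TRUE)] <- 0
  d <- sqrt(rowSums(diff^2) / pmax(shared[, 1L], 1))
  d[shared[, 1L] == 0] <- Inf
  d[i] <- Inf
  d
}
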