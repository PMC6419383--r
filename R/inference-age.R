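#' Train an epigenetic age predictor
#'
#' Fits an elastic-net regression of chronological age on single-CpG beta
#' values. The penalty is chosen by cross-validated mean squared error over
#' a lambda grid; cross-validation folds are assigned from a hash of the
#' sample ids (balanced round-robin over samples ordered by hash), so the
#' chosen penalty and coefficients are invariant under sample permutation.
#' Only sites with nonzero coefficients are stored, together with their
#' training-set mean beta values, which [predict_age()] substitutes for
#' sites missing from a new dataset.
#'
#' @param dataset A `MethylationDataset` without missing beta values
#'   (impute first).
#' @param ages Numeric vector of known ages (years), aligned to samples;
#'   defaults to the sheet's `age` column. Samples with missing age are
#'   dropped from training.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param lambda_grid Optional penalty grid (default: glmnet's path).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Unused by the deterministic fold assignment; kept in the
#'   model metadata for provenance.
#' @return An object of class `AgeModel`: `intercept`, `coefficients`
#'   (named by site id), `training_means`, `alpha`, `lambda`, `metadata`.
#' @export
train_age_model <- function(dataset, ages = NULL, alpha = 0.5,
                            lambda_grid = NULL, cv_folds = 10L, seed = 1L) {
  check_number(alpha, "alpha", 0, 1)
  check_number(cv_folds, "cv_folds", 3)
  if (is.null(ages)) {
    if (!"age" %in% names(dataset$samples))
      stop_mw("no 'age' column in sample sheet and no 'ages' given")
    ages <- dataset$samples$age
  }
  if (length(ages) != n_samples(dataset))
    stop_mw("'ages' length does not match sample count")
  keep <- !is.na(ages)
  if (sum(keep) < 10L)
    stop_mw("need at least 10 samples with known age (got ", sum(keep), ")")
  y <- ages[keep]
  if (stats::sd(y) == 0) stop_mw("age is constant across training samples")
  x <- t(dataset$beta[, keep, drop = FALSE])
  if (any(is.na(x)))
    stop_mw("dataset has missing beta values; run impute_missing() first")
  foldid <- hash_folds(dataset$samples$sample_id[keep], cv_folds)
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, lambda = lambda_grid,
                          foldid = foldid, family = "gaussian",
                          type.measure = "mse")
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1L]
  w <- co[-1L]
  nz <- w != 0
  structure(list(
    intercept = unname(co[1L]),
    coefficients = w[nz],
    training_means = colMeans(x[, nz, drop = FALSE]),
    alpha = alpha,
    lambda = cv$lambda.min,
    metadata = list(platform = dataset$platform, n_samples = sum(keep),
                    cv_folds = cv_folds, seed = seed)
  ), class = "AgeModel")
}

# Balanced, order-independent fold assignment: samples are sorted by
# (hash(sample_id), sample_id) and folds assigned round-robin.
hash_folds <- function(sample_ids, k) {
  h <- string_hash(sample_ids)
  pos <- order(h, sample_ids)
  fold <- integer(length(sample_ids))
  fold[pos] <- ((seq_along(sample_ids) - 1L) %% k) + 1L
  fold
}

#' @export
print.AgeModel <- function(x, ...) {
  cat("AgeModel: ", length(x$coefficients), " CpGs, intercept ",
      sprintf("%.2f", x$intercept), ", alpha ", x$alpha, ", lambda ",
      signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Predict epigenetic age
#'
#' Applies an [train_age_model()] predictor:
#' `age = intercept + sum(weight * beta)` over the model's CpGs. Model
#' sites absent from the dataset, and missing cells at present sites, are
#' substituted by the stored training means; the per-sample substitution
#' count is reported. Prediction refuses to run when fewer than
#' `min_overlap` of the model sites are present.
#'
#' @param model An `AgeModel`.
#' @param dataset A `MethylationDataset`.
#' @param min_overlap Minimum fraction of model sites that must be present
#'   (default 0.5).
#' @return `data.frame` with `sample_id`, `age_pred`, `n_substituted`.
#' @export
predict_age <- function(model, dataset, min_overlap = 0.5) {
  check_number(min_overlap, "min_overlap", 0, 1)
  sites <- names(model$coefficients)
  idx <- match(sites, dataset$sites$site_id)
  frac <- mean(!is.na(idx))
  if (frac < min_overlap)
    stop_mw(sprintf(
      "only %.1f%% of %d model sites present (minimum %.1f%%)",
      100 * frac, length(sites), 100 * min_overlap))
  vals <- matrix(rep(model$training_means, n_samples(dataset)),
                 nrow = length(sites),
                 dimnames = list(sites, dataset$samples$sample_id))
  present <- !is.na(idx)
  b <- dataset$beta[idx[present], , drop = FALSE]
  subbed <- matrix(TRUE, length(sites), n_samples(dataset))
  subbed[present, ] <- is.na(b)
  b[is.na(b)] <- vals[present, ][is.na(b)]
  vals[present, ] <- b
  pred <- model$intercept + drop(model$coefficients %*% vals)
  data.frame(sample_id = dataset$samples$sample_id,
             age_pred = unname(pred),
             n_substituted = colSums(subbed),
             stringsAsFactors = FALSE)
}

#' Serialize an age model to TSV
#'
#' Format: `#`-prefixed `key=value` header lines (alpha, lambda, platform,
#' n_samples), then a three-column table `term`, `weight`, `training_mean`
#' with the intercept as term `(Intercept)`. Round-trips exactly at full
#' double precision.
#'
#' @param model An `AgeModel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_age_model <- function(model, path) {
  hdr <- c(
    paste0("# alpha=", format_full(model$alpha)),
    paste0("# lambda=", format_full(model$lambda)),
    paste0("# platform=", model$metadata$platform %||% "unknown"),
    paste0("# n_samples=", model$metadata$n_samples %||% NA)
  )
  tab <- data.frame(
    term = c("(Intercept)", names(model$coefficients)),
    weight = format_full(c(model$intercept, unname(model$coefficients))),
    training_mean = c("NA", format_full(unname(model$training_means))),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- sub("^# *", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ic <- tab$term == "(Intercept)"
  structure(list(
    intercept = as.numeric(tab$weight[ic]),
    coefficients = stats::setNames(as.numeric(tab$weight[!ic]),
                                   tab$term[!ic]),
    training_means = stats::setNames(as.numeric(tab$training_mean[!ic]),
                                     tab$term[!ic]),
    alpha = as.numeric(vals[keys == "alpha"]),
    lambda = as.numeric(vals[keys == "lambda"]),
    metadata = list(platform = vals[keys == "platform"],
                    n_samples = as.integer(vals[keys == "n_samples"]))
  ), class = "AgeModel")
}
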