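#' Sex-chromosome signal features
#'
#' Computes the two features used for methylation-based sex prediction: for
#' sequencing data, the log2 ratio of mean read coverage on each sex
#' chromosome to mean autosomal coverage,
#' `fX = log2((mean_cov_chrX + eps) / (mean_cov_autosomes + eps))` and
#' likewise `fY`, with pseudo-count `eps = 0.01`. For array-derived data a
#' per-site mean signal-intensity matrix is supplied instead and enters
#' the same formula in place of coverage. Males show roughly halved chrX
#' coverage (one X) and substantial chrY coverage; females show chrX at
#' autosomal level and near-zero chrY.
#'
#' @param dataset A `MethylationDataset` with chrX, chrY and autosomal
#'   sites.
#' @param intensities Optional site x sample numeric matrix of mean signal
#'   intensities (rows aligned to dataset sites) for array platforms.
#' @param eps Pseudo-count (default 0.01).
#' @return `data.frame` with `sample_id`, `fX`, `fY`.
#' @export
sex_features <- function(dataset, intensities = NULL, eps = 0.01) {
  chrom <- dataset$sites$chrom
  on_x <- chrom %in% c("chrX", "X")
  on_y <- chrom %in% c("chrY", "Y")
  auto <- is_autosome(chrom)
  if (!any(on_x) || !any(on_y))
    stop_mw("dataset lacks chrX and/or chrY sites; cannot derive sex features")
  if (!any(auto)) stop_mw("dataset has no autosomal sites")
  sig <- if (!is.null(intensities)) {
    as.matrix(intensities)
  } else {
    if (all(is.na(dataset$coverage)))
      stop_mw("dataset has no coverage; supply 'intensities' for array data")
    dataset$coverage
  }
  m_auto <- colMeans(sig[auto, , drop = FALSE], na.rm = TRUE)
  m_x <- colMeans(sig[on_x, , drop = FALSE], na.rm = TRUE)
  m_y <- colMeans(sig[on_y, , drop = FALSE], na.rm = TRUE)
  data.frame(sample_id = dataset$samples$sample_id,
             fX = log2((m_x + eps) / (m_auto + eps)),
             fY = log2((m_y + eps) / (m_auto + eps)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Train a sex classifier on signal-ratio features
#'
#' Standard logistic regression of the known sex label on `(fX, fY)`.
#' Both classes must be present in training.
#'
#' @param features `data.frame` with columns `fX`, `fY` (from
#'   [sex_features()]).
#' @param labels Sex labels (two classes, e.g. `"male"`/`"female"`),
#'   aligned to feature rows; missing labels are dropped.
#' @param feature_type `"sequencing-coverage"` or `"array-intensity"`
#'   (metadata tag).
#' @return An object of class `SexModel` with the logistic coefficients
#'   (intercept, weight_fX, weight_fY) and the class labels.
#' @export
train_sex_model <- function(features, labels,
                            feature_type = "sequencing-coverage") {
  keep <- !is.na(labels) & labels != "unknown"
  labels <- as.character(labels[keep])
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop_mw("training labels must contain exactly two classes (got ",
            length(classes), ")")
  df <- data.frame(y = as.integer(labels == classes[2L]),
                   fX = features$fX[keep], fY = features$fY[keep])
  # suppress the perfect-separation warning: separable cohorts are the
  # expected case here and the fitted decision boundary is still valid
  fit <- suppressWarnings(stats::glm(y ~ fX + fY, family = stats::binomial(),
                                     data = df))
  structure(list(feature_type = feature_type,
                 coefficients = stats::coef(fit),
                 classes = classes),
            class = "SexModel")
}

#' @export
print.SexModel <- function(x, ...) {
  cat("SexModel [", x$feature_type, "]: classes ",
      paste(x$classes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Predict sex from signal-ratio features
#'
#' Applies a [train_sex_model()] classifier; the predicted class is the one
#' with higher probability, and `"unknown"` is returned where the winning
#' probability is below the confidence threshold.
#'
#' @param model A `SexModel`.
#' @param features `data.frame` with `fX`, `fY` columns.
#' @param confidence Minimum winning probability (default 0.8).
#' @return `data.frame` with `sample_id` (if present in `features`),
#'   `predicted`, and the per-class probabilities.
#' @export
predict_sex <- function(model, features, confidence = 0.8) {
  check_number(confidence, "confidence", 0.5, 1)
  co <- model$coefficients
  eta <- co[1L] + co[2L] * features$fX + co[3L] * features$fY
  p2 <- stats::plogis(eta)
  predicted <- ifelse(p2 >= 0.5, model$classes[2L], model$classes[1L])
  predicted[pmax(p2, 1 - p2) < confidence] <- "unknown"
  out <- data.frame(predicted = predicted, stringsAsFactors = FALSE)
  out[[paste0("prob_", model$classes[1L])]] <- 1 - p2
  out[[paste0("prob_", model$classes[2L])]] <- p2
  if ("sample_id" %in% names(features))
    out <- cbind(data.frame(sample_id = features$sample_id,
                            stringsAsFactors = FALSE), out)
  out
}

#' Serialize a sex model to TSV
#'
#' @param model A `SexModel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sex_model <- function(model, path) {
  lines <- c(
    paste0("# feature_type=", model$feature_type),
    paste0("# classes=", paste(model$classes, collapse = ",")),
    "term\tweight",
    paste(c("(Intercept)", "fX", "fY"),
          format_full(unname(model$coefficients)), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sex_model
#' @export
read_sex_model <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# *", "", lines[startsWith(lines, "#")])
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(list(
    feature_type = sub("^feature_type=", "",
                       hdr[startsWith(hdr, "feature_type=")]),
    coefficients = stats::setNames(as.numeric(tab$weight), tab$term),
    classes = strsplit(sub("^classes=", "",
                           hdr[startsWith(hdr, "classes=")]), ",")[[1L]]
  ), class = "SexModel")
}
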