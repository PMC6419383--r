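#' Principal component embedding of samples
#'
#' Computes principal components of the sample x unit matrix after
#' unit-wise centering. Components are ordered by explained variance, and
#' the sign of each component is fixed so that its largest-magnitude unit
#' loading is positive (removes the arbitrary SVD sign).
#'
#' @param values Unit x sample numeric matrix without missing values.
#' @param n_components Number of components to return (default all).
#' @return List of class `PCAEmbedding` with `coords` (sample x component
#'   scores), `explained_variance` (all component variances),
#'   `proportion` (explained-variance fractions) and `rotation` (unit
#'   loadings for the returned components).
#' @export
pca_embed <- function(values, n_components = NULL) {
  values <- as.matrix(values)
  if (any(is.na(values)))
    stop_mw("values contain missing entries; run impute_missing() first")
  if (ncol(values) < 2L) stop_mw("need at least 2 samples")
  pc <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
  k <- min(n_components %||% ncol(pc$x), ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- colnames(values)
  structure(list(coords = coords,
                 explained_variance = pc$sdev^2,
                 proportion = pc$sdev^2 / sum(pc$sdev^2),
                 rotation = rot),
            class = "PCAEmbedding")
}

#' @export
print.PCAEmbedding <- function(x, ...) {
  k <- ncol(x$coords)
  cat("PCAEmbedding: ", nrow(x$coords), " samples, ", k, " components (",
      sprintf("%.1f%%", 100 * sum(x$proportion[seq_len(k)])),
      " variance)\n", sep = "")
  invisible(x)
}

#' Associate principal components with sample annotations
#'
#' Tests every (component, annotation) pair for statistical association:
#' numeric annotations with the Pearson correlation test, categorical
#' annotations with at least two populated levels with the Kruskal-Wallis
#' test across levels. Annotations with a single populated level are
#' skipped with a notice.
#'
#' @param embedding A [pca_embed()] result, or a sample x component matrix.
#' @param samples A `SampleSheet` aligned to the embedding's samples.
#' @param alpha Significance level for the mask (default 0.01).
#' @return List with `p` (component x annotation p-value matrix),
#'   `significant` (logical mask `p < alpha`) and `skipped` (character
#'   vector of untestable annotations).
#' @export
associate_components <- function(embedding, samples, alpha = 0.01) {
  check_number(alpha, "alpha", 0, 1)
  coords <- if (inherits(embedding, "PCAEmbedding")) embedding$coords else
    as.matrix(embedding)
  types <- attr(samples, "col_types") %||%
    stats::setNames(ifelse(vapply(samples, is.numeric, TRUE),
                           "numeric", "categorical"), names(samples))
  ann_cols <- setdiff(names(samples), "sample_id")
  skipped <- character(0)
  testable <- character(0)
  for (nm in ann_cols) {
    col <- samples[[nm]]
    if (types[[nm]] == "numeric") {
      if (length(unique(stats::na.omit(col))) < 2L ||
          sum(!is.na(col)) < 3L) {
        skipped <- c(skipped, nm)
      } else testable <- c(testable, nm)
    } else {
      lv <- table(col[!is.na(col)])
      if (sum(lv > 0L) < 2L) skipped <- c(skipped, nm)
      else testable <- c(testable, nm)
    }
  }
  if (length(skipped))
    message("skipping untestable annotation(s): ",
            paste(skipped, collapse = ", "))
  if (length(testable) == 0L) stop_mw("no testable annotations")
  p <- matrix(NA_real_, ncol(coords), length(testable),
              dimnames = list(colnames(coords), testable))
  for (nm in testable) {
    col <- samples[[nm]]
    ok <- !is.na(col)
    for (j in seq_len(ncol(coords))) {
      p[j, nm] <- if (types[[nm]] == "numeric") {
        stats::cor.test(coords[ok, j], col[ok])$p.value
      } else {
        stats::kruskal.test(coords[ok, j], factor(col[ok]))$p.value
      }
    }
  }
  list(p = p, significant = p < alpha, skipped = skipped)
}
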