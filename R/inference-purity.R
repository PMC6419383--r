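#' Genetic-noise sample quality score
#'
#' For each sample, the mean deviation of the beta values of autosomal
#' genotyping (SNP) probes from the diploid target values: 0 and 1
#' (homozygous) and 0.5 (heterozygous). Per site the deviation is
#' `min(|b - 0|, |b - 0.5|, |b - 1|)`, so the score lies in `[0, 0.25]`;
#' elevated values indicate technical problems, cross-individual
#' contamination, or aneuploidy. Missing values are skipped.
#'
#' @param dataset A `MethylationDataset` with at least one autosomal site
#'   flagged `is_snp_probe`.
#' @return `data.frame` with `sample_id`, `genetic_noise`, `n_sites`.
#' @export
genetic_noise <- function(dataset) {
  use <- dataset$sites$is_snp_probe & is_autosome(dataset$sites$chrom)
  if (!any(use))
    stop_mw("no autosomal SNP-probe sites flagged (is_snp_probe)")
  b <- dataset$beta[use, , drop = FALSE]
  dev <- pmin(abs(b), abs(b - 0.5), abs(b - 1))
  data.frame(sample_id = dataset$samples$sample_id,
             genetic_noise = colMeans(dev, na.rm = TRUE),
             n_sites = colSums(!is.na(dev)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LUMP tumor-purity estimate
#'
#' Estimates immune-cell content from a preselected set of CpGs that are
#' unmethylated in leukocytes: the mean beta value over the available LUMP
#' sites, divided by a scale constant (default 0.85) and capped at 1,
#' gives the non-immune ("purity") fraction; its complement is the immune
#' fraction. Fully unmethylated LUMP sites therefore indicate a pure blood
#' signal (purity 0, immune fraction 1).
#'
#' @param dataset A `MethylationDataset`.
#' @param lump_sites Character vector of LUMP site ids (at least one must
#'   be present in the dataset).
#' @param scale Scale constant (default 0.85).
#' @return `data.frame` with `sample_id`, `purity`, `immune_fraction`, and
#'   an `"n_sites_used"` attribute.
#' @export
lump_purity <- function(dataset, lump_sites, scale = 0.85) {
  check_number(scale, "scale", 1e-6)
  idx <- stats::na.omit(match(lump_sites, dataset$sites$site_id))
  if (length(idx) == 0L)
    stop_mw("none of the ", length(lump_sites),
            " LUMP sites are present in the dataset")
  mb <- colMeans(dataset$beta[idx, , drop = FALSE], na.rm = TRUE)
  purity <- pmin(1, mb / scale)
  out <- data.frame(sample_id = dataset$samples$sample_id,
                    purity = purity, immune_fraction = 1 - purity,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_sites_used") <- length(idx)
  out
}

#' Read / write a LUMP site list (one site id per line)
#'
#' @param path Text file.
#' @return Character vector of site ids.
#' @export
read_lump_sites <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_lump_sites
#' @param sites Character vector of site ids.
#' @export
write_lump_sites <- function(sites, path) {
  writeLines(sites, path)
  invisible(path)
}

#' Construct reference methylation profiles
#'
#' Mean beta profiles of purified cell populations, used for
#' reference-based cell-type deconvolution. Rows are keyed by site id,
#' columns by cell type; no missing entries allowed, at least two cell
#' types.
#'
#' @param profile Numeric matrix (sites x cell types) in `[0, 1]` with
#'   site-id rownames and cell-type colnames.
#' @return The validated matrix with class `ReferenceProfiles`.
#' @export
reference_profiles <- function(profile) {
  profile <- as.matrix(profile)
  if (ncol(profile) < 2L) stop_mw("need at least 2 cell types")
  if (is.null(rownames(profile)) || is.null(colnames(profile)))
    stop_mw("reference profiles need site-id rownames and cell-type colnames")
  if (any(is.na(profile))) stop_mw("reference profiles contain missing values")
  if (any(profile < 0 | profile > 1))
    stop_mw("reference profiles must lie in [0, 1]")
  class(profile) <- c("ReferenceProfiles", class(profile))
  profile
}

#' @rdname reference_profiles
#' @param path TSV with a `site_id` column and one column per cell type.
#' @export
read_reference_profiles <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  reference_profiles(m)
}

#' @rdname reference_profiles
#' @export
write_reference_profiles <- function(profile, path) {
  out <- data.frame(site_id = rownames(profile),
                    unclass(as.data.frame(matrix(profile, nrow(profile),
                                                 dimnames = dimnames(profile)))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference-based cell-type deconvolution
#'
#' For each sample solves the constrained least-squares problem
#' `min || b - R w ||^2` over the sites shared between the dataset and the
#' reference profiles, subject to `w >= 0` and `sum(w) <= 1` (or `= 1`).
#' The quadratic program is solved exactly by enumerating active sets
#' (support subsets of the cell types plus the state of the sum
#' constraint), solving each reduced least-squares/KKT system, and taking
#' the feasible candidate with the smallest objective — exact for the small
#' cell-type counts typical of reference panels.
#'
#' @param dataset A `MethylationDataset` with no missing betas at the
#'   shared sites (impute first).
#' @param reference A [reference_profiles()] matrix.
#' @param constraint `"sum_le_one"` (default) or `"sum_eq_one"`.
#' @return `data.frame` with `sample_id`, one weight column per cell type,
#'   and `residual` (the residual norm).
#' @export
deconvolve_celltypes <- function(dataset, reference,
                                 constraint = c("sum_le_one", "sum_eq_one")) {
  constraint <- match.arg(constraint)
  K <- ncol(reference)
  if (K > 14L) stop_mw("active-set enumeration supports at most 14 cell types")
  shared <- intersect(rownames(reference), dataset$sites$site_id)
  if (length(shared) < K)
    stop_mw("only ", length(shared), " shared sites for ", K,
            " cell types; need at least ", K)
  R <- reference[shared, , drop = FALSE]
  class(R) <- "matrix"
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    if (all(abs(R[, i] - R[, j]) < 1e-12))
      stop_mw("reference is rank-deficient: cell types '", colnames(R)[i],
              "' and '", colnames(R)[j], "' have identical profiles")
  }
  B <- dataset$beta[match(shared, dataset$sites$site_id), , drop = FALSE]
  if (any(is.na(B)))
    stop_mw("missing beta values at shared sites; run impute_missing() first")
  W <- matrix(0, n_samples(dataset), K,
              dimnames = list(dataset$samples$sample_id, colnames(R)))
  resid <- numeric(n_samples(dataset))
  Gram <- crossprod(R)
  Rtb <- crossprod(R, B)
  bb_all <- colSums(B^2)
  for (j in seq_len(n_samples(dataset))) {
    sol <- solve_simplex_ls(Gram, Rtb[, j], bb_all[j], constraint)
    W[j, ] <- sol$w
    resid[j] <- sol$residual
  }
  out <- data.frame(sample_id = dataset$samples$sample_id,
                    W, residual = resid,
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_shared_sites") <- length(shared)
  out
}

# Exact constrained least squares over the (sub-)simplex by support
# enumeration, parameterized by the Gram matrix `Gram = R'R`, `g = R'b`
# and `bb = b'b`. The optimum of the convex QP is attained at the solution
# of one of the reduced equality systems, and every candidate checked is
# primal feasible, so the best feasible candidate is the global optimum.
solve_simplex_ls <- function(Gram, g_full, bb, constraint) {
  K <- ncol(Gram)
  best_obj <- if (constraint == "sum_le_one") bb else Inf  # w = 0 candidate
  best_w <- numeric(K)
  for (mask in seq_len(2^K - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0L)
    G <- Gram[S, S, drop = FALSE]
    g <- g_full[S]
    if (constraint == "sum_le_one") {
      ws <- tryCatch(solve(G, g), error = function(e) NULL)
      if (!is.null(ws) && all(ws >= -1e-12) && sum(ws) <= 1 + 1e-12) {
        obj <- bb - 2 * sum(g * ws) + drop(crossprod(ws, G %*% ws))
        if (obj < best_obj - 1e-15) {
          best_obj <- obj
          best_w <- numeric(K)
          best_w[S] <- pmax(ws, 0)
        }
      }
    }
    # sum-equality candidate (also the boundary case of the inequality)
    m <- length(S)
    kkt <- rbind(cbind(2 * G, rep(1, m)), c(rep(1, m), 0))
    rhs <- c(2 * g, 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      ws <- sol[seq_len(m)]
      if (all(ws >= -1e-12)) {
        obj <- bb - 2 * sum(g * ws) + drop(crossprod(ws, G %*% ws))
        if (obj < best_obj - 1e-15) {
          best_obj <- obj
          best_w <- numeric(K)
          best_w[S] <- pmax(ws, 0)
        }
      }
    }
  }
  list(w = best_w, residual = sqrt(max(best_obj, 0)))
}
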