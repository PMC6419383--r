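#' Construct a CpG site table
#'
#' Builds and validates the site annotation table used by
#' [methylation_dataset()]. Sites are keyed by `"chrom:pos:strand"` (with
#' strand `"*"` keyed as `"+"`), must be unique, and are stored sorted by
#' `(chrom, pos)`.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based cytosine positions on the + strand.
#' @param strand Strand of each site: `"+"`, `"-"` or `"*"` (unknown).
#' @param is_snp Logical; site overlaps a user-supplied SNP (filter target).
#' @param is_snp_probe Logical; site is a genotyping control probe used by
#'   the genetic-noise metric.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `site_id`,
#'   `is_snp`, `is_snp_probe`, sorted by `(chrom, pos)`.
#' @export
cpg_site_table <- function(chrom, pos, strand = "*", is_snp = FALSE,
                           is_snp_probe = FALSE) {
  n <- length(chrom)
  pos <- as.integer(pos)
  if (length(pos) != n) stop_mw("'chrom' and 'pos' lengths differ")
  if (any(is.na(pos)) || any(pos < 1L)) stop_mw("'pos' must be >= 1")
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", "*"))) stop_mw("strand must be +, - or *")
  sites <- data.frame(
    chrom = as.character(chrom), pos = pos, strand = strand,
    site_id = site_key(chrom, pos, strand),
    is_snp = rep_len(as.logical(is_snp), n),
    is_snp_probe = rep_len(as.logical(is_snp_probe), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sites$site_id))
    stop_mw("duplicated site keys: ",
            paste(utils::head(sites$site_id[duplicated(sites$site_id)], 3),
                  collapse = ", "))
  sites[order(sites$chrom, sites$pos), , drop = FALSE]
}

#' Construct a typed sample annotation sheet
#'
#' A sample sheet is a `data.frame` with one row per sample and a mandatory
#' unique `sample_id` column. Every other column is explicitly typed as
#' numeric or categorical: a column is numeric iff all its non-missing
#' entries parse as numbers; otherwise it is kept as character and treated
#' as categorical. The inferred types are recorded in the `"col_types"`
#' attribute so downstream association tests never have to guess.
#'
#' @param df A `data.frame` holding the annotations; must contain
#'   `sample_id` (or the first column is taken as the id when absent).
#' @return The typed sample sheet with a `"col_types"` attribute
#'   (named character vector, values `"id"`, `"numeric"` or `"categorical"`).
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_mw("sample sheet is empty")
  if (!"sample_id" %in% names(df)) names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_mw("duplicate sample_id: ",
            paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  types <- c(sample_id = "id")
  for (nm in setdiff(names(df), "sample_id")) {
    col <- df[[nm]]
    if (is.numeric(col)) {
      types[nm] <- "numeric"
      next
    }
    col <- as.character(col)
    col[col %in% c("NA", "NaN", "")] <- NA_character_
    parsed <- suppressWarnings(as.numeric(col))
    if (all(is.na(parsed) == is.na(col)) && any(!is.na(col))) {
      df[[nm]] <- parsed
      types[nm] <- "numeric"
    } else {
      df[[nm]] <- col
      types[nm] <- "categorical"
    }
  }
  rownames(df) <- NULL
  attr(df, "col_types") <- types
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Assemble a methylation dataset
#'
#' The central container of the package: per-CpG methylation levels (beta
#' values in `[0, 1]`) and read coverage for a set of samples, together with
#' site and sample annotations. Invariants enforced here:
#' beta values lie in `[0, 1]` or are missing; coverage values are
#' non-negative integers or missing; both matrices share the same shape,
#' aligned to sites (rows) and samples (columns); a cell with zero coverage
#' has a missing beta value (masked on construction).
#'
#' @param beta Numeric matrix (sites x samples) of methylation levels.
#' @param sites A site table from [cpg_site_table()] (rows are reordered to
#'   its sorted order).
#' @param samples A sample sheet ([sample_sheet()]) or `data.frame`.
#' @param coverage Optional integer matrix of read counts, same shape as
#'   `beta`; `NULL` (e.g. for array-derived data) stores an all-missing
#'   coverage matrix.
#' @param platform One of `"wgbs"`, `"rrbs"`, `"array27k"`, `"array450k"`,
#'   `"arrayEPIC"`, `"merged"`, `"synthetic"`.
#' @return An object of class `MethylationDataset`: a list with elements
#'   `sites`, `samples`, `beta`, `coverage`, `platform`.
#' @export
methylation_dataset <- function(beta, sites, samples, coverage = NULL,
                                platform = "synthetic") {
  platforms <- c("wgbs", "rrbs", "array27k", "array450k", "arrayEPIC",
                 "merged", "synthetic")
  if (!platform %in% platforms)
    stop_mw("unknown platform '", platform, "'")
  if (!inherits(samples, "SampleSheet")) samples <- sample_sheet(samples)
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(sites))
    stop_mw("beta has ", nrow(beta), " rows but ", nrow(sites), " sites")
  if (ncol(beta) != nrow(samples))
    stop_mw("beta has ", ncol(beta), " columns but ", nrow(samples), " samples")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad))
    stop_mw("beta values outside [0,1] at ", length(bad), " cell(s)")
  if (is.null(coverage)) {
    coverage <- matrix(NA_integer_, nrow(beta), ncol(beta))
  } else {
    coverage <- as.matrix(coverage)
    if (!identical(dim(coverage), dim(beta)))
      stop_mw("beta and coverage shapes differ")
    if (any(!is.na(coverage) & coverage < 0))
      stop_mw("negative coverage values")
    storage.mode(coverage) <- "integer"
  }
  # order rows by the canonical site sort
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  coverage <- coverage[ord, , drop = FALSE]
  rownames(sites) <- NULL
  dimnames(beta) <- list(sites$site_id, samples$sample_id)
  dimnames(coverage) <- dimnames(beta)
  # zero coverage implies missing methylation call
  beta[!is.na(coverage) & coverage == 0L] <- NA_real_
  structure(
    list(sites = sites, samples = samples, beta = beta,
         coverage = coverage, platform = platform),
    class = "MethylationDataset"
  )
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat("MethylationDataset [", x$platform, "]\n", sep = "")
  cat("  sites:   ", nrow(x$sites), " (",
      length(unique(x$sites$chrom)), " chromosomes)\n", sep = "")
  cat("  samples: ", nrow(x$samples), "\n", sep = "")
  cat("  missing beta: ",
      sprintf("%.1f%%", 100 * mean(is.na(x$beta))), "\n", sep = "")
  invisible(x)
}

#' Number of sites / samples in a dataset
#' @param dataset A `MethylationDataset`.
#' @return Integer count.
#' @export
n_sites <- function(dataset) nrow(dataset$sites)

#' @rdname n_sites
#' @export
n_samples <- function(dataset) nrow(dataset$samples)

#' Subset a methylation dataset
#'
#' @param dataset A `MethylationDataset`.
#' @param sites Logical/integer index over site rows, or character site ids.
#' @param samples Logical/integer index over samples, or character ids.
#' @return The subsetted `MethylationDataset` (site and sample order is the
#'   input order restricted to the kept entries).
#' @export
subset_dataset <- function(dataset, sites = NULL, samples = NULL) {
  si <- seq_len(n_sites(dataset))
  sj <- seq_len(n_samples(dataset))
  if (!is.null(sites)) {
    si <- if (is.character(sites)) match(sites, dataset$sites$site_id) else si[sites]
    if (any(is.na(si))) stop_mw("unknown site id in subset")
  }
  if (!is.null(samples)) {
    sj <- if (is.character(samples)) match(samples, dataset$samples$sample_id) else sj[samples]
    if (any(is.na(sj))) stop_mw("unknown sample id in subset")
  }
  out <- dataset
  out$sites <- dataset$sites[si, , drop = FALSE]
  rownames(out$sites) <- NULL
  smp <- dataset$samples[sj, , drop = FALSE]
  attr(smp, "col_types") <- attr(dataset$samples, "col_types")
  rownames(smp) <- NULL
  out$samples <- smp
  out$beta <- dataset$beta[si, sj, drop = FALSE]
  out$coverage <- dataset$coverage[si, sj, drop = FALSE]
  out
}

#' Serialize a dataset to a directory
#'
#' On-disk layout: `sites.tsv` and `samples.tsv` (plain TSV), `beta.rds` and
#' `coverage.rds` (lossless matrix serialization), `meta.yaml` (platform and
#' shape). [read_dataset_dir()] restores the object exactly.
#'
#' @param dataset A `MethylationDataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_dir <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$sites, file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(dataset$samples),
                     file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(dataset$beta, file.path(dir, "beta.rds"))
  saveRDS(dataset$coverage, file.path(dir, "coverage.rds"))
  yaml::write_yaml(list(platform = dataset$platform,
                        n_sites = n_sites(dataset),
                        n_samples = n_samples(dataset)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_dataset_dir
#' @export
read_dataset_dir <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  sites <- utils::read.table(file.path(dir, "sites.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  samples <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  methylation_dataset(
    beta = readRDS(file.path(dir, "beta.rds")),
    sites = cpg_site_table(sites$chrom, sites$pos, sites$strand,
                           sites$is_snp, sites$is_snp_probe),
    samples = sample_sheet(samples),
    coverage = readRDS(file.path(dir, "coverage.rds")),
    platform = meta$platform
  )
}
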