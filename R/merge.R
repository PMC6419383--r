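#' Merge methylation datasets across platforms
#'
#' Combines two or more datasets into one, keying sites by
#' `(chrom, pos, strand)` with strand `"*"` matching `"+"`, never by row
#' order. `mode = "intersect"` keeps exactly the sites present in every
#' input (the cross-platform "shared CpGs" analysis); `mode = "union"`
#' keeps all sites, with missing beta where a platform did not cover a
#' site. Beta values are copied unchanged from their source dataset. The
#' merged sample sheet gains a `source_platform` provenance column.
#'
#' @param datasets List of at least two `MethylationDataset` objects with
#'   disjoint sample ids.
#' @param mode `"intersect"` or `"union"`.
#' @return A `MethylationDataset` with `platform = "merged"`.
#' @export
merge_datasets <- function(datasets, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  if (!is.list(datasets) || length(datasets) < 2L)
    stop_mw("need at least two datasets to merge")
  lapply(datasets, function(d) {
    if (!inherits(d, "MethylationDataset"))
      stop_mw("all inputs must be MethylationDataset objects")
  })
  ids <- unlist(lapply(datasets, function(d) d$samples$sample_id))
  if (anyDuplicated(ids))
    stop_mw("overlapping sample ids across datasets: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keys <- lapply(datasets, function(d)
    site_key(d$sites$chrom, d$sites$pos, d$sites$strand))
  merged_keys <- if (mode == "intersect") {
    Reduce(intersect, keys)
  } else {
    unique(unlist(keys))
  }
  if (length(merged_keys) == 0L) {
    counts <- vapply(keys, length, integer(1))
    stop_mw("empty site intersection across ", length(datasets),
            " datasets (per-input site counts: ",
            paste(counts, collapse = ", "), ")")
  }
  # site annotation from first dataset carrying each key
  all_sites <- do.call(rbind, lapply(datasets, `[[`, "sites"))
  all_keys <- unlist(keys)
  site_info <- all_sites[match(merged_keys, all_keys), , drop = FALSE]
  snp_flags <- rowsum((all_sites$is_snp) + 0, all_keys)
  probe_flags <- rowsum((all_sites$is_snp_probe) + 0, all_keys)
  sites <- cpg_site_table(site_info$chrom, site_info$pos, site_info$strand,
                          is_snp = snp_flags[merged_keys, 1L] > 0,
                          is_snp_probe = probe_flags[merged_keys, 1L] > 0)
  skey <- site_key(sites$chrom, sites$pos, sites$strand)
  n <- nrow(sites)
  m <- length(ids)
  beta <- matrix(NA_real_, n, m)
  coverage <- matrix(NA_integer_, n, m)
  col0 <- 0L
  sheets <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    ridx <- match(keys[[k]], skey)
    jj <- col0 + seq_len(n_samples(d))
    ok <- !is.na(ridx)
    beta[ridx[ok], jj] <- d$beta[ok, , drop = FALSE]
    coverage[ridx[ok], jj] <- d$coverage[ok, , drop = FALSE]
    sh <- as.data.frame(d$samples)
    sh$source_platform <- d$platform
    sheets[[k]] <- sh
    col0 <- col0 + n_samples(d)
  }
  common <- Reduce(union, lapply(sheets, names))
  sheets <- lapply(sheets, function(s) {
    for (nm in setdiff(common, names(s))) s[[nm]] <- NA
    s[, common, drop = FALSE]
  })
  methylation_dataset(beta = beta, sites = sites,
                      samples = sample_sheet(do.call(rbind, sheets)),
                      coverage = coverage, platform = "merged")
}
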