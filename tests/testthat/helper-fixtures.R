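# Small in-code builders shared across test files.

# Dataset from an explicit beta matrix; one chromosome unless chrom given.
make_dataset <- function(beta, coverage = NULL, chrom = NULL, pos = NULL,
                         platform = "synthetic", samples = NULL,
                         is_snp_probe = FALSE) {
  beta <- as.matrix(beta)
  n <- nrow(beta)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq(10L, by = 10L, length.out = n)
  ord <- order(chrom, pos)          # keep rows aligned with the site sort
  chrom <- chrom[ord]
  pos <- pos[ord]
  beta <- beta[ord, , drop = FALSE]
  if (!is.null(coverage)) coverage <- as.matrix(coverage)[ord, , drop = FALSE]
  is_snp_probe <- rep_len(is_snp_probe, n)[ord]
  if (is.null(samples))
    samples <- data.frame(sample_id = paste0("s", seq_len(ncol(beta))),
                          stringsAsFactors = FALSE)
  methylation_dataset(
    beta = beta,
    sites = cpg_site_table(chrom, pos, is_snp_probe = is_snp_probe),
    samples = samples, coverage = coverage, platform = platform
  )
}

# Two-group comparison over the columns of a matrix with ncol = n0 + n1.
make_comparison <- function(n0, n1) {
  sheet <- data.frame(
    sample_id = paste0("s", seq_len(n0 + n1)),
    group = rep(c("g0", "g1"), c(n0, n1)),
    stringsAsFactors = FALSE
  )
  group_comparison(sample_sheet(sheet), "group", c("g0", "g1"))
}

# Write a Bismark-style coverage file from count vectors.
write_cov_file <- function(path, chrom, pos, n_meth, n_unmeth,
                           pct = NULL) {
  if (is.null(pct)) {
    tot <- n_meth + n_unmeth
    pct <- ifelse(tot > 0, 100 * n_meth / tot, 0)
  }
  writeLines(sprintf("%s\t%d\t%d\t%g\t%d\t%d", chrom, pos, pos, pct,
                     n_meth, n_unmeth), path)
  path
}

# Brute-force KNN oracle: enumerates all pairwise distances explicitly and
# averages the k nearest rows observed in the target column.
knn_oracle <- function(x, k) {
  out <- x
  n <- nrow(x)
  obs <- !is.na(x)
  for (i in seq_len(n)) {
    if (!any(!obs[i, ])) next
    d <- rep(Inf, n)
    for (r in seq_len(n)) {
      if (r == i) next
      sh <- obs[i, ] & obs[r, ]
      if (!any(sh)) next
      d[r] <- sqrt(sum((x[i, sh] - x[r, sh])^2) / sum(sh))
    }
    for (j in which(!obs[i, ])) {
      cand <- setdiff(which(obs[, j] & is.finite(d)), i)
      if (length(cand) == 0L) {
        out[i, j] <- mean(x[i, obs[i, ]])
        next
      }
      cand <- cand[order(d[cand])]
      out[i, j] <- mean(x[cand[seq_len(min(k, length(cand)))], j])
    }
  }
  out
}

# Independent min-tie ranking: 1 + count of strictly better values.
rank_min_oracle <- function(x) {
  vapply(x, function(xi) sum(x < xi) + 1L, integer(1))
}
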