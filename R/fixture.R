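#' Specify a synthetic methylation cohort
#'
#' Collects the parameters of the synthetic fixture generator with the
#' standard study conditions as defaults: a two-group sequencing cohort of
#' 20 samples per group over 5000 CpGs, 100 planted differentially
#' methylated CpGs (mean shift 0.3, arranged in blocks of 5 so that the
#' blocks define differentially methylated regions), 100 planted
#' differentially variable CpGs (variance ratio 4), an age signal (10
#' causal CpGs with age = 20 + 100 x mean causal beta + Gaussian noise of
#' 2 years), a balanced sex composition with sex-linked coverage, 50
#' autosomal genotyping-probe sites, and 100 leukocyte-unmethylated (LUMP)
#' sites driven by a per-sample purity. Betas are drawn from beta
#' distributions (precision 50 at null sites); coverage from a negative
#' binomial (mean 30, size 8), with chrX/chrY coverage scaled by sex.
#'
#' @param n_per_group Samples per group (default 20).
#' @param n_sites Total CpG count (default 5000).
#' @param n_dmc,dmc_delta Planted DMC count and group-1 mean shift.
#' @param n_dvc,dvc_var_ratio Planted DVC count and group-1/group-0
#'   variance ratio.
#' @param block_size Planted sites per region block (default 5).
#' @param age_causal,age_slope,age_intercept,age_noise_sd Age-signal
#'   parameters (years).
#' @param prop_female Fraction of female samples (default 0.5).
#' @param n_snp_probes,n_lump_sites Counts of flagged control sites.
#' @param coverage_mu,coverage_size Negative-binomial coverage model.
#' @param beta_precision Beta-distribution precision at null sites.
#' @param platform Platform tag (default `"rrbs"`).
#' @param seed Random seed driving the whole fixture.
#' @return A list of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_per_group = 20L, n_sites = 5000L,
                         n_dmc = 100L, dmc_delta = 0.3,
                         n_dvc = 100L, dvc_var_ratio = 4,
                         block_size = 5L,
                         age_causal = 10L, age_slope = 100,
                         age_intercept = 20, age_noise_sd = 2,
                         prop_female = 0.5,
                         n_snp_probes = 50L, n_lump_sites = 100L,
                         coverage_mu = 30, coverage_size = 8,
                         beta_precision = 50, platform = "rrbs",
                         seed = 1L) {
  spec <- list(n_per_group = as.integer(n_per_group),
               n_sites = as.integer(n_sites),
               n_dmc = as.integer(n_dmc), dmc_delta = dmc_delta,
               n_dvc = as.integer(n_dvc), dvc_var_ratio = dvc_var_ratio,
               block_size = as.integer(block_size),
               age_causal = as.integer(age_causal), age_slope = age_slope,
               age_intercept = age_intercept, age_noise_sd = age_noise_sd,
               prop_female = prop_female,
               n_snp_probes = as.integer(n_snp_probes),
               n_lump_sites = as.integer(n_lump_sites),
               coverage_mu = coverage_mu, coverage_size = coverage_size,
               beta_precision = beta_precision, platform = platform,
               seed = as.integer(seed))
  planted <- spec$n_dmc + spec$n_dvc + spec$age_causal +
    spec$n_snp_probes + spec$n_lump_sites
  if (planted > 0.8 * spec$n_sites)
    stop_mw("infeasible spec: ", planted, " planted sites for ",
            spec$n_sites, " total sites")
  class(spec) <- "FixtureSpec"
  spec
}

# clipped beta draw with mean m and the given precision
rbeta_mean <- function(n, m, precision) {
  m <- pmin(pmax(m, 0.02), 0.98)
  stats::rbeta(n, m * precision, (1 - m) * precision)
}

#' Generate a synthetic methylation cohort with known ground truth
#'
#' Draws a complete `MethylationDataset` according to a [fixture_spec()],
#' together with the ground-truth tables and the BED region sets covering
#' the planted DMR/DVR blocks. Identical seeds give byte-identical
#' fixtures.
#'
#' @param spec A `FixtureSpec`.
#' @return List with `dataset`, `truth` (list of `sites` and `samples`
#'   ground-truth `data.frame`s), `region_sets` (list with `dmr`, `dvr`),
#'   `lump_sites`, `chrom_sizes`, and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  n_smp <- 2L * spec$n_per_group
  ## -- site layout ---------------------------------------------------------
  n_y <- max(2L, round(0.01 * spec$n_sites))
  n_x <- max(2L, round(0.04 * spec$n_sites))
  n_auto <- spec$n_sites - n_x - n_y
  autosomes <- paste0("chr", 1:5)
  chrom <- c(sort(rep_len(autosomes, n_auto)), rep("chrX", n_x),
             rep("chrY", n_y))
  pos <- unlist(lapply(split(seq_along(chrom), chrom)[unique(chrom)],
                       function(idx) sort(sample.int(length(idx) * 60L,
                                                     length(idx)))),
                use.names = FALSE)
  chrom <- unlist(split(chrom, chrom)[unique(chrom)], use.names = FALSE)
  auto_idx <- which(chrom %in% autosomes)

  ## -- planted site roles (disjoint, autosomal) ----------------------------
  role <- rep("null", spec$n_sites)
  n_dmr_blocks <- spec$n_dmc %/% spec$block_size
  n_dvr_blocks <- spec$n_dvc %/% spec$block_size
  pick_blocks <- function(n_blocks, free) {
    starts <- integer(0)
    cand <- free
    while (length(starts) < n_blocks && length(cand)) {
      s <- cand[sample.int(length(cand), 1L)]
      block <- s:(s + spec$block_size - 1L)
      # a block must stay inside one chromosome and only use free sites
      if (max(block) <= spec$n_sites && all(block %in% free) &&
          chrom[s] == chrom[max(block)]) {
        starts <- c(starts, s)
        free <- setdiff(free, block)
      }
      cand <- setdiff(cand, s)
    }
    if (length(starts) < n_blocks)
      stop_mw("could not place ", n_blocks, " planted blocks")
    sort(starts)
  }
  free <- auto_idx
  dmr_starts <- if (n_dmr_blocks) pick_blocks(n_dmr_blocks, free) else integer(0)
  dmc_idx <- unlist(lapply(dmr_starts, function(s)
    s:(s + spec$block_size - 1L)))
  free <- setdiff(free, dmc_idx)
  dvr_starts <- if (n_dvr_blocks) pick_blocks(n_dvr_blocks, free) else integer(0)
  dvc_idx <- unlist(lapply(dvr_starts, function(s)
    s:(s + spec$block_size - 1L)))
  free <- setdiff(free, dvc_idx)
  age_idx <- sort(sample(free, spec$age_causal))
  free <- setdiff(free, age_idx)
  snp_idx <- sort(sample(free, spec$n_snp_probes))
  free <- setdiff(free, snp_idx)
  lump_idx <- sort(sample(free, spec$n_lump_sites))
  role[dmc_idx] <- "dmc"
  role[dvc_idx] <- "dvc"
  role[age_idx] <- "age"
  role[snp_idx] <- "snp_probe"
  role[lump_idx] <- "lump"

  ## -- sample annotations --------------------------------------------------
  group <- rep(c("control", "case"), each = spec$n_per_group)
  sex <- sample(c("female", "male"), n_smp, replace = TRUE,
                prob = c(spec$prop_female, 1 - spec$prop_female))
  purity <- stats::runif(n_smp, 0.5, 1)

  ## -- beta matrix ---------------------------------------------------------
  base_mean <- 0.03 + 0.94 * stats::rbeta(spec$n_sites, 0.85, 0.85)
  base_mean[c(dmc_idx, dvc_idx)] <- stats::runif(
    length(dmc_idx) + length(dvc_idx), 0.2, 0.6)
  beta <- matrix(NA_real_, spec$n_sites, n_smp)
  g1 <- group == "case"
  prec <- matrix(spec$beta_precision, spec$n_sites, n_smp)
  prec[dvc_idx, g1] <- spec$beta_precision / spec$dvc_var_ratio
  mu <- matrix(base_mean, spec$n_sites, n_smp)
  mu[dmc_idx, g1] <- mu[dmc_idx, g1] + spec$dmc_delta
  beta[] <- rbeta_mean(length(mu), as.vector(mu), as.vector(prec))
  # age-causal sites: uniform betas shared with the age formula
  age_beta <- matrix(stats::runif(spec$age_causal * n_smp),
                     spec$age_causal, n_smp)
  beta[age_idx, ] <- age_beta
  age <- spec$age_intercept + spec$age_slope * colMeans(age_beta) +
    stats::rnorm(n_smp, sd = spec$age_noise_sd)
  # SNP probes: diploid genotypes under Hardy-Weinberg (p = 0.4) + noise
  geno <- matrix(sample(c(0, 0.5, 1), spec$n_snp_probes * n_smp,
                        replace = TRUE, prob = c(0.36, 0.48, 0.16)),
                 spec$n_snp_probes, n_smp)
  beta[snp_idx, ] <- pmin(pmax(geno + stats::rnorm(length(geno), sd = 0.01),
                               0), 1)
  # LUMP sites track per-sample purity on the 0.85 scale
  beta[lump_idx, ] <- pmin(pmax(
    rep(0.85 * purity, each = spec$n_lump_sites) +
      stats::rnorm(spec$n_lump_sites * n_smp, sd = 0.02), 0), 1)

  ## -- coverage with sex-linked structure ----------------------------------
  cov_factor <- matrix(1, spec$n_sites, n_smp)
  cov_factor[chrom == "chrX", sex == "male"] <- 0.5
  cov_factor[chrom == "chrY", sex == "male"] <- 0.5
  cov_factor[chrom == "chrY", sex == "female"] <- 0.01
  coverage <- matrix(stats::rnbinom(spec$n_sites * n_smp,
                                    mu = spec$coverage_mu * cov_factor,
                                    size = spec$coverage_size),
                     spec$n_sites, n_smp)

  ## -- assemble ------------------------------------------------------------
  sites <- cpg_site_table(chrom, pos,
                          is_snp_probe = role == "snp_probe")
  # cpg_site_table sorts by (chrom, pos); map planted roles along
  ord <- order(chrom, pos)
  role_sorted <- role[ord]
  samples <- sample_sheet(data.frame(
    sample_id = sprintf("s%02d", seq_len(n_smp)),
    group = group, sex = sex, age = round(age, 1),
    stringsAsFactors = FALSE))
  ds <- methylation_dataset(beta = beta[ord, , drop = FALSE],
                            sites = sites, samples = samples,
                            coverage = coverage[ord, , drop = FALSE],
                            platform = spec$platform)
  block_regions <- function(starts) {
    if (!length(starts)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    do.call(rbind, lapply(starts, function(s) {
      block <- s:(s + spec$block_size - 1L)
      data.frame(chrom = chrom[s], start = min(pos[block]) - 1L,
                 end = max(pos[block]) + 1L, stringsAsFactors = FALSE)
    }))
  }
  truth_sites <- data.frame(site_id = ds$sites$site_id, role = role_sorted,
                            stringsAsFactors = FALSE)
  truth_samples <- data.frame(sample_id = samples$sample_id, group = group,
                              sex = sex, age = age, purity = purity,
                              stringsAsFactors = FALSE)
  max_pos <- vapply(split(pos, chrom), max, numeric(1))
  list(dataset = ds,
       truth = list(sites = truth_sites, samples = truth_samples),
       region_sets = list(
         dmr = region_set("planted_dmr", block_regions(dmr_starts),
                          source = "generate_fixture"),
         dvr = region_set("planted_dvr", block_regions(dvr_starts),
                          source = "generate_fixture")),
       lump_sites = ds$sites$site_id[role_sorted == "lump"],
       chrom_sizes = stats::setNames(as.numeric(max_pos + 100),
                                     names(max_pos)),
       spec = spec)
}

#' Simulate an age-training cohort
#'
#' Generates a cohort whose chronological age is a linear function of the
#' mean beta of a small set of causal CpGs:
#' `age = intercept + slope * mean(causal betas) + N(0, noise_sd)`.
#' Causal betas are uniform on `[0, 1]`; all other sites carry unrelated
#' beta-distributed methylation. Used to validate elastic-net age-model
#' recovery.
#'
#' @param n_samples Cohort size (default 300).
#' @param n_sites Total sites (default 2000).
#' @param n_causal Causal CpG count (default 10).
#' @param slope,intercept,noise_sd Age model parameters (years).
#' @param seed Random seed.
#' @return List with `dataset` (complete, no missing values), `age_true`,
#'   and `causal_sites`.
#' @export
simulate_age_cohort <- function(n_samples = 300L, n_sites = 2000L,
                                n_causal = 10L, slope = 100,
                                intercept = 20, noise_sd = 2, seed = 1L) {
  with_seed(seed, {
    chrom <- sort(rep_len(paste0("chr", 1:5), n_sites))
    pos <- unlist(lapply(split(seq_along(chrom), chrom)[unique(chrom)],
                         function(idx) sort(sample.int(length(idx) * 60L,
                                                       length(idx)))),
                  use.names = FALSE)
    base_mean <- 0.03 + 0.94 * stats::rbeta(n_sites, 0.85, 0.85)
    beta <- matrix(rbeta_mean(n_sites * n_samples, rep(base_mean, n_samples),
                              50), n_sites, n_samples)
    causal <- sort(sample.int(n_sites, n_causal))
    beta[causal, ] <- stats::runif(n_causal * n_samples)
    age <- intercept + slope * colMeans(beta[causal, , drop = FALSE]) +
      stats::rnorm(n_samples, sd = noise_sd)
    sites <- cpg_site_table(chrom, pos)
    ds <- methylation_dataset(
      beta = beta, sites = sites,
      samples = sample_sheet(data.frame(
        sample_id = sprintf("a%03d", seq_len(n_samples)),
        age = age, stringsAsFactors = FALSE)),
      platform = "synthetic")
    ord <- order(chrom, pos)
    list(dataset = ds, age_true = age,
         causal_sites = sites$site_id[match(causal, ord)])
  })
}

#' Simulate sex-prediction features
#'
#' Draws the `(fX, fY)` log2 coverage-ratio features of a clean
#' sex-separable cohort: males at `(-1, -1)` (one X, one Y against diploid
#' autosomes) and females at `(0, -6)` (two X, residual Y signal), plus
#' Gaussian noise.
#'
#' @param n_per_sex Samples per sex (default 100).
#' @param noise_sd Feature noise (default 0.05).
#' @param seed Random seed.
#' @return `data.frame` with `sample_id`, `fX`, `fY`, `sex`.
#' @export
simulate_sex_features <- function(n_per_sex = 100L, noise_sd = 0.05,
                                  seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_sex
    sex <- rep(c("male", "female"), each = n_per_sex)
    fX <- ifelse(sex == "male", -1, 0) + stats::rnorm(n, sd = noise_sd)
    fY <- ifelse(sex == "male", -1, -6) + stats::rnorm(n, sd = noise_sd)
    data.frame(sample_id = sprintf("x%03d", seq_len(n)), fX = fX, fY = fY,
               sex = sex, stringsAsFactors = FALSE)
  })
}

#' Simulate reference profiles and cell-type mixtures
#'
#' Builds a reference panel of cell-type methylation profiles (betas drawn
#' uniformly per site and type) and bulk samples mixed from it with
#' Dirichlet weights plus Gaussian measurement noise, for validating the
#' constrained-least-squares deconvolution.
#'
#' @param n_samples Mixture count (default 100).
#' @param n_sites Shared site count (default 2000).
#' @param n_types Cell types (default 5).
#' @param noise_sd Measurement noise on the mixture betas (default 0.02).
#' @param alpha Dirichlet concentration (default 1, uniform simplex).
#' @param seed Random seed.
#' @return List with `dataset`, `reference` ([reference_profiles()]), and
#'   `weights_true` (samples x types).
#' @export
simulate_mixtures <- function(n_samples = 100L, n_sites = 2000L,
                              n_types = 5L, noise_sd = 0.02, alpha = 1,
                              seed = 1L) {
  with_seed(seed, {
    chrom <- sort(rep_len(paste0("chr", 1:5), n_sites))
    pos <- unlist(lapply(split(seq_along(chrom), chrom)[unique(chrom)],
                         function(idx) sort(sample.int(length(idx) * 60L,
                                                       length(idx)))),
                  use.names = FALSE)
    sites <- cpg_site_table(chrom, pos)
    types <- paste0("type", seq_len(n_types))
    R <- matrix(stats::runif(n_sites * n_types), n_sites, n_types,
                dimnames = list(sites$site_id, types))
    g <- matrix(stats::rgamma(n_samples * n_types, shape = alpha),
                n_samples, n_types)
    W <- g / rowSums(g)
    B <- R %*% t(W) + stats::rnorm(n_sites * n_samples, sd = noise_sd)
    B <- pmin(pmax(B, 0), 1)
    ds <- methylation_dataset(
      beta = B, sites = sites,
      samples = sample_sheet(data.frame(
        sample_id = sprintf("m%03d", seq_len(n_samples)),
        stringsAsFactors = FALSE)),
      platform = "synthetic")
    dimnames(W) <- list(ds$samples$sample_id, types)
    list(dataset = ds, reference = reference_profiles(R), weights_true = W)
  })
}
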