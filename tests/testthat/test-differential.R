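test_that("with the prior off the statistic equals the classical Student t", {
  set.seed(31)
  x <- matrix(rnorm(50 * 12), 50)
  cmp <- make_comparison(6, 6)
  res <- moderated_t_table(x, cmp, prior = FALSE)
  for (i in sample(50, 10)) {
    tt <- t.test(x[i, cmp$idx1], x[i, cmp$idx0], var.equal = TRUE)
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("variance prior recovers known (d0, s0^2) and shrinks correctly", {
  set.seed(32)
  d0 <- 8; s02 <- 0.04; dg <- 38
  s2 <- s02 * (rchisq(20000, dg) / dg) / (rchisq(20000, d0) / d0)
  pr <- methworks:::fit_variance_prior(s2, dg)
  expect_equal(pr$d0, d0, tolerance = 0.1)     # relative
  expect_equal(pr$s02, s02, tolerance = 0.05)  # relative
  # exactly equal unit variances drive d0 to infinity (full shrinkage)
  x <- matrix(rep(c(0, 1, 2, 3), 30), nrow = 30, byrow = TRUE)
  cmp <- make_comparison(2, 2)
  res <- moderated_t_table(x, cmp, prior = TRUE)
  expect_true(is.infinite(attr(res, "d0")))
})

test_that("moderated t agrees closely with an established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(33)
  x <- matrix(rnorm(2000 * 16, sd = rep(sqrt(0.04 *
    rf(2000, 14, 10)), 16)), 2000)
  cmp <- make_comparison(8, 8)
  res <- moderated_t_table(x, cmp, prior = TRUE)
  design <- cbind(1, rep(c(0, 1), each = 8))
  fit <- limma::eBayes(limma::lmFit(x, design))
  # same estimator family (scaled-F moment fit); allow small deviations
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.1 * fit$df.prior)
  expect_gt(cor(res$statistic, fit$t[, 2]), 0.999)
})

test_that("zero-variance units are flagged, not silently significant", {
  x <- rbind(c(1, 1, 1, 2, 2, 2), c(1, 1, 1, 1, 1, 1))
  cmp <- make_comparison(3, 3)
  expect_warning(res <- moderated_t_table(x, cmp, prior = FALSE),
                 "zero pooled variance")
  expect_equal(res$p[1], .Machine$double.xmin)
  expect_equal(res$p[2], 1)        # no difference, no variance
  expect_equal(res$statistic[2], 0)
})

test_that("diffvar equals the moderated machinery applied to deviations", {
  set.seed(34)
  x <- matrix(runif(200 * 14), 200)
  cmp <- make_comparison(7, 7)
  z <- x
  for (idx in list(cmp$idx0, cmp$idx1)) {
    med <- apply(x[, idx], 1, median)
    z[, idx] <- abs(x[, idx] - med)
  }
  dv <- diffvar_table(x, cmp, prior = FALSE)
  mt <- moderated_t_table(z, cmp, prior = FALSE)
  expect_identical(dv$statistic, mt$statistic)
  expect_identical(dv$p, mt$p)
  # var columns describe the original values
  expect_equal(dv$var0, apply(x[, cmp$idx0], 1, var))
  expect_equal(dv$var1, apply(x[, cmp$idx1], 1, var))
})

test_that("diffvar sign and symmetry conventions", {
  # identical value multisets in both groups: no variability difference
  x <- rbind(c(0.1, 0.5, 0.9, 0.9, 0.5, 0.1))
  cmp <- make_comparison(3, 3)
  dv <- diffvar_table(x, cmp, prior = FALSE)
  expect_equal(dv$statistic, 0)
  expect_equal(dv$p, 1)
  # more spread in group1 gives a positive statistic
  x2 <- rbind(c(0.5, 0.5, 0.5, 0.52, 0.1, 0.9, 0.3, 0.7))
  cmp2 <- make_comparison(4, 4)
  dv2 <- diffvar_table(x2, cmp2, prior = FALSE)
  expect_gt(dv2$statistic, 2)
})

test_that("diffvar null p-values are approximately uniform", {
  set.seed(35)
  x <- matrix(rnorm(5000 * 40), 5000)
  cmp <- make_comparison(20, 20)
  dv <- diffvar_table(x, cmp)
  ks <- suppressWarnings(ks.test(dv$p, "punif"))
  # median-centered deviations are mildly conservative at n = 20 per group,
  # so the null p distribution sits slightly above uniform
  expect_lt(unname(ks$statistic), 0.05)
  expect_gte(min(dv$p), 0)
})

test_that("Bartlett closed form matches stats::bartlett.test", {
  set.seed(36)
  # construct groups with sample variances exactly 1 and 4
  scale_to_var <- function(v, target) {
    v <- v - mean(v)
    v * sqrt(target / var(v)) }
  g0 <- scale_to_var(rnorm(20), 1)
  g1 <- scale_to_var(rnorm(20), 4)
  x <- matrix(c(g0, g1), 1)
  cmp <- make_comparison(20, 20)
  res <- ievora_table(x, cmp)
  ref <- bartlett.test(list(g0, g1))
  expect_equal(res$bartlett_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$bartlett_p, ref$p.value, tolerance = 1e-10)
  # equal variances: statistic exactly 0, p exactly 1
  xe <- matrix(c(g0, g0 + 5), 1)
  rese <- ievora_table(xe, cmp)
  expect_equal(rese$bartlett_stat, 0)
  expect_equal(rese$bartlett_p, 1)
})

test_that("iEVORA selects by q and t thresholds, ordered by t-test p", {
  set.seed(37)
  n <- 500
  x <- matrix(rnorm(n * 40), n)
  # plant 20 strong variability differences (sd ratio 6)
  planted <- 1:20
  x[planted, 21:40] <- x[planted, 21:40] * 6
  # give planted units a clear mean shift so the t regularizer keeps them
  x[planted, 21:40] <- x[planted, 21:40] + 5
  cmp <- make_comparison(20, 20)
  res <- ievora_table(x, cmp)   # default q < 0.001 and t-p < 0.05
  expect_true(all(which(res$selected) %in% planted))
  expect_gte(sum(res$selected), 15)
  sel <- res[res$selected, ]
  expect_identical(order(sel$t_p), order(sel$select_rank))
  expect_true(all(res$bartlett_q[res$selected] < 0.001 &
                    res$t_p[res$selected] < 0.05))
})

test_that("worst-rank combination follows the worked example and oracle", {
  tab <- data.frame(unit = c("A", "B", "C"),
                    p_adj = c(0.01, 0.02, 0.03),
                    diff = c(0.2, 0.5, 0.3),
                    log_quotient = c(0.3, 0.4, 0.1))
  # criterion ranks: p A=1,B=2,C=3; effect B=1,C=2,A=3; quotient B=1,A=2,C=3
  out <- combine_ranks(tab)
  expect_identical(out$unit, c("B", "A", "C"))
  expect_identical(out$combined_rank[match(c("A", "B", "C"), out$unit)],
                   c(3L, 2L, 3L))
  single <- combine_ranks(data.frame(unit = "z", p_adj = 0.5, diff = 1,
                                     log_quotient = 1))
  expect_equal(single$combined_rank, 1L)
})

test_that("combined ranks equal the naive sorted-rank oracle on random tables", {
  set.seed(38)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    tab <- data.frame(unit = paste0("u", seq_len(n)),
                      p_adj = round(runif(n), 2),   # rounding forces ties
                      diff = round(rnorm(n), 1),
                      log_quotient = round(rnorm(n), 1))
    out <- combine_ranks(tab)
    m <- match(tab$unit, out$unit)
    expect_identical(out$rank_p[m], rank_min_oracle(tab$p_adj))
    expect_identical(out$rank_effect[m], rank_min_oracle(-abs(tab$diff)))
    expect_identical(out$rank_quotient[m],
                     rank_min_oracle(-abs(tab$log_quotient)))
    expect_identical(out$combined_rank,
                     pmax(out$rank_p, out$rank_effect, out$rank_quotient))
    expect_false(is.unsorted(out$combined_rank))
  }
})

test_that("combined ranks are invariant under monotone criterion transforms", {
  set.seed(39)
  tab <- data.frame(unit = paste0("u", 1:30), p_adj = runif(30),
                    diff = rnorm(30), log_quotient = rnorm(30))
  out1 <- combine_ranks(tab)
  tab2 <- tab
  tab2$p_adj <- tab$p_adj^3                     # strictly monotone
  tab2$diff <- sign(tab$diff) * abs(tab$diff)^2 # preserves |.| order
  out2 <- combine_ranks(tab2)
  expect_identical(out1$unit, out2$unit)
  expect_identical(out1$combined_rank, out2$combined_rank)
  # permutation invariance
  perm <- sample(30)
  out3 <- combine_ranks(tab[perm, ])
  expect_identical(out3$combined_rank[match(out1$unit, out3$unit)],
                   out1$combined_rank)
})

test_that("missing criterion values rank last with a recorded count", {
  tab <- data.frame(unit = c("a", "b", "c"), p_adj = c(0.1, NA, 0.2),
                    diff = c(1, 2, 3), log_quotient = c(1, 2, 3))
  out <- combine_ranks(tab)
  expect_equal(attr(out, "n_missing"), 1L)
  expect_equal(out$rank_p[out$unit == "b"], 3L)
})

test_that("auto rank cutoff counts BH-significant units", {
  tab <- combine_ranks(data.frame(unit = c("a", "b", "c"),
                                  p_adj = c(0.01, 0.02, 0.2),
                                  diff = c(1, 2, 3),
                                  log_quotient = c(1, 2, 3)))
  expect_equal(as.integer(auto_rank_cutoff(tab, fdr = 0.05)), 2L)
  tab1 <- combine_ranks(data.frame(unit = "a", p_adj = 1, diff = 0,
                                   log_quotient = 0))
  expect_equal(as.integer(auto_rank_cutoff(tab1)), 0L)
})

test_that("BH adjustment matches its step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.7), 0.7)
  expect_error(adjust_bh(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_bh(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(40)
  for (rep in 1:20) {
    p <- runif(sample(2:100, 1))
    adj <- adjust_bh(p)
    # definition: adj_i = min over j with p_j >= p_i of m * p_(j) / rank
    ord <- order(p)
    m <- length(p)
    defn <- numeric(m)
    for (i in seq_len(m)) {
      pos <- which(ord == i)
      defn[i] <- min(1, min(m * p[ord[pos:m]] / (pos:m)))
    }
    expect_equal(adj, defn, tolerance = 1e-12)
  }
})

test_that("methylation and variability share one ranking code path", {
  set.seed(41)
  x <- matrix(runif(300 * 20), 300)
  cmp <- make_comparison(10, 10)
  dm <- differential_methylation(x, cmp)
  dv <- differential_variability(x, cmp)
  expect_identical(dm$combined_rank,
                   pmax(dm$rank_p, dm$rank_effect, dm$rank_quotient))
  expect_identical(dv$combined_rank,
                   pmax(dv$rank_p, dv$rank_effect, dv$rank_quotient))
  # same scheme applied to different criterion triplets
  redo <- combine_ranks(dm[order(match(dm$unit, paste0("unit",
    seq_len(300)))), c("unit", "p_adj", "diff", "log_quotient")])
  expect_identical(redo$unit, dm$unit)
  iv <- differential_variability(x, cmp, method = "ievora")
  expect_true(all(c("bartlett_q", "combined_rank") %in% names(iv)))
})
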