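test_that("age prediction applies weights with training-mean substitution", {
  model <- structure(list(
    intercept = 10,
    coefficients = c("chr1:10:+" = 5),
    training_means = c("chr1:10:+" = 0.6),
    alpha = 0.5, lambda = 0.1,
    metadata = list(platform = "synthetic", n_samples = 10)
  ), class = "AgeModel")
  ds <- make_dataset(matrix(0.4, 1, 1), pos = 10L)
  pred <- predict_age(model, ds, min_overlap = 0)
  expect_equal(pred$age_pred, 12.0)            # 10 + 5 * 0.4
  expect_equal(pred$n_substituted, 0L)
  # site absent: substitute the training mean
  ds2 <- make_dataset(matrix(0.4, 1, 1), pos = 99L)
  pred2 <- predict_age(model, ds2, min_overlap = 0)
  expect_equal(pred2$age_pred, 13.0)           # 10 + 5 * 0.6
  expect_equal(pred2$n_substituted, 1L)
  expect_error(predict_age(model, ds2, min_overlap = 0.5), "model sites")
})

test_that("when every model site is missing the prediction is constant", {
  model <- structure(list(
    intercept = 30,
    coefficients = c("chr1:10:+" = 5, "chr1:20:+" = -2),
    training_means = c("chr1:10:+" = 0.5, "chr1:20:+" = 0.25),
    alpha = 0.5, lambda = 0.1, metadata = list()
  ), class = "AgeModel")
  beta <- matrix(NA_real_, 2, 3)
  ds <- make_dataset(beta, pos = c(10L, 20L))
  pred <- predict_age(model, ds)
  expect_equal(pred$age_pred, rep(30 + 5 * 0.5 - 2 * 0.25, 3))
  expect_equal(pred$n_substituted, rep(2L, 3))
})

test_that("elastic-net age model recovers a planted linear clock", {
  ac <- simulate_age_cohort(n_samples = 150, n_sites = 600, noise_sd = 2,
                            seed = 51)
  train <- subset_dataset(ac$dataset, samples = 1:100)
  test <- subset_dataset(ac$dataset, samples = 101:150)
  model <- train_age_model(train, seed = 1)
  pred <- predict_age(model, test)
  expect_gt(cor(pred$age_pred, ac$age_true[101:150]), 0.9)
  # in-sample predictions equal the fit's own predictions
  pin <- predict_age(model, train)
  expect_equal(pin$age_pred,
               unname(model$intercept + drop(model$coefficients %*%
                 train$beta[names(model$coefficients), ])),
               tolerance = 1e-12)
  # noiseless, near-unpenalized limit: essentially exact recovery
  ac0 <- simulate_age_cohort(n_samples = 80, n_sites = 40, noise_sd = 0,
                             seed = 52)
  m0 <- train_age_model(ac0$dataset, alpha = 0.5,
                        lambda_grid = c(1e-4, 1e-5, 1e-6))
  p0 <- predict_age(m0, ac0$dataset)
  expect_lt(max(abs(p0$age_pred - ac0$age_true)), 0.5)
})

test_that("age-model training is invariant under sample permutation", {
  ac <- simulate_age_cohort(n_samples = 60, n_sites = 200, seed = 53)
  m1 <- train_age_model(ac$dataset, cv_folds = 5)
  perm <- withr::with_seed(1, sample(60))
  dsp <- subset_dataset(ac$dataset, samples = perm)
  m2 <- train_age_model(dsp, cv_folds = 5)
  expect_equal(m1$lambda, m2$lambda)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
})

test_that("age-model guards: constant age, missing betas, small cohorts", {
  ac <- simulate_age_cohort(n_samples = 30, n_sites = 50, seed = 54)
  expect_error(train_age_model(ac$dataset, ages = rep(50, 30)), "constant")
  ds_na <- ac$dataset
  ds_na$beta[1, 1] <- NA
  expect_error(train_age_model(ds_na), "impute_missing")
  expect_error(train_age_model(subset_dataset(ac$dataset, samples = 1:5)),
               "at least 10")
})

test_that("age models round-trip through their TSV serialization exactly", {
  ac <- simulate_age_cohort(n_samples = 40, n_sites = 100, seed = 55)
  model <- train_age_model(ac$dataset)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_age_model(model, f)
  back <- read_age_model(f)
  expect_identical(back$coefficients, model$coefficients)
  expect_identical(back$training_means, model$training_means)
  expect_identical(back$intercept, model$intercept)
  expect_identical(back$lambda, model$lambda)
})

test_that("sex features are log2 signal ratios against autosomes", {
  mkcov <- function(auto, x, y) {
    # 10 autosomal, 10 chrX, 10 chrY sites with exact mean coverages
    cov <- matrix(c(rep(auto, 10), rep(x, 10), rep(y, 10)), ncol = 1)
    make_dataset(matrix(0.5, 30, 1), coverage = round(cov),
                 chrom = rep(c("chr1", "chrX", "chrY"), each = 10),
                 pos = rep(seq(10, 100, 10), 3))
  }
  f0 <- sex_features(mkcov(30, 30, 30))
  expect_equal(c(f0$fX, f0$fY), c(0, 0), tolerance = 1e-9)
  f1 <- sex_features(mkcov(30, 15, 15))
  expect_equal(c(f1$fX, f1$fY), log2(15.01 / 30.01) * c(1, 1))
  # chrY mean 0.3 from coverage (3,0,...,0)
  ds <- mkcov(30, 30, 0)
  ds$coverage[ds$sites$chrom == "chrY", 1][1] <- 3L
  f2 <- sex_features(ds)
  expect_equal(f2$fY, log2(0.31 / 30.01))
  expect_equal(f2$fY, -6.6, tolerance = 0.02)
  expect_error(sex_features(make_dataset(matrix(0.5, 2, 1),
                                         coverage = matrix(5L, 2, 1))),
               "chrX")
})

test_that("sex classifier separates a clean cohort and respects confidence", {
  feats <- simulate_sex_features(n_per_sex = 100, seed = 56)
  train_idx <- c(1:50, 101:150)
  model <- train_sex_model(feats[train_idx, ], feats$sex[train_idx])
  pred <- predict_sex(model, feats[-train_idx, ])
  expect_identical(pred$predicted, feats$sex[-train_idx])  # 100% held out
  # a sample exactly on the decision boundary is "unknown" at 0.8
  co <- model$coefficients
  boundary <- data.frame(fX = 0.5, fY = -(co[1] + co[2] * 0.5) / co[3])
  expect_identical(predict_sex(model, boundary, confidence = 0.8)$predicted,
                   "unknown")
  expect_error(train_sex_model(feats[1:50, ], feats$sex[1:50]),
               "two classes")
})

test_that("sex prediction is invariant under a global coverage rescale", {
  fix <- generate_fixture(fixture_spec(n_sites = 800, seed = 57))
  f1 <- sex_features(fix$dataset)
  ds2 <- fix$dataset
  ds2$coverage <- ds2$coverage * 3L
  f2 <- sex_features(ds2)
  expect_equal(f1$fX, f2$fX, tolerance = 0.01)
  expect_equal(f1$fY, f2$fY, tolerance = 0.05)
  model <- train_sex_model(f1, fix$dataset$samples$sex)
  expect_identical(predict_sex(model, f2)$predicted,
                   predict_sex(model, f1)$predicted)
})

test_that("genetic noise measures deviation from diploid beta targets", {
  mk <- function(b) make_dataset(matrix(b, length(b), 1),
                                 is_snp_probe = TRUE)
  expect_equal(genetic_noise(mk(c(0, 0.5, 1)))$genetic_noise, 0)
  expect_equal(genetic_noise(mk(0.25))$genetic_noise, 0.25)
  expect_equal(genetic_noise(mk(c(0.1, 0.45, 0.9)))$genetic_noise,
               mean(c(0.1, 0.05, 0.1)))
  # symmetry under b -> 1 - b
  set.seed(58)
  b <- runif(20)
  expect_equal(genetic_noise(mk(b))$genetic_noise,
               genetic_noise(mk(1 - b))$genetic_noise)
  # sex-chromosome SNP probes are excluded; none left -> error
  ds <- make_dataset(matrix(0.2, 1, 1), chrom = "chrX", is_snp_probe = TRUE)
  expect_error(genetic_noise(ds), "autosomal")
})

test_that("LUMP purity is the capped scaled mean over available sites", {
  mk <- function(b) {
    ds <- make_dataset(matrix(b, length(b), 1))
    list(ds = ds, sites = ds$sites$site_id)
  }
  z <- mk(rep(0, 5))
  r0 <- lump_purity(z$ds, z$sites)
  expect_equal(r0$purity, 0)
  expect_equal(r0$immune_fraction, 1)
  hi <- mk(rep(0.9, 5))
  expect_equal(lump_purity(hi$ds, hi$sites)$purity, 1)   # cap at 1
  mid <- mk(rep(0.425, 4))
  expect_equal(lump_purity(mid$ds, mid$sites)$purity, 0.5)
  expect_error(lump_purity(z$ds, c("chrZ:1:+")), "LUMP sites")
  # monotone in mean lump beta; complement identity exact
  set.seed(59)
  for (m in seq(0.05, 0.95, 0.15)) {
    d <- mk(rep(m, 6))
    r <- lump_purity(d$ds, d$sites)
    expect_equal(r$purity + r$immune_fraction, 1)
  }
})

test_that("deconvolution recovers exact and noisy mixtures", {
  set.seed(60)
  # noiseless 2-type mixture with w* = (0.3, 0.7)
  R <- matrix(runif(100 * 2), 100,
              dimnames = list(sprintf("chr1:%d:+", seq(10, 1000, 10)),
                              c("t1", "t2")))
  w_star <- c(0.3, 0.7)
  b <- drop(R %*% w_star)
  ds <- make_dataset(matrix(b, 100, 1), pos = seq(10L, 1000L, 10L))
  res <- deconvolve_celltypes(ds, reference_profiles(R))
  expect_equal(unlist(res[1, c("t1", "t2")]), c(t1 = 0.3, t2 = 0.7),
               tolerance = 1e-6)
  expect_lt(res$residual, 1e-8)
  # b equal to one reference column
  ds2 <- make_dataset(matrix(R[, 2], 100, 1), pos = seq(10L, 1000L, 10L))
  res2 <- deconvolve_celltypes(ds2, reference_profiles(R), "sum_eq_one")
  expect_equal(unlist(res2[1, c("t1", "t2")]), c(t1 = 0, t2 = 1),
               tolerance = 1e-6)
  # duplicate reference columns are refused by name
  Rdup <- cbind(R, t3 = R[, 1])
  expect_error(deconvolve_celltypes(ds, reference_profiles(Rdup)),
               "t1.*t3|identical")
  # noisy Dirichlet mixtures: small mean absolute error
  mx <- simulate_mixtures(n_samples = 40, n_sites = 800, noise_sd = 0.02,
                          seed = 61)
  dw <- deconvolve_celltypes(mx$dataset, mx$reference)
  err <- mean(abs(as.matrix(dw[, colnames(mx$weights_true)]) -
                    mx$weights_true))
  expect_lt(err, 0.05)
})

test_that("reference profiles round-trip and reject invalid panels", {
  mx <- simulate_mixtures(n_samples = 3, n_sites = 50, seed = 62)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reference_profiles(mx$reference, f)
  back <- read_reference_profiles(f)
  expect_equal(unclass(back)[, ], unclass(mx$reference)[, ],
               tolerance = 1e-12)
  expect_error(reference_profiles(matrix(0.5, 3, 1)), "2 cell types")
  bad <- matrix(c(0.5, NA), 1, 2,
                dimnames = list("s", c("a", "b")))
  expect_error(reference_profiles(bad), "missing")
})
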