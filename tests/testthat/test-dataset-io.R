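test_that("bismark coverage parsing recomputes beta from counts", {
  f <- withr::local_tempfile(fileext = ".cov")
  write_cov_file(f, c("chr1", "chr1", "chr2"), c(100L, 200L, 50L),
                 n_meth = c(3L, 0L, 5L), n_unmeth = c(1L, 0L, 0L))
  rec <- read_bismark_cov(f, sample_id = "a")
  expect_equal(rec$pos, c(100L, 200L, 50L))
  expect_equal(rec$coverage, c(4L, 0L, 5L))
  expect_equal(rec$beta, c(0.75, NA, 1.0))
  expect_identical(attr(rec, "sample_id"), "a")
})

test_that("bismark betas are forced by count ratios", {
  f <- withr::local_tempfile(fileext = ".cov")
  write_cov_file(f, rep("chr1", 3), c(10L, 20L, 30L),
                 n_meth = c(5L, 2L, 0L), n_unmeth = c(0L, 2L, 10L))
  rec <- read_bismark_cov(f)
  expect_equal(rec$beta, c(1.0, 0.5, 0.0))
})

test_that("bismark parser rejects bad input and warns on stale percentages", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t10\t10\t50\t1\t1", "chr1\t20\t20\t50"), f)
  expect_error(read_bismark_cov(f), "malformed")

  f2 <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t10\t10\t50\t-1\t3", f2)
  expect_error(read_bismark_cov(f2), "negative")

  f3 <- withr::local_tempfile(fileext = ".cov")
  write_cov_file(f3, "chr1", 10L, n_meth = 3L, n_unmeth = 1L, pct = 10)
  expect_warning(rec <- read_bismark_cov(f3), "disagrees")
  expect_equal(rec$beta, 0.75)  # counts win
})

test_that("beta tables ingest identically and reject bad values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\ta\tb", "chr1\t10\t0.1\t0.9",
               "chr1\t20\t0.5\t0.5"), f)
  ds <- read_beta_table(f)
  expect_equal(unname(ds$beta), matrix(c(0.1, 0.5, 0.9, 0.5), 2),
               tolerance = 0)
  expect_true(all(is.na(ds$coverage)))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\ta", "chr1\t10\t1.2"), f2)
  expect_error(read_beta_table(f2), "outside \\[0,1\\]")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\ta\tb", "chr1\t10\tNA\t0.4"), f3)
  ds3 <- read_beta_table(f3)
  expect_true(is.na(ds3$beta[1, "a"]))
  expect_equal(ds3$beta[1, "b"], 0.4)

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\ta", "chr1\t10\t0.2", "chr1\t10\t0.3"), f4)
  expect_error(read_beta_table(f4), "duplicated site key")
})

test_that("sample sheets are typed by parseability, not guessed", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tsex\tmix",
               "s1\t34\tmale\t1", "s2\t56\tfemale\t2", "s3\tNA\tfemale\tx"),
             f)
  sh <- read_sample_sheet(f)
  types <- attr(sh, "col_types")
  expect_identical(unname(types[c("age", "sex", "mix")]),
                   c("numeric", "categorical", "categorical"))
  expect_equal(sh$age, c(34, 56, NA))
  expect_equal(length(unique(sh$sex)), 2L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage", "s1\t3", "s1\t4"), f2)
  expect_error(read_sample_sheet(f2), "duplicate sample_id")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tage", f3)
  expect_error(read_sample_sheet(f3), "empty")
})

test_that("dataset construction enforces the zero-coverage and range rules", {
  beta <- matrix(c(0.4, 0.5, 0.6, 0.7), 2)
  cov <- matrix(c(10L, 0L, 5L, 3L), 2)
  ds <- make_dataset(beta, coverage = cov)
  expect_true(is.na(ds$beta[2, 1]))          # coverage 0 -> missing
  expect_equal(ds$beta[1, 1], 0.4)
  expect_error(make_dataset(matrix(c(1.4, 0.5), 1)), "outside")
  expect_error(make_dataset(matrix(0.5, 2, 2),
                            coverage = matrix(-1L, 2, 2)), "negative")
})

test_that("bedGraph export uses 0-based half-open intervals, omits missing", {
  ds <- make_dataset(matrix(c(0.75, NA), 2), pos = c(100L, 200L))
  dir <- withr::local_tempdir()
  paths <- export_tracks(ds, dir)
  lines <- readLines(paths[1])
  expect_equal(lines, "chr1\t99\t100\t0.75")
})

test_that("export -> re-import round-trips every non-missing beta exactly", {
  set.seed(42)
  beta <- matrix(runif(60), 20)
  beta[sample(60, 8)] <- NA
  ds <- make_dataset(beta, chrom = rep(c("chr1", "chr2"), each = 10))
  dir <- withr::local_tempdir()
  paths <- export_tracks(ds, dir)
  recs <- lapply(seq_along(paths), function(i)
    read_bedgraph(paths[i], sample_id = ds$samples$sample_id[i]))
  ds2 <- assemble_dataset(recs, platform = "synthetic")
  common <- intersect(rownames(ds$beta), rownames(ds2$beta))
  expect_identical(sort(common),
                   sort(rownames(ds$beta)[rowSums(!is.na(ds$beta)) > 0]))
  for (id in ds$samples$sample_id) {
    orig <- ds$beta[common, id]
    back <- ds2$beta[common, id]
    keep <- !is.na(orig)
    expect_identical(unname(back[keep]), unname(orig[keep]))
  }
})

test_that("dataset directory serialization restores the object exactly", {
  fix <- generate_fixture(fixture_spec(n_sites = 200, n_dmc = 10, n_dvc = 10,
                                       n_snp_probes = 5, n_lump_sites = 10,
                                       seed = 4))
  dir <- withr::local_tempdir()
  write_dataset_dir(fix$dataset, dir)
  ds2 <- read_dataset_dir(dir)
  expect_identical(ds2$beta, fix$dataset$beta)
  expect_identical(ds2$coverage, fix$dataset$coverage)
  expect_identical(ds2$sites$site_id, fix$dataset$sites$site_id)
  expect_identical(ds2$platform, fix$dataset$platform)
})

test_that("minus-strand records collapse onto the +strand CpG when asked", {
  rec <- data.frame(chrom = "chr1", pos = c(100L, 101L),
                    strand = c("+", "-"), coverage = c(4L, 6L),
                    beta = c(0.5, 0.5), stringsAsFactors = FALSE)
  attr(rec, "sample_id") <- "s1"
  ds <- assemble_dataset(list(rec), merge_strands = TRUE)
  expect_equal(n_sites(ds), 1L)
  expect_equal(unname(ds$coverage[1, 1]), 10L)
  expect_equal(unname(ds$beta[1, 1]), 0.5)
})
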