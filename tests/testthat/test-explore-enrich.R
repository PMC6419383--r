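test_that("PCA separates planted clusters and conserves variance", {
  set.seed(71)
  n <- 200
  x <- matrix(rnorm(n * 20, sd = 0.05), n)
  x[1:100, 11:20] <- x[1:100, 11:20] + 2    # cluster shift on half the units
  emb <- pca_embed(x, n_components = 3)
  expect_gt(emb$proportion[1], 0.9)
  pc1 <- emb$coords[, 1]
  expect_true(max(pc1[1:10]) < min(pc1[11:20]) ||
                min(pc1[1:10]) > max(pc1[11:20]))
  # explained variances sum to the total unit variance
  total <- sum(apply(t(x) , 2, var))
  expect_equal(sum(emb$explained_variance), total, tolerance = 1e-8)
  # duplicated sample gets identical coordinates
  xd <- cbind(x, x[, 1])
  embd <- pca_embed(xd)
  expect_equal(embd$coords[21, ], embd$coords[1, ], tolerance = 1e-8)
  expect_error(pca_embed(matrix(c(1, NA), 1)), "missing")
})

test_that("component-annotation association flags real signals only", {
  set.seed(72)
  n <- 60
  x <- matrix(rnorm(500 * n), 500)
  emb <- pca_embed(x, n_components = 2)
  sheet <- sample_sheet(data.frame(
    sample_id = paste0("s", 1:n),
    tracked = emb$coords[, 1] + rnorm(n, sd = 1e-3),
    constant = rep("one", n),
    stringsAsFactors = FALSE))
  expect_message(res <- associate_components(emb$coords, sheet), "constant")
  expect_lt(res$p["PC2", "tracked"], 1)
  expect_lt(res$p["PC1", "tracked"], 1e-10)
  expect_true(res$significant["PC1", "tracked"])
  expect_identical(res$skipped, "constant")
  # categorical two-level annotation is symmetric in its level labels
  grp <- rep(c("a", "b"), each = n / 2)
  sh1 <- sample_sheet(data.frame(sample_id = paste0("s", 1:n), g = grp,
                                 stringsAsFactors = FALSE))
  sh2 <- sample_sheet(data.frame(sample_id = paste0("s", 1:n),
                                 g = rev(grp), stringsAsFactors = FALSE))
  r1 <- associate_components(emb$coords, sh1)
  r2 <- associate_components(emb$coords[n:1, , drop = FALSE], sh2)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  sh_bad <- sample_sheet(data.frame(sample_id = paste0("s", 1:n),
                                    k = rep("x", n), stringsAsFactors = FALSE))
  expect_error(suppressMessages(associate_components(emb$coords, sh_bad)),
               "no testable")
})

test_that("null annotations are flagged at roughly the nominal rate", {
  set.seed(73)
  n <- 40
  coords <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "PC1"))
  hits <- 0L
  runs <- 400
  for (r in seq_len(runs)) {
    sheet <- sample_sheet(data.frame(sample_id = paste0("s", 1:n),
                                     noise = rnorm(n),
                                     stringsAsFactors = FALSE))
    res <- associate_components(coords, sheet, alpha = 0.05)
    hits <- hits + sum(res$significant)
  }
  rate <- hits / runs
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / runs))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / runs))
})

# helper: catalogue over a 1-region-per-unit universe so that overlap
# counting reduces to simple set membership
toy_universe <- function(N) {
  region_set("universe", data.frame(chrom = "chr1",
                                    start = seq(0, by = 10, length.out = N),
                                    end = seq(5, by = 10, length.out = N)))
}
pick_regions <- function(universe, idx, name) {
  region_set(name, universe$regions[idx, c("chrom", "start", "end")])
}

test_that("enrichment p equals the hypergeometric tail on a worked table", {
  N <- 100
  uni <- toy_universe(N)
  set_idx <- 1:20
  query_idx <- c(1:8, 50, 60)      # 8 of 10 in the set
  catalog <- enrichment_catalog(list(s = pick_regions(uni, set_idx, "s")),
                                universe = uni)
  res <- region_enrichment(pick_regions(uni, query_idx, "q"), catalog)
  expect_equal(res$a, 8)
  oracle <- sum(dhyper(8:10, 20, 80, 10))
  expect_equal(res$fisher_p, oracle, tolerance = 1e-12)
  expect_equal(res$fisher_p,
               fisher.test(matrix(c(8, 2, 12, 78), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-10)
})

test_that("a query identical to a catalogue set attains the best rank", {
  set.seed(74)
  uni <- toy_universe(80)
  sets <- list(match = pick_regions(uni, 1:10, "match"),
               other = pick_regions(uni, 30:70, "other"),
               small = pick_regions(uni, 75:78, "small"))
  catalog <- enrichment_catalog(sets, universe = uni)
  res <- region_enrichment(pick_regions(uni, 1:10, "q"), catalog)
  expect_identical(res$name[1], "match")
  expect_equal(res$max_rank[1], min(res$max_rank))
  # disjoint set: zero support, Haldane-corrected OR, depletion-side p
  dis <- res[res$name == "small", ]
  expect_equal(dis$a, 0)
  expect_gte(dis$fisher_p, 0.5)
  expect_equal(dis$odds_ratio,
               (0.5 * (80 - 10 - 4 + 0.5)) / ((10 + 0.5) * (4 + 0.5)))
  # catalogue order invariance
  res2 <- region_enrichment(pick_regions(uni, 1:10, "q"),
                            enrichment_catalog(rev(sets), universe = uni))
  m <- match(res$name, res2$name)
  expect_equal(res2$fisher_p[m], res$fisher_p)
  expect_equal(res2$max_rank[m], res$max_rank)
})

test_that("query regions outside the universe are dropped with a count", {
  uni <- toy_universe(30)
  q <- region_set("q", data.frame(chrom = c("chr1", "chr9"),
                                  start = c(0, 1000), end = c(5, 1100)))
  catalog <- enrichment_catalog(list(s = pick_regions(uni, 1:5, "s")), uni)
  res <- region_enrichment(q, catalog)
  expect_equal(attr(res, "n_query_dropped"), 1L)
  expect_equal(attr(res, "query_size"), 1L)
  q_bad <- region_set("qb", data.frame(chrom = "chr9", start = 0, end = 5))
  expect_error(region_enrichment(q_bad, catalog), "universe")
})

test_that("catalogues load from an indexed directory of BED files", {
  dir <- withr::local_tempdir()
  uni <- toy_universe(20)
  write_region_set(uni, file.path(dir, "universe.bed"))
  write_region_set(pick_regions(uni, 1:5, "tf_sites"),
                   file.path(dir, "tf.bed"))
  writeLines(c("file\tname\tcollection\tdescription",
               "tf.bed\ttf_sites\ttfbs\tsynthetic factor sites"),
             file.path(dir, "index.tsv"))
  cat2 <- load_catalog(dir)
  expect_identical(names(cat2$sets), "tf_sites")
  expect_equal(length(cat2$universe), 20L)
  res <- region_enrichment(pick_regions(uni, 1:5, "q"), cat2)
  expect_identical(res$collection, "tfbs")
})
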