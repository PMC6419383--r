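# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_mw <- function(..., class = "methworks_error", data = NULL) {
  cond <- structure(
    class = c(class, "methworks_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1), data = data)
  )
  stop(cond)
}

is_sex_chromosome <- function(chrom) {
  chrom %in% c("chrX", "chrY", "X", "Y")
}

is_autosome <- function(chrom) !is_sex_chromosome(chrom)

# Site key "chrom:pos:strand"; "*" strand is keyed as "+" so that unstranded
# records match +strand records across platforms.
site_key <- function(chrom, pos, strand = "*") {
  strand <- ifelse(strand == "*", "+", strand)
  paste(chrom, pos, strand, sep = ":")
}

# Deterministic 31-bit string hash (djb2 variant). Used for cross-validation
# fold assignment so that folds depend on sample identity, not sample order.
string_hash <- function(x) {
  vapply(x, function(s) {
    h <- 5381
    for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Row-wise variance without extra dependencies (denominator n - 1).
row_vars <- function(x, na.rm = FALSE) {
  n <- if (na.rm) rowSums(!is.na(x)) else rep(ncol(x), nrow(x))
  mu <- rowMeans(x, na.rm = na.rm)
  ss <- rowSums((x - mu)^2, na.rm = na.rm)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

row_medians <- function(x) apply(x, 1L, stats::median)

# Full-precision number formatting for text exports (round-trips doubles).
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_mw(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_mw(sprintf("'%s' must be a single number in [%s, %s]", name, min, max))
  invisible(x)
}

# Run an expression under a local RNG state derived from `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# take an explicit seed and go through this helper.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
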