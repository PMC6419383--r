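#' Construct a region set
#'
#' A named collection of genomic intervals in 0-based half-open coordinates
#' (BED convention). Regions are validated (`start < end`), sorted by
#' `(chrom, start)`, and labels, when present, must be unique.
#'
#' @param name Name of the set.
#' @param regions `data.frame` with columns `chrom`, `start`, `end` and
#'   optional `label`.
#' @param source Provenance string (file path or generator tag).
#' @return An object of class `RegionSet`.
#' @export
region_set <- function(name, regions, source = "in-memory") {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions)))
    stop_mw("regions need columns chrom, start, end")
  regions$chrom <- as.character(regions$chrom)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  bad <- which(regions$start >= regions$end)
  if (length(bad))
    stop_mw("region ", bad[1L], " has start >= end (",
            regions$chrom[bad[1L]], ":", regions$start[bad[1L]], "-",
            regions$end[bad[1L]], ")")
  if (any(regions$start < 0L)) stop_mw("negative region start")
  if ("label" %in% names(regions) && anyDuplicated(regions$label))
    stop_mw("duplicate region labels")
  regions <- regions[order(regions$chrom, regions$start, regions$end), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  structure(list(name = name, regions = regions, source = source),
            class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat("RegionSet '", x$name, "': ", nrow(x$regions), " regions on ",
      length(unique(x$regions$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
length.RegionSet <- function(x) nrow(x$regions)

#' Tile chromosomes into fixed windows
#'
#' Produces genomic tiling regions: non-overlapping windows when
#' `window == step`, sliding windows when `step < window`. The last partial
#' tile at a chromosome end is retained, so for `window == step` the tile
#' count per chromosome is `ceiling(length / step)`.
#'
#' @param chrom_sizes Named numeric vector (or two-column `data.frame`) of
#'   chromosome lengths in bp.
#' @param window Window width in bp.
#' @param step Stride in bp; `1 <= step <= window`.
#' @return A `RegionSet` of 0-based half-open tiles.
#' @export
tile_genome <- function(chrom_sizes, window, step = window) {
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- stats::setNames(chrom_sizes[[2L]], chrom_sizes[[1L]])
  if (length(chrom_sizes) == 0L) stop_mw("empty chrom_sizes")
  if (any(chrom_sizes <= 0)) stop_mw("chromosome lengths must be positive")
  check_number(window, "window", 1)
  check_number(step, "step", 1, window)
  tiles <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    starts <- seq.int(0L, len - 1L, by = step)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + window, len),
               stringsAsFactors = FALSE)
  })
  region_set(sprintf("tiles_%dbp", as.integer(window)), do.call(rbind, tiles),
             source = sprintf("tile_genome(window=%d, step=%d)",
                              as.integer(window), as.integer(step)))
}

#' Load a region set from a BED file
#'
#' Reads BED3/BED4 (0-based half-open); the optional fourth column becomes
#' the region label. Zero-length or inverted intervals are rejected with
#' their line number; output is sorted.
#'
#' @param path BED file.
#' @param name Name for the set (defaults to the file name).
#' @return A `RegionSet`.
#' @export
load_region_set <- function(path, name = sub("\\.bed$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_mw("no regions in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop_mw("line ", which(nf < 3L)[1L], " of ", path,
            " has fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop_mw("non-numeric coordinates at line ", bad[1L], " of ", path)
  bad <- which(start >= end)
  if (length(bad))
    stop_mw("start >= end at line ", bad[1L], " of ", path)
  regions <- data.frame(chrom = chrom, start = start, end = end,
                        stringsAsFactors = FALSE)
  if (all(nf >= 4L)) regions$label <- vapply(parts, `[[`, "", 4L)
  region_set(name, regions, source = path)
}

#' Write a region set to BED
#'
#' @param rs A `RegionSet`.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(rs, path) {
  r <- rs$regions
  lines <- if ("label" %in% names(r)) {
    sprintf("%s\t%d\t%d\t%s", r$chrom, r$start, r$end, r$label)
  } else {
    sprintf("%s\t%d\t%d", r$chrom, r$start, r$end)
  }
  writeLines(lines, path)
  invisible(path)
}

regions_to_granges <- function(rs) {
  r <- if (inherits(rs, "RegionSet")) rs$regions else rs
  GenomicRanges::GRanges(r$chrom,
                         IRanges::IRanges(start = r$start + 1L, end = r$end))
}

sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(start = sites$pos, width = 1L))
}

#' Aggregate CpG methylation over a region set
#'
#' Summarizes the site-level beta matrix into one value per region and
#' sample. A CpG at 1-based position p belongs to region `[s, e)` iff
#' `s <= p - 1 < e` (point overlap of the cytosine; strand is ignored, and
#' a CpG may contribute to several overlapping regions). `mode = "mean"`
#' averages the non-missing member betas; `mode = "coverage_weighted"`
#' weights each cell by its read coverage (cells with missing coverage get
#' weight 1). A (region, sample) cell with no observed member CpGs is
#' missing; regions with fewer than `min_cpgs` member sites in the dataset
#' are all-missing.
#'
#' @param dataset A `MethylationDataset`.
#' @param rs A `RegionSet`.
#' @param mode `"mean"` or `"coverage_weighted"`.
#' @param min_cpgs Minimum member CpGs for a region to be scored; default 1
#'   for array platforms and 3 for sequencing platforms, where sparse
#'   coverage makes small regions unstable.
#' @return An object of class `RegionMethylome`: list with `region_set`,
#'   `samples`, `meth` (regions x samples), `n_cpgs`, `mode`.
#' @export
aggregate_regions <- function(dataset, rs,
                              mode = c("mean", "coverage_weighted"),
                              min_cpgs = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_cpgs))
    min_cpgs <- if (dataset$platform %in% c("wgbs", "rrbs")) 3L else 1L
  check_number(min_cpgs, "min_cpgs", 1)
  nr <- length(rs)
  ns <- n_samples(dataset)
  region_key <- sprintf("%s:%d-%d", rs$regions$chrom, rs$regions$start,
                        rs$regions$end)
  meth <- matrix(NA_real_, nr, ns,
                 dimnames = list(region_key, dataset$samples$sample_id))
  n_cpgs <- integer(nr)
  if (!any(unique(dataset$sites$chrom) %in% unique(rs$regions$chrom))) {
    warning("dataset and region set share no chromosomes", call. = FALSE)
  } else {
    hits <- GenomicRanges::findOverlaps(regions_to_granges(rs),
                                        sites_to_granges(dataset$sites))
    ri <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(ri)) {
      cnt <- table(factor(ri, levels = seq_len(nr)))
      n_cpgs <- as.integer(cnt)
      b <- dataset$beta[si, , drop = FALSE]
      obs <- !is.na(b)
      w <- if (mode == "coverage_weighted") {
        wv <- dataset$coverage[si, , drop = FALSE]
        wv[is.na(wv)] <- 1L
        wv
      } else {
        matrix(1, length(si), ns)
      }
      b0 <- b
      b0[!obs] <- 0
      num <- rowsum(b0 * w, ri)
      den <- rowsum(w * obs, ri)
      vals <- num / den
      vals[den == 0] <- NA_real_
      meth[as.integer(rownames(num)), ] <- vals
    }
  }
  meth[n_cpgs < min_cpgs, ] <- NA_real_
  structure(list(region_set = rs, samples = dataset$samples, meth = meth,
                 n_cpgs = n_cpgs, mode = mode, min_cpgs = min_cpgs),
            class = "RegionMethylome")
}

#' @export
print.RegionMethylome <- function(x, ...) {
  cat("RegionMethylome '", x$region_set$name, "' [", x$mode, "]: ",
      nrow(x$meth), " regions x ", ncol(x$meth), " samples\n", sep = "")
  invisible(x)
}

#' Export a region methylome as TSV
#'
#' Rows are keyed by region coordinates (`chrom`, `start`, `end`, optional
#' `label`), followed by `n_cpgs` and one column per sample.
#'
#' @param rm A `RegionMethylome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_region_methylome <- function(rm, path) {
  out <- cbind(rm$region_set$regions,
               data.frame(n_cpgs = rm$n_cpgs), as.data.frame(rm$meth))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
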