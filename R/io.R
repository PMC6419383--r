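#' Read a Bismark coverage file
#'
#' Parses the Bismark coverage dialect: tab-separated
#' `chrom, start, end, methylation_percentage, count_methylated,
#' count_unmethylated`, with 1-based `start == end` for CpGs. The beta value
#' is always recomputed from the counts
#' (`count_methylated / (count_methylated + count_unmethylated)`); the
#' percentage column is only used as a consistency check, and a disagreement
#' beyond 0.5 percentage points raises a warning (the counts win).
#' Zero-coverage rows yield a missing beta.
#'
#' @param path Path to a `.cov` or `.cov.gz` file.
#' @param sample_id Sample identifier to attach to the records.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand` (`"*"`),
#'   `coverage`, `beta` and a `"sample_id"` attribute.
#' @export
read_bismark_cov <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop_mw("file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "pct",
                                    "n_meth", "n_unmeth"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric", "integer", "integer"),
                      quote = "", comment.char = ""),
    error = function(e) stop_mw("malformed coverage file '", path, "': ",
                                conditionMessage(e))
  )
  if (nrow(tab) == 0L) stop_mw("empty coverage file: ", path)
  bad <- which(is.na(tab$start) | is.na(tab$n_meth) | is.na(tab$n_unmeth))
  if (length(bad))
    stop_mw("malformed coverage record at line ", bad[1L], " of ", path)
  neg <- which(tab$n_meth < 0L | tab$n_unmeth < 0L)
  if (length(neg))
    stop_mw("negative read count at line ", neg[1L], " of ", path)
  coverage <- tab$n_meth + tab$n_unmeth
  beta <- ifelse(coverage > 0L, tab$n_meth / coverage, NA_real_)
  obs <- coverage > 0L
  if (any(obs & abs(beta * 100 - tab$pct) > 0.5, na.rm = TRUE)) {
    k <- sum(obs & abs(beta * 100 - tab$pct) > 0.5, na.rm = TRUE)
    warning("methylation percentage disagrees with counts at ", k,
            " line(s) of ", path, "; using counts", call. = FALSE)
  }
  out <- data.frame(chrom = tab$chrom, pos = tab$start, strand = "*",
                    coverage = as.integer(coverage), beta = beta,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  out
}

#' Assemble a dataset from per-sample coverage records
#'
#' Takes one set of per-site records per sample (as returned by
#' [read_bismark_cov()] or [read_bedgraph()]) and aligns them into a single
#' [methylation_dataset()] over the union of observed sites. Optionally
#' collapses -strand records at position p+1 onto the +strand CpG at p by
#' summing counts and recomputing beta (`merge_strands`).
#'
#' @param records List of per-sample record `data.frame`s.
#' @param samples Sample sheet; defaults to one built from the records'
#'   `sample_id` attributes.
#' @param platform Dataset platform tag (default `"wgbs"`).
#' @param merge_strands Collapse strand pairs before assembly (default off).
#' @return A `MethylationDataset`.
#' @export
assemble_dataset <- function(records, samples = NULL, platform = "wgbs",
                             merge_strands = FALSE) {
  ids <- vapply(seq_along(records), function(i) {
    attr(records[[i]], "sample_id") %||% names(records)[i] %||%
      paste0("sample", i)
  }, character(1))
  if (anyDuplicated(ids)) stop_mw("duplicate sample ids among records")
  if (merge_strands) records <- lapply(records, collapse_strands)
  keys <- lapply(records, function(r) site_key(r$chrom, r$pos, r$strand))
  all_keys <- unique(unlist(keys))
  first <- !duplicated(unlist(keys))
  site_info <- do.call(rbind, records)[first, c("chrom", "pos", "strand")]
  ord <- order(site_info$chrom, site_info$pos)
  site_info <- site_info[ord, , drop = FALSE]
  all_keys <- all_keys[ord]
  n <- length(all_keys)
  beta <- matrix(NA_real_, n, length(records))
  coverage <- matrix(NA_integer_, n, length(records))
  for (i in seq_along(records)) {
    idx <- match(keys[[i]], all_keys)
    beta[idx, i] <- records[[i]]$beta
    cov_i <- records[[i]]$coverage
    if (!is.null(cov_i)) coverage[idx, i] <- cov_i
  }
  if (is.null(samples))
    samples <- sample_sheet(data.frame(sample_id = ids,
                                       stringsAsFactors = FALSE))
  methylation_dataset(
    beta = beta,
    sites = cpg_site_table(site_info$chrom, site_info$pos, site_info$strand),
    samples = samples, coverage = coverage, platform = platform
  )
}

# Collapse a -strand record at pos p+1 onto the +strand CpG at pos p by
# summing counts; beta is recomputed from the pooled counts.
collapse_strands <- function(rec) {
  minus <- rec$strand == "-"
  if (!any(minus)) return(rec)
  plus <- rec[!minus, , drop = FALSE]
  mrec <- rec[minus, , drop = FALSE]
  mrec$pos <- mrec$pos - 1L
  key_p <- paste(plus$chrom, plus$pos)
  key_m <- paste(mrec$chrom, mrec$pos)
  hit <- match(key_m, key_p)
  merged <- plus
  for (j in which(!is.na(hit))) {
    i <- hit[j]
    cov <- (merged$coverage[i] %||% 0L) + mrec$coverage[j]
    nm <- merged$beta[i] * merged$coverage[i]
    nm[is.na(nm)] <- 0
    nm2 <- mrec$beta[j] * mrec$coverage[j]
    nm2[is.na(nm2)] <- 0
    merged$coverage[i] <- cov
    merged$beta[i] <- if (cov > 0) (nm + nm2) / cov else NA_real_
  }
  orphan <- mrec[is.na(hit), , drop = FALSE]
  out <- rbind(merged, orphan)
  out$strand <- "+"
  attr(out, "sample_id") <- attr(rec, "sample_id")
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Read a tabular beta-value matrix
#'
#' Ingests preprocessed methylation data in tabular form: one row per site
#' with coordinate columns (`chrom`, `pos`, optional `strand`) or a single
#' probe-key column, and one numeric column per sample with values in
#' `[0, 1]` or a missing token (`NA`, `NaN`, empty; configurable).
#' Out-of-range values and duplicated site keys are rejected. The returned
#' dataset has an all-missing coverage matrix.
#'
#' @param path Delimited text file (TSV by default).
#' @param id_scheme `"coordinate"` (chrom/pos columns) or `"probe"` (a
#'   single id column; synthetic coordinates are assigned in id order and
#'   recorded as chromosome `"probe"`).
#' @param platform Platform tag for the resulting dataset
#'   (default `"array450k"`).
#' @param sep Field separator (`"\t"`; use `","` for CSV).
#' @param na_strings Tokens to treat as missing.
#' @return A `MethylationDataset`.
#' @export
read_beta_table <- function(path, id_scheme = c("coordinate", "probe"),
                            platform = "array450k", sep = "\t",
                            na_strings = c("NA", "NaN", "")) {
  id_scheme <- match.arg(id_scheme)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = na_strings, quote = "",
                           comment.char = "")
  if (nrow(tab) == 0L) stop_mw("empty beta table: ", path)
  if (id_scheme == "coordinate") {
    need <- c("chrom", "pos")
    if (!all(need %in% names(tab)))
      stop_mw("coordinate scheme requires columns 'chrom' and 'pos'")
    strand <- if ("strand" %in% names(tab)) tab$strand else "*"
    sites <- cpg_site_table(tab$chrom, tab$pos, strand)
    key <- site_key(tab$chrom, tab$pos, strand)
    value_cols <- setdiff(names(tab), c("chrom", "pos", "strand"))
  } else {
    idcol <- names(tab)[1L]
    ids <- as.character(tab[[idcol]])
    if (anyDuplicated(ids))
      stop_mw("duplicated site key '", ids[duplicated(ids)][1L], "' in ", path)
    # probe ids carry no genomic position; assign synthetic 1-based
    # coordinates in lexicographic id order on pseudo-chromosome "probe"
    sites <- cpg_site_table("probe", match(ids, sort(ids)), "*")
    sites$site_id <- sort(ids)
    key <- ids
    value_cols <- setdiff(names(tab), idcol)
  }
  if (length(value_cols) == 0L) stop_mw("no sample columns in ", path)
  beta <- as.matrix(tab[, value_cols, drop = FALSE])
  if (!is.numeric(beta)) {
    bad <- which(vapply(tab[value_cols], function(c) !is.numeric(c), TRUE))
    stop_mw("non-numeric beta column: ", value_cols[bad[1L]])
  }
  out_rc <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(out_rc))
    stop_mw(sprintf("beta value %g outside [0,1] at row %d, column '%s'",
                    beta[out_rc[1L, 1L], out_rc[1L, 2L]],
                    out_rc[1L, 1L], value_cols[out_rc[1L, 2L]]))
  if (anyDuplicated(key))
    stop_mw("duplicated site key '", key[duplicated(key)][1L], "' in ", path)
  if (id_scheme == "probe") {
    ord <- order(sites$pos)
    beta <- beta[match(sites$site_id, key), , drop = FALSE]
  } else {
    beta <- beta[match(sites$site_id, key), , drop = FALSE]
  }
  methylation_dataset(
    beta = beta, sites = sites,
    samples = sample_sheet(data.frame(sample_id = value_cols,
                                      stringsAsFactors = FALSE)),
    coverage = NULL, platform = platform
  )
}

#' Read a sample annotation sheet
#'
#' Reads a delimited sample table (one row per sample, header required) and
#' types each column via [sample_sheet()]: numeric iff every non-missing
#' entry parses as a number, categorical otherwise.
#'
#' @param path Delimited text file.
#' @param sep Field separator (default tab).
#' @return A `SampleSheet`.
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(tab) == 0L) stop_mw("empty sample sheet: ", path)
  sample_sheet(tab)
}

#' Export per-sample bedGraph tracks
#'
#' Writes one bedGraph file per sample with 0-based half-open intervals
#' `[pos - 1, pos)` and the beta value, at full double precision so that a
#' re-import reproduces every non-missing beta exactly. Missing cells are
#' omitted; lines are sorted by `(chrom, pos)`.
#'
#' @param dataset A `MethylationDataset`.
#' @param dir Output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
export_tracks <- function(dataset, dir) {
  if (n_sites(dataset) == 0L) stop_mw("dataset has no sites")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_samples(dataset))
  for (j in seq_len(n_samples(dataset))) {
    id <- dataset$samples$sample_id[j]
    keep <- !is.na(dataset$beta[, j])
    s <- dataset$sites[keep, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%s", s$chrom, s$pos - 1L, s$pos,
                     format_full(dataset$beta[keep, j]))
    paths[j] <- file.path(dir, paste0(id, ".bedGraph"))
    writeLines(lines, paths[j])
  }
  invisible(paths)
}

#' Read a bedGraph methylation track
#'
#' Counterpart of [export_tracks()]: 0-based half-open intervals carrying a
#' beta value; position is taken as the interval end (1-based cytosine).
#'
#' @param path bedGraph file.
#' @param sample_id Sample identifier to attach.
#' @return Per-sample records as in [read_bismark_cov()] (coverage `NA`).
#' @export
read_bedgraph <- function(path, sample_id = basename(path)) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start0", "end0", "beta"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric"),
                      quote = "", comment.char = ""),
    error = function(e) stop_mw("malformed bedGraph '", path, "': ",
                                conditionMessage(e))
  )
  if (any(!is.na(tab$beta) & (tab$beta < 0 | tab$beta > 1)))
    stop_mw("beta outside [0,1] in ", path)
  out <- data.frame(chrom = tab$chrom, pos = tab$end0, strand = "*",
                    coverage = NA_integer_, beta = tab$beta,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  out
}
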