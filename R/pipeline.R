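#' Build a pipeline run configuration
#'
#' A run configuration bundles module toggles and parameters with a seed
#' and a resource profile. It is fully serializable ([write_run_config()])
#' and the effective configuration is embedded verbatim in the run report.
#' The resource profile gates only optional extras; it never changes the
#' numerics of enabled stages.
#'
#' @param modules Named logical list toggling the stages `import`,
#'   `preprocess`, `regions`, `inference`, `exploratory`, `differential`,
#'   `enrichment`.
#' @param params Named list of per-stage parameter overrides; see defaults
#'   in the implementation (`filter` rules, `impute` strategy, tiling
#'   `window`, comparison `column`, `fdr`, ...).
#' @param seed Integer seed for all stochastic steps.
#' @param resource_profile `"low"`, `"medium"` or `"high"`.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(modules = list(), params = list(), seed = 1L,
                       resource_profile = "medium") {
  mod_defaults <- list(import = TRUE, preprocess = TRUE, regions = TRUE,
                       inference = TRUE, exploratory = TRUE,
                       differential = TRUE, enrichment = TRUE)
  par_defaults <- list(
    filter = list(remove_sex_chromosomes = TRUE, remove_snp_sites = FALSE,
                  min_coverage = 5, min_fraction_covered = 0.5),
    impute = list(strategy = "cpg_mean", k = 10),
    regions = list(window = 100, min_cpgs = 3),
    comparison = list(column = "group"),
    differential = list(fdr = 0.05, variability_method = "diffvar"),
    exploratory = list(n_components = 4, alpha = 0.01)
  )
  unknown <- setdiff(names(modules), names(mod_defaults))
  if (length(unknown)) stop_mw("unknown module(s): ",
                               paste(unknown, collapse = ", "))
  mod <- utils::modifyList(mod_defaults, modules)
  if (!resource_profile %in% c("low", "medium", "high"))
    stop_mw("resource_profile must be low, medium or high")
  structure(list(modules = mod,
                 params = utils::modifyList(par_defaults, params),
                 seed = as.integer(seed),
                 resource_profile = resource_profile),
            class = "RunConfig")
}

#' @rdname run_config
#' @param config A `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(modules = raw$modules %||% list(),
             params = raw$params %||% list(),
             seed = raw$seed %||% 1L,
             resource_profile = raw$resource_profile %||% "medium")
}

log_line <- function(run_dir, ...) {
  cat(paste0(...), "\n", sep = "", file = file.path(run_dir, "log.txt"),
      append = TRUE)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  for (nm in names(df)[num]) df[[nm]] <- format_full(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full methylation analysis pipeline
#'
#' Executes the enabled stages in fixed order — import, preprocess,
#' regions, inference, exploratory, differential, enrichment — writing
#' every stage's outputs as TSV into the run directory together with a log
#' and the effective configuration. Failures of optional downstream stages
#' (inference, exploratory, enrichment) are recorded in the log and do not
#' abort the run; failures of import or preprocessing abort with an error.
#' A run is fully determined by `(config, input)`: re-running with the
#' same configuration and seed reproduces every numeric output exactly.
#'
#' @param config A [run_config()].
#' @param input A `MethylationDataset`, a fixture list from
#'   [generate_fixture()], or `NULL` to generate the standard fixture from
#'   the configuration seed.
#' @param out_dir Run directory (created; must not exist or be empty).
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config, input = NULL, out_dir) {
  if (!inherits(config, "RunConfig")) stop_mw("config must be a RunConfig")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.exists(file.path(out_dir, "log.txt")))
    file.remove(file.path(out_dir, "log.txt"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  p <- config$params

  ## import -----------------------------------------------------------------
  fixture <- NULL
  if (is.null(input)) {
    input <- generate_fixture(fixture_spec(seed = config$seed))
  }
  if (is.list(input) && !inherits(input, "MethylationDataset") &&
      !is.null(input$dataset)) {
    fixture <- input
    ds <- input$dataset
  } else if (inherits(input, "MethylationDataset")) {
    ds <- input
  } else {
    stop_mw("input must be a MethylationDataset or fixture list")
  }
  log_line(out_dir, "import: ", n_sites(ds), " sites, ", n_samples(ds),
           " samples [", ds$platform, "]")
  write_dataset_dir(ds, file.path(out_dir, "dataset"))

  ## preprocess (fatal on failure) ------------------------------------------
  if (isTRUE(config$modules$preprocess)) {
    fl <- do.call(filter_sites, c(list(ds), p$filter))
    write_tsv(as.data.frame(fl$report), file.path(out_dir, "filter_report.tsv"))
    ds <- fl$dataset
    log_line(out_dir, "preprocess: retained ", n_sites(ds), " sites")
  }

  ## regions ----------------------------------------------------------------
  region_meth <- NULL
  if (isTRUE(config$modules$regions)) {
    chrom_sizes <- if (!is.null(fixture$chrom_sizes)) fixture$chrom_sizes else
      vapply(split(ds$sites$pos, ds$sites$chrom), function(x)
        as.numeric(max(x) + 100), numeric(1))
    tiles <- tile_genome(chrom_sizes, window = p$regions$window)
    region_meth <- aggregate_regions(ds, tiles, mode = "mean",
                                     min_cpgs = p$regions$min_cpgs)
    export_region_methylome(region_meth,
                            file.path(out_dir, "region_methylation.tsv"))
    log_line(out_dir, "regions: ", length(tiles), " tiles, ",
             sum(rowSums(!is.na(region_meth$meth)) > 0), " scored")
  }

  ## optional stages are non-fatal ------------------------------------------
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(out_dir, name, ": FAILED (", conditionMessage(e), ")")
      NULL
    })
  }

  if (isTRUE(config$modules$inference)) {
    try_stage("inference", {
      inf <- data.frame(sample_id = ds$samples$sample_id,
                        stringsAsFactors = FALSE)
      sx <- try_stage("inference/sex", {
        feats <- sex_features(ds)
        known <- ds$samples$sex
        model <- train_sex_model(feats, known)
        cbind(feats[, c("fX", "fY")],
              sex_pred = predict_sex(model, feats)$predicted)
      })
      if (!is.null(sx)) inf <- cbind(inf, sx)
      gn <- try_stage("inference/genetic_noise",
                      genetic_noise(ds)$genetic_noise)
      if (!is.null(gn)) inf$genetic_noise <- gn
      if (!is.null(fixture$lump_sites)) {
        lp <- try_stage("inference/lump",
                        lump_purity(ds, fixture$lump_sites))
        if (!is.null(lp)) {
          inf$purity <- lp$purity
          inf$immune_fraction <- lp$immune_fraction
        }
      }
      write_tsv(inf, file.path(out_dir, "inference.tsv"))
      log_line(out_dir, "inference: ", ncol(inf) - 1L, " covariates")
    })
  }

  if (isTRUE(config$modules$exploratory)) {
    try_stage("exploratory", {
      b <- impute_missing(ds, strategy = p$impute$strategy,
                          k = p$impute$k, seed = config$seed)$beta
      emb <- pca_embed(b, n_components = p$exploratory$n_components)
      coords <- data.frame(sample_id = rownames(emb$coords), emb$coords,
                           stringsAsFactors = FALSE)
      write_tsv(coords, file.path(out_dir, "pca_coordinates.tsv"))
      assoc <- associate_components(emb, ds$samples,
                                    alpha = p$exploratory$alpha)
      ptab <- data.frame(component = rownames(assoc$p), assoc$p,
                         check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(ptab, file.path(out_dir, "component_associations.tsv"))
      log_line(out_dir, "exploratory: ", ncol(emb$coords), " components")
    })
  }

  diff_tables <- list()
  if (isTRUE(config$modules$differential)) {
    cmp <- group_comparison(ds$samples, p$comparison$column)
    dmt <- differential_methylation(ds$beta, cmp)
    export_differential_table(dmt, file.path(out_dir, "diff_methylation.tsv"))
    dvt <- differential_variability(ds$beta, cmp,
                                    method = p$differential$variability_method)
    export_differential_table(dvt, file.path(out_dir, "diff_variability.tsv"))
    diff_tables <- list(methylation = dmt, variability = dvt)
    if (!is.null(region_meth)) {
      keep <- rowSums(is.na(region_meth$meth)) == 0
      if (sum(keep) >= 2L) {
        rv <- region_meth$meth[keep, , drop = FALSE]
        rownames(rv) <- sprintf("%s:%d-%d",
                                region_meth$region_set$regions$chrom,
                                region_meth$region_set$regions$start,
                                region_meth$region_set$regions$end)[keep]
        dmr <- differential_methylation(rv, cmp)
        export_differential_table(dmr, file.path(out_dir, "diff_regions.tsv"))
        diff_tables$regions <- dmr
      }
    }
    log_line(out_dir, "differential: cutoff ",
             auto_rank_cutoff(dmt, p$differential$fdr), " DMCs at FDR ",
             p$differential$fdr)
  } else {
    log_line(out_dir, "differential: skipped")
  }

  if (isTRUE(config$modules$enrichment) &&
      length(diff_tables) && !is.null(fixture)) {
    try_stage("enrichment", {
      dmt <- diff_tables$methylation
      cutoff <- auto_rank_cutoff(dmt, p$differential$fdr)
      sel <- attr(cutoff, "selected")
      if (length(sel) == 0L) {
        log_line(out_dir, "enrichment: empty selection, skipped")
      } else {
        hit <- match(sel, ds$sites$site_id)
        query <- region_set("selected_dmcs", data.frame(
          chrom = ds$sites$chrom[hit], start = ds$sites$pos[hit] - 1L,
          end = ds$sites$pos[hit], stringsAsFactors = FALSE))
        universe <- tile_genome(fixture$chrom_sizes,
                                window = p$regions$window)
        nonempty <- vapply(fixture$region_sets, length, integer(1)) > 0L
        catalog <- enrichment_catalog(
          sets = fixture$region_sets[nonempty], universe = universe)
        enr <- region_enrichment(query, catalog)
        write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
        log_line(out_dir, "enrichment: ", nrow(enr), " catalogue entries")
      }
    })
  }
  log_line(out_dir, "run complete")
  invisible(out_dir)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 20L) {
  df <- utils::head(df, max_rows)
  num <- vapply(df, is.numeric, TRUE)
  for (nm in names(df)[num]) df[[nm]] <- signif(df[[nm]], 4)
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)),
                                    "</th>", collapse = ""), "</tr>")
  body <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table>", head_row, paste(body, collapse = ""), "</table>")
}

# Render a plot expression to a base64 <img>, or NULL if no png device is
# available on this system.
html_plot <- function(expr, width = 640, height = 480) {
  tmp <- tempfile(fileext = ".png")
  ok <- tryCatch({
    grDevices::png(tmp, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    eval(expr)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(tmp)) return(NULL)
  raw <- readBin(tmp, "raw", file.info(tmp)$size)
  unlink(tmp)
  paste0("<img src=\"data:image/png;base64,",
         jsonlite::base64_enc(raw), "\"/>")
}

#' Render an HTML report for a pipeline run
#'
#' Produces a single self-contained HTML file with one section per stage
#' found in the run directory: the verbatim effective configuration, the
#' filter report, covariate-inference table, PCA scatter, group mean/mean
#' and variance/variance scatter plots with the top-ranked units
#' highlighted, the top-20 enrichment entries by worst rank with a
#' log-odds bar plot, and links to the exported TSV tables. Regenerating
#' the report from the same directory is byte-stable except for the
#' timestamp line.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @param out Output HTML path (default `report.html` inside `run_dir`).
#' @return The report path, invisibly.
#' @export
render_report <- function(run_dir, out = file.path(run_dir, "report.html")) {
  tsvs <- list.files(run_dir, pattern = "\\.tsv$")
  if (!file.exists(file.path(run_dir, "config.yaml")) && length(tsvs) == 0L)
    stop_mw("no pipeline outputs found in ", run_dir)
  read_tsv <- function(name) {
    path <- file.path(run_dir, name)
    if (!file.exists(path)) return(NULL)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>methworks run report</title>",
    "<style>body{font-family:sans-serif;margin:2em;}table{border-collapse:collapse;}",
    "td,th{border:1px solid #999;padding:2px 6px;font-size:12px;}",
    "pre{background:#f4f4f4;padding:1em;}h2{border-bottom:1px solid #ccc;}",
    "</style></head><body>",
    "<h1>methworks run report</h1>",
    paste0("<p class=\"timestamp\">generated: ",
           format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "</p>")
  )
  cfg_path <- file.path(run_dir, "config.yaml")
  if (file.exists(cfg_path)) {
    parts <- c(parts, "<h2>Configuration</h2><pre>",
               html_escape(paste(readLines(cfg_path), collapse = "\n")),
               "</pre>")
  }
  fr <- read_tsv("filter_report.tsv")
  if (!is.null(fr))
    parts <- c(parts, "<h2>Preprocessing</h2>", html_table(fr))
  inf <- read_tsv("inference.tsv")
  if (!is.null(inf))
    parts <- c(parts, "<h2>Covariate inference</h2>", html_table(inf))
  pca <- read_tsv("pca_coordinates.tsv")
  if (!is.null(pca)) {
    parts <- c(parts, "<h2>Exploratory analysis</h2>")
    img <- html_plot(quote(graphics::plot(
      pca$PC1, pca$PC2, pch = 19, xlab = "PC1", ylab = "PC2",
      main = "Principal component embedding")))
    if (!is.null(img)) parts <- c(parts, img)
    assoc <- read_tsv("component_associations.tsv")
    if (!is.null(assoc)) parts <- c(parts, html_table(assoc))
  }
  for (nm in c(methylation = "diff_methylation.tsv",
               variability = "diff_variability.tsv",
               regions = "diff_regions.tsv")) {
    dt <- read_tsv(nm)
    if (is.null(dt)) next
    label <- sub("\\.tsv$", "", nm)
    parts <- c(parts, paste0("<h2>Differential analysis: ", label, "</h2>"))
    if (all(c("mean0", "mean1", "combined_rank") %in% names(dt))) {
      top <- rank(dt$combined_rank, ties.method = "first") <=
        min(100L, nrow(dt))
      img <- html_plot(bquote({
        graphics::plot(.(dt$mean0), .(dt$mean1), pch = 16,
                       col = grDevices::adjustcolor("grey30", 0.4),
                       xlab = "group0 mean", ylab = "group1 mean",
                       main = .(paste0(label, ": group means")))
        graphics::points(.(dt$mean0[top]), .(dt$mean1[top]), pch = 16,
                         col = "purple")
      }))
      if (!is.null(img)) parts <- c(parts, img)
    }
    parts <- c(parts, html_table(dt[, intersect(
      c("unit", "diff", "var_diff", "statistic", "p", "p_adj",
        "combined_rank"), names(dt)), drop = FALSE]))
  }
  enr <- read_tsv("enrichment.tsv")
  if (!is.null(enr)) {
    parts <- c(parts, "<h2>Region-set enrichment (top 20 by worst rank)</h2>")
    top20 <- utils::head(enr[order(enr$max_rank), , drop = FALSE], 20L)
    img <- html_plot(bquote(graphics::barplot(
      rev(.(top20$log_odds)), names.arg = rev(.(top20$name)), horiz = TRUE,
      las = 1, xlab = "log2 odds ratio", main = "Enrichment")))
    if (!is.null(img)) parts <- c(parts, img)
    parts <- c(parts, html_table(top20))
  }
  parts <- c(parts, "<h2>Exported tables</h2><ul>",
             paste0("<li><a href=\"", tsvs, "\">", tsvs, "</a></li>"),
             "</ul></body></html>")
  writeLines(parts, out)
  invisible(out)
}
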