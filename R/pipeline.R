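# Pipeline orchestration: one config in, a bundle of machine-readable
# reports out (stability TSV + JSON, aggregated ranking, target
# quantification tables, run log). Numbers in JSON reports are rounded to
# 6 decimal places so that reruns with the same config and seed are
# byte-identical; timestamps live only in the plain-text log.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read a pipeline config from JSON
#'
#' Recognised keys: `ct` (Ct table CSV, required), `ct_dialect`
#' (`"long"`/`"wide"`), `primers` (primer CSV), `collapse`
#' (`"median"`/`"mean"`), `use_groups` (grouped NormFinder), `algorithms`,
#' `efficiency_default`, `expression` + `design` (+ `comparisons`, list of
#' condition pairs) for candidate mining, `window` (logFC bounds),
#' `targets`, `reference_genes`, `calibrator`, `seed`, `output_dir`.
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path JSON file path.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (key in c("ct", "primers", "expression", "design")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full reference-gene pipeline
#'
#' Stages, in order: (optional) candidate mining from an expression matrix
#' by logFC-window intersection; Ct parsing and replicate collapse;
#' four-algorithm stability scoring; geometric-mean rank aggregation;
#' (optional) target quantification against the configured reference set
#' with consecutive-stage statistics. Every stage error is re-signalled
#' with the stage name so failures are attributable.
#'
#' @param config a `pipeline_config` (or path to one, or plain list).
#' @param output_dir overrides `config$output_dir`.
#' @return Invisibly, a list with the in-memory results and `files`, the
#'   paths written: `stability_report.tsv`, `report.json`, per-target
#'   `relquant_<gene>.tsv`, `run_log.txt`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop("no output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("refstab ", as.character(utils::packageVersion("refstab")),
           " | R ", getRversion()),
    paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed %||% "none"),
    paste0("config: ", paste(utils::capture.output(utils::str(
      unclass(config), give.attr = FALSE)), collapse = " "))
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  results <- list()

  if (!is.null(config$expression)) {
    results$candidates <- stage("candidates", {
      mat <- read_expression_matrix(config$expression, config$design)
      window <- config$window %||% c(-0.1, 0.1)
      cmps <- config$comparisons
      sets <- lapply(cmps, function(cmp) {
        stable_gene_filter(log_fold_change(mat, cmp[[1]], cmp[[2]]),
                           window = window)
      })
      if (length(sets) >= 2) intersect_stable_sets(sets)
      else list(core = sets[[1]]$genes, venn_counts = NULL)
    })
    log_lines <- c(log_lines,
                   paste0("candidates: core of ",
                          length(results$candidates$core), " gene(s)"))
  }

  ctab <- stage("ct_input", {
    if (is.null(config$ct)) stop("config$ct is required")
    if (!file.exists(config$ct)) stop("Ct file not found: ", config$ct)
    read_ct_table(config$ct, dialect = config$ct_dialect %||% "long")
  })
  primers <- stage("primers", {
    if (is.null(config$primers)) NULL
    else {
      if (!file.exists(config$primers))
        stop("primer file not found: ", config$primers)
      read_primer_table(config$primers)
    }
  })
  m <- stage("collapse", {
    collapse_replicates(ctab, method = config$collapse %||% "median")
  })

  rep <- stage("stability", {
    stability_report(
      m, primers = primers,
      use_groups = isTRUE(config$use_groups),
      efficiency_default = config$efficiency_default %||% 2,
      algorithms = config$algorithms %||%
        c("genorm", "deltact", "bestkeeper", "normfinder"))
  })
  results$stability <- rep

  tsv <- stability_report_table(rep)
  files <- character(0)
  f <- file.path(out_dir, "stability_report.tsv")
  utils::write.table(tsv, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(config$targets)) {
    results$relquant <- stage("relquant", {
      rq <- quantify_targets(
        m, targets = config$targets,
        reference_genes = config$reference_genes,
        calibrator_group = config$calibrator,
        primers = primers,
        efficiency_default = config$efficiency_default %||% 2)
      for (g in names(rq)) {
        fq <- file.path(out_dir, paste0("relquant_", g, ".tsv"))
        sm <- rq[[g]]$summary
        sm <- cbind(gene = g, sm)
        sm$mean <- round(sm$mean, 6); sm$sem <- round(sm$sem, 6)
        utils::write.table(sm, fq, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <<- c(files, fq)
        cmpdf <- compare_consecutive_stages(rq[[g]])
        fc <- file.path(out_dir, paste0("relquant_", g, "_comparisons.tsv"))
        num <- vapply(cmpdf, is.numeric, TRUE)
        cmpdf[num] <- lapply(cmpdf[num], round, 6)
        utils::write.table(cmpdf, fc, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <<- c(files, fc)
      }
      rq
    })
  }

  js <- report_json(config, results, tsv)
  fj <- file.path(out_dir, "report.json")
  jsonlite::write_json(js, fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, fj)

  log_lines <- c(log_lines, paste0("wrote: ", files),
                 paste0("finished: ", format(Sys.time(),
                                             "%Y-%m-%d %H:%M:%S")))
  fl <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, fl)
  files <- c(files, fl)

  invisible(c(results, list(files = files)))
}

# One row per gene: every algorithm's score and rank plus the aggregate.
stability_report_table <- function(rep) {
  agg <- rep$aggregated
  genes <- agg$overall
  pos <- agg$positions
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!is.null(rep$genorm)) {
    df$genorm_m <- round(rep$genorm$m_values[genes], 6)
    df$genorm_rank <- pos[genes, "genorm"]
  }
  if (!is.null(rep$deltact)) {
    df$deltact <- round(rep$deltact$score[genes], 6)
    df$deltact_rank <- pos[genes, "deltact"]
  }
  if (!is.null(rep$bestkeeper)) {
    df$bestkeeper_sd <- round(rep$bestkeeper$score[genes], 6)
    df$bestkeeper_rank <- pos[genes, "bestkeeper"]
  }
  if (!is.null(rep$normfinder)) {
    df$normfinder <- round(rep$normfinder$score[genes], 6)
    df$normfinder_rank <- pos[genes, "normfinder"]
  }
  df$geomean_rank <- round(agg$geomean_rank[genes], 6)
  df$overall_rank <- seq_along(genes)
  df
}

report_json <- function(config, results, tsv) {
  rep <- results$stability
  out <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    parameters = list(
      seed = config$seed %||% NA,
      collapse = config$collapse %||% "median",
      efficiency_default = config$efficiency_default %||% 2,
      algorithms = names(rep)[names(rep) != "aggregated"],
      use_groups = isTRUE(config$use_groups)
    ),
    stability = tsv,
    overall_ranking = rep$aggregated$overall
  )
  if (!is.null(rep$genorm)) {
    out$genorm_pairwise_variation <-
      as.list(round(rep$genorm$pairwise_v, 6))
  }
  if (!is.null(results$candidates)) {
    out$candidates <- list(
      core = results$candidates$core,
      venn_counts = as.list(results$candidates$venn_counts))
  }
  if (!is.null(results$relquant)) {
    out$relquant <- lapply(results$relquant, function(r) {
      sm <- r$summary
      sm$mean <- round(sm$mean, 6); sm$sem <- round(sm$sem, 6)
      list(calibrator = r$calibrator_group, summary = sm)
    })
  }
  out
}
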