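# End-to-end pipeline driver: files in, TSV stage outputs + manifest out.

#' Assemble a pipeline configuration
#'
#' Paths plus every tunable threshold of the pipeline. `config_file`, when
#' given, is read first (one `key = value` or `key<TAB>value` pair per line,
#' `#` comments allowed); explicit arguments override file values.
#'
#' @param segments,genes,cytobands,clinical,pathways input paths
#'   (`cytobands`/`pathways` optional — without cytobands the gene model
#'   must carry its own band column).
#' @param out_dir output directory.
#' @param min_markers,min_length_bp segment filters ([read_segments()]).
#' @param mode carrier mode for the grade tests.
#' @param min_g3,r_g3,min_g1,r_g1 ratio-set constraints ([derive_hro201()]).
#' @param tp20_min recurrence threshold ([derive_tp20()]).
#' @param burden_threshold genes per category for group presence
#'   ([assign_patient_groups()]).
#' @param endpoint `"DOTD_only"` or `"all"`.
#' @param seed integer; the pipeline itself is deterministic but the seed is
#'   recorded and forwarded to any simulation step.
#' @param config_file optional key-value file.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(segments = NULL, genes = NULL, cytobands = NULL,
                            clinical = NULL, pathways = NULL,
                            out_dir = "cnastrat_out",
                            min_markers = 5L, min_length_bp = 100000L,
                            mode = "any_alteration",
                            min_g3 = 4L, r_g3 = -2 / 3,
                            min_g1 = 5L, r_g1 = 2 / 5,
                            tp20_min = 20L, burden_threshold = 3L,
                            endpoint = "DOTD_only", seed = 1L,
                            config_file = NULL) {
  cfg <- as.list(environment())
  cfg$config_file <- NULL
  if (!is.null(config_file)) {
    file_cfg <- parse_config_file(config_file)
    given <- names(as.list(match.call()))[-1]
    for (k in names(file_cfg))
      if (!k %in% given) cfg[[k]] <- file_cfg[[k]]
  }
  num <- c("min_markers", "min_length_bp", "min_g3", "r_g3", "min_g1",
           "r_g1", "tp20_min", "burden_threshold", "seed")
  for (k in num) cfg[[k]] <- as.numeric(cfg[[k]])
  structure(cfg, class = "pipeline_config")
}

parse_config_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=\t]", perl = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2) stop_data("malformed config line: ", paste(p, collapse = ""))
    out[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
  }
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full CNA stratification pipeline
#'
#' Reads the configured inputs, builds the CNA matrix, computes gene and
#' cytoband statistics, derives the ratio-based and recurrence gene sets,
#' assigns patient groups, compares group survival, and writes every stage
#' output plus a run manifest to `config$out_dir`. Deterministic given
#' inputs and config.
#'
#' @param config a [pipeline_config()].
#' @return named vector of output file paths, invisibly; the manifest
#'   records row counts per output.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (k in c("segments", "genes", "clinical"))
    if (is.null(config[[k]]))
      stop_data("pipeline config lacks required input: ", k)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- c()

  inputs <- run_stage("load_inputs", {
    genes <- read_gene_model(config$genes)
    if (!is.null(config$cytobands))
      genes <- assign_cytobands(genes, read_cytobands(config$cytobands))
    if (is.null(genes$cytoband))
      stop_data("gene model has no cytobands and no cytoband table given")
    list(segments = read_segments(config$segments,
                                  min_markers = config$min_markers,
                                  min_length_bp = config$min_length_bp),
         genes = genes, clinical = read_clinical(config$clinical),
         pathways = if (!is.null(config$pathways))
           read_pathways(config$pathways))
  })

  mat <- run_stage("build_matrix", {
    triples <- annotate_segments_to_genes(inputs$segments, inputs$genes)
    build_cna_matrix(triples, inputs$clinical$sample_id,
                     inputs$genes$symbol)
  })
  paths["matrix"] <- write_matrix(mat, out("matrix.tsv"))

  strat <- run_stage("gene_stats", {
    prof <- profile_genes(mat, inputs$clinical)
    st <- stratify_all_genes(mat, inputs$clinical, mode = config$mode)
    res <- merge(st$results,
                 prof[, c("symbol", "n_loss", "n_gain", "cna_class")],
                 by = "symbol", sort = FALSE)
    res$cytoband <- inputs$genes$cytoband[match(res$symbol,
                                                inputs$genes$symbol)]
    write.table(res[order(res$p_value, res$symbol), ],
                out("gene_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    st
  })
  paths["gene_stats"] <- out("gene_stats.tsv")

  run_stage("cytoband_stats", {
    cy <- summarize_cytobands(mat, inputs$genes, inputs$clinical)
    write.table(cy, out("cytoband_stats.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  paths["cytoband_stats"] <- out("cytoband_stats.tsv")

  sets <- run_stage("gene_sets", {
    hro <- derive_hro201(mat, inputs$clinical, min_g3 = config$min_g3,
                         r_g3 = config$r_g3, min_g1 = config$min_g1,
                         r_g1 = config$r_g1, mode = config$mode)
    write_gene_set(hro, out("ratio_gene_set.tsv"))
    tp <- derive_tp20(mat, min_tumours = config$tp20_min)
    tp_df <- data.frame(
      symbol = unlist(tp, use.names = FALSE),
      label = rep(names(tp), lengths(tp)), stringsAsFactors = FALSE)
    write.table(tp_df, out("recurrent_gene_set.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(hro = hro, tp = tp)
  })
  paths["ratio_gene_set"] <- out("ratio_gene_set.tsv")
  paths["recurrent_gene_set"] <- out("recurrent_gene_set.tsv")

  if (!is.null(inputs$pathways)) {
    run_stage("pathway_projection", {
      pb <- pathway_burden(mat, inputs$clinical, inputs$pathways)
      write.table(pb, out("pathway_burden.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
    paths["pathway_burden"] <- out("pathway_burden.tsv")
  }

  groups <- run_stage("stratification", {
    th <- rep(as.integer(config$burden_threshold), 4)
    names(th) <- c("G1_loss", "G1_gain", "G3_loss", "G3_gain")
    g <- assign_patient_groups(mat, sets$hro, thresholds = th)
    write.table(g, out("patient_groups.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    g
  })
  paths["patient_groups"] <- out("patient_groups.tsv")

  run_stage("survival", {
    if (is.null(inputs$clinical$surv_time)) {
      message("no survival columns; skipping survival comparison")
      return(invisible(NULL))
    }
    cmp <- compare_group_survival(inputs$clinical, groups,
                                  cause_filter = config$endpoint)
    df <- data.frame(arm1 = paste(cmp$arm1, collapse = ","),
                     arm2 = paste(cmp$arm2, collapse = ","),
                     hazard_ratio = cmp$hazard_ratio,
                     ci_low = cmp$ci_low, ci_high = cmp$ci_high,
                     logrank_p = cmp$logrank_p, estimable = cmp$estimable,
                     n = cmp$n, events = cmp$events)
    write.table(df, out("survival_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  paths["survival"] <- out("survival_comparison.tsv")

  run_stage("manifest", {
    cfg_flat <- vapply(unclass(config), function(x)
      paste(format(x), collapse = ","), "")
    counts <- vapply(paths, function(p)
      if (file.exists(p)) length(readLines(p)) - 1L else NA_integer_, 0L)
    writeLines(c(
      paste0("cnastrat_version\t",
             as.character(utils::packageVersion("cnastrat"))),
      paste0("config_", names(cfg_flat), "\t", cfg_flat),
      paste0("rows_", names(counts), "\t", counts)),
      out("manifest.tsv"))
  })
  paths["manifest"] <- out("manifest.tsv")
  invisible(paths)
}
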