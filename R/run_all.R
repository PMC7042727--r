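#' Run the full analysis bundle from a configuration
#'
#' Orchestrates the complete pipeline on one configuration: load (or
#' simulate) the inputs, run the prioritization funnel, the
#' maximal-LOD power analysis, and the expression correlation analysis,
#' and write deterministic reports (funnel TSV, linkage and expression
#' JSON, run log) into `out_dir`.
#'
#' @param config a [read_run_config()] result (or an equivalent list).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `funnel`, `power`, `expression`
#'   results and the output paths.
#' @export
run_all <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log <- c(sprintf("pedfunnel %s", as.character(utils::packageVersion("pedfunnel"))),
           sprintf("seed: %d", seed))

  if (!is.null(config$simulate)) {
    ped <- ad_family("wgs")
    sim <- config$simulate
    gd <- gene_drop(ped, gene_drop_config(
      n_variants = sim$n_variants %||% 1000L,
      nocall_rate = sim$nocall_rate %||% 0.02,
      lowq_rate = sim$lowq_rate %||% 0.05,
      planted = list(chrom = "2", pos = 9628047L, ref = "G", alt = "T")),
      seed = seed)
    vs <- gd$vs
    ann <- make_annotations(vs, gd$truth, seed = seed)
    annotations <- ann$annotations
    cmd_genes <- ann$cmd_genes; brain_genes <- ann$brain_genes
    nd_genes <- ann$nd_genes; network <- ann$network
    es <- make_expression(seed = seed)
    log <- c(log, "inputs: simulated")
  } else {
    paths <- config$paths
    ped <- read_ped(paths$ped, genotyped = config$typed_ids %||% character())
    vs <- read_vcf(paths$vcf)
    annotations <- read_annotations(paths$annotations)
    cmd_genes <- read_gene_list(paths$cmd_genes)
    brain_genes <- read_gene_list(paths$brain_genes)
    nd_genes <- read_gene_list(paths$nd_genes)
    network <- read_network(paths$network)
    es <- if (!is.null(paths$expression_matrix))
      read_expression_set(paths$expression_matrix, paths$detection_p,
                          paths$samples, paths$probe_map)
    else NULL
    log <- c(log, sprintf("inputs: %s", paths$vcf))
  }

  fc_args <- config$funnel %||% list()
  if (is.null(fc_args$case_ids))
    fc_args$case_ids <- ped$id[ped$affection == "affected" & ped$genotyped]
  if (is.null(fc_args$control_ids))
    fc_args$control_ids <- ped$id[ped$affection == "unaffected" & ped$genotyped &
                                    !ped$id %in% c("201", "202")]
  fc <- do.call(funnel_config, fc_args)
  report <- run_funnel(vs, annotations, cmd_genes, brain_genes, nd_genes,
                       network, fc, apply_shared_regions = FALSE)
  write_funnel_report(report, file.path(out_dir, "funnel.tsv"))

  dmv <- config$disease_model %||% list(freq = 0.0001,
                                        penetrances = c(0.0001, 1, 1))
  dm <- disease_model(dmv$freq, dmv$penetrances[1], dmv$penetrances[2],
                      dmv$penetrances[3])
  typed <- config$typed_ids %||% ped$id[ped$genotyped]
  pw <- max_lod_power(ped, dm, typed,
                      n_markers = config$n_markers %||% 1000L,
                      seed = seed)
  jsonlite::write_json(
    list(max_lod = round(pw$max_lod, 5), n_markers = pw$n_markers,
         typed_ids = typed),
    file.path(out_dir, "linkage.json"), auto_unbox = TRUE, digits = NA)

  expr_out <- NULL
  if (!is.null(es)) {
    ecfg <- config$expression %||% list()
    retained <- call_rate_filter(es, ecfg$alpha %||% 0.05,
                                 ecfg$min_rate %||% 0.90)
    anchor <- ecfg$anchor %||% "ADAM17"
    targets <- ecfg$targets %||%
      setdiff(unique(es$probe_map$gene), anchor)
    fitres <- tryCatch({
      fy <- gene_signal(es, targets[1], retained)
      fx <- gene_signal(es, anchor, retained)
      fit_pair(fx, fy)
    }, error = function(e) NULL)
    screen <- pearson_screen(es, anchor, targets, retained)
    expr_out <- list(anchor = anchor,
                     fit = if (is.null(fitres)) NULL else
                       fitres[c("n", "r", "r2_adj", "slope", "slope_p")],
                     screen = screen)
    jsonlite::write_json(expr_out, file.path(out_dir, "expression.json"),
                         auto_unbox = TRUE, digits = 6, dataframe = "rows")
  }

  log <- c(log,
           sprintf("funnel final: %d variants",
                   nrow(attr(report, "final")$variants)),
           sprintf("max LOD: %.5f (%d markers)", pw$max_lod, pw$n_markers))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(funnel = report, power = pw, expression = expr_out,
                 out_dir = out_dir))
}
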