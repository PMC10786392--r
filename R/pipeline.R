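#' Build a pipeline configuration
#'
#' A pipeline run either simulates its inputs (set `simulate = TRUE`) or
#' reads per-miRNA count matrices from disk. Thresholds default to the
#' published filtering rule (raw p < 0.05, signed log2 fold change).
#'
#' @param out_dir Output directory.
#' @param simulate Logical; when TRUE inputs come from
#'   [simulate_targetome_study()].
#' @param sim Named list of [sim_config()] overrides (e.g. `n_genes`).
#' @param mirnas Character vector of miRNA labels (simulation mode), or a
#'   named list `list(label = list(counts =, samples =, truth =))` of paths.
#' @param shared_fraction Shared direct-target fraction in simulation mode.
#' @param utrs,mirna_seqs Optional FASTA of transcript regions and TSV/FASTA
#'   of mature miRNA sequences; when both are given the called targets are
#'   annotated with seed sites.
#' @param p_max,lfc_up,lfc_down DE thresholds.
#' @param pca_exclude Drop PCA-flagged outlier samples before testing.
#' @param strict_igg Any-direction IgG exclusion (see [ago2_specific_up()]).
#' @param seed Integer seed for simulation mode.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "ripscope_out", simulate = TRUE,
                            sim = list(), mirnas = c("miR-34c", "miR-449a"),
                            shared_fraction = 0.3,
                            utrs = NULL, mirna_seqs = NULL,
                            p_max = 0.05, lfc_up = 0, lfc_down = 0,
                            pca_exclude = FALSE, strict_igg = FALSE,
                            seed = 1L) {
  stopifnot(p_max > 0, p_max <= 1)
  structure(list(out_dir = out_dir, simulate = simulate, sim = sim,
                 mirnas = mirnas, shared_fraction = shared_fraction,
                 utrs = utrs, mirna_seqs = mirna_seqs,
                 p_max = p_max, lfc_up = lfc_up, lfc_down = lfc_down,
                 pca_exclude = pca_exclude, strict_igg = strict_igg,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full targetome pipeline
#'
#' End-to-end orchestration: obtain one count bundle per miRNA (simulated
#' or read from disk), optionally screen/exclude PCA outliers, run the
#' three fraction-matched contrasts, call direct targets, optionally
#' annotate them with seed sites, and intersect direct-target sets across
#' miRNAs. All stage tables are written as TSV and a machine-readable JSON
#' summary (set sizes, thresholds, excluded samples, seed) is produced.
#' Rerunning with the same config reproduces identical gene sets.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param quiet Suppress progress messages.
#' @return List of class `ripscope_report`: `targetomes` (per miRNA),
#'   `coregulated`, `evaluation` (per miRNA, when truth is available),
#'   `annotations` (when sequences given), `summary` (the JSON content),
#'   `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[ripscope] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- inputs ---------------------------------------------------------
  if (isTRUE(config$simulate)) {
    say("simulating ", length(config$mirnas), "-miRNA study (seed ",
        config$seed, ")")
    sim_args <- config$sim
    sim_args$seed <- config$seed
    base_cfg <- do.call(sim_config, sim_args)
    bundles <- simulate_targetome_study(base_cfg, mirnas = config$mirnas,
                                        shared_fraction = config$shared_fraction)
  } else {
    stopifnot(is.list(config$mirnas), length(names(config$mirnas)) > 0)
    bundles <- lapply(config$mirnas, function(m)
      read_counts(m$counts, m$samples, m$truth %||% NULL))
  }

  mirna_objs <- NULL
  regions <- NULL
  if (!is.null(config$mirna_seqs)) mirna_objs <- read_mirnas(config$mirna_seqs)
  if (!is.null(config$utrs)) regions <- read_fasta(config$utrs)

  # --- per-miRNA stages -----------------------------------------------
  targetomes <- list()
  evaluation <- list()
  annotations <- list()
  for (label in names(bundles)) {
    b <- bundles[[label]]
    say("contrasts for ", label)
    cs <- tryCatch(
      run_three_contrasts(b, mirna_label = label,
                          pca_exclude = config$pca_exclude,
                          p_max = config$p_max,
                          lfc_up = config$lfc_up, lfc_down = config$lfc_down),
      error = function(e) stop("stage run_three_contrasts [", label, "]: ",
                               conditionMessage(e)))
    tg <- call_direct_targets(cs, strict_igg = config$strict_igg)
    targetomes[[label]] <- tg
    safe <- gsub("[^A-Za-z0-9._-]", "_", label)
    for (fr in c("ago2", "igg", "input"))
      write_de_result(cs[[fr]],
                      file.path(config$out_dir,
                                paste0(safe, "_de_", fr, ".tsv")))
    # stage-flag table: one row per gene with per-contrast stats + calls
    flags <- data.frame(gene_id = cs$ago2$gene_id,
                        lfc_ago2 = cs$ago2$log2FC, p_ago2 = cs$ago2$pvalue,
                        lfc_igg = cs$igg$log2FC, p_igg = cs$igg$pvalue,
                        lfc_input = cs$input$log2FC, p_input = cs$input$pvalue,
                        up_ago2 = cs$ago2$gene_id %in% tg$up_ago2,
                        ago2_specific = cs$ago2$gene_id %in% tg$ago2_specific,
                        down_input = cs$ago2$gene_id %in% tg$down_input,
                        direct_target = cs$ago2$gene_id %in% tg$direct_targets,
                        stringsAsFactors = FALSE)
    utils::write.table(flags,
                       file.path(config$out_dir, paste0(safe, "_targets.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(b$truth))
      evaluation[[label]] <- evaluate_calls(tg, b$truth)
    mir_obj <- if (!is.null(mirna_objs)) {
      mirna_objs[[label]] %||% mirna_objs[[1]]
    } else NULL
    if (!is.null(mir_obj) && !is.null(regions)) {
      ann <- annotate_targets(tg, regions, mir_obj)
      annotations[[label]] <- ann
      utils::write.table(ann,
                         file.path(config$out_dir,
                                   paste0(safe, "_seed_sites.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  coreg <- if (length(targetomes) >= 2)
    Reduce(coregulated_targets, targetomes) else NULL

  summary_obj <- list(
    thresholds = list(p_max = config$p_max, lfc_up = config$lfc_up,
                      lfc_down = config$lfc_down),
    flags = list(pca_exclude = config$pca_exclude,
                 strict_igg = config$strict_igg),
    seed = config$seed,
    mirnas = lapply(targetomes, function(tg) list(
      up_ago2 = length(tg$up_ago2), up_igg = length(tg$up_igg),
      up_input = length(tg$up_input),
      ago2_specific = length(tg$ago2_specific),
      down_input = length(tg$down_input),
      direct_targets = length(tg$direct_targets),
      direct_target_genes = tg$direct_targets,
      excluded_samples = tg$excluded_samples)),
    coregulated = list(n = length(coreg), genes = coreg),
    package_version = as.character(utils::packageVersion("ripscope")))
  json_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary_obj, json_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  say("direct targets: ",
      paste(vapply(targetomes, function(t) length(t$direct_targets),
                   integer(1)), collapse = " / "),
      if (!is.null(coreg)) paste0("; coregulated: ", length(coreg)))

  structure(list(targetomes = targetomes, coregulated = coreg,
                 evaluation = evaluation, annotations = annotations,
                 summary = summary_obj,
                 paths = list(out_dir = config$out_dir, summary = json_path)),
            class = "ripscope_report")
}

#' @export
print.ripscope_report <- function(x, ...) {
  cat("ripscope pipeline report\n")
  for (tg in x$targetomes) print(tg)
  if (!is.null(x$coregulated))
    cat("co-regulated direct targets:", length(x$coregulated), "\n")
  for (label in names(x$evaluation)) {
    ev <- x$evaluation[[label]]
    cat(sprintf("recovery [%s]: sensitivity %.2f, FDR %.2f (%d called / %d true)\n",
                label, ev$sensitivity, ev$fdr, ev$n_called, ev$n_true))
  }
  invisible(x)
}
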