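#' Run the three fraction-matched contrasts of a RIP-seq design
#'
#' For one miRNA bundle, tests mimic vs scramble within each fraction
#' (AGO2-IP, IgG-IP, Input), optionally after excluding PCA-flagged outlier
#' samples. All three results share the bundle's gene universe.
#'
#' @param bundle A `rip_bundle` containing both treatments for all three
#'   fractions (>= 2 replicates per cell after any exclusion).
#' @param mirna_label miRNA name recorded on the result (default "miR").
#' @param pca_exclude When `TRUE`, run [pca_outlier_screen()] and drop
#'   flagged samples before testing (the exclusion is recorded).
#' @param p_max,lfc_up,lfc_down Significance and signed fold-change
#'   thresholds used downstream (defaults p < 0.05, log2FC > 0 / < 0).
#' @param ... Passed to [nb_wald_contrast()].
#' @return List of class `contrast_set`: `mirna`, `ago2`, `igg`, `input`
#'   (each a `de_result`), `thresholds`, `excluded_samples`.
#' @export
run_three_contrasts <- function(bundle, mirna_label = "miR",
                                pca_exclude = FALSE,
                                p_max = 0.05, lfc_up = 0, lfc_down = 0, ...) {
  stopifnot(inherits(bundle, "rip_bundle") ||
            (is.list(bundle) && !is.null(bundle$counts) && !is.null(bundle$samples)))
  samples <- bundle$samples
  excluded <- character(0)
  if (pca_exclude) {
    scr <- pca_outlier_screen(bundle)
    excluded <- scr$flagged
    samples <- samples[!samples$sample_id %in% excluded, , drop = FALSE]
  }
  fractions <- c("AGO2-IP", "IgG-IP", "Input")
  for (fr in fractions) for (tr in c("miR", "scramble")) {
    n <- sum(samples$fraction == fr & samples$treatment == tr)
    if (n < 2L)
      stop("missing or underpowered design cell: ", fr, " / ", tr,
           " (", n, " sample", if (n == 1) "" else "s", ")")
  }
  one <- function(fr) {
    a <- samples$sample_id[samples$fraction == fr & samples$treatment == "miR"]
    b <- samples$sample_id[samples$fraction == fr &
                           samples$treatment == "scramble"]
    nb_wald_contrast(bundle$counts,
                     de_contrast(paste0(fr, " ", mirna_label,
                                        " vs ", fr, " scramble"), a, b), ...)
  }
  structure(list(mirna = mirna_label,
                 ago2 = one("AGO2-IP"),
                 igg = one("IgG-IP"),
                 input = one("Input"),
                 thresholds = list(p_max = p_max, lfc_up = lfc_up,
                                   lfc_down = lfc_down),
                 excluded_samples = excluded),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("RIP-seq contrast set for", x$mirna, "\n")
  for (nm in c("ago2", "igg", "input")) print(x[[nm]])
  if (length(x$excluded_samples))
    cat("  excluded samples:", paste(x$excluded_samples, collapse = ", "), "\n")
  invisible(x)
}

de_up_set <- function(de, p_max, lfc_min = 0) {
  de$gene_id[de$tested & de$pvalue < p_max & de$log2FC > lfc_min]
}
de_down_set <- function(de, p_max, lfc_max = 0) {
  de$gene_id[de$tested & de$pvalue < p_max & de$log2FC < lfc_max]
}
de_sig_set <- function(de, p_max) {
  de$gene_id[de$tested & de$pvalue < p_max]
}

#' AGO2-specific up-regulated genes
#'
#' Genes significantly up in the AGO2-IP contrast but not in the IgG-IP or
#' Input contrasts: the intersection scheme removing nonspecific bead
#' binding and transcriptome-wide secondary responses. By default a gene is
#' excluded only when significantly UP in IgG or Input (the published Venn
#' logic); `strict_igg = TRUE` additionally excludes genes significant in
#' the IgG contrast in either direction.
#'
#' @param cs A `contrast_set` from [run_three_contrasts()].
#' @param strict_igg Exclude any-direction IgG significance (default FALSE).
#' @return Character vector of gene ids, with attribute `provenance`
#'   (data.frame recording which exclusion applied per AGO2-up gene).
#' @export
ago2_specific_up <- function(cs, strict_igg = FALSE) {
  stopifnot(inherits(cs, "contrast_set"))
  p_max <- cs$thresholds$p_max
  up_a <- de_up_set(cs$ago2, p_max)
  ex_igg <- if (strict_igg) de_sig_set(cs$igg, p_max)
            else de_up_set(cs$igg, p_max)
  ex_inp <- de_up_set(cs$input, p_max)
  keep <- setdiff(up_a, union(ex_igg, ex_inp))
  prov <- data.frame(gene_id = up_a,
                     excluded_by_igg = up_a %in% ex_igg,
                     excluded_by_input = up_a %in% ex_inp,
                     stringsAsFactors = FALSE)
  attr(keep, "provenance") <- prov
  keep
}

#' Call direct miRNA targets from a contrast set
#'
#' The operational direct-target rule: a gene is a direct target when it is
#' up-regulated specifically in the AGO2-IP contrast (not up in IgG-IP or
#' Input) AND down-regulated (p < p_max, log2FC < 0) in the Input contrast
#' -- enriched in the silencing complex while depleted from the
#' transcriptome.
#'
#' @inheritParams ago2_specific_up
#' @return List of class `targetome`: gene sets `up_ago2`, `up_igg`,
#'   `up_input`, `ago2_specific`, `down_input`, `direct_targets`, plus
#'   `provenance` (per AGO2-up gene: which filters it passed), `mirna`,
#'   `thresholds`.
#' @export
call_direct_targets <- function(cs, strict_igg = FALSE) {
  stopifnot(inherits(cs, "contrast_set"))
  p_max <- cs$thresholds$p_max
  up_a <- de_up_set(cs$ago2, p_max)
  up_g <- de_up_set(cs$igg, p_max)
  up_i <- de_up_set(cs$input, p_max)
  spec <- ago2_specific_up(cs, strict_igg = strict_igg)
  down_i <- de_down_set(cs$input, p_max)
  direct <- intersect(spec, down_i)
  prov <- attr(spec, "provenance")
  prov$ago2_specific <- prov$gene_id %in% spec
  prov$down_input <- prov$gene_id %in% down_i
  prov$direct_target <- prov$gene_id %in% direct
  structure(list(mirna = cs$mirna,
                 up_ago2 = up_a, up_igg = up_g, up_input = up_i,
                 ago2_specific = as.character(spec), down_input = down_i,
                 direct_targets = direct,
                 provenance = prov,
                 thresholds = cs$thresholds,
                 strict_igg = strict_igg,
                 excluded_samples = cs$excluded_samples),
            class = "targetome")
}

#' @export
print.targetome <- function(x, ...) {
  cat("Targetome for", x$mirna, "(p <", x$thresholds$p_max, ")\n")
  cat(sprintf("  up in AGO2-IP: %d | up in IgG-IP: %d | up in Input: %d\n",
              length(x$up_ago2), length(x$up_igg), length(x$up_input)))
  cat(sprintf("  AGO2-specific: %d | down in Input: %d | direct targets: %d\n",
              length(x$ago2_specific), length(x$down_input),
              length(x$direct_targets)))
  invisible(x)
}

#' @export
summary.targetome <- function(object, ...) {
  data.frame(stage = c("up_ago2", "up_igg", "up_input", "ago2_specific",
                       "down_input", "direct_targets"),
             n = c(length(object$up_ago2), length(object$up_igg),
                   length(object$up_input), length(object$ago2_specific),
                   length(object$down_input), length(object$direct_targets)))
}

#' Targets co-regulated by two miRNAs
#'
#' Intersection of two direct-target sets (e.g. the genes shared by
#' miR-34c and miR-449a, which share a seed region).
#'
#' @param t_a,t_b `targetome` objects or character vectors of gene ids.
#' @return Character vector of shared gene ids.
#' @export
coregulated_targets <- function(t_a, t_b) {
  ga <- if (inherits(t_a, "targetome")) t_a$direct_targets else as.character(t_a)
  gb <- if (inherits(t_b, "targetome")) t_b$direct_targets else as.character(t_b)
  intersect(ga, gb)
}

#' Score called targets against simulation truth
#'
#' @param result A `targetome` or character vector of called gene ids.
#' @param truth Truth data.frame (columns `gene_id`, `class`) from
#'   [simulate_ripseq_counts()].
#' @return List: `sensitivity` = |called & true| / |true|, `fdr` =
#'   |called \ true| / max(1, |called|), `n_called`, `n_true`,
#'   `leakage` (table of truth classes among false calls).
#' @export
evaluate_calls <- function(result, truth) {
  called <- if (inherits(result, "targetome")) result$direct_targets
            else as.character(result)
  true_t <- truth$gene_id[truth$class == "direct_target"]
  tp <- intersect(called, true_t)
  fp <- setdiff(called, true_t)
  sens <- if (length(true_t)) length(tp) / length(true_t) else NA_real_
  fdr <- length(fp) / max(1L, length(called))
  leak <- table(factor(truth$class[match(fp, truth$gene_id)],
                       levels = c("null", "bead_binder", "secondary")))
  list(sensitivity = sens, fdr = fdr,
       n_called = length(called), n_true = length(true_t),
       leakage = leak)
}
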