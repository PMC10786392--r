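#' Apply the Ct reliability cutoff
#'
#' Replicate Ct values above the cutoff (default 35 cycles, the usual
#' limit of reliable quantification) are excluded. Applying the filter
#' twice equals applying it once.
#'
#' @param ct Numeric vector of replicate Ct values.
#' @param cutoff Maximum retained Ct (default 35).
#' @return The retained Ct values (possibly empty).
#' @export
filter_ct <- function(ct, cutoff = 35) {
  ct[is.finite(ct) & ct <= cutoff]
}

#' Relative expression by the delta-Ct method
#'
#' Averages replicate Ct values after the `Ct > cutoff` exclusion, forms
#' delta-Ct = mean Ct(target) - mean Ct(reference) within the same sample,
#' and returns 2^-delta-Ct. When every replicate of either assay is
#' excluded the result is undetermined: flagged, never imputed as zero.
#'
#' @param target_ct,reference_ct Numeric vectors of replicate Ct values for
#'   the target and reference (housekeeping) assays of one sample.
#' @param cutoff Ct exclusion threshold (default 35).
#' @return List of class `qpcr_rel`: `delta_ct`, `rel_expr` (2^-delta-Ct),
#'   `undetermined`, `n_target`, `n_reference` (replicates retained).
#' @examples
#' relative_expression(25, 20)$rel_expr   # 2^-5
#' @export
relative_expression <- function(target_ct, reference_ct, cutoff = 35) {
  t_ <- filter_ct(target_ct, cutoff)
  r_ <- filter_ct(reference_ct, cutoff)
  if (!length(t_) || !length(r_)) {
    return(structure(list(delta_ct = NA_real_, rel_expr = NA_real_,
                          undetermined = TRUE,
                          n_target = length(t_), n_reference = length(r_)),
                     class = "qpcr_rel"))
  }
  dct <- mean(t_) - mean(r_)
  structure(list(delta_ct = dct, rel_expr = 2^(-dct), undetermined = FALSE,
                 n_target = length(t_), n_reference = length(r_)),
            class = "qpcr_rel")
}

#' @export
print.qpcr_rel <- function(x, ...) {
  if (x$undetermined) cat("qPCR relative expression: undetermined",
                          "(all replicates excluded)\n")
  else cat(sprintf("qPCR: delta-Ct = %.3f, 2^-dCt = %.4g\n",
                   x$delta_ct, x$rel_expr))
  invisible(x)
}

#' Fold change by the delta-delta-Ct method
#'
#' delta-delta-Ct = delta-Ct(condition) - delta-Ct(control);
#' fold change = 2^-delta-delta-Ct. Both inputs must be determined.
#'
#' @param target_cond,target_ctrl Either `qpcr_rel` objects from
#'   [relative_expression()] or numeric delta-Ct values.
#' @return Numeric fold change.
#' @examples
#' fold_change_ddct(5, 3)   # 0.25
#' @export
fold_change_ddct <- function(target_cond, target_ctrl) {
  dct <- function(x) {
    if (inherits(x, "qpcr_rel")) {
      if (x$undetermined) stop("delta-Ct is undetermined (all replicates excluded)")
      x$delta_ct
    } else as.numeric(x)
  }
  d1 <- dct(target_cond); d0 <- dct(target_ctrl)
  if (is.na(d1) || is.na(d0)) stop("delta-Ct must be determined for both conditions")
  2^(-(d1 - d0))
}

#' Quantify a Ct table
#'
#' Table-level wrapper: for each sample x assay (other than the reference
#' assay), computes delta-Ct against the reference assay of the same
#' sample and the relative expression 2^-delta-Ct, with undetermined
#' results flagged. Input columns: `sample_id`, `assay`, then replicate Ct
#' columns (`ct_rep1`, `ct_rep2`, ...); extra annotation columns (e.g.
#' `condition`) are carried through.
#'
#' @param ct_table data.frame as described above.
#' @param reference_assay Name of the housekeeping assay (e.g. "GAPDH" for
#'   genes, "miR-99b" for miRNAs).
#' @param cutoff Ct exclusion threshold (default 35).
#' @return data.frame: sample_id, assay, carried annotations, delta_ct,
#'   rel_expr, undetermined, n_replicates_used.
#' @export
quantify_ct <- function(ct_table, reference_assay, cutoff = 35) {
  stopifnot(all(c("sample_id", "assay") %in% names(ct_table)))
  ct_cols <- grep("^ct_rep", names(ct_table), value = TRUE)
  if (!length(ct_cols)) stop("no replicate Ct columns (ct_rep1, ct_rep2, ...)")
  anno_cols <- setdiff(names(ct_table), c("sample_id", "assay", ct_cols))
  out <- list()
  n_dropped <- 0L
  for (sid in unique(ct_table$sample_id)) {
    sub <- ct_table[ct_table$sample_id == sid, , drop = FALSE]
    ref <- sub[sub$assay == reference_assay, , drop = FALSE]
    if (nrow(ref) != 1L)
      stop("sample ", sid, ": expected exactly one row for reference assay ",
           reference_assay)
    ref_ct <- as.numeric(ref[1, ct_cols])
    for (i in which(sub$assay != reference_assay)) {
      r <- relative_expression(as.numeric(sub[i, ct_cols]), ref_ct, cutoff)
      if (r$undetermined) n_dropped <- n_dropped + 1L
      row <- data.frame(sample_id = sid, assay = sub$assay[i],
                        stringsAsFactors = FALSE)
      for (ac in anno_cols) row[[ac]] <- sub[[ac]][i]
      row$delta_ct <- r$delta_ct
      row$rel_expr <- r$rel_expr
      row$undetermined <- r$undetermined
      row$n_replicates_used <- r$n_target
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  if (n_dropped)
    message(n_dropped, " sample/assay result(s) undetermined (all replicates above Ct ",
            cutoff, ")")
  res
}
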