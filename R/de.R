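#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' nonzero counts in every sample, of the ratio of the gene's count to its
#' geometric mean across samples; factors are rescaled to geometric mean 1.
#' If no gene is expressed in all samples, falls back to total-count scaling
#' with a warning.
#'
#' @param counts Nonnegative gene x sample matrix.
#' @return Named numeric vector of positive size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("need at least one sample")
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    warning("no gene expressed in all samples; falling back to total-count scaling")
    s <- colSums(counts)
    if (any(s <= 0)) stop("sample with zero total counts")
    s <- s / exp(mean(log(s)))
    return(stats::setNames(s, colnames(counts)))
  }
  ck <- counts[keep, , drop = FALSE]
  gm <- exp(rowMeans(log(ck)))
  s <- apply(sweep(ck, 1, gm, "/"), 2, stats::median)
  s <- s / exp(mean(log(s)))            # rescale to geometric mean 1
  stats::setNames(s, colnames(counts))
}

#' Method-of-moments NB dispersion estimates
#'
#' Estimates the negative-binomial dispersion alpha (variance =
#' mu + alpha mu^2) per gene on size-factor-normalized counts. The raw
#' per-gene moment estimator is `(var - mean * mean(1/s_j)) / mean^2`
#' (the `mean(1/s_j)` term accounts for the Poisson component of
#' depth-normalized counts). With a handful of replicates the per-gene
#' estimates are extremely noisy, so the default `"trend"` method replaces
#' them by a mean-abundance trend fitted by binned averaging of the raw
#' (unfloored) estimates, in the spirit of the moderation used by
#' established RNA-seq DE tools.
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors (from [size_factors()]); computed if `NULL`.
#' @param groups Optional factor (one per sample); when given, gene
#'   variances are pooled within groups so planted between-group effects do
#'   not inflate the estimates.
#' @param method `"trend"` (default), `"per-gene"` (raw floored moment
#'   estimates), or `"pooled"` (a single common alpha).
#' @param floor Lower bound for alpha (default 1e-8). Zero-mean or
#'   constant genes are set to the floor and flagged.
#' @return Object of class `dispersion_estimate`: list with `alpha`
#'   (named vector >= floor), `raw`, `method`, `floor`, `flagged`.
#' @export
estimate_dispersion <- function(counts, sf = NULL, groups = NULL,
                                method = c("trend", "per-gene", "pooled"),
                                floor = 1e-8) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  m <- rowMeans(q)
  if (is.null(groups)) {
    v <- apply(q, 1, stats::var)
  } else {
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(q))
    ss <- 0; df <- 0
    for (g in levels(groups)) {
      qg <- q[, groups == g, drop = FALSE]
      ng <- ncol(qg)
      if (ng >= 2) {
        mg <- rowMeans(qg)
        ss <- ss + rowSums((qg - mg)^2)
        df <- df + (ng - 1)
      }
    }
    if (df == 0) stop("need at least one group with >= 2 samples")
    v <- ss / df
  }
  k <- mean(1 / sf)
  raw <- ifelse(m > 0, (v - m * k) / m^2, NA_real_)
  flagged <- m <= 0 | v == 0
  alpha <- switch(method,
    "per-gene" = pmax(floor, ifelse(is.na(raw), floor, raw)),
    "pooled" = {
      ok <- !is.na(raw) & m >= 1
      rep(max(floor, mean(raw[ok])), length(raw))
    },
    "trend" = {
      ok <- !is.na(raw) & m >= 1
      if (sum(ok) < 20) {
        rep(max(floor, mean(raw[ok], na.rm = TRUE)), length(raw))
      } else {
        lm_ <- log10(m[ok]); r_ <- raw[ok]
        nb <- max(3L, min(20L, as.integer(sum(ok) / 50)))
        br <- unique(stats::quantile(lm_, probs = seq(0, 1, length.out = nb + 1)))
        bin <- cut(lm_, br, include.lowest = TRUE)
        # bin means of the unfloored raw estimates are unbiased for the
        # true dispersion; medians would be biased low at few replicates
        ctr <- tapply(lm_, bin, mean)
        val <- tapply(r_, bin, mean)
        keep <- !is.na(ctr) & !is.na(val)
        fit <- stats::approx(ctr[keep], val[keep], xout = log10(pmax(m, 1e-8)),
                             rule = 2)$y
        pmax(floor, fit)
      }
    })
  alpha <- stats::setNames(pmax(floor, alpha), rownames(counts))
  structure(list(alpha = alpha, raw = raw, method = method, floor = floor,
                 flagged = flagged),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("NB dispersion estimates (", x$method, "): ",
      length(x$alpha), " genes, median alpha = ",
      signif(stats::median(x$alpha), 3), "\n", sep = "")
  invisible(x)
}

#' Define a two-group contrast
#'
#' @param name Contrast label, e.g. "AGO2-IP miR vs AGO2-IP scramble".
#' @param group_a,group_b Disjoint sample-id vectors (each >= 2 samples);
#'   `group_b` is the reference (scramble) group.
#' @return List of class `de_contrast`.
#' @export
de_contrast <- function(name, group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each contrast group needs >= 2 samples: ", name)
  if (length(intersect(group_a, group_b)))
    stop("contrast groups must be disjoint: ", name)
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "de_contrast")
}

#' Negative-binomial Wald test for one contrast
#'
#' Computes, per gene, the log2 fold change of group means of normalized
#' counts (with a pseudocount for stability), a delta-method standard error
#' under the NB model (variance mu + alpha mu^2), the Wald z statistic and
#' its two-sided normal p-value. Size factors are computed on the union of
#' the two groups; dispersion defaults to the trend estimate pooled within
#' groups. Genes whose mean normalized count over the contrast falls below
#' `min_mean` are marked untested (`p = 1` convention, kept in the table);
#' a BH-adjusted p-value column is provided for convenience but the
#' intersection-based target calling uses raw p-values.
#'
#' @param x A `rip_bundle` or a gene x sample count matrix.
#' @param contrast A [de_contrast()] object.
#' @param dispersion Optional `dispersion_estimate`; computed if `NULL`.
#' @param pseudocount Pseudocount on the normalized scale (default 0.5).
#' @param min_mean Expression filter on the mean normalized count (default 1).
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `baseMean_a`, `baseMean_b`, `log2FC`, `se`, `wald_z`, `pvalue`, `padj`,
#'   `tested`; attributes `contrast` (name) and `size_factors`.
#' @export
nb_wald_contrast <- function(x, contrast, dispersion = NULL,
                             pseudocount = 0.5, min_mean = 1) {
  counts <- if (inherits(x, "rip_bundle")) x$counts else as.matrix(x)
  stopifnot(inherits(contrast, "de_contrast"))
  ids <- c(contrast$group_a, contrast$group_b)
  missing_ids <- setdiff(ids, colnames(counts))
  if (length(missing_ids))
    stop("samples not in count matrix: ", paste(missing_ids, collapse = ", "))
  sub <- counts[, ids, drop = FALSE]
  if (is.null(rownames(sub)))
    rownames(sub) <- sprintf("gene%d", seq_len(nrow(sub)))
  sf <- size_factors(sub)
  grp <- factor(rep(c("a", "b"), c(length(contrast$group_a),
                                   length(contrast$group_b))))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(sub, sf, groups = grp)
  alpha <- dispersion$alpha
  stopifnot(length(alpha) == nrow(sub))

  q <- sweep(sub, 2, sf, "/")
  ia <- grp == "a"; ib <- grp == "b"
  na <- sum(ia); nb <- sum(ib)
  ma <- rowMeans(q[, ia, drop = FALSE])
  mb <- rowMeans(q[, ib, drop = FALSE])
  c_ <- pseudocount
  lfc <- log2((ma + c_) / (mb + c_))
  # Var of the group mean of depth-normalized NB counts:
  #   Var(K_ij/s_j) = mu/s_j + alpha mu^2
  ka <- mean(1 / sf[ia]); kb <- mean(1 / sf[ib])
  va <- (ma * ka + alpha * ma^2) / na
  vb <- (mb * kb + alpha * mb^2) / nb
  se <- sqrt(va / (ma + c_)^2 + vb / (mb + c_)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  tested <- rowMeans(q) >= min_mean & se > 0
  p[!tested] <- 1
  z[!tested] <- 0
  padj <- rep(NA_real_, length(p))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(gene_id = rownames(sub),
                    baseMean_a = ma, baseMean_b = mb,
                    log2FC = lfc, se = se, wald_z = z,
                    pvalue = p, padj = padj, tested = tested,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast$name
  attr(out, "size_factors") <- sf
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat("NB Wald contrast:", attr(x, "contrast"), "\n")
  cat("  ", nrow(x), " genes (", sum(x$tested), " tested); ",
      sum(x$tested & x$pvalue < 0.05 & x$log2FC > 0), " up / ",
      sum(x$tested & x$pvalue < 0.05 & x$log2FC < 0),
      " down at p < 0.05\n", sep = "")
  invisible(x)
}

#' PCA-based sample outlier screen
#'
#' Runs PCA on log2(normalized counts + 1) of the most variable genes and
#' flags samples whose PC1-PC2 distance to their (fraction, treatment)
#' group centroid reaches `m` times the median distance within the group
#' (groups with zero spread are never flagged).
#' Flagged samples are reported; they are excluded from downstream analysis
#' only when the caller opts in (see [run_three_contrasts()]).
#'
#' @param bundle A `rip_bundle` (or count matrix with `samples` given).
#' @param samples Sample sheet (needed only when `bundle` is a bare matrix).
#' @param top_n Number of most-variable genes used (default 500).
#' @param m Flagging multiplier (default 3).
#' @param n_pcs Number of PCs retained (default 2; reduced with a warning
#'   when fewer samples are available).
#' @return List of class `pca_screen`: `flagged` (sample ids), `coords`
#'   (data.frame sample_id, PC1, PC2, group, dist, threshold, flagged),
#'   `var_explained`.
#' @export
pca_outlier_screen <- function(bundle, samples = NULL, top_n = 500L, m = 3,
                               n_pcs = 2L) {
  if (inherits(bundle, "rip_bundle")) {
    counts <- bundle$counts
    samples <- bundle$samples
  } else counts <- as.matrix(bundle)
  if (is.null(samples)) stop("sample sheet required")
  if (ncol(counts) < 3L) stop("need at least 3 samples for a PCA screen")
  sf <- size_factors(counts)
  lq <- log2(sweep(counts, 2, sf, "/") + 1)
  rv <- apply(lq, 1, stats::var)
  top <- order(rv, decreasing = TRUE)[seq_len(min(top_n, nrow(lq)))]
  mat <- t(lq[top, , drop = FALSE])
  n_pcs_max <- min(nrow(mat) - 1L, ncol(mat))
  if (n_pcs > n_pcs_max) {
    warning("reducing number of PCs to ", n_pcs_max)
    n_pcs <- n_pcs_max
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(n_pcs), drop = FALSE]
  grp <- interaction(samples$fraction, samples$treatment, drop = TRUE)
  d <- numeric(nrow(sc)); thr <- numeric(nrow(sc))
  for (g in levels(grp)) {
    i <- which(grp == g)
    ctr <- colMeans(sc[i, , drop = FALSE])
    di <- sqrt(rowSums(sweep(sc[i, , drop = FALSE], 2, ctr)^2))
    d[i] <- di
    thr[i] <- m * stats::median(di)
  }
  # "reaches m x median": >= with a relative tolerance, since the boundary
  # case (k identical replicates + one outlier) lands exactly on m x median
  is_out <- thr > 0 & (d - thr) > -1e-8 * pmax(thr, 1)
  flagged <- samples$sample_id[is_out]
  coords <- data.frame(sample_id = samples$sample_id,
                       PC1 = sc[, 1],
                       PC2 = if (n_pcs >= 2) sc[, 2] else NA_real_,
                       group = as.character(grp),
                       dist = d, threshold = thr,
                       flagged = is_out,
                       stringsAsFactors = FALSE, row.names = NULL)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(flagged = flagged, coords = coords,
                 var_explained = ve[seq_len(n_pcs)]),
            class = "pca_screen")
}

#' @export
print.pca_screen <- function(x, ...) {
  cat("PCA sample screen:", nrow(x$coords), "samples;",
      length(x$flagged), "flagged\n")
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_screen <- function(x, ...) {
  cols <- as.integer(factor(x$coords$group))
  graphics::plot(x$coords$PC1, x$coords$PC2, col = cols,
                 pch = ifelse(x$coords$flagged, 17, 19),
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$var_explained[1]),
                 ylab = sprintf("PC2 (%.0f%%)",
                                100 * x$var_explained[min(2, length(x$var_explained))]),
                 ...)
  if (any(x$coords$flagged))
    graphics::text(x$coords$PC1[x$coords$flagged],
                   x$coords$PC2[x$coords$flagged],
                   labels = x$coords$sample_id[x$coords$flagged],
                   pos = 3, cex = 0.7)
  invisible(x)
}
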