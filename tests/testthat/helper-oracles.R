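# Independent oracles used to validate the package implementations.
# Each is written from the defining formula, on a different code path from
# the functions it checks.

# median-of-ratios normalization, straight from the definition
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  gm <- apply(counts[keep, , drop = FALSE], 1,
              function(r) exp(mean(log(r))))
  s <- vapply(seq_len(ncol(counts)), function(j)
    stats::median(counts[keep, j] / gm), numeric(1))
  s / exp(mean(log(s)))
}

# product-limit estimator by record-by-record recursion
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  tk <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tk, surv = NA_real_)
  for (i in seq_along(tk)) {
    at_risk <- sum(time >= tk[i])
    deaths <- sum(time == tk[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    out$surv[i] <- s
  }
  out
}

# per-start seed-site classification by brute-force substring comparison,
# highest class wins at each start
oracle_scan <- function(region, patterns_rna) {
  seq <- chartr("Tt", "Uu", toupper(region))
  classes <- c("6mer", "7mer-A1", "7mer-m8", "8mer")  # increasing precedence
  n <- nchar(seq)
  hits <- list()
  for (s in seq_len(n)) {
    best <- NA_character_
    for (cls in classes) {
      pat <- patterns_rna[[cls]]
      if (s + nchar(pat) - 1L <= n &&
          substr(seq, s, s + nchar(pat) - 1L) == pat)
        best <- cls
    }
    if (!is.na(best))
      hits[[length(hits) + 1L]] <- data.frame(start = s, site_class = best,
                                              stringsAsFactors = FALSE)
  }
  if (!length(hits)) data.frame(start = integer(0), site_class = character(0))
  else do.call(rbind, hits)
}

# direct-target calling re-derived gene by gene from the three DE tables
oracle_direct_targets <- function(ago2, igg, input, p_max = 0.05) {
  stopifnot(identical(ago2$gene_id, igg$gene_id),
            identical(ago2$gene_id, input$gene_id))
  out <- character(0)
  for (i in seq_len(nrow(ago2))) {
    up_a <- ago2$tested[i] && ago2$pvalue[i] < p_max && ago2$log2FC[i] > 0
    up_g <- igg$tested[i] && igg$pvalue[i] < p_max && igg$log2FC[i] > 0
    up_i <- input$tested[i] && input$pvalue[i] < p_max && input$log2FC[i] > 0
    dn_i <- input$tested[i] && input$pvalue[i] < p_max && input$log2FC[i] < 0
    if (up_a && !up_g && !up_i && dn_i) out <- c(out, ago2$gene_id[i])
  }
  out
}

# Cox log partial likelihood for one covariate, no ties (Breslow = Efron),
# written independently for grid-search maximization
oracle_cox_loglik_1cov <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

oracle_cox_grid_1cov <- function(time, event, x, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik_1cov, numeric(1),
               time = time, event = event, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_cox_loglik_1cov, numeric(1),
                time = time, event = event, x = x)
  fine[which.max(llf)]
}

# synthetic DE tables with random significance structure, for set-logic
# property tests
random_de_table <- function(n_genes, seed) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
             baseMean_a = stats::runif(n_genes, 0, 100),
             baseMean_b = stats::runif(n_genes, 0, 100),
             log2FC = stats::rnorm(n_genes),
             se = stats::runif(n_genes, 0.1, 1),
             wald_z = stats::rnorm(n_genes),
             pvalue = stats::runif(n_genes),
             padj = NA_real_,
             tested = stats::runif(n_genes) > 0.05,
             stringsAsFactors = FALSE)
}

# wrap three DE tables as a contrast_set without re-running the NB test
fake_contrast_set <- function(ago2, igg, input, p_max = 0.05) {
  structure(list(mirna = "miR-test",
                 ago2 = ago2, igg = igg, input = input,
                 thresholds = list(p_max = p_max, lfc_up = 0, lfc_down = 0),
                 excluded_samples = character(0)),
            class = "contrast_set")
}

# small mixed-censoring survival fixture generator
random_surv_fixture <- function(n, seed, round_times = FALSE) {
  set.seed(seed)
  d <- data.frame(time = stats::rexp(n, 0.05),
                  event = stats::rbinom(n, 1, 0.7),
                  x = stats::rnorm(n),
                  g = stats::rbinom(n, 1, 0.5))
  if (round_times) {
    d$time <- ceiling(d$time)
  }
  d
}
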