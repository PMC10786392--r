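#' Configuration for the RIP-seq count simulator
#'
#' Defines the study design emulated by [simulate_ripseq_counts()]: three
#' fractions (Input, AGO2-IP, IgG-IP) x two treatments (miR mimic, scramble)
#' x `n_replicates` biological replicates of negative-binomially distributed
#' gene counts, with planted gene classes:
#' \itemize{
#'   \item direct targets: enriched `ip_enrichment_fold` in AGO2-IP and
#'     depleted `input_depletion_fold` in Input under the mimic;
#'   \item bead binders: up `bead_fold` in BOTH IP fractions under the mimic
#'     (nonspecific sepharose-bead binding, removable by the IgG contrast);
#'   \item secondary responders: a per-gene log2 effect drawn from
#'     N(0, `secondary_fold_log2_sd`) applied in the Input and
#'     proportionally in both IPs (transcriptome-wide indirect response);
#'   \item null genes: no effect anywhere.
#' }
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_replicates Biological replicates per fraction x treatment cell
#'   (default 3; must be >= 2 so differential tests have within-group
#'   variance).
#' @param frac_direct_target,frac_bead_binder,frac_secondary Proportions of
#'   genes in each planted class; must sum to < 1.
#' @param ip_enrichment_fold Fold applied to direct targets in AGO2-IP under
#'   the mimic (>= 1, default 3).
#' @param input_depletion_fold Fold applied to direct targets in Input under
#'   the mimic (in (0, 1], default 0.6).
#' @param bead_fold Fold applied to bead binders in both IP fractions under
#'   the mimic (>= 1, default 3).
#' @param secondary_fold_log2_sd SD of the per-gene log2 secondary effect.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline abundance
#'   (natural-log scale). Defaults give a median baseline of ~150 counts.
#' @param dispersion Negative-binomial dispersion alpha (> 0), variance
#'   mu + alpha * mu^2. Default 0.02, typical of biological replicates of a
#'   clonal cell line.
#' @param library_size_range Range of per-sample depth multipliers, drawn
#'   uniformly.
#' @param seed Integer RNG seed; the simulator is a pure function of the
#'   config including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_replicates = 3L,
                       frac_direct_target = 0.025,
                       frac_bead_binder = 0.025,
                       frac_secondary = 0.05,
                       ip_enrichment_fold = 3,
                       input_depletion_fold = 0.6,
                       bead_fold = 3,
                       secondary_fold_log2_sd = 0.5,
                       baseline_log_mean = 5,
                       baseline_log_sd = 1.5,
                       dispersion = 0.02,
                       library_size_range = c(0.7, 1.3),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              fractions = c("Input", "AGO2-IP", "IgG-IP"),
              treatments = c("miR", "scramble"),
              frac_direct_target = frac_direct_target,
              frac_bead_binder = frac_bead_binder,
              frac_secondary = frac_secondary,
              ip_enrichment_fold = ip_enrichment_fold,
              input_depletion_fold = input_depletion_fold,
              bead_fold = bead_fold,
              secondary_fold_log2_sd = secondary_fold_log2_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion,
              library_size_range = library_size_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$n_replicates < 2L)
    stop("n_replicates must be >= 2 (differential testing needs within-group variance)")
  fr <- c(cfg$frac_direct_target, cfg$frac_bead_binder, cfg$frac_secondary)
  if (any(fr < 0)) stop("class fractions must be nonnegative")
  if (sum(fr) >= 1) stop("class fractions must sum to < 1")
  folds <- c(cfg$ip_enrichment_fold, cfg$input_depletion_fold, cfg$bead_fold)
  if (any(!is.finite(folds)) || any(folds <= 0))
    stop("fold parameters must be strictly positive")
  if (cfg$ip_enrichment_fold < 1) stop("ip_enrichment_fold must be >= 1")
  if (cfg$input_depletion_fold > 1) stop("input_depletion_fold must be in (0, 1]")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (length(cfg$library_size_range) != 2L || any(cfg$library_size_range <= 0))
    stop("library_size_range must be two positive numbers")
  invisible(cfg)
}

# evaluate `expr` under a private RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an AGO2-RIP-seq count bundle with planted ground truth
#'
#' Draws gene x sample counts from NB(mean = depth_j x baseline_i x
#' fold_ij, dispersion alpha) under the design in [sim_config()], and
#' attaches per-gene truth labels so downstream target calling can be scored
#' by recovery.
#'
#' @param config A [sim_config()] object.
#' @param class_assignment Optional character vector (length `n_genes`) of
#'   classes in `{direct_target, bead_binder, secondary, null}`, overriding
#'   random assignment (used to build multi-miRNA studies with overlapping
#'   target sets).
#' @param baseline Optional vector of baseline abundances (length
#'   `n_genes`), overriding the log-normal draw.
#' @return A list of class `rip_bundle`: `counts` (integer matrix, genes x
#'   samples), `samples` (data.frame: sample_id, fraction, treatment,
#'   replicate), `truth` (data.frame: gene_id, class, and expected fold
#'   effects per fraction under the mimic), `config`.
#' @examples
#' b <- simulate_ripseq_counts(sim_config(n_genes = 200, seed = 7))
#' table(b$truth$class)
#' @export
simulate_ripseq_counts <- function(config, class_assignment = NULL,
                                   baseline = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    ng <- config$n_genes
    gene_id <- sprintf("gene%05d", seq_len(ng))
    if (is.null(class_assignment)) {
      n_dt  <- round(config$frac_direct_target * ng)
      n_bb  <- round(config$frac_bead_binder * ng)
      n_sec <- round(config$frac_secondary * ng)
      cls <- rep("null", ng)
      idx <- sample.int(ng, n_dt + n_bb + n_sec)
      cls[idx[seq_len(n_dt)]] <- "direct_target"
      if (n_bb)  cls[idx[n_dt + seq_len(n_bb)]] <- "bead_binder"
      if (n_sec) cls[idx[n_dt + n_bb + seq_len(n_sec)]] <- "secondary"
    } else {
      stopifnot(length(class_assignment) == ng)
      cls <- class_assignment
    }
    if (is.null(baseline)) {
      baseline <- stats::rlnorm(ng, config$baseline_log_mean,
                                config$baseline_log_sd)
    }
    stopifnot(length(baseline) == ng, all(baseline > 0))

    # per-gene expected fold under the mimic, by fraction
    sec_eff <- ifelse(cls == "secondary",
                      2^stats::rnorm(ng, 0, config$secondary_fold_log2_sd), 1)
    fold_ago2 <- ifelse(cls == "direct_target", config$ip_enrichment_fold,
                 ifelse(cls == "bead_binder", config$bead_fold, 1)) * sec_eff
    fold_igg <- ifelse(cls == "bead_binder", config$bead_fold, 1) * sec_eff
    fold_input <- ifelse(cls == "direct_target", config$input_depletion_fold,
                         1) * sec_eff

    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        treatment = config$treatments,
                        fraction = config$fractions,
                        stringsAsFactors = FALSE)
    samples <- data.frame(fraction = grid$fraction,
                          treatment = grid$treatment,
                          replicate = grid$replicate,
                          stringsAsFactors = FALSE)
    samples$sample_id <- paste(samples$fraction, samples$treatment,
                               samples$replicate, sep = "_")
    depth <- stats::runif(nrow(samples), config$library_size_range[1],
                          config$library_size_range[2])
    names(depth) <- samples$sample_id

    counts <- matrix(0L, nrow = ng, ncol = nrow(samples),
                     dimnames = list(gene_id, samples$sample_id))
    size <- 1 / config$dispersion
    for (j in seq_len(nrow(samples))) {
      fold <- if (samples$treatment[j] == "miR") {
        switch(samples$fraction[j],
               "AGO2-IP" = fold_ago2, "IgG-IP" = fold_igg, "Input" = fold_input)
      } else rep(1, ng)
      mu <- depth[j] * baseline * fold
      counts[, j] <- stats::rnbinom(ng, mu = mu, size = size)
    }
    storage.mode(counts) <- "integer"

    truth <- data.frame(gene_id = gene_id, class = cls,
                        baseline = baseline,
                        fold_ago2_mir = fold_ago2,
                        fold_igg_mir = fold_igg,
                        fold_input_mir = fold_input,
                        stringsAsFactors = FALSE)
    structure(list(counts = counts,
                   samples = samples[, c("sample_id", "fraction", "treatment",
                                         "replicate")],
                   truth = truth, depth = depth, config = config),
              class = "rip_bundle")
  })
}

#' @export
print.rip_bundle <- function(x, ...) {
  cat("RIP-seq count bundle:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  cat("  design:", paste(unique(x$samples$fraction), collapse = ", "),
      "x", paste(unique(x$samples$treatment), collapse = "/"),
      "x", max(x$samples$replicate), "replicates\n")
  if (!is.null(x$truth)) {
    tab <- table(x$truth$class)
    cat("  truth classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate transcript regions carrying planted seed sites
#'
#' Generates one random DNA region per gene. Regions of direct-target genes
#' carry at least one planted canonical seed site for `mirna` (class drawn
#' from 7mer-A1 / 7mer-m8 / 8mer); all other regions are rejection-sampled
#' to contain no exact seed match of any class (no 6mer core occurrence).
#'
#' @param truth Truth data.frame from [simulate_ripseq_counts()] (columns
#'   `gene_id`, `class`), or a character vector of classes named by gene id.
#' @param mirna A [mature_mirna()] object (>= 8 nt).
#' @param length Region length in nt (default 300); must exceed the longest
#'   site pattern.
#' @param seed RNG seed.
#' @return Named character vector of DNA sequences (one per gene), with
#'   attribute `planted` (data.frame: gene_id, start, site_class for planted
#'   sites). Writable as FASTA via [write_fasta()].
#' @export
simulate_utrs <- function(truth, mirna, length = 300L, seed = 1L) {
  if (is.data.frame(truth)) {
    cls <- stats::setNames(truth$class, truth$gene_id)
  } else cls <- truth
  pats_rna <- seed_site_patterns(mirna)
  pats <- chartr("U", "T", pats_rna)    # regions are DNA
  if (length <= max(nchar(pats)))
    stop("region length must exceed the longest site pattern")
  six <- pats[["6mer"]]
  planted_classes <- c("7mer-A1", "7mer-m8", "8mer")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rand_clean <- function(n) {
      # region with no 6mer-core occurrence (hence no site of any class)
      repeat {
        s <- paste(sample(bases, n, replace = TRUE), collapse = "")
        if (!grepl(six, s, fixed = TRUE)) return(s)
      }
    }
    out <- character(length(cls))
    names(out) <- names(cls)
    planted <- list()
    for (i in seq_along(cls)) {
      if (cls[[i]] == "direct_target") {
        for (try in 1:200) {
          site_class <- sample(planted_classes, 1)
          pat <- pats[[site_class]]
          s <- rand_clean(length)
          pos <- sample.int(length - nchar(pat) - 1L, 1) + 1L
          substr(s, pos, pos + nchar(pat) - 1L) <- pat
          # verify the planted start classifies as intended and nothing
          # at the junctions upgraded/duplicated the site unexpectedly
          hits <- scan_sequence(s, mirna, gene_id = names(cls)[i])
          ok <- any(hits$start == pos & hits$site_class == site_class)
          if (ok) {
            out[i] <- s
            planted[[names(cls)[i]]] <-
              data.frame(gene_id = names(cls)[i], start = pos,
                         site_class = site_class, stringsAsFactors = FALSE)
            break
          }
        }
        if (out[i] == "") stop("failed to plant a seed site for ",
                               names(cls)[i])
      } else {
        out[i] <- rand_clean(length)
      }
    }
    attr(out, "planted") <- if (length(planted))
      do.call(rbind, c(planted, list(make.row.names = FALSE)))
    else data.frame(gene_id = character(0), start = integer(0),
                    site_class = character(0))
    out
  })
}

#' Configuration for the synthetic patient cohort generator
#'
#' @param n_patients Cohort size (>= 10).
#' @param baseline_hazard Baseline event hazard per month (> 0). The default
#'   0.02/month gives a median event time of ~35 months in the low-risk
#'   group.
#' @param log_hazard_ratio_per_group Log hazard ratio of the high vs low
#'   marker-expression group.
#' @param censoring_rate Expected fraction of censored records, in [0, 1].
#' @param covariates Optional list of covariate specs, each a list with
#'   `name`, `dist` ("normal" or "binary"), distribution parameters
#'   (`mean`/`sd` or `prob`), and `loghr`.
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 80L, baseline_hazard = 0.02,
                          log_hazard_ratio_per_group = log(2),
                          censoring_rate = 0.3, covariates = list(),
                          seed = 1L) {
  if (n_patients < 10L) stop("n_patients must be >= 10")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 baseline_hazard = baseline_hazard,
                 log_hazard_ratio_per_group = log_hazard_ratio_per_group,
                 censoring_rate = censoring_rate,
                 covariates = covariates, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a patient cohort with exponential event times
#'
#' Event times are exponential with hazard `baseline_hazard *
#' exp(beta_group * group + sum(beta_k * x_k))`; censoring is independent
#' exponential, with its rate calibrated so the expected censored fraction
#' equals `censoring_rate` (with `censoring_rate = 1` every record is
#' censored at a uniform fraction of its event time).
#'
#' @param config A [cohort_config()] object.
#' @param endpoint Endpoint label recorded on each record ("OS" or "DFS").
#' @return data.frame of class `cohort`: patient_id, time (months), event
#'   (1 = event), endpoint, group ("low"/"high"), plus one column per
#'   covariate.
#' @export
simulate_cohort <- function(config, endpoint = c("OS", "DFS")) {
  stopifnot(inherits(config, "cohort_config"))
  endpoint <- match.arg(endpoint)
  with_seed(config$seed, {
    n <- config$n_patients
    group <- sample(c(0L, 1L), n, replace = TRUE)
    lp <- config$log_hazard_ratio_per_group * group
    covs <- list()
    for (cv in config$covariates) {
      x <- switch(cv$dist,
                  normal = stats::rnorm(n, cv$mean %||% 0, cv$sd %||% 1),
                  binary = stats::rbinom(n, 1L, cv$prob %||% 0.5),
                  stop("unknown covariate distribution: ", cv$dist))
      lp <- lp + (cv$loghr %||% 0) * x
      covs[[cv$name]] <- x
    }
    rate <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = rate)
    r <- config$censoring_rate
    if (r >= 1) {
      time <- t_event * stats::runif(n)
      event <- rep(0L, n)
    } else if (r <= 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      c_rate <- mean(rate) * r / (1 - r)
      t_cens <- stats::rexp(n, rate = c_rate)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      time = time, event = event, endpoint = endpoint,
                      group = ifelse(group == 1L, "high", "low"),
                      stringsAsFactors = FALSE)
    for (nm in names(covs)) out[[nm]] <- covs[[nm]]
    class(out) <- c("cohort", "data.frame")
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-miRNA RIP-seq study with overlapping targetomes
#'
#' Builds one count bundle per miRNA over a shared gene universe and shared
#' baseline abundances, with a controllable fraction of direct targets
#' common to all miRNAs (mirroring seed-family co-regulation). Bead binders
#' are shared across miRNAs (the beads do not depend on the mimic).
#'
#' @param config Base [sim_config()]; its `seed` seeds the study.
#' @param mirnas Character vector of miRNA labels.
#' @param shared_fraction Fraction of each miRNA's direct targets shared by
#'   all miRNAs.
#' @return Named list of `rip_bundle`, one per miRNA.
#' @export
simulate_targetome_study <- function(config, mirnas = c("miR-34c", "miR-449a"),
                                     shared_fraction = 0.3) {
  stopifnot(inherits(config, "sim_config"), length(mirnas) >= 1L)
  with_seed(config$seed, {
    ng <- config$n_genes
    n_dt  <- round(config$frac_direct_target * ng)
    n_bb  <- round(config$frac_bead_binder * ng)
    n_sec <- round(config$frac_secondary * ng)
    n_shared <- round(shared_fraction * n_dt)
    pool <- sample.int(ng)
    shared_dt <- pool[seq_len(n_shared)]
    pool <- pool[-seq_len(n_shared)]
    bead <- pool[seq_len(n_bb)]
    pool <- pool[-seq_len(n_bb)]
    baseline <- stats::rlnorm(ng, config$baseline_log_mean,
                              config$baseline_log_sd)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, length(mirnas))
    bundles <- list()
    for (k in seq_along(mirnas)) {
      own_dt <- pool[seq_len(n_dt - n_shared)]
      pool <- pool[-seq_len(n_dt - n_shared)]
      sec <- pool[seq_len(n_sec)]
      pool <- pool[-seq_len(n_sec)]
      cls <- rep("null", ng)
      cls[c(shared_dt, own_dt)] <- "direct_target"
      cls[bead] <- "bead_binder"
      cls[sec] <- "secondary"
      cfg_k <- config
      cfg_k$seed <- sub_seeds[k]
      bundles[[mirnas[k]]] <- simulate_ripseq_counts(cfg_k,
                                                     class_assignment = cls,
                                                     baseline = baseline)
    }
    bundles
  })
}

#' Load the packaged direct-target gene-list fixture
#'
#' Returns the published per-miRNA direct-target gene lists shipped with the
#' package as a plain-text fixture: genes specific to miR-34c, genes
#' specific to miR-449a, and the genes shared by both (the co-regulated
#' set containing STK3, C9orf78 and STRN3).
#'
#' @return A list with elements `mir34c_specific`, `mir449a_specific`,
#'   `shared` (character vectors of gene symbols, verbatim spellings),
#'   `mir34c_targets` and `mir449a_targets` (specific union shared), and
#'   `table` (the full data.frame with descriptions).
#' @examples
#' fx <- load_table2_fixture()
#' length(fx$shared)
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_targets.tsv", package = "ripscope",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sp34 <- tab$gene_id[tab$set == "miR-34c"]
  sp449 <- tab$gene_id[tab$set == "miR-449a"]
  shared <- tab$gene_id[tab$set == "shared"]
  list(mir34c_specific = sp34,
       mir449a_specific = sp449,
       shared = shared,
       mir34c_targets = c(sp34, shared),
       mir449a_targets = c(sp449, shared),
       table = tab)
}
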