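#' Read a count matrix and sample sheet into a bundle
#'
#' Counts TSV: `gene_id` column plus one integer column per sample. Sample
#' sheet TSV: columns `sample_id`, `fraction`, `treatment`, `replicate`.
#' Windows line endings and stray surrounding whitespace in identifiers are
#' tolerated. Duplicate gene ids, or sheet samples missing from the matrix,
#' are errors.
#'
#' @param counts_path Path to the counts TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @param truth_path Optional path to a truth-label TSV (columns `gene_id`,
#'   `class`).
#' @return A `rip_bundle`.
#' @export
read_counts <- function(counts_path, samples_path, truth_path = NULL) {
  ctab <- utils::read.delim(counts_path, check.names = FALSE,
                            stringsAsFactors = FALSE, strip.white = TRUE)
  if (!"gene_id" %in% names(ctab)) stop("counts file must have a gene_id column")
  gene_id <- trimws(as.character(ctab$gene_id))
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop("duplicate gene id(s) in counts: ", paste(unique(dup), collapse = ", "))
  counts <- as.matrix(ctab[, setdiff(names(ctab), "gene_id"), drop = FALSE])
  colnames(counts) <- trimws(colnames(counts))
  rownames(counts) <- gene_id
  if (any(counts < 0)) stop("negative counts")
  storage.mode(counts) <- "integer"
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               strip.white = TRUE)
  need <- c("sample_id", "fraction", "treatment", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- trimws(samples$sample_id)
  absent <- setdiff(samples$sample_id, colnames(counts))
  if (length(absent))
    stop("sample(s) in sheet but not in count matrix: ",
         paste(absent, collapse = ", "))
  counts <- counts[, samples$sample_id, drop = FALSE]
  truth <- NULL
  if (!is.null(truth_path)) {
    truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE,
                               strip.white = TRUE)
    stopifnot(all(c("gene_id", "class") %in% names(truth)))
  }
  structure(list(counts = counts,
                 samples = samples[, need],
                 truth = truth, config = NULL),
            class = "rip_bundle")
}

#' Write a bundle's counts, sample sheet and truth labels as TSV
#'
#' @param bundle A `rip_bundle`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "bundle").
#' @return Invisibly, the paths written (counts, samples, and truth when
#'   present).
#' @export
write_bundle <- function(bundle, dir, prefix = "bundle") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, paste0(prefix, "_counts.tsv"))
  sp <- file.path(dir, paste0(prefix, "_samples.tsv"))
  ctab <- data.frame(gene_id = rownames(bundle$counts), bundle$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ctab, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$samples, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(counts = cp, samples = sp)
  if (!is.null(bundle$truth)) {
    tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
    utils::write.table(bundle$truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA as a named character vector
#'
#' @param path FASTA path (headers become names; first whitespace-delimited
#'   token).
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Read mature miRNAs from a 2-column TSV or FASTA
#'
#' @param path TSV with columns `name`, `sequence`, or a FASTA file.
#' @return Named list of [mature_mirna()] objects.
#' @export
read_mirnas <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    seqs <- read_fasta(path)
    out <- mapply(mature_mirna, names(seqs), seqs, SIMPLIFY = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             strip.white = TRUE)
    stopifnot(all(c("name", "sequence") %in% names(tab)))
    out <- mapply(mature_mirna, tab$name, tab$sequence, SIMPLIFY = FALSE)
  }
  out
}

#' Read a patient cohort TSV
#'
#' Expected columns: `patient_id`, `time`, `event`; everything else is
#' treated as covariates / annotations.
#'
#' @param path Cohort TSV path.
#' @return data.frame of class `cohort`.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, strip.white = TRUE)
  miss <- setdiff(c("patient_id", "time", "event"), names(tab))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "))
  surv_args(tab)   # validates time/event
  class(tab) <- c("cohort", "data.frame")
  tab
}

#' Write a DE result table as TSV
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @export
write_de_result <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
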