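#' Construct a mature miRNA object
#'
#' Holds a mature miRNA sequence (5'->3') and validates it for seed-site
#' scanning. The seed region is nucleotides 2-8, so at least 8 nt are
#' required. DNA-alphabet input (T) is transliterated to RNA (U).
#'
#' @param name miRNA name, e.g. "miR-34c-3p".
#' @param sequence Mature sequence 5'->3', RNA or DNA alphabet.
#' @return An object of class `mature_mirna` with elements `name` and
#'   `sequence` (RNA alphabet, upper case).
#' @examples
#' mir <- mature_mirna("let-7-like", "UAGCAGCACGUAAAUAUUGGCG")
#' seed_site_patterns(mir)
#' @export
mature_mirna <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  seq <- chartr("Tt", "Uu", toupper(sequence))
  seq <- toupper(seq)
  if (nchar(seq) < 8L)
    stop("miRNA sequence must be at least 8 nt (seed positions 1-8): ", name)
  if (grepl("[^ACGU]", seq))
    stop("miRNA sequence contains characters outside {A,C,G,U/T}: ", name)
  structure(list(name = name, sequence = seq), class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat("mature miRNA", x$name, " (", nchar(x$sequence), "nt)\n", sep = " ")
  cat("  5'-", x$sequence, "-3'\n", sep = "")
  invisible(x)
}

# reverse complement of an RNA string (5'->3' in, 5'->3' out)
rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Canonical seed-match patterns for a miRNA
#'
#' Derives the four canonical target-site patterns from the seed region
#' (miRNA positions m1-m8), written in the target-strand RNA alphabet:
#' \itemize{
#'   \item 6mer: reverse complement of m2-m7
#'   \item 7mer-m8: reverse complement of m2-m8
#'   \item 7mer-A1: reverse complement of m2-m7 followed by A
#'   \item 8mer: reverse complement of m2-m8 followed by A
#' }
#' The 8mer therefore contains the 7mer-m8 as a prefix and the 7mer-A1 as a
#' suffix.
#'
#' @param mirna A [mature_mirna()] object.
#' @return Named character vector with elements `6mer`, `7mer-A1`,
#'   `7mer-m8`, `8mer`.
#' @export
seed_site_patterns <- function(mirna) {
  if (!inherits(mirna, "mature_mirna")) stop("expected a 'mature_mirna' object")
  s <- mirna$sequence
  six  <- rna_revcomp(substr(s, 2L, 7L))
  sevm8 <- rna_revcomp(substr(s, 2L, 8L))
  c("6mer"    = six,
    "7mer-A1" = paste0(six, "A"),
    "7mer-m8" = sevm8,
    "8mer"    = paste0(sevm8, "A"))
}

# site classes in increasing precedence order
SEED_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

# all (possibly overlapping) start positions of a literal pattern;
# perl lookahead gives overlapping hits, which fixed matching would miss
literal_starts <- function(pattern, subject) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Scan a transcript region for canonical miRNA seed-match sites
#'
#' Every start position matching at least one canonical pattern is reported
#' exactly once, labelled with the highest-precedence class matching at that
#' start (8mer > 7mer-m8 > 7mer-A1 > 6mer). Overlapping sites with distinct
#' starts are distinct. DNA input is transliterated (T -> U) before
#' matching; ambiguous bases (N) never match. Coordinates are 1-based
#' inclusive.
#'
#' @param region Character scalar: the sequence to scan (RNA or DNA).
#' @param mirna A [mature_mirna()] object.
#' @param gene_id Identifier recorded in the output (default `NA`).
#' @return data.frame with columns `gene_id`, `start`, `site_class`,
#'   `matched_subsequence` (RNA alphabet), ordered by `start`.
#' @export
scan_sequence <- function(region, mirna, gene_id = NA_character_) {
  stopifnot(is.character(region), length(region) == 1L)
  seq <- chartr("Tt", "Uu", toupper(region))
  pats <- seed_site_patterns(mirna)
  best <- integer(0)          # start -> class rank
  starts_env <- new.env(parent = emptyenv())
  # precedence: iterate classes in increasing rank, later overwrite earlier
  hits <- list()
  for (k in seq_along(SEED_CLASSES)) {
    cls <- SEED_CLASSES[k]
    for (st in literal_starts(pats[[cls]], seq)) {
      key <- as.character(st)
      cur <- hits[[key]]
      if (is.null(cur) || cur < k) hits[[key]] <- k
    }
  }
  if (!length(hits)) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      site_class = character(0),
                      matched_subsequence = character(0),
                      stringsAsFactors = FALSE))
  }
  st <- sort(as.integer(names(hits)))
  rank <- vapply(as.character(st), function(k) hits[[k]], integer(1))
  cls <- SEED_CLASSES[rank]
  len <- nchar(pats[cls])
  data.frame(gene_id = rep(gene_id, length(st)),
             start = st,
             site_class = cls,
             matched_subsequence = substring(seq, st, st + len - 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate called direct targets with seed-site counts
#'
#' For each direct target in a targetome, scans its transcript region (3'UTR
#' or any user-supplied region) and tabulates canonical site counts per
#' class plus the best (highest-precedence) class found. Targets without a
#' region are kept and flagged, never dropped.
#'
#' @param targetome A `targetome` object from [call_direct_targets()], or a
#'   character vector of gene ids.
#' @param regions Named character vector (or coercible, e.g. a
#'   `DNAStringSet`) of sequences; names are gene ids.
#' @param mirna A [mature_mirna()] object.
#' @return data.frame with columns `gene_id`, `n_8mer`, `n_7mer_m8`,
#'   `n_7mer_A1`, `n_6mer`, `best_class` (`NA` if no site), `no_sequence`.
#' @export
annotate_targets <- function(targetome, regions, mirna) {
  genes <- if (inherits(targetome, "targetome")) targetome$direct_targets
           else as.character(targetome)
  region_names <- names(regions)
  regions <- as.character(regions)
  names(regions) <- region_names
  if (is.null(names(regions)) && length(regions) > 0)
    stop("'regions' must be named by gene id")
  n <- length(genes)
  out <- data.frame(gene_id = genes,
                    n_8mer = integer(n), n_7mer_m8 = integer(n),
                    n_7mer_A1 = integer(n), n_6mer = integer(n),
                    best_class = rep(NA_character_, n),
                    no_sequence = logical(n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (!g %in% names(regions)) {
      out$no_sequence[i] <- TRUE
      next
    }
    sites <- scan_sequence(regions[[g]], mirna, gene_id = g)
    tab <- table(factor(sites$site_class, levels = SEED_CLASSES))
    out$n_6mer[i]    <- tab[["6mer"]]
    out$n_7mer_A1[i] <- tab[["7mer-A1"]]
    out$n_7mer_m8[i] <- tab[["7mer-m8"]]
    out$n_8mer[i]    <- tab[["8mer"]]
    present <- SEED_CLASSES[tab > 0]
    if (length(present)) out$best_class[i] <- present[length(present)]
  }
  out
}
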