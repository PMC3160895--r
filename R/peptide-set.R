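#' @importFrom stats as.dist coef cor cutree glm.fit hclust lm median
#'   predict runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Alphabet: the 20 standard residues plus the ambiguity codes used in
# peptide-array annotations (B = N/D, Z = Q/E, J = L/I, X = unknown).
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AMBIGUITY_AA <- c("B", "X", "Z", "J")
PEPTIDE_ALPHABET <- c(STANDARD_AA, AMBIGUITY_AA)

#' Construct a validated peptide set
#'
#' A `PeptideSet` is the unit of computation for the whole toolkit: an
#' ordered table of peptides with a binary reactivity label and an optional
#' quantitative reactivity. Sequences use the 20 standard one-letter amino
#' acid codes plus the ambiguity codes `B`, `X`, `Z`, `J`.
#'
#' Labelled reactivities are checked against the assay convention: positive
#' peptides have reactivity in \[10000, 65536\], negative peptides in
#' \[1, 1000\].
#'
#' @param id Character vector of unique peptide identifiers.
#' @param sequence Character vector of uppercase peptide sequences.
#' @param label Character vector over `"positive"`, `"negative"`,
#'   `"unknown"`; recycled if length 1. Default `"unknown"`.
#' @param reactivity Optional numeric reactivity in \[1, 65536\] (`NA`
#'   allowed).
#' @param strict If `TRUE` (default), duplicate sequences are an error,
#'   matching the deduplicated assay sets.
#' @return A `PeptideSet`: a data frame with columns `id`, `sequence`,
#'   `label`, `reactivity`.
#' @examples
#' peptide_set(c("p1", "p2"), c("ACDEFGHIKLMNPQR", "YYYYYYYYYYYYY"),
#'             label = c("positive", "negative"),
#'             reactivity = c(20000, 50))
#' @export
peptide_set <- function(id, sequence, label = "unknown", reactivity = NA_real_,
                        strict = TRUE) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  n <- length(sequence)
  if (length(id) != n) stop("'id' and 'sequence' lengths differ")
  label <- rep_len(as.character(label), n)
  reactivity <- rep_len(as.numeric(reactivity), n)
  ps <- data.frame(id = id, sequence = sequence, label = label,
                   reactivity = reactivity, stringsAsFactors = FALSE)
  class(ps) <- c("PeptideSet", "data.frame")
  validate_peptide_set(ps, strict = strict)
}

validate_peptide_set <- function(ps, strict = TRUE) {
  if (anyDuplicated(ps$id))
    stop("duplicate peptide ids: ", paste(unique(ps$id[duplicated(ps$id)]),
                                          collapse = ", "))
  if (strict && anyDuplicated(ps$sequence))
    stop("duplicate peptide sequences (use strict = FALSE to allow): ",
         paste(ps$id[duplicated(ps$sequence)], collapse = ", "))
  bad_label <- !ps$label %in% c("positive", "negative", "unknown")
  if (any(bad_label))
    stop("invalid label for peptide ", ps$id[which(bad_label)[1]],
         ": ", ps$label[which(bad_label)[1]])
  for (k in seq_len(nrow(ps))) {
    s <- ps$sequence[k]
    if (!nzchar(s)) stop("empty sequence for peptide ", ps$id[k])
    if (s != toupper(s)) stop("sequence not uppercase for peptide ", ps$id[k])
    res <- strsplit(s, "")[[1]]
    bad <- setdiff(res, PEPTIDE_ALPHABET)
    if (length(bad))
      stop("invalid residue(s) ", paste(bad, collapse = ""),
           " in peptide ", ps$id[k])
  }
  r <- ps$reactivity
  if (any(!is.na(r) & (r < 1 | r > 65536)))
    stop("reactivity outside [1, 65536] for peptide ",
         ps$id[which(!is.na(r) & (r < 1 | r > 65536))[1]])
  bad_pos <- ps$label == "positive" & !is.na(r) & r < 10000
  bad_neg <- ps$label == "negative" & !is.na(r) & r > 1000
  if (any(bad_pos))
    stop("positive peptide with reactivity < 10000: ", ps$id[which(bad_pos)[1]])
  if (any(bad_neg))
    stop("negative peptide with reactivity > 1000: ", ps$id[which(bad_neg)[1]])
  ps
}

#' @method print PeptideSet
#' @export
print.PeptideSet <- function(x, ...) {
  cat(sprintf("PeptideSet with %d peptides (%d positive, %d negative, %d unknown)\n",
              nrow(x), sum(x$label == "positive"), sum(x$label == "negative"),
              sum(x$label == "unknown")))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a peptide set from TSV or FASTA
#'
#' TSV files are tab-delimited with a header row and columns
#' `id`, `sequence` and optionally `label`, `reactivity`. FASTA description
#' lines may carry `label=...` and `reactivity=...` key-value tokens;
#' records without them default to label `"unknown"`.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"fasta"`; default guessed from the extension.
#' @param strict Forwarded to [peptide_set()].
#' @return A `PeptideSet`.
#' @export
read_peptides <- function(path, format = c("auto", "tsv", "fasta"),
                          strict = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("id", "sequence") %in% names(tab)))
      stop("TSV parse error in ", path, ": need columns 'id' and 'sequence'")
    peptide_set(tab$id, tab$sequence,
                label = if ("label" %in% names(tab)) tab$label else "unknown",
                reactivity = if ("reactivity" %in% names(tab))
                  tab$reactivity else NA_real_,
                strict = strict)
  } else {
    seqs <- Biostrings::readAAStringSet(path)
    hdr <- names(seqs)
    toks <- strsplit(hdr, "[ \t]+")
    id <- vapply(toks, `[[`, "", 1L)
    grab <- function(tk, key) {
      hit <- grep(paste0("^", key, "="), tk, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    label <- vapply(toks, grab, "", key = "label")
    label[is.na(label)] <- "unknown"
    reactivity <- as.numeric(vapply(toks, grab, "", key = "reactivity"))
    peptide_set(id, as.character(seqs), label = label,
                reactivity = reactivity, strict = strict)
  }
}

#' Write a peptide set
#'
#' @param ps A `PeptideSet`.
#' @param path Output path.
#' @param format `"tsv"` or `"fasta"`.
#' @export
write_peptides <- function(ps, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(as.data.frame(ps), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    hdr <- ifelse(is.na(ps$reactivity),
                  sprintf("%s label=%s", ps$id, ps$label),
                  sprintf("%s label=%s reactivity=%g", ps$id, ps$label,
                          ps$reactivity))
    writeLines(paste0(">", hdr, "\n", ps$sequence), path)
  }
  invisible(path)
}

#' Write / read a de novo candidate list
#'
#' Candidate lists are TSV with columns `id`, `sequence`,
#' `predicted_reactivity` and `class` (one of `H`, `L`, `M`); they round-trip
#' exactly through [read_candidates()].
#'
#' @param candidates A `CandidateList` (see [rank_and_select()]) or a data
#'   frame with the four columns above.
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0) stop("candidate list is empty")
  need <- c("id", "sequence", "predicted_reactivity", "class")
  if (!all(need %in% names(candidates)))
    stop("candidate list must have columns ", paste(need, collapse = ", "))
  write.table(candidates[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "predicted_reactivity", "class")
  if (!all(need %in% names(tab)))
    stop("candidate TSV parse error in ", path)
  if (!all(tab$class %in% c("H", "L", "M")))
    stop("candidate class must be H, L or M")
  class(tab) <- c("CandidateList", "data.frame")
  tab
}

#' Toolkit run configuration
#'
#' Collects the tunable constants of the pipeline in one place. All
#' randomness in the toolkit (candidate sampling, medium-list selection,
#' synthetic data) flows from the single `seed`.
#'
#' @param window Sliding-window length for the propensity-scale features
#'   (residues). Default 9, the typical antibody binding-site footprint.
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param substitution_matrix Substitution matrix name (only `"BLOSUM50"`
#'   ships).
#' @param cluster_cutoff Complete-linkage dendrogram cut height on the
#'   \[0, 1\] local-alignment distance. Default 0.7.
#' @param min_h,min_l,min_m Minimum sizes of positive (H), negative (L) and
#'   mixed (M) clusters: 5, 8, 5.
#' @param m_tolerance Maximum deviation of an M cluster's positive fraction
#'   from the training positive fraction. Default 0.05.
#' @param select_count Candidates selected per reactivity class. Default
#'   1100.
#' @param max_common_stretch Longest common substring allowed between a
#'   candidate and any training/test sequence (residues). Default 3.
#' @param max_identity,identity_window Identity cap within a sliding
#'   comparison window against the training set: at most 5 matches in any
#'   window of 11.
#' @param enumeration_cap Maximum sequences enumerated per motif; larger
#'   motif spaces are down-sampled with the run seed.
#' @param pool_cap Maximum candidates per class carried into novelty
#'   filtering and reactivity prediction; larger pools are down-sampled
#'   with the run seed.
#' @param collinearity_threshold Absolute correlation above which one of a
#'   feature pair is dropped before M5 selection.
#' @param seed Integer RNG seed.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(window = 9L, gap_open = 10, gap_extend = 1,
                       substitution_matrix = "BLOSUM50",
                       cluster_cutoff = 0.7,
                       min_h = 5L, min_l = 8L, min_m = 5L,
                       m_tolerance = 0.05,
                       select_count = 1100L,
                       max_common_stretch = 3L,
                       max_identity = 5L, identity_window = 11L,
                       enumeration_cap = 1e5,
                       pool_cap = 2e4,
                       collinearity_threshold = 0.95,
                       seed = 1L) {
  stopifnot(window >= 1, gap_open >= gap_extend, gap_extend > 0,
            cluster_cutoff > 0, cluster_cutoff < 1,
            min_h >= 1, min_l >= 1, min_m >= 1,
            select_count >= 1, max_common_stretch >= 1,
            max_identity >= 1, identity_window >= max_identity,
            enumeration_cap >= 1, pool_cap >= 1)
  cfg <- list(window = as.integer(window), gap_open = gap_open,
              gap_extend = gap_extend,
              substitution_matrix = substitution_matrix,
              cluster_cutoff = cluster_cutoff,
              min_h = as.integer(min_h), min_l = as.integer(min_l),
              min_m = as.integer(min_m), m_tolerance = m_tolerance,
              select_count = as.integer(select_count),
              max_common_stretch = as.integer(max_common_stretch),
              max_identity = as.integer(max_identity),
              identity_window = as.integer(identity_window),
              enumeration_cap = enumeration_cap,
              pool_cap = pool_cap,
              collinearity_threshold = collinearity_threshold,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

# split sequences into residue character vectors
seq_residues <- function(sequences) strsplit(sequences, "", fixed = TRUE)
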