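# Cached BLOSUM50 extended with a J (Leu/Ile ambiguity) row copied from X,
# which BLOSUM50 does not define. Ambiguity codes B, Z, X use the matrix's
# own rows.
.align_cache <- new.env(parent = emptyenv())

blosum_matrix <- function(name = "BLOSUM50") {
  if (name != "BLOSUM50") stop("only BLOSUM50 ships with the toolkit")
  if (is.null(.align_cache$BLOSUM50)) {
    env <- new.env()
    utils::data("BLOSUM50", package = "Biostrings", envir = env)
    m <- env$BLOSUM50
    keep <- intersect(rownames(m), c(STANDARD_AA, "B", "Z", "X"))
    m <- m[keep, keep]
    m <- rbind(m, J = m["X", ])
    m <- cbind(m, J = c(m["X", colnames(m) != "J"], m["X", "X"]))
    .align_cache$BLOSUM50 <- m[PEPTIDE_ALPHABET, PEPTIDE_ALPHABET]
  }
  .align_cache$BLOSUM50
}

#' Pairwise alignment parameters
#'
#' @param mode `"global"` (Needleman-Wunsch) or `"local"`
#'   (Smith-Waterman).
#' @param substitution_matrix Matrix name; only `"BLOSUM50"` ships.
#' @param gap_open,gap_extend Affine gap penalties: a gap of length L costs
#'   `gap_open + L * gap_extend`. Defaults 10 and 1.
#' @return A list of class `AlignmentParams`.
#' @export
alignment_params <- function(mode = c("global", "local"),
                             substitution_matrix = "BLOSUM50",
                             gap_open = 10, gap_extend = 1) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  structure(list(mode = mode, substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "AlignmentParams")
}

align_type <- function(params) {
  if (params$mode == "global") "global" else "local"
}

#' Optimal pairwise alignment score
#'
#' Exact affine-gap dynamic-programming score of two peptide sequences,
#' global (Needleman-Wunsch) or local (Smith-Waterman). Local scores are
#' bounded below by zero (the empty alignment).
#'
#' @param a,b Peptide sequences.
#' @param params An [alignment_params()] object.
#' @return The optimal alignment score.
#' @export
align_score <- function(a, b, params = alignment_params()) {
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, type = align_type(params),
    substitutionMatrix = blosum_matrix(params$substitution_matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE))
}

# Score a set of query sequences against one subject in a single call.
align_score_many <- function(queries, subject, params) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), subject, type = align_type(params),
    substitutionMatrix = blosum_matrix(params$substitution_matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE))
}

#' All-vs-all alignment score matrix
#'
#' Aligns every peptide of a set against every other (and itself) and
#' returns the symmetric score matrix for one alignment mode.
#'
#' @param ps A `PeptideSet`.
#' @param params An [alignment_params()] object.
#' @return A `PairwiseScoreMatrix`: an n x n numeric matrix with peptide
#'   ids as dimnames and attributes `mode` and `params`.
#' @export
score_matrix <- function(ps, params = alignment_params()) {
  n <- nrow(ps)
  if (n < 2) stop("need at least 2 peptides")
  m <- matrix(0, n, n, dimnames = list(ps$id, ps$id))
  for (j in seq_len(n)) {
    m[, j] <- align_score_many(ps$sequence, ps$sequence[j], params)
  }
  # the DP is symmetric; enforce exactly against round-off
  m <- (m + t(m)) / 2
  structure(m, mode_name = params$mode, params = params,
            class = c("PairwiseScoreMatrix", class(m)))
}

# Score a new set of sequences against a reference set: rows = queries,
# columns = reference peptides.
cross_score_matrix <- function(sequences, ref, params = alignment_params()) {
  m <- matrix(0, length(sequences), nrow(ref),
              dimnames = list(NULL, ref$id))
  for (j in seq_len(nrow(ref))) {
    m[, j] <- align_score_many(sequences, ref$sequence[j], params)
  }
  m
}

#' Alignment-derived features for one peptide
#'
#' For one peptide the maxima of its alignment scores against the
#' positive-labelled and negative-labelled reference peptides, and their
#' difference, per alignment mode: `MaxScore0` (best score against a
#' negative), `MaxScore1` (best against a positive) and
#' `DiffMaxScore = MaxScore1 - MaxScore0`. The peptide itself is always
#' excluded from the maxima.
#'
#' @param i Row index of the peptide in the matrices.
#' @param m_global,m_local Score matrices from [score_matrix()] (global and
#'   local mode).
#' @param labels Character vector of reference labels aligned with the
#'   matrix columns.
#' @param mask Optional indices excluded from the reference sets (e.g. the
#'   held-out peptide of a cross-validation fold).
#' @return A named numeric vector with components `MaxScore0_nw`,
#'   `MaxScore1_nw`, `MaxScore0_sw`, `MaxScore1_sw`, `DiffMaxScore_nw`,
#'   `DiffMaxScore_sw`.
#' @export
alignment_features <- function(i, m_global, m_local, labels, mask = integer(0)) {
  drop <- unique(c(i, mask))
  pos <- setdiff(which(labels == "positive"), drop)
  neg <- setdiff(which(labels == "negative"), drop)
  if (!length(pos) || !length(neg))
    stop("alignment features undefined: empty positive or negative reference set")
  f <- c(MaxScore0_nw = max(m_global[i, neg]),
         MaxScore1_nw = max(m_global[i, pos]),
         MaxScore0_sw = max(m_local[i, neg]),
         MaxScore1_sw = max(m_local[i, pos]))
  c(f, DiffMaxScore_nw = unname(f["MaxScore1_nw"] - f["MaxScore0_nw"]),
    DiffMaxScore_sw = unname(f["MaxScore1_sw"] - f["MaxScore0_sw"]))
}

ALIGN_FEATURE_NAMES <- c("MaxScore0_nw", "MaxScore1_nw",
                         "MaxScore0_sw", "MaxScore1_sw",
                         "DiffMaxScore_nw", "DiffMaxScore_sw")

#' Alignment feature matrix for a whole set
#'
#' Applies [alignment_features()] to every row index, optionally masking
#' indices from the reference sets.
#'
#' @inheritParams alignment_features
#' @param rows Indices for which to compute features (default: all).
#' @return A numeric matrix, one row per requested index, with the six
#'   alignment feature columns.
#' @export
alignment_feature_matrix <- function(m_global, m_local, labels,
                                     rows = seq_along(labels),
                                     mask = integer(0)) {
  out <- t(vapply(rows, alignment_features, numeric(6),
                  m_global = m_global, m_local = m_local,
                  labels = labels, mask = mask))
  colnames(out) <- ALIGN_FEATURE_NAMES
  out
}

# Alignment features of external query sequences against a labelled
# reference set (rows of cross matrices = queries).
cross_alignment_features <- function(x_global, x_local, ref_labels) {
  pos <- which(ref_labels == "positive")
  neg <- which(ref_labels == "negative")
  if (!length(pos) || !length(neg))
    stop("alignment features undefined: empty positive or negative reference set")
  f <- cbind(MaxScore0_nw = apply(x_global[, neg, drop = FALSE], 1, max),
             MaxScore1_nw = apply(x_global[, pos, drop = FALSE], 1, max),
             MaxScore0_sw = apply(x_local[, neg, drop = FALSE], 1, max),
             MaxScore1_sw = apply(x_local[, pos, drop = FALSE], 1, max))
  cbind(f, DiffMaxScore_nw = f[, "MaxScore1_nw"] - f[, "MaxScore0_nw"],
        DiffMaxScore_sw = f[, "MaxScore1_sw"] - f[, "MaxScore0_sw"])
}
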