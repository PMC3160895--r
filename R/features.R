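# The 37 feature columns, in the order used throughout: sequence length,
# isoelectric point, 24 residue occurrence counts, the five window-scale
# features, then the six alignment-derived features.
FEATURE_NAMES <- c(
  "LengthSeq", "IsoelPoint",
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
  "R", "S", "T", "V", "W", "Y", "B", "X", "J", "Z",
  "Antigenicity", "Accessibility", "Hydrophilicity", "Flexibility",
  "BetaTurn",
  "MaxScore0_nw", "MaxScore1_nw", "MaxScore0_sw", "MaxScore1_sw",
  "DiffMaxScore_nw", "DiffMaxScore_sw")

SCALE_FEATURE_MAP <- c(Antigenicity = "antigenicity",
                       Accessibility = "accessibility",
                       Hydrophilicity = "hydrophilicity",
                       Flexibility = "flexibility",
                       BetaTurn = "beta_turn")

#' Sequence-derived feature block
#'
#' Computes the 31 sequence-dependent features of the toolkit for each
#' peptide: sequence length, isoelectric point, the 24 residue occurrence
#' counts, and the five window-maximum propensity-scale features.
#'
#' @param ps A `PeptideSet`.
#' @param window Sliding-window length for the scale features. Default 9.
#' @return A numeric matrix, peptides x 31 named columns.
#' @export
sequence_features <- function(ps, window = 9L) {
  scales <- lapply(SCALE_FEATURE_MAP, aa_scale)
  rows <- lapply(ps$sequence, function(s) {
    c(LengthSeq = nchar(s),
      IsoelPoint = isoelectric_point(s),
      aa_counts(s),
      vapply(scales, function(sc) scale_window_feature(s, sc, window), 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ps$id
  colnames(out) <- c("LengthSeq", "IsoelPoint", PEPTIDE_ALPHABET,
                     names(SCALE_FEATURE_MAP))
  out
}

#' Build a normalized training feature table
#'
#' Assembles the full 37-column feature table (sequence block plus the six
#' alignment features), min-max normalizes each column into \[0, 1\] and
#' stores the per-feature (min, max) so that test peptides can later be
#' normalized on the training scale. Constant columns normalize to 0.
#'
#' @param ps A `PeptideSet` (the training set).
#' @param align_features Numeric matrix of the six alignment features, rows
#'   aligned with `ps` (see [alignment_feature_matrix()]).
#' @param window Scale-feature window length.
#' @return A `FeatureTable`: list with `values` (normalized matrix),
#'   `raw` (raw matrix), `norm_params` (2 x 37 min/max matrix) and
#'   `feature_names`.
#' @export
build_feature_table <- function(ps, align_features, window = 9L) {
  align_features <- check_align_block(ps, align_features)
  raw <- cbind(sequence_features(ps, window), align_features)
  raw <- raw[, FEATURE_NAMES, drop = FALSE]
  mins <- apply(raw, 2, min)
  maxs <- apply(raw, 2, max)
  structure(list(values = normalize_features(raw, mins, maxs, clip = FALSE),
                 raw = raw,
                 norm_params = rbind(min = mins, max = maxs),
                 feature_names = FEATURE_NAMES),
            class = "FeatureTable")
}

#' Featurize peptides on a previously learned normalization
#'
#' Computes raw features identically to [build_feature_table()], then
#' normalizes with the stored training (min, max) and clips into \[0, 1\].
#'
#' @param ps A `PeptideSet` (test peptides).
#' @param norm_params The `norm_params` of a training `FeatureTable`.
#' @param align_features Alignment feature matrix for `ps` computed against
#'   the training references.
#' @param window Scale-feature window length.
#' @return A `FeatureTable` normalized on the training scale.
#' @export
apply_feature_table <- function(ps, norm_params, align_features, window = 9L) {
  if (!identical(colnames(norm_params), FEATURE_NAMES))
    stop("norm_params feature names do not match the toolkit feature set")
  align_features <- check_align_block(ps, align_features)
  raw <- cbind(sequence_features(ps, window), align_features)
  raw <- raw[, FEATURE_NAMES, drop = FALSE]
  structure(list(values = normalize_features(raw, norm_params["min", ],
                                             norm_params["max", ],
                                             clip = TRUE),
                 raw = raw, norm_params = norm_params,
                 feature_names = FEATURE_NAMES),
            class = "FeatureTable")
}

check_align_block <- function(ps, align_features) {
  align_features <- as.matrix(align_features)
  if (nrow(align_features) != nrow(ps))
    stop("alignment feature rows do not match the peptide set")
  if (!all(ALIGN_FEATURE_NAMES %in% colnames(align_features)))
    stop("alignment feature columns must be ",
         paste(ALIGN_FEATURE_NAMES, collapse = ", "))
  align_features[, ALIGN_FEATURE_NAMES, drop = FALSE]
}

# Min-max scaling; a constant training column (span 0) maps its own value
# to 0, and out-of-range test values are clipped into [0,1].
normalize_features <- function(raw, mins, maxs, clip) {
  span <- maxs - mins
  out <- sweep(raw, 2, mins)
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Invert the min-max normalization of one cell or column
#'
#' @param value Normalized value(s) in \[0, 1\].
#' @param feature Feature name.
#' @param norm_params A `FeatureTable` `norm_params` matrix.
#' @return The raw-scale value(s).
#' @export
denormalize_feature <- function(value, feature, norm_params) {
  norm_params["min", feature] +
    value * (norm_params["max", feature] - norm_params["min", feature])
}

#' @method print FeatureTable
#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d peptides x %d features (normalized to [0,1])\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a feature table as TSV
#'
#' @param ft A `FeatureTable`.
#' @param path Output path.
#' @param raw Write raw instead of normalized values.
#' @export
write_feature_table <- function(ft, path, raw = FALSE) {
  m <- if (raw) ft$raw else ft$values
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
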