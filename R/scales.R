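# The five per-residue propensity scales used for the window features:
# antigenicity (Kolaskar), accessibility (Janin), hydrophilicity (Parker),
# flexibility (Bhaskaran) and Chou-Fasman beta-turn propensity.
AA_SCALE_TABLE <- local({
  tab <- matrix(c(
    # antigen. access. hydro.  flex.  beta-turn
    1.064,  6.6,   2.10, 0.36, 0.66,  # A
    1.412,  0.9,   1.40, 0.35, 1.19,  # C
    0.866,  7.7,  10.00, 0.51, 1.46,  # D
    0.851,  5.7,   7.80, 0.50, 0.74,  # E
    1.091,  2.4,  -9.20, 0.31, 0.60,  # F
    0.874,  6.7,   5.70, 0.54, 1.56,  # G
    1.105,  2.5,   2.10, 0.32, 0.95,  # H
    1.152,  2.8,  -8.00, 0.46, 0.47,  # I
    0.930, 10.3,   5.70, 0.47, 1.01,  # K
    1.250,  4.8,  -9.20, 0.37, 0.59,  # L
    0.826,  1.0,  -4.20, 0.30, 0.60,  # M
    0.776,  6.7,   7.00, 0.46, 1.56,  # N
    1.064,  4.8,   2.10, 0.51, 1.52,  # P
    1.015,  5.2,   6.00, 0.49, 0.98,  # Q
    0.873,  4.5,   4.20, 0.53, 0.95,  # R
    1.012,  9.4,   6.50, 0.51, 1.43,  # S
    0.909,  7.0,   5.20, 0.44, 0.96,  # T
    1.383,  4.5,  -3.70, 0.39, 0.50,  # V
    0.893,  1.4, -10.00, 0.31, 0.96,  # W
    1.161,  5.1,  -1.90, 0.42, 1.14   # Y
  ), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("antigenicity", "accessibility", "hydrophilicity",
                    "flexibility", "beta_turn")))
  tab
})

SCALE_NAMES <- colnames(AA_SCALE_TABLE)

#' Built-in amino acid propensity scales
#'
#' Returns one of the five per-residue propensity scales shipped with the
#' toolkit: Kolaskar antigenicity, Janin accessibility, Parker
#' hydrophilicity, Bhaskaran flexibility and Chou-Fasman beta-turn
#' propensity. Values for the ambiguity codes are derived: `B = (N + D)/2`,
#' `Z = (Q + E)/2`, `J = (L + I)/2` and `X` is the mean over the 20
#' standard residues.
#'
#' @param name One of `"antigenicity"`, `"accessibility"`,
#'   `"hydrophilicity"`, `"flexibility"`, `"beta_turn"`.
#' @return A named numeric vector of length 24 (20 residues + B, X, Z, J).
#' @examples
#' aa_scale("antigenicity")["A"]  # 1.064
#' @export
aa_scale <- function(name = SCALE_NAMES) {
  name <- match.arg(name)
  v <- AA_SCALE_TABLE[, name]
  c(v,
    B = unname((v["N"] + v["D"]) / 2),
    X = mean(v),
    Z = unname((v["Q"] + v["E"]) / 2),
    J = unname((v["L"] + v["I"]) / 2))
}

#' Residue occurrence counts
#'
#' Counts the occurrences of each of the 24 alphabet symbols (20 standard
#' residues plus B, X, Z, J, each counted as itself) in a peptide sequence.
#'
#' @param sequence A single peptide sequence.
#' @return A named integer vector of length 24 summing to `nchar(sequence)`.
#' @export
aa_counts <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, PEPTIDE_ALPHABET)
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ""))
  tab <- table(factor(res, levels = PEPTIDE_ALPHABET))
  setNames(as.integer(tab), PEPTIDE_ALPHABET)
}

# Side-chain and terminal pKa values (EMBOSS-style) for the iterative
# isoelectric point computation. Positive groups gain a proton below their
# pKa; acidic groups lose one above theirs.
PKA <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the amino terminus, carboxy terminus and
#' the ionizable side chains (D, E, C, Y, H, K, R). Ambiguity codes carry
#' no side-chain charge.
#'
#' @param sequence A peptide sequence.
#' @param pH pH value (vectorized).
#' @return Net charge (positive minus negative) at each pH.
#' @export
net_charge <- function(sequence, pH) {
  counts <- aa_counts(sequence)
  pos_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_frac <- function(pka) 1 / (1 + 10^(pka - pH))
  pos <- pos_frac(PKA$nterm)
  for (r in names(PKA$positive))
    pos <- pos + counts[[r]] * pos_frac(PKA$positive[[r]])
  neg <- neg_frac(PKA$cterm)
  for (r in names(PKA$negative))
    neg <- neg + counts[[r]] * neg_frac(PKA$negative[[r]])
  pos - neg
}

#' Peptide isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the peptide is
#' zero, found iteratively by bisection on \[0, 14\]. The net charge is
#' strictly decreasing in pH, so the root is unique.
#'
#' @param sequence A peptide sequence.
#' @param tol Bisection tolerance on the pH interval. Default `1e-4`
#'   (the returned charge is then well below 1e-3 in magnitude for any
#'   peptide).
#' @return The isoelectric point (pH units).
#' @examples
#' isoelectric_point("KKKKK") > isoelectric_point("DDDDD")
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  lo <- 0; hi <- 14
  while ((hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sliding-window propensity-scale feature
#'
#' Profiles a peptide with a per-residue propensity scale and summarizes the
#' profile as the maximum over all contiguous windows of `window` residues
#' of the within-window statistic (mean by default). Peptides shorter than
#' the window are summarized with a single window spanning the whole
#' sequence.
#'
#' @param sequence A peptide sequence.
#' @param scale A scale name accepted by [aa_scale()], or a named numeric
#'   vector covering the sequence's residues.
#' @param window Window length in residues. Default 9.
#' @param stat Within-window statistic, `"mean"` (default) or `"max"`.
#' @return The window feature value (scale units).
#' @examples
#' scale_window_feature(strrep("A", 15), "antigenicity")  # 1.064
#' @export
scale_window_feature <- function(sequence, scale, window = 9L,
                                 stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (is.character(scale)) scale <- aa_scale(scale)
  res <- strsplit(sequence, "")[[1]]
  vals <- scale[res]
  if (anyNA(vals)) stop("scale has no value for residue(s): ",
                        paste(unique(res[is.na(vals)]), collapse = ""))
  n <- length(vals)
  w <- min(as.integer(window), n)
  if (stat == "mean") {
    cs <- c(0, cumsum(vals))
    max((cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w)
  } else {
    max(vapply(1:(n - w + 1), function(i) max(vals[i:(i + w - 1)]), 0))
  }
}

#' Amino acid groups derived from BLOSUM50
#'
#' Partitions the 20 standard residues by complete-linkage hierarchical
#' clustering of the BLOSUM50 substitution matrix, after converting
#' similarities to distances with the self-score normalization
#' `d(a, b) = 1 - s(a, b) / sqrt(s(a, a) * s(b, b))`. The default of
#' eight groups recovers the familiar chemistry classes (aliphatic
#' I/L/M/V, aromatic F/W/Y, basic K/R/Q, acid/amide D/E/N, small polar
#' A/S/T, and G, P, C, H split off).
#'
#' @param k Number of groups. Default 8.
#' @return A named character vector mapping each residue to its group,
#'   where a group is the sorted concatenation of its member residues.
#' @export
aa_groups <- function(k = 8L) {
  m <- blosum_matrix()[STANDARD_AA, STANDARD_AA]
  d <- 1 - m / sqrt(outer(diag(m), diag(m)))
  cl <- cutree(hclust(as.dist(d), method = "complete"), k = k)
  grp <- vapply(split(names(cl), cl), function(g)
    paste(sort(g), collapse = ""), "")
  setNames(grp[as.character(cl)], names(cl))
}
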