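#' Synthetic peptide-set configuration
#'
#' Describes the statistical structure of a simulated labelled peptide
#' set: class balance, the length mix of the assay (mostly 15-mers, some
#' 13-mers, rare other lengths), and the planted-motif signal that makes
#' local-alignment features informative — every positive carries one
#' mutated copy of a family motif at a random offset, while a configurable
#' fraction of negatives carries a decoy motif so that sequence length
#' alone cannot solve the task.
#'
#' @param n_peptides Number of peptides.
#' @param positive_fraction Fraction labelled positive. Default 0.25.
#' @param lengths,length_probs Peptide length values and probabilities.
#'   Default: 15 (85%), 13 (10%), and 9/16/18/20/21 sharing 5%.
#' @param n_motif_families Number of positive motif families (0 disables
#'   the planted signal). Default 3.
#' @param motif_length Motif length in residues (the 8-10 residue span of
#'   a typical antibody binding site). Default 8.
#' @param mutation_rate Per-position probability that an implanted motif
#'   residue is replaced by a random other residue. Default 0.1.
#' @param decoy_fraction Fraction of negatives carrying a decoy motif.
#'   Default 0.1.
#' @param ambiguity_rate Per-residue probability of replacement by an
#'   ambiguity code (B/X/Z/J), exercising those code paths. Default 0.001.
#' @param seed RNG seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_peptides = 100L, positive_fraction = 0.25,
                       lengths = c(15L, 13L, 9L, 16L, 18L, 20L, 21L),
                       length_probs = c(0.85, 0.10, rep(0.01, 5)),
                       n_motif_families = 3L, motif_length = 8L,
                       mutation_rate = 0.1, decoy_fraction = 0.1,
                       ambiguity_rate = 0.001, seed = 1L) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1,
            length(lengths) == length(length_probs),
            abs(sum(length_probs) - 1) < 1e-8,
            mutation_rate >= 0, mutation_rate <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  if (n_motif_families > 0 && motif_length > min(lengths))
    stop("motif_length exceeds the shortest allowed peptide length")
  structure(list(n_peptides = as.integer(n_peptides),
                 positive_fraction = positive_fraction,
                 lengths = as.integer(lengths), length_probs = length_probs,
                 n_motif_families = as.integer(n_motif_families),
                 motif_length = as.integer(motif_length),
                 mutation_rate = mutation_rate,
                 decoy_fraction = decoy_fraction,
                 ambiguity_rate = ambiguity_rate,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

random_background <- function(n_res) {
  paste(sample(STANDARD_AA, n_res, replace = TRUE), collapse = "")
}

mutate_motif <- function(motif, rate) {
  res <- strsplit(motif, "")[[1]]
  hit <- runif(length(res)) < rate
  res[hit] <- vapply(res[hit], function(r)
    sample(setdiff(STANDARD_AA, r), 1), "")
  paste(res, collapse = "")
}

implant <- function(background, insert) {
  lb <- nchar(background); li <- nchar(insert)
  off <- sample.int(lb - li + 1, 1)
  paste0(substr(background, 1, off - 1), insert,
         substr(background, off + li, lb))
}

#' Simulate a labelled peptide set
#'
#' Positives carry one mutated copy of a family motif at a random offset;
#' negatives are background-sampled, a fraction of them with a decoy
#' motif. Reactivities are drawn uniformly on \[10000, 65536\] for
#' positives and \[1, 1000\] for negatives. Fully reproducible from the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A `PeptideSet` with the attribute `"motifs"` carrying the
#'   planted family and decoy motifs.
#' @export
simulate_peptides <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_peptides
  n_pos <- round(n * config$positive_fraction)
  n_neg <- n - n_pos
  fams <- if (config$n_motif_families > 0)
    vapply(seq_len(config$n_motif_families), function(i)
      random_background(config$motif_length), "") else character(0)
  decoys <- if (config$n_motif_families > 0)
    vapply(seq_len(config$n_motif_families), function(i)
      random_background(config$motif_length), "") else character(0)

  draw_lengths <- function(n)
    config$lengths[sample.int(length(config$lengths), n, replace = TRUE,
                              prob = config$length_probs)]
  lens_pos <- draw_lengths(n_pos)
  lens_neg <- draw_lengths(n_neg)
  pos_seq <- vapply(lens_pos, function(L) {
    bg <- random_background(L)
    if (!length(fams)) return(bg)
    implant(bg, mutate_motif(sample(fams, 1), config$mutation_rate))
  }, "")
  neg_seq <- vapply(lens_neg, function(L) {
    bg <- random_background(L)
    if (length(decoys) && runif(1) < config$decoy_fraction)
      implant(bg, mutate_motif(sample(decoys, 1), config$mutation_rate))
    else bg
  }, "")
  seqs <- c(pos_seq, neg_seq)
  if (config$ambiguity_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      res <- strsplit(s, "")[[1]]
      hit <- runif(length(res)) < config$ambiguity_rate
      res[hit] <- sample(AMBIGUITY_AA, sum(hit), replace = TRUE)
      paste(res, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  reactivity <- c(runif(n_pos, 10000, 65536), runif(n_neg, 1, 1000))
  ps <- peptide_set(id = c(sprintf("pos%04d", seq_len(n_pos)),
                           sprintf("neg%04d", seq_len(n_neg))),
                    sequence = seqs,
                    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
                    reactivity = reactivity, strict = FALSE)
  attr(ps, "motifs") <- list(families = fams, decoys = decoys)
  ps
}

#' Named synthetic fixtures
#'
#' Reproducible peptide sets with known statistical structure:
#' \describe{
#'   \item{tiny}{30 peptides, planted signal; small enough for exhaustive
#'     oracle checks.}
#'   \item{medium}{300 peptides, planted signal; sized for leave-one-out
#'     properties.}
#'   \item{separable}{60 all-15-mer peptides whose positives share exact
#'     (unmutated) family motifs and whose negatives carry no decoys, so a
#'     leave-one-out run is expected to classify every peptide correctly.}
#'   \item{null}{200 peptides with no planted motifs: labels are
#'     independent of sequence, so any cross-validated AUROC above chance
#'     indicates information leakage. The size keeps the well-known
#'     pessimistic small-sample bias of leave-one-out with many features
#'     well inside the tolerance of a chance-level check.}
#' }
#'
#' @param name Fixture name.
#' @param seed RNG seed forwarded to [sim_config()].
#' @return A `PeptideSet`.
#' @export
make_fixture <- function(name = c("tiny", "medium", "separable", "null"),
                         seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(n_peptides = 30L, n_motif_families = 2L, seed = seed),
    medium = sim_config(n_peptides = 300L, n_motif_families = 4L,
                        mutation_rate = 0.05, seed = seed),
    separable = sim_config(n_peptides = 60L, n_motif_families = 2L,
                           motif_length = 10L, mutation_rate = 0,
                           decoy_fraction = 0, ambiguity_rate = 0,
                           lengths = 15L, length_probs = 1,
                           seed = seed),
    null = sim_config(n_peptides = 200L, n_motif_families = 0L,
                      ambiguity_rate = 0, seed = seed))
  simulate_peptides(cfg)
}
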