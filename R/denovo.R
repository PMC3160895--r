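#' Normalized local-alignment distance matrix
#'
#' Converts a non-negative local-alignment score matrix to distances in
#' \[0, 1\] by self-score normalization followed by subtraction from one:
#' `d(i, j) = 1 - s(i, j) / sqrt(s(i, i) * s(j, j))`. Identical peptides
#' are at distance 0; pairs with no local similarity at distance 1.
#'
#' @param m A local-mode [score_matrix()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(m) {
  if (any(m < 0)) stop("distance matrix requires a local (non-negative) score matrix")
  s <- diag(m)
  if (any(s <= 0)) stop("zero self-alignment score: cannot normalize")
  d <- 1 - m / sqrt(outer(s, s))
  d[d < 0] <- 0          # round-off guard
  diag(d) <- 0
  d
}

#' Complete-linkage peptide clustering
#'
#' Hierarchical clustering of the peptides with complete linkage on the
#' \[0, 1\] local-alignment distance, cut at `cutoff`. Complete linkage
#' guarantees that the maximum pairwise distance inside any returned
#' cluster is at most the cutoff.
#'
#' @param d Distance matrix from [distance_matrix()].
#' @param cutoff Dendrogram cut height. Default 0.7.
#' @return List of integer vectors of member indices, one per cluster.
#' @export
cluster_peptides <- function(d, cutoff = 0.7) {
  hc <- hclust(as.dist(d), method = "complete")
  unname(split(seq_len(nrow(d)), cutree(hc, h = cutoff)))
}

#' Select reactivity-typed clusters
#'
#' Applies the cluster selection rules: positive (H) clusters have at least
#' `min_h` members, all positive; negative (L) clusters at least `min_l`
#' members, all negative; uncertain (M) clusters at least `min_m` members
#' with a positive fraction within `m_tolerance` of the training positive
#' fraction. Everything else is `unselected`.
#'
#' @param clusters List of member-index vectors from [cluster_peptides()].
#' @param labels Peptide labels aligned with the distance-matrix indices.
#' @param train_pos_fraction Positive fraction of the training set.
#' @param config A [run_config()] providing the size thresholds and
#'   tolerance.
#' @return A data frame with one row per cluster: `cluster`, `size`,
#'   `n_pos`, `n_neg`, `type`; the member vectors are kept in the
#'   `members` list column.
#' @export
select_clusters <- function(clusters, labels,
                            train_pos_fraction = mean(labels == "positive"),
                            config = run_config()) {
  rows <- lapply(seq_along(clusters), function(k) {
    idx <- clusters[[k]]
    np <- sum(labels[idx] == "positive")
    nn <- sum(labels[idx] == "negative")
    size <- length(idx)
    type <- if (np == size && size >= config$min_h) "H"
      else if (nn == size && size >= config$min_l) "L"
      else if (size >= config$min_m &&
               abs(np / size - train_pos_fraction) <= config$m_tolerance) "M"
      else "unselected"
    data.frame(cluster = k, size = size, n_pos = np, n_neg = nn,
               type = type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- clusters
  out
}

#' Star-progressive multiple alignment of a cluster
#'
#' Aligns all cluster members to a seed sequence (the medoid: the member
#' with the largest summed local-alignment score to the others) with
#' global pairwise alignment, and merges the pairwise alignments on the
#' seed coordinates under "once a gap, always a gap".
#'
#' @param sequences Character vector of the cluster member sequences.
#' @param params Pairwise [alignment_params()] (global mode is forced).
#' @param seed_index Optional seed override; default is the medoid under
#'   local-alignment scores.
#' @return A `MultipleAlignment`: list with `rows` (gapped sequences, in
#'   input order), `matrix` (aligned symbol matrix), `information`
#'   (per-column bits) and `seed_index`.
#' @export
align_cluster <- function(sequences, params = alignment_params("global"),
                          seed_index = NULL) {
  n <- length(sequences)
  if (n < 2) stop("cluster multiple alignment needs at least 2 sequences")
  if (is.null(seed_index)) {
    lp <- alignment_params("local", params$substitution_matrix,
                           params$gap_open, params$gap_extend)
    tot <- vapply(seq_len(n), function(i)
      sum(align_score_many(sequences, sequences[i], lp)), 0)
    seed_index <- which.max(tot)
  }
  params$mode <- "global"
  seed <- sequences[seed_index]
  master_seed <- strsplit(seed, "")[[1]]
  rows <- list(strsplit(seed, "")[[1]])
  for (i in setdiff(seq_len(n), seed_index)) {
    pa <- Biostrings::pairwiseAlignment(
      seed, sequences[i], type = "global",
      substitutionMatrix = blosum_matrix(params$substitution_matrix),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    aseed <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    amem <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    merged <- merge_onto_seed(master_seed, rows, aseed, amem)
    master_seed <- merged$master_seed
    rows <- merged$rows
  }
  m <- do.call(rbind, rows)
  # restore input order: seed first in `rows`, members appended in order
  ord <- order(c(seed_index, setdiff(seq_len(n), seed_index)))
  m <- m[ord, , drop = FALSE]
  info <- apply(m, 2, column_information)
  structure(list(rows = apply(m, 1, paste, collapse = ""),
                 matrix = m, information = info, seed_index = seed_index),
            class = "MultipleAlignment")
}

# Merge one pairwise (seed, member) alignment into the running master
# alignment. Gap columns already in the master are kept ("once a gap,
# always a gap"); new gaps in the seed open new columns for all rows.
merge_onto_seed <- function(master_seed, rows, aseed, amem) {
  i <- 1L; j <- 1L
  L1 <- length(master_seed); L2 <- length(aseed)
  new_master <- character(0)
  take_old <- integer(0)   # per output column: old master column or NA
  new_mem <- character(0)
  while (i <= L1 || j <= L2) {
    if (i <= L1 && master_seed[i] == "-") {
      new_master <- c(new_master, "-"); take_old <- c(take_old, i)
      new_mem <- c(new_mem, "-"); i <- i + 1L
    } else if (j <= L2 && aseed[j] == "-") {
      new_master <- c(new_master, "-"); take_old <- c(take_old, NA)
      new_mem <- c(new_mem, amem[j]); j <- j + 1L
    } else {
      new_master <- c(new_master, master_seed[i]); take_old <- c(take_old, i)
      new_mem <- c(new_mem, amem[j]); i <- i + 1L; j <- j + 1L
    }
  }
  rows <- lapply(rows, function(r)
    ifelse(is.na(take_old), "-", r[replace(take_old, is.na(take_old), 1L)]))
  rows[[length(rows) + 1L]] <- new_mem
  list(master_seed = new_master, rows = rows)
}

#' Per-column information content in bits
#'
#' `IC = log2(20) - H`, with `H` the Shannon entropy of the residue
#' frequencies among the non-gap symbols of the column. No small-sample
#' correction is applied. An all-gap column has information 0.
#'
#' @param column Character vector of aligned symbols (residues and `"-"`).
#' @return Information content in bits, in \[0, log2(20)\].
#' @export
column_information <- function(column) {
  res <- column[column != "-"]
  if (!length(res)) return(0)
  p <- table(res) / length(res)
  h <- -sum(p * log2(p))
  max(0, log2(20) - h)
}

#' Build a k-mer index of reference sequences
#'
#' @param sequences Character vector of reference sequences.
#' @param k Substring length; default 4 (one more than the longest common
#'   stretch allowed by the novelty rules).
#' @return Character vector of the distinct k-mers (use with `%in%`).
#' @export
build_kmer_index <- function(sequences, k = 4L) {
  unique(unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  })))
}

#' Extract a constrained motif from a cluster member
#'
#' Builds a length-15 motif from one ungapped 15-mer member of a cluster
#' multiple alignment. Positions are visited in decreasing order of the
#' member's column information (ties by ascending position). A position is
#' kept fixed if fixing it does not create a run of
#' `max_common_stretch + 1` consecutive fixed residues whose concatenation
#' occurs as a substring of the reference k-mer index; otherwise it is made
#' variable, with allowed set the residue's BLOSUM50 group united with the
#' residues observed in its alignment column, pruned of choices that
#' recreate an indexed k-mer together with flanking fixed runs. If the
#' group offers no admissible residue the whole alphabet is searched; a
#' motif with a position left empty even then is marked non-viable and
#' enumerates to nothing. The downstream novelty filter remains the final
#' gate for candidates.
#'
#' @param sequence The ungapped member sequence (length 15).
#' @param row Its row index in the alignment.
#' @param msa A `MultipleAlignment` from [align_cluster()].
#' @param kmer_index Index from [build_kmer_index()] over training plus
#'   test sequences.
#' @param groups Residue groups from [aa_groups()].
#' @param max_common_stretch Longest permitted fixed common stretch.
#'   Default 3.
#' @param max_identity,identity_window Identity budget of the second
#'   novelty rule. Because the source sequence is itself a training
#'   member, every fixed position is an identity against it, so after the
#'   common-stretch pass the extractor releases the least-conserved fixed
#'   positions (ties by descending position) until no window of
#'   `identity_window` positions holds more than `max_identity` fixed
#'   residues — otherwise no candidate of the motif could ever satisfy
#'   that rule.
#' @return A `Motif`: list with `positions` (list of allowed residue sets;
#'   singletons are fixed), `fixed` (logical), `sequence`.
#' @export
extract_motif <- function(sequence, row, msa, kmer_index,
                          groups = aa_groups(), max_common_stretch = 3L,
                          max_identity = 5L, identity_window = 11L) {
  res <- strsplit(sequence, "")[[1]]
  len <- length(res)
  k <- max_common_stretch + 1L
  aligned <- msa$matrix[row, ]
  col_of <- which(aligned != "-")
  if (paste(aligned[col_of], collapse = "") != sequence)
    stop("row does not ungap to the given sequence")
  info <- msa$information[col_of]
  order_pos <- order(-info, seq_len(len))
  fixed <- rep(FALSE, len)
  run_word_indexed <- function(fx, p) {
    # any k-window of all-fixed positions containing p whose word is indexed?
    for (s in max(1, p - k + 1):min(p, len - k + 1)) {
      w <- s:(s + k - 1)
      if (all(fx[w]) &&
          paste(res[w], collapse = "") %in% kmer_index) return(TRUE)
    }
    FALSE
  }
  for (p in order_pos) {
    fx <- fixed; fx[p] <- TRUE
    if (!run_word_indexed(fx, p)) fixed[p] <- TRUE
  }
  # identity budget: cap fixed positions per identity window (only against
  # a non-empty reference index; with no references both novelty rules are
  # vacuous and the motif degenerates to the sequence itself)
  w2 <- min(identity_window, len)
  while (length(kmer_index) > 0) {
    counts <- vapply(1:(len - w2 + 1), function(s)
      sum(fixed[s:(s + w2 - 1)]), 0L)
    if (max(counts) <= max_identity) break
    win <- which.max(counts) + 0:(w2 - 1)
    fp <- win[fixed[win]]
    fixed[fp[order(info[fp], -fp)][1]] <- FALSE
  }
  recreates <- function(r, p) {
    tmp <- res; tmp[p] <- r
    for (s in max(1, p - k + 1):min(p, len - k + 1)) {
      w <- s:(s + k - 1)
      if (all(fixed[setdiff(w, p)]) &&
          paste(tmp[w], collapse = "") %in% kmer_index) return(TRUE)
    }
    FALSE
  }
  positions <- vector("list", len)
  viable <- TRUE
  for (p in seq_len(len)) {
    if (fixed[p]) { positions[[p]] <- res[p]; next }
    grp <- if (res[p] %in% names(groups))
      strsplit(groups[[res[p]]], "")[[1]] else character(0)
    seen <- msa$matrix[, col_of[p]]
    allowed <- sort(unique(c(grp, intersect(seen, STANDARD_AA))))
    # prune choices recreating an indexed k-mer with flanking fixed runs;
    # widen to the whole alphabet if the group offers no novel residue
    pruned <- allowed[!vapply(allowed, recreates, logical(1), p = p)]
    if (!length(pruned))
      pruned <- STANDARD_AA[!vapply(STANDARD_AA, recreates, logical(1),
                                    p = p)]
    if (!length(pruned)) viable <- FALSE
    positions[[p]] <- pruned
  }
  structure(list(positions = positions, fixed = fixed, sequence = sequence,
                 viable = viable),
            class = "Motif")
}

#' Enumerate candidate sequences from a motif
#'
#' Cartesian expansion of the motif's allowed residue sets. When the
#' product of set sizes exceeds `cap`, a uniform sample of `cap` distinct
#' sequences is drawn from the product space instead (reproducible given
#' the RNG state).
#'
#' @param motif A `Motif`.
#' @param cap Maximum number of sequences.
#' @return Character vector of candidate sequences (all of motif length).
#' @export
enumerate_candidates <- function(motif, cap = 1e5) {
  if (isFALSE(motif$viable)) return(character(0))
  sizes <- lengths(motif$positions)
  total <- prod(sizes)
  if (total <= cap) {
    return(Reduce(function(acc, set) as.vector(outer(acc, set, paste0)),
                  motif$positions, ""))
  }
  out <- character(0)
  while (length(out) < cap) {
    draw <- replicate(min(2 * cap, 2 * (cap - length(out)) + 100),
                      paste(vapply(motif$positions, function(s)
                        s[sample.int(length(s), 1)], ""), collapse = ""))
    out <- unique(c(out, draw))
  }
  out[seq_len(cap)]
}

#' Novelty filter for de novo candidates
#'
#' A candidate passes if (1) none of its `(max_common_stretch + 1)`-mers
#' occurs in any training or test sequence, and (2) in every ungapped
#' sliding comparison against every training sequence, at most
#' `max_identity` positional matches fall within any window of
#' `identity_window` compared positions.
#'
#' @param sequence Candidate sequence.
#' @param train_sequences Training sequences (constraint 2 reference, and
#'   part of constraint 1).
#' @param kmer_index Optional precomputed [build_kmer_index()] over
#'   training plus test sequences for constraint 1; built from
#'   `train_sequences` and `test_sequences` when missing.
#' @param test_sequences Additional constraint-1 references.
#' @param config A [run_config()] with the constraint parameters.
#' @return List with `pass` (logical) and `reason` (`""`,
#'   `"common_stretch"` or `"identity_window"`).
#' @export
novelty_filter <- function(sequence, train_sequences, kmer_index = NULL,
                           test_sequences = character(0),
                           config = run_config()) {
  k <- config$max_common_stretch + 1L
  if (is.null(kmer_index))
    kmer_index <- build_kmer_index(c(train_sequences, test_sequences), k)
  n <- nchar(sequence)
  kmers <- substring(sequence, 1:(n - k + 1), k:n)
  if (any(kmers %in% kmer_index))
    return(list(pass = FALSE, reason = "common_stretch"))
  scan <- identity_scanner(train_sequences, n, config$identity_window,
                           config$max_identity)
  if (scan(strsplit(sequence, "")[[1]]))
    return(list(pass = FALSE, reason = "identity_window"))
  list(pass = TRUE, reason = "")
}

# Sliding identity scan of a length-ls query against every training
# sequence at every ungapped offset, vectorized by concatenating the
# training set with runs of non-matching separator symbols long enough
# that no identity window can straddle two sequences. Returns a closure
# evaluating one query (as a residue vector) to TRUE when some window of
# `w` compared positions holds more than `maxid` matches.
identity_scanner <- function(train_sequences, ls, w, maxid) {
  pad <- rep("#", max(w, ls))
  tv <- c(pad, unlist(lapply(train_sequences, function(t)
    c(strsplit(t, "")[[1]], pad))))
  D <- length(tv) - ls + 1L
  shift_idx <- outer(seq_len(D) - 1L, seq_len(ls), "+")
  tmat <- matrix(tv[shift_idx], D, ls)
  weff <- min(w, ls)
  function(s_res) {
    cs <- 1 * (tmat == matrix(s_res, D, ls, byrow = TRUE))
    for (j in 2:ls) cs[, j] <- cs[, j] + cs[, j - 1]
    best <- cs[, weff]
    if (ls > weff) {
      for (a in 2:(ls - weff + 1))
        best <- pmax(best, cs[, a + weff - 1] - cs[, a - 1])
    }
    max(best) > maxid
  }
}

#' Rank and select the final candidate lists
#'
#' H candidates are the `count` positive-cluster candidates with the
#' highest predicted reactivity, L candidates the `count` negative-cluster
#' candidates with the lowest, and M candidates a uniform random sample of
#' `count` from the uncertain-cluster pool. Ties in predicted reactivity
#' are broken by lexicographic sequence order.
#'
#' @param pools Named list of data frames (`H`, `L`, `M`), each with
#'   columns `sequence` and `predicted_reactivity`.
#' @param count Candidates selected per class.
#' @param classes Classes to select (default all three).
#' @return A `CandidateList` data frame with columns `id`, `sequence`,
#'   `predicted_reactivity`, `class`.
#' @export
rank_and_select <- function(pools, count = 1100L,
                            classes = c("H", "L", "M")) {
  pick <- function(pool, class, decreasing) {
    if (is.null(pool) || nrow(pool) < count)
      stop("candidate pool for class ", class, " has ",
           if (is.null(pool)) 0 else nrow(pool),
           " sequences; need ", count)
    if (class == "M") {
      sel <- pool[sample.int(nrow(pool), count), ]
    } else {
      ord <- order(pool$predicted_reactivity, pool$sequence,
                   decreasing = c(decreasing, FALSE), method = "radix")
      sel <- pool[ord[seq_len(count)], ]
    }
    data.frame(id = sprintf("%s%05d", class, seq_len(count)),
               sequence = sel$sequence,
               predicted_reactivity = sel$predicted_reactivity,
               class = class, stringsAsFactors = FALSE)
  }
  parts <- list()
  if ("H" %in% classes) parts$H <- pick(pools$H, "H", TRUE)
  if ("L" %in% classes) parts$L <- pick(pools$L, "L", FALSE)
  if ("M" %in% classes) parts$M <- pick(pools$M, "M", FALSE)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("CandidateList", "data.frame")
  out
}

#' End-to-end de novo peptide generation
#'
#' Runs the full generator: local-alignment distances, complete-linkage
#' clustering, cluster typing, per-cluster multiple alignment,
#' information-ordered motif extraction under the novelty constraints,
#' candidate enumeration, novelty filtering, model-based reactivity
#' prediction, and selection of the H/L/M lists.
#'
#' @param train Labelled training `PeptideSet`.
#' @param fit A [train_model()] result for `train` (model + score matrices
#'   + normalization); computed with `selection = "m5"` when missing.
#' @param test Optional unlabelled `PeptideSet` whose sequences extend the
#'   constraint-1 k-mer index.
#' @param config A [run_config()]; `config$seed` seeds all sampling.
#' @param classes Reactivity classes to emit; the full-run default is all
#'   three of `H`, `L`, `M`.
#' @return List with `candidates` (a `CandidateList`), `clusters` (the
#'   cluster report from [select_clusters()]), `pools` (the filtered
#'   per-class candidate pools) and `model`.
#' @export
generate_candidates <- function(train, fit = NULL, test = NULL,
                                config = run_config(),
                                classes = c("H", "L", "M")) {
  classes <- match.arg(classes, several.ok = TRUE)
  set.seed(config$seed)
  if (is.null(fit)) fit <- train_model(train, config, selection = "m5")
  d <- distance_matrix(fit$matrices$local)
  clusters <- cluster_peptides(d, config$cluster_cutoff)
  report <- select_clusters(clusters, train$label,
                            mean(train$label == "positive"), config)
  k <- config$max_common_stretch + 1L
  ref_seqs <- c(train$sequence, if (!is.null(test)) test$sequence)
  kidx <- build_kmer_index(ref_seqs, k)
  groups <- aa_groups()
  ap <- alignment_params("global", config$substitution_matrix,
                         config$gap_open, config$gap_extend)

  pools <- list(H = NULL, L = NULL, M = NULL)
  for (ci in which(report$type %in% classes)) {
    idx <- report$members[[ci]]
    msa <- align_cluster(train$sequence[idx], ap)
    for (r in seq_along(idx)) {
      if (nchar(train$sequence[idx[r]]) != 15L) next
      motif <- extract_motif(train$sequence[idx[r]], r, msa, kidx,
                             groups, config$max_common_stretch,
                             config$max_identity, config$identity_window)
      cand <- enumerate_candidates(motif, config$enumeration_cap)
      pools[[report$type[ci]]] <-
        c(pools[[report$type[ci]]], cand)
    }
  }
  pools <- lapply(pools, function(cand) {
    cand <- unique(cand)
    if (length(cand) > config$pool_cap)
      cand <- sample(cand, config$pool_cap)
    cand
  })
  # novelty filter (constraint 1 via the index, constraint 2 by scanning)
  scan <- identity_scanner(train$sequence, 15L, config$identity_window,
                           config$max_identity)
  pools <- lapply(pools, function(cand) {
    if (is.null(cand)) return(character(0))
    keep <- vapply(cand, function(s) {
      kmers <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
      !any(kmers %in% kidx) && !scan(strsplit(s, "")[[1]])
    }, logical(1))
    cand[keep]
  })
  # predicted reactivity of the surviving candidates
  pools_df <- lapply(pools, function(cand) {
    if (!length(cand)) return(NULL)
    cs <- peptide_set(paste0("c", seq_along(cand)), cand, strict = FALSE)
    ap_g <- alignment_params("global", config$substitution_matrix,
                             config$gap_open, config$gap_extend)
    ap_l <- alignment_params("local", config$substitution_matrix,
                             config$gap_open, config$gap_extend)
    xg <- cross_score_matrix(cs$sequence, train, ap_g)
    xl <- cross_score_matrix(cs$sequence, train, ap_l)
    af <- cross_alignment_features(xg, xl, train$label)
    ft <- apply_feature_table(cs, fit$table$norm_params, af, config$window)
    data.frame(sequence = cand,
               predicted_reactivity = predict_reactivity(fit$model, ft),
               stringsAsFactors = FALSE)
  })
  candidates <- rank_and_select(pools_df, config$select_count, classes)
  list(candidates = candidates,
       clusters = report[, c("cluster", "size", "n_pos", "n_neg", "type")],
       pools = pools_df, model = fit$model)
}
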