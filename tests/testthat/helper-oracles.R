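# Independent brute-force oracles used to validate the package's
# dynamic-programming, windowing and filtering code paths.

# substitution matrix for the oracles: BLOSUM50 straight from Biostrings
oracle_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM50", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM50
    }
    cache
  }
})

# Exhaustive global alignment: explores every monotone alignment path,
# charging a gap of length L as open + L * ext. No memoization.
oracle_global_score <- function(a, b, open = 10, ext = 1) {
  S <- oracle_submat()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(av))
      best <- max(best, -(ext + if (last != "D") open else 0) +
                    rec(i + 1, j, "D"))
    if (j <= length(bv))
      best <- max(best, -(ext + if (last != "I") open else 0) +
                    rec(i, j + 1, "I"))
    best
  }
  rec(1, 1, "S")
}

# Exhaustive local alignment: best global score over all pairs of
# contiguous substrings, floored at 0 (the empty alignment).
oracle_local_score <- function(a, b, open = 10, ext = 1) {
  la <- nchar(a); lb <- nchar(b)
  best <- 0
  for (i1 in 1:la) for (i2 in i1:la) for (j1 in 1:lb) for (j2 in j1:lb) {
    best <- max(best, oracle_global_score(substr(a, i1, i2),
                                          substr(b, j1, j2), open, ext))
  }
  best
}

# Explicit window enumeration for the scale features.
oracle_window_feature <- function(sequence, scale, w = 9) {
  res <- strsplit(sequence, "")[[1]]
  vals <- scale[res]
  n <- length(vals)
  if (n < w) return(sum(vals) / n)
  best <- -Inf
  for (i in 1:(n - w + 1)) best <- max(best, sum(vals[i:(i + w - 1)]) / w)
  best
}

# Fine-grid charge scan for the isoelectric point, with its own
# Henderson-Hasselbalch arithmetic over the same ionizable groups.
oracle_pi <- function(sequence, step = 1e-5) {
  res <- strsplit(sequence, "")[[1]]
  nK <- sum(res == "K"); nR <- sum(res == "R"); nH <- sum(res == "H")
  nD <- sum(res == "D"); nE <- sum(res == "E"); nC <- sum(res == "C")
  nY <- sum(res == "Y")
  ph <- seq(0, 14, by = step)
  q <- 1 / (1 + 10^(ph - 8.6)) +
    nK / (1 + 10^(ph - 10.8)) + nR / (1 + 10^(ph - 12.5)) +
    nH / (1 + 10^(ph - 6.5)) -
    1 / (1 + 10^(3.6 - ph)) -
    nD / (1 + 10^(3.9 - ph)) - nE / (1 + 10^(4.1 - ph)) -
    nC / (1 + 10^(8.5 - ph)) - nY / (1 + 10^(10.1 - ph))
  ph[which.min(abs(q))]
}

# Brute-force novelty re-checks.
oracle_shares_kmer <- function(sequence, refs, k = 4) {
  n <- nchar(sequence)
  kmers <- substring(sequence, 1:(n - k + 1), k:n)
  any(vapply(kmers, function(km)
    any(grepl(km, refs, fixed = TRUE)), logical(1)))
}

oracle_identity_violation <- function(sequence, refs, w = 11, maxid = 5) {
  s <- strsplit(sequence, "")[[1]]
  for (t in refs) {
    tv <- strsplit(t, "")[[1]]
    for (off in -(length(tv) - 1):(length(s) - 1)) {
      i0 <- max(1, off + 1); i1 <- min(length(s), off + length(tv))
      if (i1 < i0) next
      m <- s[i0:i1] == tv[(i0 - off):(i1 - off)]
      L <- length(m)
      for (a in 1:max(1, L - w + 1)) {
        if (sum(m[a:min(L, a + w - 1)]) > maxid) return(TRUE)
      }
    }
  }
  FALSE
}

random_peptide <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# small labelled toy set used by several module tests
toy_set <- function(n_pos = 3, n_neg = 5, len = 12, seed = 42) {
  set.seed(seed)
  peptide_set(sprintf("t%02d", 1:(n_pos + n_neg)),
              vapply(rep(len, n_pos + n_neg), random_peptide, ""),
              label = rep(c("positive", "negative"), c(n_pos, n_neg)),
              strict = FALSE)
}
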