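test_that("distance matrix applies geometric self-score normalization", {
  s <- matrix(c(10, 5, 0,
                5, 10, 0,
                0, 0, 8), 3, 3, byrow = TRUE)
  d <- distance_matrix(s)
  expect_equal(d[1, 2], 0.5)
  expect_equal(d[1, 3], 1)
  expect_equal(diag(d), rep(0, 3))
  expect_true(isSymmetric(d))
  expect_error(distance_matrix(matrix(c(0, 0, 0, 0), 2, 2)), "self-alignment")
  expect_error(distance_matrix(matrix(c(1, -1, -1, 1), 2, 2)), "non-negative")
})

test_that("complete-linkage clustering respects the cutoff", {
  # all distances 1 -> all singletons
  d1 <- matrix(1, 5, 5); diag(d1) <- 0
  cl1 <- cluster_peptides(d1, 0.7)
  expect_length(cl1, 5)
  # all distances 0 -> one cluster
  d0 <- matrix(0, 5, 5)
  expect_length(cluster_peptides(d0, 0.7), 1)

  # planted two-family structure: within < 0.4, between > 0.9
  set.seed(61)
  fam <- rep(1:2, each = 6)
  d <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    if (i != j)
      d[i, j] <- if (fam[i] == fam[j]) runif(1, 0.1, 0.4)
                 else runif(1, 0.9, 1)
  }
  d <- (d + t(d)) / 2
  cl <- cluster_peptides(d, 0.7)
  sizes <- lengths(cl)
  expect_length(cl, 2)
  expect_setequal(lapply(cl, sort), split(1:12, fam))
  # complete-linkage guarantee: intra-cluster diameter <= cutoff
  for (members in cl) {
    if (length(members) > 1)
      expect_lte(max(d[members, members]), 0.7)
  }
})

test_that("cluster typing follows the H/L/M rules", {
  clusters <- list(1:5, 6:12, 13:20, 21:22)
  labels <- c(rep("positive", 5),            # 5 positives -> H
              rep("negative", 7),            # 7 negatives -> below L size
              c("positive", "positive", rep("negative", 6)),  # 2/8 -> M
              rep("positive", 2))
  rep <- select_clusters(clusters, labels, train_pos_fraction = 0.25)
  expect_equal(rep$type, c("H", "unselected", "M", "unselected"))
  expect_equal(rep$n_pos, c(5, 0, 2, 2))
  # 8 negatives qualify as L
  rep2 <- select_clusters(list(1:8), rep("negative", 8), 0.25)
  expect_equal(rep2$type, "L")
})

test_that("cluster multiple alignment of identical sequences has no gaps and maximal information", {
  seqs <- rep("ACDEFGHIKLMNPQR", 4)
  msa <- align_cluster(seqs)
  expect_true(all(msa$matrix != "-"))
  expect_equal(msa$information, rep(log2(20), 15))
  expect_equal(unique(msa$rows), "ACDEFGHIKLMNPQR")
})

test_that("ungapping alignment rows recovers the original sequences", {
  set.seed(62)
  seqs <- c(random_peptide(15), random_peptide(13), random_peptide(15),
            random_peptide(16))
  msa <- align_cluster(seqs)
  for (k in seq_along(seqs)) {
    expect_equal(gsub("-", "", msa$rows[k]), seqs[k])
  }
})

test_that("a single substitution yields exactly one mixed column", {
  a <- "ACDEFGHIKLMNPQR"
  b <- "ACDEFGHIKLMNPQW"
  msa <- align_cluster(c(a, b))
  n_mixed <- sum(apply(msa$matrix, 2, function(col)
    length(unique(col[col != "-"])) > 1))
  expect_equal(n_mixed, 1)
  expect_equal(ncol(msa$matrix), 15)
})

test_that("column information follows the entropy formula", {
  expect_equal(column_information(rep("A", 7)), log2(20))
  expect_equal(column_information(c("A", "C", "A", "C")), log2(20) - 1)
  expect_equal(column_information(LETTERS[1:20]), 0, tolerance = 1e-12)
  expect_equal(column_information(c("-", "-")), 0)
  expect_equal(column_information(c("A", "-", "-")), log2(20))
})

test_that("motif extraction with an empty reference index fixes every position", {
  seqs <- c("ACDEFGHIKLMNPQR", "ACDEFGHIKLMNPQW")
  msa <- align_cluster(seqs)
  m <- extract_motif(seqs[1], 1, msa, kmer_index = character(0))
  expect_true(all(m$fixed))
  expect_equal(enumerate_candidates(m), seqs[1])
})

test_that("fixed runs never reproduce an indexed 4-mer", {
  seqs <- c("ACDEFGHIKLMNPQR", "ACDEFGHIKLMNPQW", "ACDEFGHIKLMNPQY")
  msa <- align_cluster(seqs)
  kidx <- build_kmer_index(seqs, 4)
  m <- extract_motif(seqs[1], 1, msa, kidx)
  # the sequence itself is indexed: every 4-run of fixed residues would be a
  # shared 4-mer, so runs are capped at 3
  runs <- rle(m$fixed)
  expect_lte(max(runs$lengths[runs$values]), 3)
  # brute-force: no fixed 4-window's word occurs in the index
  for (s in 1:12) {
    w <- s:(s + 3)
    if (all(m$fixed[w])) {
      word <- substr(seqs[1], s, s + 3)
      expect_false(any(grepl(word, seqs, fixed = TRUE)))
    }
  }
})

test_that("motif extraction caps fixed density at the identity budget", {
  seqs <- c("ACDEFGHIKLMNPQR", "ACDEFGHIKLMNPQW", "ACDEFGHIKLMNPQY")
  msa <- align_cluster(seqs)
  kidx <- build_kmer_index(seqs, 4)
  m <- extract_motif(seqs[1], 1, msa, kidx,
                     max_identity = 5, identity_window = 11)
  for (s in 1:5) {
    expect_lte(sum(m$fixed[s:(s + 10)]), 5)
  }
})

test_that("candidate enumeration counts products and samples reproducibly", {
  fixed_motif <- structure(list(positions = as.list(strsplit("AAAA", "")[[1]]),
                                fixed = rep(TRUE, 4), sequence = "AAAA",
                                viable = TRUE), class = "Motif")
  expect_equal(enumerate_candidates(fixed_motif), "AAAA")

  m23 <- structure(list(positions = list("A", c("C", "D"), c("E", "F", "G")),
                        fixed = c(TRUE, FALSE, FALSE), sequence = "ACE",
                        viable = TRUE), class = "Motif")
  expect_setequal(enumerate_candidates(m23),
                  c("ACE", "ACF", "ACG", "ADE", "ADF", "ADG"))

  big <- structure(list(positions = rep(list(c("A", "C", "D", "E", "F")), 5),
                        fixed = rep(FALSE, 5), sequence = "AAAAA",
                        viable = TRUE), class = "Motif")
  set.seed(63); s1 <- enumerate_candidates(big, cap = 10)
  set.seed(63); s2 <- enumerate_candidates(big, cap = 10)
  expect_equal(s1, s2)
  expect_length(unique(s1), 10)
})

test_that("novelty filter enforces both constraints", {
  train <- c("ACDEFGHIKLMNPQR", "YWYWYWYWYWYWYWY")
  # identity with a training peptide -> shared 4-mer
  expect_false(novelty_filter("ACDEFGHIKLMNPQR", train)$pass)
  expect_equal(novelty_filter("ACDEFGHIKLMNPQR", train)$reason,
               "common_stretch")
  # disjoint residue usage -> vacuous pass
  expect_true(novelty_filter("SSSTTTSSSTTTSSS", train)$pass)
})

test_that("identity-window rule matches the exhaustive offset-scan oracle at the boundary", {
  ref <- "AAAAAAAAAAAAAAA"
  cfg <- run_config()
  # 5 matches within 11 positions: pass; 6: fail. Non-matching residues are
  # drawn from letters absent from ref so no 4-mer fires first.
  five <- "ACADACACADCCCCC"   # A at 1,3,5,7,9 (+ none later)
  six  <- "ACADACACADACCCC"   # A at 1,3,5,7,9,11
  expect_equal(sum(strsplit(five, "")[[1]][1:11] == "A"), 5)
  expect_equal(sum(strsplit(six, "")[[1]][1:11] == "A"), 6)
  r5 <- novelty_filter(five, ref, config = cfg)
  r6 <- novelty_filter(six, ref, config = cfg)
  expect_false(oracle_identity_violation(five, ref))
  expect_true(oracle_identity_violation(six, ref))
  expect_true(r5$pass)
  expect_false(r6$pass)
  expect_equal(r6$reason, "identity_window")
})

test_that("novelty filter agrees with both brute-force oracles on random candidates", {
  set.seed(64)
  refs <- vapply(rep(15, 6), random_peptide, "")
  cfg <- run_config()
  kidx <- build_kmer_index(refs, 4)
  for (i in 1:40) {
    # mix free candidates with mosaics of reference fragments
    cand <- if (i %% 2 == 0) random_peptide(15) else {
      r <- sample(refs, 1)
      paste0(substr(r, 1, sample(3:8, 1)), random_peptide(7),
             substr(r, 12, 15))
    }
    cand <- substr(cand, 1, 15)
    got <- novelty_filter(cand, refs, kidx, config = cfg)
    want <- !oracle_shares_kmer(cand, refs, 4) &&
      !oracle_identity_violation(cand, refs, 11, 5)
    expect_equal(got$pass, want, info = cand)
  }
})

test_that("rank_and_select picks extremes, samples M reproducibly and checks pool sizes", {
  pool <- function(n, lo, hi) {
    data.frame(sequence = vapply(rep(15, n), random_peptide, ""),
               predicted_reactivity = seq(lo, hi, length.out = n),
               stringsAsFactors = FALSE)
  }
  set.seed(65)
  pools <- list(H = pool(30, 0.5, 1), L = pool(30, 0, 0.5),
                M = pool(30, 0.2, 0.8))
  sel <- rank_and_select(pools, count = 10)
  expect_equal(as.vector(table(sel$class)[c("H", "L", "M")]), rep(10L, 3))
  expect_equal(min(sel$predicted_reactivity[sel$class == "H"]),
               max(pools$H$predicted_reactivity) -
                 diff(range(pools$H$predicted_reactivity)) * 9 / 29)
  expect_equal(max(sel$predicted_reactivity[sel$class == "L"]),
               min(pools$L$predicted_reactivity) +
                 diff(range(pools$L$predicted_reactivity)) * 9 / 29)

  # exact-fit pools select everything
  sel_all <- rank_and_select(lapply(pools, head, 10), count = 10)
  expect_equal(nrow(sel_all), 30)

  # M sampling reproducible under the same seed
  set.seed(66); m1 <- rank_and_select(pools, 10)$sequence
  set.seed(66); m2 <- rank_and_select(pools, 10)$sequence
  expect_equal(m1, m2)

  expect_error(rank_and_select(list(H = pool(5, 0, 1), L = pool(30, 0, 1),
                                    M = pool(30, 0, 1)), count = 10),
               "class H")
})
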