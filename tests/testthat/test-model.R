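test_that("SRCs recover sign and magnitude structure", {
  set.seed(31)
  y <- rep(c(1, 0), 50)
  labels <- ifelse(y == 1, "positive", "negative")
  x <- cbind(agree = y, disagree = 1 - y,
             noise = runif(100), const = 1)
  expect_warning(src <- single_regression_coefficients(x, labels),
                 "constant")
  expect_gt(src["agree"], 0)
  expect_lt(src["disagree"], 0)
  expect_equal(unname(src["agree"]), unname(-src["disagree"]))
  expect_equal(unname(src["const"]), 0)
  expect_lt(abs(src["noise"]), abs(src["agree"]))
})

test_that("SRC signs recover planted correlations", {
  set.seed(32)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  labels <- ifelse(y == 1, "positive", "negative")
  x <- cbind(up = y + rnorm(n, sd = 0.5),
             down = -y + rnorm(n, sd = 0.5),
             flat = rnorm(n))
  src <- single_regression_coefficients(x, labels)
  expect_gt(src["up"], 0)
  expect_lt(src["down"], 0)
})

test_that("collinearity elimination keeps one of each correlated block", {
  set.seed(33)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  labels <- ifelse(y == 1, "positive", "negative")
  base <- y + rnorm(n, sd = 0.8)
  x <- cbind(f1 = base, f2 = base, indep1 = rnorm(n), indep2 = rnorm(n))
  keep <- remove_collinear(x, labels)
  expect_length(intersect(c("f1", "f2"), keep), 1)
  expect_true(all(c("indep1", "indep2") %in% keep))

  # three mutually collinear columns -> exactly one survivor
  x3 <- cbind(a = base, b = base + rnorm(n, sd = 1e-4),
              c = 2 * base, other = rnorm(n))
  keep3 <- remove_collinear(x3, labels)
  expect_length(intersect(c("a", "b", "c"), keep3), 1)
  expect_true("other" %in% keep3)
})

test_that("M5 backward elimination drops pure-noise columns and is deterministic", {
  # Under the Akaike criterion a pure-noise column survives a backward step
  # when its squared t-statistic exceeds 2, which happens with probability
  # P(chisq_1 > 2) ~ 0.16 per replicate; 20 replicates therefore eliminate
  # the noise column at least 12 times with probability > 0.999, while the
  # informative columns must always survive.
  set.seed(34)
  dropped <- 0
  for (rep in 1:20) {
    n <- 120
    y <- rbinom(n, 1, 0.4)
    labels <- ifelse(y == 1, "positive", "negative")
    x <- cbind(sig1 = y + rnorm(n, sd = 0.4),
               sig2 = y + rnorm(n, sd = 0.6),
               noise = runif(n))
    sel <- select_m5(x, labels)
    if (!"noise" %in% sel) dropped <- dropped + 1
    expect_true(all(c("sig1", "sig2") %in% sel))
  }
  expect_gte(dropped, 12)

  # determinism and non-empty output on near-duplicate-signal tables
  set.seed(35)
  y <- rbinom(100, 1, 0.5)
  labels <- ifelse(y == 1, "positive", "negative")
  x <- cbind(a = y + rnorm(100, sd = 0.01), b = y + rnorm(100, sd = 0.01))
  s1 <- select_m5(x, labels)
  s2 <- select_m5(x, labels)
  expect_identical(s1, s2)
  expect_gt(length(s1), 0)
})

test_that("LASSO selection spans the shrinkage limits and keeps planted signal", {
  set.seed(36)
  n <- 500
  x <- matrix(runif(n * 37), n, 37,
              dimnames = list(NULL, paste0("f", 1:37)))
  eta <- -2 + 4 * (x[, 1] + x[, 2] + x[, 3] + x[, 4] + x[, 5])
  y <- rbinom(n, 1, plogis(eta - mean(eta)))
  labels <- ifelse(y == 1, "positive", "negative")

  expect_length(select_lasso(x, labels, lambda = 10), 0)
  expect_length(select_lasso(x, labels, lambda = 0), 37)
  sel <- select_lasso(x, labels)
  expect_gte(length(intersect(paste0("f", 1:5), sel)), 4)
})

test_that("logistic fit recovers signs, zeroes unselected features and flags separation", {
  set.seed(37)
  n <- 300
  x <- cbind(sig = runif(n), other = runif(n))
  y <- rbinom(n, 1, plogis(4 * x[, "sig"] - 2))
  labels <- ifelse(y == 1, "positive", "negative")
  m <- fit_logistic(x, labels, subset = "sig")
  expect_gt(m$coefficients["sig"], 0)
  expect_equal(unname(m$coefficients["other"]), 0)
  p <- predict_reactivity(m, x)
  expect_true(all(p > 0 & p < 1))

  # labels independent of features -> near-chance refit AUC
  y0 <- rbinom(n, 1, 0.5)
  labels0 <- ifelse(y0 == 1, "positive", "negative")
  m0 <- fit_logistic(x, labels0)
  ev <- evaluate(predict_reactivity(m0, x), labels0)
  expect_lt(abs(ev$auroc - 0.5), 0.15)

  # perfectly separated data falls back to the ridge with a warning
  xs <- cbind(s = c(rep(0, 20), rep(1, 20)))
  lsep <- rep(c("negative", "positive"), each = 20)
  expect_warning(msep <- fit_logistic(xs, lsep), "separation")
  psep <- predict_reactivity(msep, xs)
  expect_true(all((psep > 0.5) == (lsep == "positive")))
})

test_that("model text serialization round-trips", {
  set.seed(38)
  x <- matrix(runif(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(50, 1, plogis(2 * x[, 1] - 1))
  labels <- ifelse(y == 1, "positive", "negative")
  m <- fit_logistic(x, labels, subset = c("a", "c"), selection_method = "m5")
  path <- tempfile(fileext = ".txt")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$selection_method, "m5")
  expect_equal(predict_reactivity(m2, x), predict_reactivity(m, x))
})

test_that("evaluation metrics follow their closed forms", {
  # TP=2, FP=1, FN=1, TN=6
  prob <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.3, 0.2, 0.2, 0.1, 0.1)
  labels <- c("positive", "positive", "negative", "positive",
              rep("negative", 6))
  ev <- evaluate(prob, labels)
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$f_measure, 2 / 3)
  expect_equal(ev$accuracy, 0.8)
  expect_equal(ev$specificity, 6 / 7)
  # Brier of a perfect 0/1 predictor is 0
  perfect <- as.numeric(labels == "positive")
  expect_equal(evaluate(perfect, labels)$brier, 0)
  expect_equal(evaluate(perfect, labels)$accuracy, 1)
})

test_that("AUROC is symmetric under score reversal and matches pROC", {
  set.seed(39)
  prob <- runif(200)
  labels <- ifelse(rbinom(200, 1, plogis(3 * prob - 1.5)) == 1,
                   "positive", "negative")
  ev <- evaluate(prob, labels)
  ev_rev <- evaluate(1 - prob, labels)
  expect_equal(ev_rev$auroc, 1 - ev$auroc)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = prob, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(ev$auroc, ref, tolerance = 1e-10)
})

test_that("random scores on balanced labels give chance-level AUROC", {
  set.seed(40)
  n <- 10000
  prob <- runif(n)
  labels <- ifelse(rbinom(n, 1, 0.5) == 1, "positive", "negative")
  expect_lt(abs(evaluate(prob, labels)$auroc - 0.5), 0.02)
})

test_that("LOOCV yields one held-out prediction per peptide and is order-invariant", {
  ps <- toy_set(4, 8, len = 12, seed = 55)
  res <- loocv(ps)
  expect_equal(nrow(res$predictions), 12)
  expect_equal(res$predictions$id, ps$id)
  expect_true(all(res$predictions$prob >= 0 & res$predictions$prob <= 1))

  perm <- sample(nrow(ps))
  ps2 <- ps[perm, ]
  res2 <- loocv(ps2)
  merged <- merge(res$predictions, res2$predictions, by = "id")
  expect_equal(merged$prob.x, merged$prob.y, tolerance = 1e-8)

  one_class <- peptide_set(c("a", "b", "c"),
                           c("AAAAAAAAAA", "CCCCCCCCCC", "DDDDDDDDDD"),
                           label = "positive")
  expect_error(loocv(one_class), "both classes")
})
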