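label_to_binary <- function(labels) {
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  as.numeric(labels == "positive")
}

#' Single regression coefficients (SRCs)
#'
#' For each feature, the slope of the univariate linear regression of the
#' 0/1 class on the standardized feature. The SRC's sign equals the sign of
#' the feature-class correlation; its magnitude is comparable across
#' features because each is standardized first.
#'
#' @param values Numeric feature matrix (peptides x features).
#' @param labels `"positive"`/`"negative"` labels.
#' @return Named numeric vector of SRCs; constant features get 0 with a
#'   warning.
#' @export
single_regression_coefficients <- function(values, labels) {
  y <- label_to_binary(labels)
  src <- apply(values, 2, function(x) {
    s <- sd(x)
    if (s == 0) return(NA_real_)
    unname(coef(lm(y ~ I((x - mean(x)) / s)))[2])
  })
  if (anyNA(src)) {
    warning("constant feature(s) assigned SRC 0: ",
            paste(names(src)[is.na(src)], collapse = ", "))
    src[is.na(src)] <- 0
  }
  src
}

#' Drop collinear features
#'
#' Greedy elimination: while any feature pair has absolute correlation
#' above the threshold, the member of the most correlated pair with the
#' smaller absolute SRC is dropped.
#'
#' @param values Numeric feature matrix.
#' @param labels Class labels (used for the SRC tie-break between the pair
#'   members).
#' @param threshold Absolute-correlation threshold. Default 0.95.
#' @return Character vector of surviving feature names.
#' @export
remove_collinear <- function(values, labels, threshold = 0.95) {
  src <- abs(suppressWarnings(single_regression_coefficients(values, labels)))
  keep <- colnames(values)
  repeat {
    sub <- values[, keep, drop = FALSE]
    ok <- apply(sub, 2, sd) > 0
    cm <- suppressWarnings(cor(sub))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    worst <- max(abs(cm))
    if (worst <= threshold) break
    idx <- which(abs(cm) == worst, arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    drop <- if (src[pair[1]] < src[pair[2]]) pair[1]
            else if (src[pair[2]] < src[pair[1]]) pair[2]
            else sort(pair)[1]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' M5 backward feature elimination ("subset B" selection)
#'
#' Starting from the full linear fit of the 0/1 class on the (typically
#' collinearity-pruned) features, repeatedly removes the feature with the
#' smallest standardized coefficient as long as the Akaike information
#' criterion does not worsen. Ties are broken by dropping the
#' lexicographically first name. Deterministic given the table.
#'
#' @param values Numeric feature matrix.
#' @param labels Class labels.
#' @param candidates Feature names to start from (default: all columns,
#'   after you have applied [remove_collinear()]).
#' @return Character vector of selected feature names (original column
#'   order).
#' @export
select_m5 <- function(values, labels, candidates = colnames(values)) {
  y <- label_to_binary(labels)
  keep <- candidates
  fit_aic <- function(feats) {
    if (!length(feats)) return(list(aic = stats::AIC(lm(y ~ 1)), coef = NULL))
    d <- data.frame(values[, feats, drop = FALSE], check.names = FALSE)
    f <- lm(y ~ ., data = d)
    list(aic = stats::AIC(f), fit = f)
  }
  cur <- fit_aic(keep)
  while (length(keep) > 1) {
    cf <- coef(cur$fit)[-1]
    names(cf) <- keep
    std <- abs(cf) * apply(values[, keep, drop = FALSE], 2, sd)
    std[is.na(std)] <- 0
    weakest <- sort(names(std)[std == min(std)])[1]
    trial <- fit_aic(setdiff(keep, weakest))
    if (trial$aic <= cur$aic) {
      keep <- setdiff(keep, weakest)
      cur <- trial
    } else break
  }
  colnames(values)[colnames(values) %in% keep]
}

#' LASSO feature selection ("subset C")
#'
#' L1-regularized logistic regression with the penalty chosen by 5-fold
#' cross-validated binomial deviance; features with zero coefficient at the
#' selected penalty are removed. Folds are assigned deterministically by
#' row order so the subset is reproducible without touching the RNG.
#'
#' @param values Numeric feature matrix (normalized).
#' @param labels Class labels.
#' @param lambda Optional fixed penalty overriding cross-validation; 0
#'   reduces to the unpenalized fit (nothing removed).
#' @return Character vector of selected feature names.
#' @export
select_lasso <- function(values, labels, lambda = NULL) {
  y <- label_to_binary(labels)
  x <- as.matrix(values)
  ok <- apply(x, 2, sd) > 0
  if (!is.null(lambda) && lambda == 0) return(colnames(x)[ok])
  xs <- x[, ok, drop = FALSE]
  if (is.null(lambda)) {
    foldid <- rep_len(1:5, length(y))
    cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                            foldid = foldid, type.measure = "deviance")
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1)
  }
  b <- as.matrix(coef(fit, s = lambda, exact = FALSE))[-1, 1]
  colnames(x)[colnames(x) %in% names(b)[b != 0]]
}

#' Fit the logistic reactivity classifier
#'
#' Maximum-likelihood logistic regression of the 0/1 class on the selected
#' feature subset; coefficients of unselected features are stored as exact
#' zeros so the coefficient vector always spans the full feature set. On
#' perfect separation (or other non-convergence) the fit falls back to a
#' small L2 ridge (lambda = 1e-6) with a warning.
#'
#' @param values Numeric feature matrix (all features).
#' @param labels Class labels.
#' @param subset Feature names to fit on; default all.
#' @param selection_method Tag recorded on the model (`"none"`, `"m5"`,
#'   `"lasso"`).
#' @return A `TrainedModel`: list with `feature_names`, `coefficients`
#'   (full-length, zeros outside the subset), `intercept`, `se` (standard
#'   errors where available), `selection_method`.
#' @export
fit_logistic <- function(values, labels, subset = colnames(values),
                         selection_method = "none") {
  y <- label_to_binary(labels)
  if (!length(subset)) stop("feature subset is empty")
  if (!all(subset %in% colnames(values)))
    stop("unknown feature(s): ",
         paste(setdiff(subset, colnames(values)), collapse = ", "))
  x <- cbind(`(Intercept)` = 1, as.matrix(values[, subset, drop = FALSE]))
  fit <- suppressWarnings(
    glm.fit(x, y, family = stats::binomial(), control = list(maxit = 100)))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  se <- rep(NA_real_, length(beta))
  eps <- 1e-8   # fitted probabilities numerically 0 or 1
  degenerate_fit <- !fit$converged || fit$boundary ||
    any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  if (degenerate_fit) {
    warning("logistic fit did not converge (perfect separation?); ",
            "refitting with L2 ridge 1e-6")
    xr <- as.matrix(values[, subset, drop = FALSE])
    pad <- ncol(xr) < 2   # glmnet needs >= 2 columns
    if (pad) xr <- cbind(xr, `.pad` = 0)
    rf <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
    b <- as.matrix(coef(rf))[, 1]
    if (pad) b <- b[-length(b)]
    beta <- c(b[1], b[-1])
    names(beta) <- c("(Intercept)", subset)
  } else {
    w <- fit$weights
    xtwx <- crossprod(x * sqrt(w))
    vc <- try(solve(xtwx), silent = TRUE)
    if (!inherits(vc, "try-error")) se <- sqrt(diag(vc))
  }
  full <- setNames(numeric(ncol(values)), colnames(values))
  full[subset] <- beta[-1]
  full_se <- setNames(rep(NA_real_, ncol(values)), colnames(values))
  full_se[subset] <- se[-1]
  structure(list(feature_names = colnames(values), coefficients = full,
                 intercept = unname(beta[1]), se = full_se,
                 selection_method = selection_method),
            class = "TrainedModel")
}

#' Predicted reactivity (positive-class probability)
#'
#' @param model A `TrainedModel`.
#' @param values Normalized feature matrix with the model's feature
#'   columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_reactivity <- function(model, values) {
  if (inherits(values, "FeatureTable")) values <- values$values
  values <- as.matrix(values)[, model$feature_names, drop = FALSE]
  as.numeric(stats::plogis(model$intercept +
                             values %*% model$coefficients))
}

#' @method print TrainedModel
#' @export
print.TrainedModel <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("TrainedModel (logistic, selection = %s): %d/%d non-zero coefficients, intercept %.3f\n",
              x$selection_method, nz, length(x$coefficients), x$intercept))
  invisible(x)
}

#' Persist / load a trained model as a plain-text coefficient table
#'
#' Two-column tab-separated table (feature, coefficient) with the intercept
#' as the last row.
#'
#' @param model A `TrainedModel`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  tab <- data.frame(feature = c(model$feature_names, "(Intercept)"),
                    coefficient = c(model$coefficients, model$intercept))
  attr_line <- paste0("# selection_method=", model$selection_method)
  writeLines(c(attr_line, "feature\tcoefficient",
               sprintf("%s\t%.17g", tab$feature, tab$coefficient)), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  sel <- sub("^# selection_method=", "", lines[1])
  tab <- read.delim(text = paste(lines[-1], collapse = "\n"),
                    stringsAsFactors = FALSE)
  ic <- tab$feature == "(Intercept)"
  structure(list(feature_names = tab$feature[!ic],
                 coefficients = setNames(tab$coefficient[!ic],
                                         tab$feature[!ic]),
                 intercept = tab$coefficient[ic],
                 se = setNames(rep(NA_real_, sum(!ic)), tab$feature[!ic]),
                 selection_method = sel),
            class = "TrainedModel")
}

#' Classifier performance metrics
#'
#' Confusion-matrix metrics at probability threshold 0.5 (accuracy,
#' sensitivity, specificity, precision, F-measure), the Brier score
#' (mean squared difference between probability and 0/1 class), the area
#' under the ROC curve (trapezoidal, equivalent to the rank statistic with
#' ties counted half) and the area under the precision-recall curve (step
#' interpolation).
#'
#' @param prob Predicted positive-class probabilities.
#' @param labels `"positive"`/`"negative"` labels.
#' @param threshold Classification threshold. Default 0.5.
#' @return An `EvaluationReport` (named list of metrics).
#' @export
evaluate <- function(prob, labels, threshold = 0.5) {
  stopifnot(all(prob >= 0 & prob <= 1))
  y <- label_to_binary(labels)
  pred <- as.numeric(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  fmeas <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = sens, specificity = spec, precision = prec,
    f_measure = fmeas,
    brier = mean((prob - y)^2),
    auroc = auroc(prob, y),
    aupr = aupr(prob, y),
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)),
    class = "EvaluationReport")
}

#' @method print EvaluationReport
#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(paste0("Acc %.3f  Sens %.3f  Spec %.3f  Prec %.3f  ",
                     "F %.3f  Brier %.4f  AUROC %.3f  AUPR %.3f\n"),
              x$accuracy, x$sensitivity, x$specificity, x$precision,
              x$f_measure, x$brier, x$auroc, x$aupr))
  invisible(x)
}

# Rank-based AUROC: probability a random positive outranks a random
# negative, ties counted half (equals the trapezoidal area over all
# thresholds).
auroc <- function(prob, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve by step interpolation over
# descending score thresholds (tied scores handled as one threshold).
aupr <- function(prob, y) {
  n1 <- sum(y == 1)
  if (n1 == 0 || all(y == 1)) return(NA_real_)
  ord <- order(prob, decreasing = TRUE)
  ys <- y[ord]; ps <- prob[ord]
  grp <- cumsum(!duplicated(ps))
  tp <- cumsum(ys); npred <- seq_along(ys)
  last <- !duplicated(grp, fromLast = TRUE)   # threshold boundaries
  tp <- tp[last]; npred <- npred[last]
  prec <- tp / npred
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Leakage-aware leave-one-out cross-validation
#'
#' For each fold the held-out peptide is removed from every reference set:
#' the alignment features of the n-1 training peptides are recomputed with
#' the held-out index masked from the MaxScore maxima, the min-max
#' normalization and (optionally) the feature selection are re-derived on
#' the n-1 training rows, the logistic model is refit, and the held-out
#' peptide's probability is recorded. Metrics are computed over all n
#' held-out predictions at threshold 0.5.
#'
#' This masking discipline is what makes the dataset-dependent MaxScore
#' features usable: they embed class labels, so a naive cross-validation
#' that computed them once on the full set would leak the held-out label
#' into its own features.
#'
#' @param ps A `PeptideSet` with both classes present.
#' @param config A [run_config()].
#' @param selection `"none"`, `"m5"` or `"lasso"`.
#' @param refit_selection Re-run feature selection inside every fold
#'   (leak-free, default). `FALSE` reuses the subset selected once on the
#'   full set — faster but optimistic.
#' @param matrices Optional precomputed list with elements `global` and
#'   `local` (from [score_matrix()]) to avoid re-alignment.
#' @return List with `report` (an `EvaluationReport`) and `predictions`
#'   (data frame: id, label, prob).
#' @export
loocv <- function(ps, config = run_config(),
                  selection = c("none", "m5", "lasso"),
                  refit_selection = TRUE, matrices = NULL) {
  selection <- match.arg(selection)
  labels <- ps$label
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  n <- nrow(ps)
  ap_g <- alignment_params("global", config$substitution_matrix,
                           config$gap_open, config$gap_extend)
  ap_l <- alignment_params("local", config$substitution_matrix,
                           config$gap_open, config$gap_extend)
  if (is.null(matrices))
    matrices <- list(global = score_matrix(ps, ap_g),
                     local = score_matrix(ps, ap_l))
  seq_raw <- sequence_features(ps, config$window)

  global_subset <- NULL
  if (!refit_selection && selection != "none") {
    af <- alignment_feature_matrix(matrices$global, matrices$local, labels)
    ft <- build_feature_table(ps, af, config$window)
    global_subset <- run_selection(ft$values, labels, selection, config)
  }

  prob <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(labels[tr])) < 2)
      stop("fold ", i, " leaves a single-class training set")
    af_tr <- alignment_feature_matrix(matrices$global, matrices$local,
                                      labels, rows = tr, mask = i)
    raw_tr <- cbind(seq_raw[tr, , drop = FALSE], af_tr)[, FEATURE_NAMES]
    mins <- apply(raw_tr, 2, min); maxs <- apply(raw_tr, 2, max)
    vals_tr <- normalize_features(raw_tr, mins, maxs, clip = FALSE)
    subset <- if (selection == "none") FEATURE_NAMES
              else if (refit_selection)
                run_selection(vals_tr, labels[tr], selection, config)
              else global_subset
    model <- suppressWarnings(
      fit_logistic(vals_tr, labels[tr], subset, selection))
    # held-out features against the n-1 retained references only
    af_i <- alignment_features(i, matrices$global, matrices$local, labels)
    raw_i <- c(seq_raw[i, ], af_i)[FEATURE_NAMES]
    vals_i <- normalize_features(matrix(raw_i, 1,
                                        dimnames = list(NULL, FEATURE_NAMES)),
                                 mins, maxs, clip = TRUE)
    prob[i] <- predict_reactivity(model, vals_i)
  }
  list(report = evaluate(prob, labels),
       predictions = data.frame(id = ps$id, label = labels, prob = prob,
                                stringsAsFactors = FALSE))
}

run_selection <- function(values, labels, selection, config) {
  if (selection == "m5") {
    cand <- remove_collinear(values, labels, config$collinearity_threshold)
    select_m5(values, labels, cand)
  } else {
    sel <- select_lasso(values, labels)
    if (!length(sel)) colnames(values) else sel
  }
}

#' Train a reactivity model on a labelled peptide set
#'
#' Convenience wrapper chaining score matrices, feature table construction,
#' feature selection and the logistic fit.
#'
#' @param ps Labelled `PeptideSet`.
#' @param config A [run_config()].
#' @param selection `"none"` (subset A), `"m5"` (subset B) or `"lasso"`
#'   (subset C).
#' @return List with `model`, `table` (the training `FeatureTable`),
#'   `matrices` (global/local score matrices) and `subset`.
#' @export
train_model <- function(ps, config = run_config(),
                        selection = c("none", "m5", "lasso")) {
  selection <- match.arg(selection)
  ap_g <- alignment_params("global", config$substitution_matrix,
                           config$gap_open, config$gap_extend)
  ap_l <- alignment_params("local", config$substitution_matrix,
                           config$gap_open, config$gap_extend)
  matrices <- list(global = score_matrix(ps, ap_g),
                   local = score_matrix(ps, ap_l))
  af <- alignment_feature_matrix(matrices$global, matrices$local, ps$label)
  ft <- build_feature_table(ps, af, config$window)
  subset <- if (selection == "none") FEATURE_NAMES
            else run_selection(ft$values, ps$label, selection, config)
  model <- fit_logistic(ft$values, ps$label, subset, selection)
  list(model = model, table = ft, matrices = matrices, subset = subset)
}
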