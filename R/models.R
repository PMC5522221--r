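# Expression models: ordinary least squares on the log scale and
# epsilon-SVR (libSVM via e1071), both evaluated by 10-fold
# cross-validation. R^2 is reported as the squared Pearson correlation of
# predictions vs observations (model-agnostic, identical across OLS and
# SVR); the 1 - SS_res/SS_tot coefficient of determination is reported
# alongside as r2_ss.

#' Log-scale expression response
#'
#' @param genes gene table with an \code{rpkm} column.
#' @param pseudocount added before the log2.
#' @return numeric vector log2(rpkm + pseudocount).
#' @export
log_expression <- function(genes, pseudocount = 1) {
  log2(genes$rpkm + pseudocount)
}

#' Seeded k-fold assignment
#'
#' Uniform shuffle into k folds with sizes differing by at most one; no
#' stratification.
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels in 1..k.
#' @export
make_folds <- function(n, k = 10, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

resolve_folds <- function(folds, n, seed) {
  if (is.null(folds)) return(make_folds(n, 10, seed))
  if (length(folds) == 1) return(make_folds(n, folds, seed))
  stopifnot(length(folds) == n)
  folds
}

#' Fit the log-linear expression model
#'
#' Ordinary least squares of log2(RPKM + pseudocount) on the logged
#' association features. Coefficients come from the full-data fit;
#' cross-validated metrics from out-of-fold predictions.
#'
#' @param X an \code{assoc_matrix} or a plain numeric matrix of features.
#' @param y log-expression response.
#' @param folds number of folds (default 10) or a full fold-label vector.
#' @param seed seed for the fold shuffle.
#' @return a \code{model_report} list: \code{model_kind},
#'   \code{feature_names}, \code{coefficients} (intercept first),
#'   \code{predictions} (out-of-fold), \code{fitted} (full fit),
#'   \code{r2}, \code{r2_ss}, \code{cv_r2}, \code{cv_r2_ss}, \code{pcc},
#'   \code{per_fold} (train_r2/test_r2 per fold), \code{stability_rmse},
#'   \code{coef_table} (estimates with standard errors),
#'   \code{fold_assignment_seed}.
#' @export
fit_log_linear <- function(X, y, folds = 10, seed = 1L) {
  X <- as_feature_matrix(X)
  check_model_inputs(X, y)
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- colnames(qrX$qr)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("collinearity error: rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  fold <- resolve_folds(folds, length(y), seed)
  k <- max(fold)
  oof <- numeric(length(y))
  per_fold <- data.frame(train_r2 = numeric(k), test_r2 = numeric(k))
  for (f in seq_len(k)) {
    te <- fold == f
    m <- stats::lm(y ~ ., data = df[!te, , drop = FALSE])
    oof[te] <- stats::predict(m, newdata = df[te, , drop = FALSE])
    per_fold$train_r2[f] <- safe_cor(stats::fitted(m), y[!te])^2
    per_fold$test_r2[f] <- safe_cor(oof[te], y[te])^2
  }
  sm <- suppressWarnings(summary(fit))  # "essentially perfect fit" is fine
  new_model_report("log_linear", colnames(X), y, oof, stats::fitted(fit),
                   per_fold, seed,
                   coefficients = stats::coef(fit),
                   coef_table = sm$coefficients)
}

#' Fit the epsilon-SVR expression model
#'
#' RBF-kernel epsilon support vector regression (libSVM through
#' \pkg{e1071}). Features and response are standardized on each training
#' fold (predictions are transformed back), the training transform being
#' applied to the corresponding test fold, so \code{cost} and
#' \code{epsilon} operate on a unit-variance response; the full-data fit
#' standardizes on all genes. Deterministic given the fold seed and
#' hyperparameters.
#'
#' @inheritParams fit_log_linear
#' @param cost,epsilon,gamma libSVM hyperparameters; \code{gamma = NULL}
#'   uses 1 / n_features on the standardized features.
#' @return a \code{model_report}; see \code{\link{fit_log_linear}}.
#'   \code{hyperparameters} records the settings used.
#' @export
fit_svr <- function(X, y, folds = 10, seed = 1L,
                    cost = 1, epsilon = 0.1, gamma = NULL) {
  X <- as_feature_matrix(X)
  check_model_inputs(X, y)
  if (stats::sd(y) == 0) stop("degenerate response: y is constant")
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  fold <- resolve_folds(folds, length(y), seed)
  k <- max(fold)
  oof <- numeric(length(y))
  per_fold <- data.frame(train_r2 = numeric(k), test_r2 = numeric(k))
  svr_fit_predict <- function(Xtr, ytr, Xpr) {
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, stats::sd)
    sg[sg == 0] <- 1
    ym <- mean(ytr); ys <- stats::sd(ytr)
    m <- e1071::svm(scale(Xtr, mu, sg), (ytr - ym) / ys,
                    type = "eps-regression", kernel = "radial",
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE)
    lapply(Xpr, function(Z) stats::predict(m, scale(Z, mu, sg)) * ys + ym)
  }
  for (f in seq_len(k)) {
    te <- fold == f
    pr <- svr_fit_predict(X[!te, , drop = FALSE], y[!te],
                          list(X[te, , drop = FALSE],
                               X[!te, , drop = FALSE]))
    oof[te] <- pr[[1]]
    per_fold$train_r2[f] <- safe_cor(pr[[2]], y[!te])^2
    per_fold$test_r2[f] <- safe_cor(pr[[1]], y[te])^2
  }
  fitted_full <- svr_fit_predict(X, y, list(X))[[1]]
  rep <- new_model_report("svr", colnames(X), y, oof, fitted_full,
                          per_fold, seed)
  rep$hyperparameters <- list(kernel = "radial", cost = cost,
                              epsilon = epsilon, gamma = gamma)
  rep
}

# NA for folds too small (or too flat) to define a correlation
safe_cor <- function(a, b) {
  if (length(a) < 3) return(NA_real_)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (is.na(sa) || is.na(sb) || sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}

new_model_report <- function(kind, feature_names, y, oof, fitted, per_fold,
                             seed, coefficients = NULL, coef_table = NULL) {
  ev_cv <- evaluate_predictions(oof, y)
  ev_full <- evaluate_predictions(fitted, y)
  structure(list(
    model_kind = kind,
    feature_names = feature_names,
    coefficients = coefficients,
    coef_table = coef_table,
    predictions = oof,
    fitted = fitted,
    observed = y,
    r2 = ev_full$r2,
    r2_ss = r2_ss(fitted, y),
    cv_r2 = ev_cv$r2,
    cv_r2_ss = r2_ss(oof, y),
    pcc = ev_cv$pcc,
    per_fold = per_fold,
    stability_rmse = stability_rmse(per_fold),
    fold_assignment_seed = seed
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("%s model on %d features: R2 = %.3f, CV-R2 = %.3f, PCC = %.3f\n",
              x$model_kind, length(x$feature_names), x$r2, x$cv_r2, x$pcc))
  invisible(x)
}

#' Squared-correlation accuracy of predictions
#'
#' @param predictions,y equal-length non-constant numeric vectors (n >= 3).
#' @return list with \code{pcc} (Pearson correlation) and \code{r2}
#'   (its square).
#' @export
evaluate_predictions <- function(predictions, y) {
  if (length(predictions) != length(y)) stop("length mismatch")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(predictions) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  pcc <- stats::cor(predictions, y)
  list(pcc = pcc, r2 = pcc^2)
}

r2_ss <- function(predictions, y) {
  1 - sum((y - predictions)^2) / sum((y - mean(y))^2)
}

#' Train/test R-squared stability
#'
#' Root mean squared difference between per-fold training and test R²,
#' the model-stability summary used to compare feature classes. Folds
#' too small to define a test correlation (NA entries) are dropped.
#'
#' @param per_fold data frame with \code{train_r2} and \code{test_r2}.
#' @return non-negative scalar.
#' @export
stability_rmse <- function(per_fold) {
  stopifnot(nrow(per_fold) >= 1)
  sqrt(mean((per_fold$train_r2 - per_fold$test_r2)^2, na.rm = TRUE))
}

as_feature_matrix <- function(X) {
  if (inherits(X, "assoc_matrix")) return(X$logged)
  as.matrix(X)
}

check_model_inputs <- function(X, y) {
  if (nrow(X) != length(y)) stop("X and y disagree in length")
  if (anyNA(X) || anyNA(y)) stop("missing values in model inputs")
  if (nrow(X) <= ncol(X) + 1) stop("need n_genes > n_features + 1")
  invisible(TRUE)
}
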