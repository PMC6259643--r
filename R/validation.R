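# Model validation battery: error metrics, external Q2, the Tropsha
# external-validation criteria, Y-randomization and mean effects.
#
# Residual/prediction conventions used throughout the package: residual =
# predicted - experimental; R2 between observed and predicted values is the
# squared Pearson correlation.

#' Root mean square error
#'
#' \eqn{\sqrt{\sum_i (\hat y_i - y_i)^2 / n}}. Applied to cross-validation
#' predictions this is the RMSECV; applied to external-set predictions, the
#' RMSEP; applied to the training fit, the RMSEC.
#'
#' @param y experimental values.
#' @param y_hat predicted values (same length).
#' @return non-negative scalar.
#' @export
rmse <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1)
  sqrt(mean((y_hat - y)^2))
}

#' Relative error of prediction (percent)
#'
#' \eqn{REP\% = \frac{100}{\bar y}\sqrt{\frac{1}{n}\sum_i (y_i-\hat y_i)^2}},
#' the RMSE as a percentage of the mean experimental value of the evaluated
#' set.
#'
#' @inheritParams rmse
#' @return scalar percentage.
#' @export
rep_percent <- function(y, y_hat) {
  ybar <- mean(y)
  if (ybar == 0) stop("mean of experimental values is zero; REP undefined")
  100 / ybar * rmse(y, y_hat)
}

#' External predictive coefficient Q2
#'
#' \eqn{Q^2_{ext} = 1 - \sum_i (y_i-\hat y_i)^2 / \sum_i (y_i-\bar y_{tr})^2}
#' over the prediction set, with the centring constant fixed at the TRAINING
#' mean.
#'
#' @inheritParams rmse
#' @param ybar_train mean activity of the training set.
#' @return scalar (1 for perfect prediction, 0 for the training-mean
#'   predictor, negative when worse).
#' @export
q2_external <- function(y, y_hat, ybar_train) {
  den <- sum((y - ybar_train)^2)
  if (den == 0) stop("degenerate prediction set: zero denominator")
  1 - sum((y - y_hat)^2) / den
}

#' Leave-one-out (or k-fold) cross-validated Q2 on the training set
#'
#' \eqn{Q^2 = 1 - SSE_{cv} / \sum_i (y_i - \bar y)^2} where the predictions
#' come from cross-validation of the supplied builder.
#'
#' @param y training activities.
#' @param y_cv cross-validation predictions of the same rows.
#' @return scalar.
#' @export
q2_loo <- function(y, y_cv) {
  1 - sum((y - y_cv)^2) / sum((y - mean(y))^2)
}

#' Tropsha external-validation criteria
#'
#' Computes the through-origin regression slopes
#' \eqn{k = \sum y_i\hat y_i / \sum \hat y_i^2},
#' \eqn{k' = \sum y_i\hat y_i / \sum y_i^2}, the squared correlation R2, the
#' through-origin coefficients
#' \eqn{R_0^2 = 1 - \sum(\hat y_i - k\hat y_i)^2 / \sum(\hat y_i -
#' \bar{\hat y})^2} and
#' \eqn{R_0'^2 = 1 - \sum(y_i - k' y_i)^2 / \sum(y_i - \bar y)^2}
#' (the printed convention; `convention = "golbraikh"` swaps the residual
#' arguments to the more common Golbraikh-Tropsha form), the two gap ratios
#' (R2 - R02)/R2, and the pass flags: Q2 > 0.5, R2 > 0.6, one slope within
#' (0.85, 1.15), and min ratio <= 0.1.
#'
#' @inheritParams rmse
#' @param q2 predictive Q2 supplied by the caller (external or
#'   cross-validated).
#' @param convention `"printed"` (default) or `"golbraikh"` for the variant
#'   R02 definitions.
#' @return list of class `tropsha` with all quantities and flags.
#' @export
tropsha <- function(y, y_hat, q2 = NA_real_,
                    convention = c("printed", "golbraikh")) {
  convention <- match.arg(convention)
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0)
    stop("constant y or y_hat; Tropsha criteria undefined")
  syy <- sum(y * y_hat)
  if (sum(y_hat^2) == 0 || sum(y^2) == 0)
    stop("zero sum of squares; slopes undefined")
  k <- syy / sum(y_hat^2)
  kp <- syy / sum(y^2)
  r2 <- stats::cor(y, y_hat)^2
  if (convention == "printed") {
    # residuals of predicted against the through-origin line y^r0 = k*y_hat,
    # normalized by the spread of the predictions (the formula as published)
    r02 <- 1 - sum((y_hat - k * y_hat)^2) / sum((y_hat - mean(y_hat))^2)
    r02p <- 1 - sum((y - kp * y)^2) / sum((y - mean(y))^2)
  } else {
    r02 <- 1 - sum((y - k * y_hat)^2) / sum((y - mean(y))^2)
    r02p <- 1 - sum((y_hat - kp * y)^2) / sum((y_hat - mean(y_hat))^2)
  }
  ratio <- (r2 - r02) / r2
  ratio_p <- (r2 - r02p) / r2
  pass <- list(
    q2 = !is.na(q2) && q2 > 0.5,
    r2 = r2 > 0.6,
    slope = (k > 0.85 && k < 1.15) || (kp > 0.85 && kp < 1.15),
    ratio = min(ratio, ratio_p) <= 0.1)
  structure(list(k = k, k_prime = kp, r_squared = r2, q2 = q2,
                 r0_squared = r02, r0_prime_squared = r02p,
                 ratio = ratio, ratio_prime = ratio_p,
                 pass = pass, overall = all(unlist(pass)),
                 convention = convention),
            class = "tropsha")
}

#' @export
print.tropsha <- function(x, ...) {
  cat("Tropsha external validation:\n")
  cat(sprintf("  R2 = %.3f  Q2 = %.3f  k = %.3f  k' = %.3f\n",
              x$r_squared, x$q2, x$k, x$k_prime))
  cat(sprintf("  R0^2 = %.3f  R0'^2 = %.3f  ratios = %.3f / %.3f\n",
              x$r0_squared, x$r0_prime_squared, x$ratio, x$ratio_prime))
  cat("  overall:", if (x$overall) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Y-randomization (response permutation) test
#'
#' Shuffles the activity vector, re-runs the full model-building procedure
#' and records R2 and Q2 of each chance model. A real structure-activity
#' relationship shows unshuffled statistics well separated from every
#' shuffled pair.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param model_builder function(X, y) returning a list with numeric
#'   elements `r2` and `q2` (see [pls_builder()]).
#' @param n_iter number of shuffles.
#' @param seed RNG seed.
#' @return data frame with columns `iteration`, `r2`, `q2`.
#' @export
y_randomization <- function(X, y, model_builder, n_iter = 10, seed = 1) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  out <- data.frame(iteration = seq_len(n_iter), r2 = NA_real_,
                    q2 = NA_real_)
  for (i in seq_len(n_iter)) {
    ys <- sample(y)
    st <- model_builder(X, ys)
    out$r2[i] <- st$r2
    out$q2[i] <- st$q2
  }
  out
}

#' PLS model builder for Y-randomization
#'
#' Returns a `model_builder` closure that fits a PLS model with `ncomp`
#' latent variables (capped by rank) and reports predictive statistics from
#' leave-one-out cross-validation: `r2` is the squared correlation between
#' observed activities and their cross-validated predictions, `q2` the
#' cross-validated Q2. Predictive statistics (rather than the training fit)
#' are what a randomization table reports: a chance model then shows a small
#' R2 and a near-zero or negative Q2 even when its training fit is inflated
#' by overfitting.
#'
#' @param ncomp latent-variable count.
#' @param scale autoscale inside the PLS fit.
#' @return function(X, y) -> list(r2, q2).
#' @export
pls_builder <- function(ncomp = 3, scale = TRUE) {
  function(X, y) {
    nc <- min(ncomp, qr(base::scale(X, scale = FALSE))$rank)
    cvp <- pls_cv_predict(X, y, nc, folds = "loo", scale = scale)[, nc]
    list(r2 = stats::cor(y, cvp)^2, q2 = q2_loo(y, cvp))
  }
}

#' Mean effect of each descriptor in an MLR model
#'
#' \eqn{MF_j = \beta_j \sum_i d_{ij} / \sum_j \beta_j \sum_i d_{ij}},
#' computed on raw descriptor values; the MF values sum to 1 by construction
#' and rank the relative contribution of each descriptor.
#'
#' @param model a `qsar_model` with MLR-style coefficients.
#' @param X_train raw training descriptor matrix (same columns as the model).
#' @return named numeric vector of mean effects.
#' @export
mean_effect <- function(model, X_train) {
  b <- model$coefficients[-1]
  cs <- colSums(X_train[, model$descriptors, drop = FALSE])
  num <- b * cs
  den <- sum(num)
  if (den == 0) stop("zero denominator in mean effect")
  num / den
}

#' Full validation report for a fitted QSAR model
#'
#' Computes training fit (R2, RMSEC), cross-validated RMSECV and Q2 on the
#' training set, external RMSEP, REP% and Q2 on the prediction set, and the
#' Tropsha criteria on external predictions.
#'
#' @param model a `qsar_model`.
#' @param X_train,y_train training descriptors and activities.
#' @param X_test,y_test external prediction set.
#' @param cv_folds folds for the training cross-validation (`"loo"` or a
#'   count; a count uses the current RNG stream).
#' @return list of class `validation_report`.
#' @export
validation_report <- function(model, X_train, y_train, X_test, y_test,
                              cv_folds = "loo") {
  pred_tr <- predict(model, X_train)
  pred_te <- predict(model, X_test)
  ncomp <- if (!is.null(model$ncomp)) model$ncomp else
    min(length(model$descriptors), nrow(X_train) - 2)
  cvp <- pls_cv_predict(X_train[, model$descriptors, drop = FALSE], y_train,
                        ncomp, folds = cv_folds)[, ncomp]
  q2ext <- q2_external(y_test, pred_te, mean(y_train))
  structure(list(
    r2_train = stats::cor(y_train, pred_tr)^2,
    rmsec = rmse(y_train, pred_tr),
    rmsecv = rmse(y_train, cvp),
    q2_cv = q2_loo(y_train, cvp),
    r2_pred = stats::cor(y_test, pred_te)^2,
    rmsep = rmse(y_test, pred_te),
    rep_pred = rep_percent(y_test, pred_te),
    q2_ext = q2ext,
    tropsha = tropsha(y_test, pred_te, q2 = q2ext)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  cat(sprintf("  training:   R2 = %.3f  RMSEC = %.3f  RMSECV = %.3f  Q2cv = %.3f\n",
              x$r2_train, x$rmsec, x$rmsecv, x$q2_cv))
  cat(sprintf("  prediction: R2 = %.3f  RMSEP = %.3f  REP%% = %.2f  Q2ext = %.3f\n",
              x$r2_pred, x$rmsep, x$rep_pred, x$q2_ext))
  print(x$tropsha)
  invisible(x)
}

#' @rdname print.validation_report
#' @param report a `validation_report`.
#' @param path output CSV path (one metric per row: name, value).
#' @export
write_validation_csv <- function(report, path) {
  flat <- c(r2_train = report$r2_train, rmsec = report$rmsec,
            rmsecv = report$rmsecv, q2_cv = report$q2_cv,
            r2_pred = report$r2_pred, rmsep = report$rmsep,
            rep_pred = report$rep_pred, q2_ext = report$q2_ext,
            k = report$tropsha$k, k_prime = report$tropsha$k_prime,
            r0_squared = report$tropsha$r0_squared,
            r0_prime_squared = report$tropsha$r0_prime_squared)
  utils::write.csv(data.frame(metric = names(flat), value = unname(flat)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
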