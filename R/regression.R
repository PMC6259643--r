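# Regression strategies: ordinary / stepwise multiple linear regression and
# NIPALS partial least squares, with latent-variable selection by
# cross-validated RMSECV. All fitted objects share the `qsar_model` S3 class
# so that prediction, residuals and validation code is method-agnostic.

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of activity on raw descriptor columns (base `lm`
#' under the hood). Refuses rank-deficient design matrices, naming the
#' collinear columns.
#'
#' @param X numeric matrix of descriptor columns (compounds x descriptors).
#' @param y numeric activity vector (pIC50).
#' @return object of class `c("qsar_mlr", "qsar_model")` with elements
#'   `coefficients` (intercept first), `descriptors`, `fitted`, `residuals`
#'   (fitted - observed), `r_squared`, `f_ratio`, `std_errors`, `n`, `p`.
#' @export
qsar_mlr <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X) + 1)
    stop("need n > p + 1 observations for MLR")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1, ncol(X) + 1)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  structure(list(
    kind = "MLR",
    coefficients = stats::coef(fit),
    descriptors = colnames(X),
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::fitted(fit)) - y,  # predicted - experimental
    r_squared = sm$r.squared,
    f_ratio = unname(sm$fstatistic[1]),
    std_errors = sm$coefficients[, "Std. Error"],
    p_values = sm$coefficients[, "Pr(>|t|)"],
    sigma = sm$sigma,
    n = nrow(X), p = ncol(X),
    lm = fit),
    class = c("qsar_mlr", "qsar_model"))
}

#' Stepwise descriptor selection by partial F tests
#'
#' Classic forward selection with backward elimination: at each step the
#' candidate descriptor with the smallest partial-F p-value enters if below
#' `alpha_enter`; any included descriptor whose p-value rises above
#' `alpha_remove` is then removed. Stops when nothing changes or `max_terms`
#' is reached.
#'
#' @param X descriptor matrix (candidate pool).
#' @param y activity vector.
#' @param alpha_enter entry threshold (p-value), must be <= `alpha_remove`.
#' @param alpha_remove removal threshold.
#' @param max_terms maximum model size.
#' @return list with `selected` (descriptor names, in entry order), `model`
#'   (a `qsar_mlr`, or NULL when nothing entered) and `trace` (data frame of
#'   steps).
#' @export
stepwise_select <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.10,
                            max_terms = ncol(X)) {
  stopifnot(alpha_enter <= alpha_remove)
  X <- as.matrix(X)
  sel <- character(0)
  pool <- colnames(X)
  trace <- data.frame(step = integer(), action = character(),
                      descriptor = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    changed <- FALSE
    # forward
    if (length(sel) < max_terms && length(pool)) {
      pvals <- vapply(pool, function(cand) {
        .partial_f_p(X[, c(sel, cand), drop = FALSE], y, cand)
      }, numeric(1))
      best <- which.min(pvals)
      if (is.finite(pvals[best]) && pvals[best] < alpha_enter) {
        cand <- pool[best]
        sel <- c(sel, cand); pool <- setdiff(pool, cand)
        step_i <- step_i + 1L
        trace[nrow(trace) + 1L, ] <- list(step_i, "enter", cand, pvals[best])
        changed <- TRUE
      }
    }
    # backward
    if (length(sel) > 1) {
      repeat {
        pv <- vapply(sel, function(d)
          .partial_f_p(X[, sel, drop = FALSE], y, d), numeric(1))
        worst <- which.max(pv)
        if (pv[worst] > alpha_remove) {
          drop <- sel[worst]
          sel <- setdiff(sel, drop); pool <- c(pool, drop)
          step_i <- step_i + 1L
          trace[nrow(trace) + 1L, ] <- list(step_i, "remove", drop, pv[worst])
          changed <- TRUE
        } else break
      }
    }
    if (!changed || length(sel) >= max_terms) break
  }
  if (!length(sel)) {
    warning("no descriptor passed the entry threshold; empty model")
    return(list(selected = character(0), model = NULL, trace = trace))
  }
  list(selected = sel, model = qsar_mlr(X[, sel, drop = FALSE], y),
       trace = trace)
}

# p-value of the partial F test for dropping `term` from the model y ~ cols.
# For a single added/dropped column this equals the square of its t statistic.
.partial_f_p <- function(Xsub, y, term) {
  n <- nrow(Xsub); p <- ncol(Xsub)
  if (n <= p + 1) return(Inf)
  qr_full <- qr(cbind(1, Xsub))
  if (qr_full$rank < p + 1) return(Inf)
  rss_full <- sum(qr.resid(qr_full, y)^2)
  keep <- setdiff(colnames(Xsub), term)
  qr_red <- qr(cbind(1, Xsub[, keep, drop = FALSE]))
  rss_red <- sum(qr.resid(qr_red, y)^2)
  df2 <- n - p - 1
  f <- (rss_red - rss_full) / (rss_full / df2)
  stats::pf(f, 1, df2, lower.tail = FALSE)
}

#' Fit a PLS regression QSAR model (NIPALS)
#'
#' Single-response partial least squares by the NIPALS algorithm. Descriptors
#' and activity are centred (and by default autoscaled) internally; the
#' regression vector is folded back so that prediction is affine in the raw
#' descriptor values. With `ncomp = rank(X)` the fit coincides with OLS.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param ncomp number of latent variables, 1..rank(X).
#' @param scale autoscale descriptor columns (default TRUE, the conventional
#'   preprocessing for heterogeneous descriptor sets).
#' @return object of class `c("qsar_pls", "qsar_model")` with `coefficients`
#'   (raw-scale, intercept first), `ncomp`, `scores`, `loadings`, `weights`,
#'   `coef_path` (raw-scale coefficient matrix for 1..ncomp LVs),
#'   `descriptors`, `fitted`, `residuals`, `r_squared`.
#' @export
qsar_pls <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncomp >= 1)
  rk <- qr(base::scale(X, scale = FALSE))$rank
  if (ncomp > rk) stop("ncomp = ", ncomp, " exceeds rank(X) = ", rk)
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(scl == 0)) stop("zero-variance column(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Xc <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  ybar <- mean(y)
  yc <- y - ybar
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  qv <- numeric(ncomp)
  Xd <- Xc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { W <- W[, seq_len(a - 1), drop = FALSE]
                      P <- P[, seq_len(a - 1), drop = FALSE]
                      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
                      qv <- qv[seq_len(a - 1)]; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pl <- crossprod(Xd, t) / tt
    q <- sum(yc * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; qv[a] <- q
  }
  ncomp_eff <- length(qv)
  # regression vectors on the centred/scaled space, for each 1..ncomp_eff;
  # a y with no covariance with X degenerates to the intercept-only model
  coef_path <- matrix(0, p, max(ncomp_eff, 1),
                      dimnames = list(colnames(X), NULL))
  if (ncomp_eff > 0) {
    R <- W %*% solve(triu_crossprod(P, W))
    for (a in seq_len(ncomp_eff))
      coef_path[, a] <- R[, seq_len(a), drop = FALSE] %*% qv[seq_len(a)]
  } else ncomp_eff <- 1L
  # fold back to raw descriptor scale
  coef_raw <- sweep(coef_path, 1, scl, `/`)
  b <- coef_raw[, ncomp_eff]
  intercept <- ybar - sum(ctr * b)
  fitted <- drop(X %*% b) + intercept
  structure(list(
    kind = "PLS",
    coefficients = c(`(Intercept)` = intercept, b),
    descriptors = colnames(X),
    ncomp = ncomp_eff,
    scores = Tm, loadings = P, weights = W, y_loadings = qv,
    coef_path = coef_raw,
    center = ctr, scale = scl, y_mean = ybar,
    fitted = fitted,
    residuals = fitted - y,
    r_squared = 1 - sum((y - fitted)^2) / sum((y - mean(y))^2),
    n = nrow(X), p = p),
    class = c("qsar_pls", "qsar_model"))
}

# P'W is upper triangular in exact arithmetic; computed explicitly.
triu_crossprod <- function(P, W) crossprod(P, W)

#' Cross-validated PLS predictions for 1..ncomp latent variables
#'
#' @param X descriptor matrix; `y` activity vector.
#' @param ncomp maximum number of latent variables.
#' @param folds either `"loo"` or an integer vector of fold labels
#'   (length n), or a number of random folds (requires a seeded RNG by the
#'   caller).
#' @param scale passed to [qsar_pls()].
#' @return n x ncomp matrix of out-of-fold predictions.
#' @export
pls_cv_predict <- function(X, y, ncomp, folds = "loo", scale = TRUE) {
  n <- nrow(X)
  fl <- if (identical(folds, "loo")) seq_len(n)
        else if (length(folds) == 1L) sample(rep_len(seq_len(folds), n))
        else folds
  stopifnot(length(fl) == n)
  if (max(table(fl)) >= n)
    stop("cross-validation folds leave no training rows")
  pred <- matrix(NA_real_, n, ncomp)
  for (f in unique(fl)) {
    hold <- fl == f
    Xt <- X[!hold, , drop = FALSE]; yt <- y[!hold]
    nc <- min(ncomp, qr(base::scale(Xt, scale = FALSE))$rank)
    if (nc < 1) next
    fit <- qsar_pls(Xt, yt, nc, scale = scale)
    cp <- fit$coef_path
    ic <- fit$y_mean - colSums(fit$center * cp)
    pr <- X[hold, , drop = FALSE] %*% cp + rep(ic, each = sum(hold))
    pred[hold, seq_len(nc)] <- pr
    if (nc < ncomp) pred[hold, seq.int(nc + 1, ncomp)] <- pr[, nc]
  }
  pred
}

#' Select the number of PLS latent variables by RMSECV
#'
#' Computes the cross-validated RMSE for 1..`max_lv` latent variables and
#' returns the argmin; ties break towards fewer latent variables (parsimony).
#'
#' @inheritParams pls_cv_predict
#' @param max_lv largest LV count to try.
#' @return list with `ncomp` (chosen LV count) and `rmsecv` (the full curve,
#'   length `max_lv`).
#' @export
select_lv <- function(X, y, max_lv, folds = "loo", scale = TRUE) {
  stopifnot(max_lv >= 1)
  pred <- pls_cv_predict(X, y, max_lv, folds = folds, scale = scale)
  curve <- apply(pred, 2, function(p) sqrt(mean((p - y)^2)))
  list(ncomp = which.min(curve), rmsecv = curve)
}

# --- shared qsar_model methods -------------------------------------------

#' Predict from a fitted QSAR model
#'
#' Affine evaluation of the model on raw descriptor values; columns are
#' matched by descriptor name.
#'
#' @param object a `qsar_model`.
#' @param newdata numeric matrix containing at least the model's descriptor
#'   columns.
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$descriptors, colnames(newdata))
  if (length(miss))
    stop("newdata lacks descriptor column(s): ", paste(miss, collapse = ", "))
  Xn <- newdata[, object$descriptors, drop = FALSE]
  b <- object$coefficients
  drop(Xn %*% b[-1]) + b[1]
}

#' @export
coef.qsar_model <- function(object, ...) object$coefficients

#' @export
residuals.qsar_model <- function(object, ...) object$residuals

#' @export
fitted.qsar_model <- function(object, ...) object$fitted

#' @export
print.qsar_model <- function(x, ...) {
  cat("QSAR", x$kind, "model:", length(x$descriptors), "descriptor(s)")
  if (!is.null(x$ncomp)) cat(",", x$ncomp, "latent variable(s)")
  cat("\n  R2 =", format(x$r_squared, digits = 4))
  if (!is.null(x$f_ratio)) cat(", F =", format(x$f_ratio, digits = 4))
  cat("\n  coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.qsar_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.qsar_model <- function(x, y = NULL, ...) {
  obs <- x$fitted - x$residuals
  graphics::plot(obs, x$fitted, xlab = "experimental pIC50",
                 ylab = "predicted pIC50",
                 main = paste(x$kind, "fit"), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize / restore a QSAR model as flat JSON
#'
#' Writes the model kind, descriptor names, coefficients, LV count and (for
#' PLS) scaling parameters as plain JSON; `read_qsar_model` restores a model
#' capable of prediction.
#'
#' @param model a `qsar_model`.
#' @param path file path.
#' @export
write_qsar_model <- function(model, path) {
  obj <- list(kind = model$kind,
              descriptors = model$descriptors,
              coefficients = as.list(model$coefficients),
              ncomp = model$ncomp,
              r_squared = model$r_squared)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = obj$kind,
                 coefficients = unlist(obj$coefficients),
                 descriptors = obj$descriptors,
                 ncomp = obj$ncomp,
                 r_squared = obj$r_squared),
            class = c(if (identical(obj$kind, "PLS")) "qsar_pls"
                      else "qsar_mlr", "qsar_model"))
}
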