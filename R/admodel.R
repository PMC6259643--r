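# Leverage-based applicability domain: per-compound leverage in model space,
# the warning leverage h* = 3(p+1)/n, standardized residuals and the
# Williams-plot classification.
#
# Model space is whatever matrix the caller supplies: for an MLR model the
# selected (autoscaled) descriptor columns, for a PLS model conventionally
# the latent-variable score space. The published leverage formula often
# appears without the matrix inverse; the standard definition
# h_i = x_i' (X'X)^{-1} x_i is what is computed here (the inverse-free form
# is not scale-invariant and is incompatible with the h* threshold).

#' Per-compound leverage
#'
#' \eqn{h_i = x_i^T (X^T X)^{-1} x_i} with X the training model-space matrix.
#' Training leverages (rows of X probed against X itself) sum to the
#' model-space dimension p (the hat-matrix trace). A pseudo-inverse is used
#' with a warning when X'X is ill-conditioned.
#'
#' @param X_train numeric training matrix (n x p), full column rank in model
#'   space.
#' @param X_probe matrix of probe rows (defaults to `X_train`, giving the
#'   training leverages).
#' @return numeric vector of leverages, one per probe row.
#' @export
leverage <- function(X_train, X_probe = X_train) {
  X_train <- as.matrix(X_train)
  X_probe <- as.matrix(X_probe)
  if (ncol(X_probe) != ncol(X_train))
    stop("probe has ", ncol(X_probe), " columns; training space has ",
         ncol(X_train))
  XtX <- crossprod(X_train)
  inv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(inv) || kappa(XtX) > 1e12) {
    warning("X'X ill-conditioned; using pseudo-inverse")
    s <- svd(XtX)
    pos <- s$d > max(s$d) * 1e-12
    inv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  rowSums((X_probe %*% inv) * X_probe)
}

#' Warning leverage h*
#'
#' \eqn{h^* = 3(p+1)/n} with n the training-set size and p the number of
#' predictor variables (descriptors for MLR, latent variables for PLS).
#'
#' @param n training-set size.
#' @param p number of predictor variables.
#' @return scalar threshold.
#' @examples
#' warning_leverage(108, 8)  # 0.25
#' @export
warning_leverage <- function(n, p) {
  stopifnot(n > 0, p >= 1)
  3 * (p + 1) / n
}

#' Williams-plot applicability-domain analysis
#'
#' Computes leverages of training and probe compounds in model space,
#' standardized residuals (residual divided by the SD of the training
#' residuals) where activities are available, the warning leverage
#' h* = 3(p+1)/n, and the in/out classification: a compound is in-domain when
#' its leverage is at most h* and (when a residual exists) |standardized
#' residual| <= 3. Probes without activity are classified on leverage alone.
#'
#' @param model a fitted `qsar_model` (used for predictions and residuals).
#' @param X_train raw training descriptor matrix (model descriptor columns
#'   are extracted by name).
#' @param y_train training activities.
#' @param X_probe optional probe descriptor matrix (defaults to none).
#' @param y_probe optional probe activities (`NA` allowed).
#' @param space `"score"` (PLS latent-variable space, the default when the
#'   model carries score weights) or `"descriptor"` (autoscaled descriptor
#'   columns).
#' @return data frame of class `ad_result` with columns `compound_id`,
#'   `set` (train/probe), `leverage`, `std_residual`, `high_leverage`,
#'   `residual_outlier`, `in_domain`; attributes `h_star`, `n`, `p`.
#' @export
williams <- function(model, X_train, y_train, X_probe = NULL, y_probe = NULL,
                     space = c("auto", "score", "descriptor")) {
  space <- match.arg(space)
  if (space == "auto")
    space <- if (!is.null(model$weights)) "score" else "descriptor"
  Xtr_raw <- as.matrix(X_train)[, model$descriptors, drop = FALSE]
  Xpr_raw <- if (!is.null(X_probe))
    as.matrix(X_probe)[, model$descriptors, drop = FALSE] else NULL
  if (space == "score") {
    if (is.null(model$weights))
      stop("model carries no score weights; use space = 'descriptor'")
    proj <- function(M) {
      Mc <- sweep(sweep(M, 2, model$center), 2, model$scale, `/`)
      Mc %*% model$weights %*%
        solve(crossprod(model$loadings, model$weights))
    }
    Ttr <- proj(Xtr_raw)
    Tpr <- if (!is.null(Xpr_raw)) proj(Xpr_raw) else NULL
  } else {
    Ttr <- autoscale(Xtr_raw)
    Tpr <- if (!is.null(Xpr_raw)) apply_scaling(Xpr_raw, Ttr) else NULL
  }
  p <- ncol(Ttr); n <- nrow(Ttr)
  h_star <- warning_leverage(n, p)
  h_tr <- leverage(Ttr)
  res_tr <- predict(model, Xtr_raw) - y_train
  s <- stats::sd(res_tr)
  if (s == 0) stop("zero residual SD; standardized residuals undefined")
  build <- function(ids, set, h, res) {
    std <- res / s
    high <- h > h_star
    outl <- !is.na(std) & abs(std) > 3
    data.frame(compound_id = ids, set = set, leverage = h,
               std_residual = std, high_leverage = high,
               residual_outlier = outl,
               in_domain = !high & !outl,
               stringsAsFactors = FALSE)
  }
  ids_tr <- rownames(Xtr_raw)
  if (is.null(ids_tr)) ids_tr <- paste0("train_", seq_len(n))
  out <- build(ids_tr, "train", h_tr, res_tr)
  if (!is.null(Tpr)) {
    h_pr <- leverage(Ttr, Tpr)
    res_pr <- if (!is.null(y_probe))
      predict(model, Xpr_raw) - y_probe else rep(NA_real_, nrow(Tpr))
    ids_pr <- rownames(Xpr_raw)
    if (is.null(ids_pr)) ids_pr <- paste0("probe_", seq_len(nrow(Tpr)))
    out <- rbind(out, build(ids_pr, "probe", h_pr, res_pr))
  }
  attr(out, "h_star") <- h_star
  attr(out, "n") <- n
  attr(out, "p") <- p
  class(out) <- c("ad_result", "data.frame")
  out
}

#' @export
print.ad_result <- function(x, ...) {
  cat("Applicability domain (Williams): h* =",
      format(attr(x, "h_star"), digits = 4),
      "(n =", attr(x, "n"), ", p =", attr(x, "p"), ")\n")
  cat(" ", sum(!x$in_domain), "of", nrow(x), "compounds outside the domain\n")
  NextMethod()
}

#' Williams plot
#'
#' Standardized residuals against leverage, with the h* and +/-3 cut-off
#' lines. Side-effect only; never load-bearing.
#'
#' @param x an `ad_result`.
#' @param y unused.
#' @param ... passed to `plot`.
#' @export
plot.ad_result <- function(x, y = NULL, ...) {
  graphics::plot(x$leverage, x$std_residual,
                 xlab = "leverage h", ylab = "standardized residual",
                 main = "Williams plot",
                 col = ifelse(x$set == "train", 1, 2), ...)
  graphics::abline(v = attr(x, "h_star"), lty = 2)
  graphics::abline(h = c(-3, 3), lty = 3)
  invisible(x)
}

#' Write an applicability-domain CSV
#'
#' @param ad an `ad_result`.
#' @param path output path.
#' @export
write_ad_csv <- function(ad, path) {
  df <- as.data.frame(ad)
  df$h_star <- attr(ad, "h_star")
  utils::write.csv(df[, c("compound_id", "leverage", "std_residual",
                          "h_star", "in_domain")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
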