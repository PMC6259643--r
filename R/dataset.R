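# Activity handling, Kennard-Stone splitting, autoscaling and the PCA
# homogeneity check.

.UNIT_FACTOR <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Convert IC50 to pIC50
#'
#' pIC50 = -log10(IC50 in mol/L). Exact; round only for display (the activity
#' tables of the field print 2 decimals). Note that published tables are not
#' always self-consistent with their own IC50 column at 2 dp; see the fixture
#' notes shipped with the package.
#'
#' @param value positive IC50 value(s).
#' @param unit one of `"M"`, `"mM"`, `"uM"` (micromolar; `"µM"` is
#'   accepted), `"nM"`. Vectorized, recycled against `value`.
#' @return numeric pIC50 value(s).
#' @examples
#' ic50_to_pic50(6, "nM")    # 8.2218...
#' ic50_to_pic50(1, "M")     # 0
#' @export
ic50_to_pic50 <- function(value, unit = "nM") {
  if (any(!is.finite(value) | value <= 0))
    stop("IC50 values must be positive and finite")
  unit <- gsub("µ", "u", unit)
  if (any(!unit %in% names(.UNIT_FACTOR)))
    stop("unknown unit(s): ", paste(setdiff(unit, names(.UNIT_FACTOR)),
                                    collapse = ", "),
         " (expected M, mM, uM or nM)")
  unname(-log10(value * .UNIT_FACTOR[unit]))
}

#' Kennard-Stone training-set selection
#'
#' Classic deterministic maximin coverage: autoscale the descriptors, seed
#' with the two mutually farthest compounds (Euclidean distance), then
#' repeatedly add the compound whose minimum distance to the selected set is
#' largest. Ties break towards the lowest row index.
#'
#' @param X numeric descriptor matrix with compound ids as row names.
#' @param n_train number of training compounds, 2..nrow(X).
#' @param scale autoscale columns before computing distances (default TRUE;
#'   set FALSE if `X` is already scaled).
#' @return list of class `ks_split` with `train` and `test` (compound ids),
#'   and `order` (ids in selection order).
#' @examples
#' X <- matrix(c(0, 1, 2, 3, 10), ncol = 1,
#'             dimnames = list(letters[1:5], "x"))
#' kennard_stone(X, 3)$train
#' @export
kennard_stone <- function(X, n_train, scale = TRUE) {
  n <- nrow(X)
  stopifnot(n_train >= 2, n_train <= n)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  Xs <- if (scale) {
    sds <- apply(X, 2, stats::sd)
    base::scale(X[, sds > 0, drop = FALSE])
  } else X
  D <- as.matrix(stats::dist(Xs))
  # seed pair: maximal distance, ties to smallest (row, col) index
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  sel <- sort(unique(as.integer(far[1, ])))[1:2]
  if (sel[1] == sel[2]) { # all points coincide
    warning("duplicate rows make the seed pair ambiguous; using rows 1, 2")
    sel <- c(1L, 2L)
  }
  rest <- setdiff(seq_len(n), sel)
  while (length(sel) < n_train) {
    mind <- apply(D[rest, sel, drop = FALSE], 1, min)
    pick <- rest[which.max(mind)]  # which.max takes the first (lowest index)
    sel <- c(sel, pick)
    rest <- setdiff(rest, pick)
  }
  structure(list(train = ids[sel], test = ids[sort(rest)], order = ids[sel]),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat("Kennard-Stone split:", length(x$train), "training /",
      length(x$test), "prediction compounds\n")
  invisible(x)
}

#' Autoscale a descriptor matrix
#'
#' Centres each column to mean 0 and scales to sample SD 1 (n - 1
#' denominator). The centres and scales are stored so that new rows - e.g.
#' prediction-set or screening compounds - can be projected with the training
#' parameters only.
#'
#' @param X numeric matrix with no zero-SD columns (run [prefilter()] first).
#' @return matrix with attributes `center` and `scale`.
#' @export
autoscale <- function(X) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-SD column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         "; prefilter first")
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, `/`)
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- sds
  Xs
}

#' @rdname autoscale
#' @param new numeric matrix of new rows; column names must match those used
#'   to fit the scaling.
#' @param scaled a matrix returned by [autoscale()] (or any object carrying
#'   `center`/`scale` attributes).
#' @export
apply_scaling <- function(new, scaled) {
  ctr <- attr(scaled, "center"); scl <- attr(scaled, "scale")
  if (is.null(ctr) || is.null(scl)) stop("no stored scaling parameters")
  if (!identical(colnames(new), names(ctr)))
    stop("column names of new data do not match the scaling parameters")
  Xs <- sweep(sweep(new, 2, ctr), 2, scl, `/`)
  Xs
}

#' PCA homogeneity check
#'
#' Principal components of an autoscaled descriptor matrix, for score-plot
#' inspection of data-set homogeneity and outliers.
#'
#' @param X autoscaled descriptor matrix.
#' @param n_components number of leading components to return.
#' @return list with `scores` (n x n_components), `explained` (percent
#'   variance per component) and `cumulative`.
#' @export
pca_check <- function(X, n_components = 2) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rk <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_components > rk)
    stop("n_components = ", n_components, " exceeds matrix rank ", rk)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       cumulative = cumsum(expl)[seq_len(n_components)])
}

#' Read an activity CSV
#'
#' Accepts either `compound_id,ic50,unit` (converted via [ic50_to_pic50()])
#' or `compound_id,pic50`.
#'
#' @param path file path.
#' @return named numeric vector of pIC50 values.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("ic50", "unit") %in% names(df))) {
    y <- ic50_to_pic50(df$ic50, df$unit)
  } else if ("pic50" %in% names(df)) {
    y <- df$pic50
  } else stop("activity CSV needs columns ic50+unit or pic50")
  names(y) <- df$compound_id
  y
}
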