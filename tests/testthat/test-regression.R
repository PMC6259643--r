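# MLR, stepwise selection, PLS and latent-variable selection.

test_that("MLR recovers exact linear systems and matches the normal equations", {
  set.seed(1)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  b_true <- c(2, -1, 0.5, 3)
  y <- drop(X %*% b_true) + 1

  fit0 <- qsar_mlr(X, y)                    # noiseless
  expect_equal(max(abs(fit0$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-12)

  yn <- y + rnorm(50, 0, 0.5)
  fit <- qsar_mlr(X, yn)
  expect_equal(unname(fit$coefficients), unname(oracle_ols(X, yn)),
               tolerance = 1e-10)

  # single column X = y: slope 1, intercept 0
  X1 <- matrix(yn, ncol = 1, dimnames = list(NULL, "d"))
  f1 <- qsar_mlr(X1, yn)
  expect_equal(unname(f1$coefficients), c(0, 1), tolerance = 1e-10)

  # rank deficiency is refused with the column named
  Xr <- cbind(X, x5 = X[, 1] * 2)
  expect_error(qsar_mlr(Xr, yn), "collinear")
})

test_that("MLR residual convention is predicted minus experimental", {
  set.seed(2)
  X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "d"))
  y <- drop(X) + rnorm(30, 0, 0.2)
  fit <- qsar_mlr(X, y)
  expect_equal(fit$residuals, fit$fitted - y)
  expect_equal(predict(fit, X), fit$fitted)
  # all-zero descriptor row predicts the intercept
  expect_equal(unname(predict(fit, matrix(0, 1, 1,
                                          dimnames = list(NULL, "d")))),
               unname(fit$coefficients[1]))
})

test_that("stepwise selection finds planted signal and honours thresholds", {
  set.seed(3)
  n <- 100
  X <- matrix(rnorm(n * 21), n, 21, dimnames = list(NULL, paste0("x", 1:21)))
  y <- 2 * X[, 3] + rnorm(n, 0, 0.1)
  res <- stepwise_select(X, y)
  expect_equal(res$trace$descriptor[1], "x3")  # dominant partial F enters first
  expect_true("x3" %in% res$selected)

  # pure noise at a tiny entry threshold: empty selection
  ynull <- rnorm(n)
  expect_warning(res0 <- stepwise_select(X, ynull, alpha_enter = 1e-6,
                                         alpha_remove = 1e-5),
                 "empty")
  expect_length(res0$selected, 0)

  # alpha_enter = 1 admits max_terms
  res1 <- stepwise_select(X, ynull, alpha_enter = 1, alpha_remove = 1,
                          max_terms = 4)
  expect_length(res1$selected, 4)
})

test_that("PLS at full rank equals OLS and is invariant to duplicate columns", {
  set.seed(4)
  for (t in 1:5) {
    X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- drop(X %*% runif(5, -2, 2)) + rnorm(40, 0, 0.3)
    fit <- qsar_pls(X, y, 5)
    expect_equal(unname(fit$coefficients), unname(oracle_ols(X, y)),
                 tolerance = 1e-8)
    # duplicated descriptor columns leave predictions unchanged
    Xd <- cbind(X, x6 = X[, 2])
    f2 <- qsar_pls(Xd, y, 5)
    expect_equal(predict(f2, Xd), predict(fit, X), tolerance = 1e-6)
  }
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
  expect_error(qsar_pls(X, rnorm(40), 6), "rank")
})

test_that("PLS on y orthogonal to X explains nothing with one LV", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("x", 1:3)))
  # construct y orthogonal to the centred columns
  Xc <- scale(X, scale = FALSE)
  y0 <- rnorm(50)
  y <- y0 - Xc %*% solve(crossprod(Xc), crossprod(Xc, y0))
  fit <- qsar_pls(X, drop(y), 1)
  expect_lt(fit$r_squared, 1e-8)
})

test_that("latent-variable selection recovers the true factor count", {
  set.seed(8)
  n <- 200; p <- 12
  Fm <- matrix(rnorm(n * 3), n, 3)
  L <- matrix(runif(3 * p, -1, 1), 3, p)
  X <- Fm %*% L   # exactly rank 3: LVs beyond 3 cannot help
  colnames(X) <- paste0("x", 1:p)
  y <- drop(Fm %*% c(1, -2, 1.5)) + rnorm(n, 0, 0.05)
  sel <- select_lv(X, y, max_lv = 8)
  expect_equal(sel$ncomp, 3)
  expect_length(sel$rmsecv, 8)
  expect_equal(select_lv(X, y, max_lv = 1)$ncomp, 1)
})

test_that("prediction demands matching descriptor columns", {
  set.seed(10)
  X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rowSums(X)
  fit <- qsar_pls(X, y, 2)
  expect_error(predict(fit, X[, "a", drop = FALSE]), "lacks")
  # extra columns and reordering are fine (matched by name)
  Xr <- cbind(b = X[, "b"], junk = rnorm(30), a = X[, "a"])
  expect_equal(predict(fit, Xr), predict(fit, X))
})

test_that("models serialize to JSON and round-trip predictions", {
  set.seed(12)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(40, 0, 0.1)
  for (fit in list(qsar_mlr(X, y), qsar_pls(X, y, 2))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_qsar_model(fit, path)
    back <- read_qsar_model(path)
    expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
    expect_equal(back$kind, fit$kind)
  }
})
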