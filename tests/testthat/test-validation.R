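# Error metrics, external Q2, Tropsha criteria, Y-randomization, mean effect.

test_that("REP and RMSE match forced arithmetic and independent oracles", {
  expect_equal(rep_percent(c(1, 1), c(1, 1)), 0)
  expect_equal(rep_percent(c(1, 1), c(2, 0)), 100)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  expect_error(rep_percent(c(1, -1), c(0, 0)), "zero")

  set.seed(51)
  for (t in 1:20) {
    y <- rnorm(15, 7); yh <- y + rnorm(15, 0, 0.5)
    expect_equal(rmse(y, yh), sqrt(sum((yh - y)^2) / 15), tolerance = 1e-12)
    expect_equal(rep_percent(y, yh), 100 * sqrt(mean((y - yh)^2)) / mean(y),
                 tolerance = 1e-12)
  }
})

test_that("external Q2 uses the training mean and honours its conventions", {
  y <- c(6, 7, 8); ytr <- 6.5
  expect_equal(q2_external(y, y, ytr), 1)
  expect_equal(q2_external(y, rep(ytr, 3), ytr), 0)
  expect_error(q2_external(rep(ytr, 3), y, ytr), "denominator")

  set.seed(52)
  for (t in 1:20) {
    y <- rnorm(10, 7); yh <- y + rnorm(10, 0, 0.4); m <- rnorm(1, 7)
    expect_equal(q2_external(y, yh, m),
                 1 - sum((y - yh)^2) / sum((y - m)^2), tolerance = 1e-12)
    # invariance under a common shift
    s <- rnorm(1)
    expect_equal(q2_external(y + s, yh + s, m + s), q2_external(y, yh, m),
                 tolerance = 1e-10)
  }
})

test_that("Tropsha criteria behave on exact, scaled and random predictions", {
  y <- c(5, 6, 7, 8, 9)
  t1 <- tropsha(y, y, q2 = 1)
  expect_equal(t1$k, 1); expect_equal(t1$k_prime, 1)
  expect_equal(t1$r_squared, 1); expect_equal(t1$r0_squared, 1)
  expect_equal(t1$ratio, 0)
  expect_true(t1$overall)

  t2 <- tropsha(y, 2 * y, q2 = 1)
  expect_equal(t2$k, 0.5); expect_equal(t2$k_prime, 2)
  expect_false(t2$pass$slope)

  set.seed(53)
  for (t in 1:20) {
    y <- rnorm(12, 7); yh <- y + rnorm(12, 0, 0.3)
    tr <- tropsha(y, yh)
    # slope identities vs direct sums
    expect_equal(tr$k, sum(y * yh) / sum(yh^2), tolerance = 1e-12)
    expect_equal(tr$k_prime, sum(y * yh) / sum(y^2), tolerance = 1e-12)
    # Cauchy-Schwarz: k * k' = (sum y yhat)^2 / (sum y^2 sum yhat^2) <= 1
    expect_lte(tr$k * tr$k_prime, 1 + 1e-12)
  }

  # near-unity slope mirrors the published convention of reporting K near 1
  yh <- y * 1.02
  expect_true(tropsha(y, yh, q2 = 1)$pass$slope)
  expect_error(tropsha(rep(1, 4), rep(2, 4)), "constant")
})

test_that("Y-randomization separates planted signal from chance models", {
  set.seed(54)
  d <- gen_descriptor_data(n_compounds = 60, n_descriptors = 15,
                           n_informative = 3, beta = 2, sigma = 0.3,
                           seed = 54)
  builder <- pls_builder(ncomp = 3)
  real <- builder(d$X, d$y)
  shuf <- y_randomization(d$X, d$y, builder, n_iter = 5, seed = 99)
  expect_gt(real$r2, 0.8)
  expect_true(all(shuf$r2 < 0.3))
  expect_true(all(shuf$q2 < real$q2))
  # identical seed gives an identical table
  expect_identical(shuf, y_randomization(d$X, d$y, builder, n_iter = 5,
                                         seed = 99))
  # the mean predictor scores zero R2 by construction
  mb <- function(X, y) list(r2 = cor(rep(mean(y), length(y)) + rnorm(length(y), 0, 1e-12), y)^2,
                            q2 = q2_loo(y, rep(mean(y), length(y))))
  z <- y_randomization(d$X, d$y, mb, n_iter = 3, seed = 1)
  expect_true(all(z$r2 < 0.2))
})

test_that("mean effects normalize to one and match direct substitution", {
  set.seed(55)
  X <- matrix(runif(60, 1, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(20, 0, 0.1)
  fit <- qsar_mlr(X, y)
  mf <- mean_effect(fit, X)
  expect_equal(sum(mf), 1, tolerance = 1e-9)

  # two descriptors, beta = (1, 1), column sums (3, 1) -> MF = (0.75, 0.25)
  toy <- structure(list(coefficients = c(`(Intercept)` = 0, a = 1, b = 1),
                        descriptors = c("a", "b")),
                   class = c("qsar_mlr", "qsar_model"))
  Xt <- matrix(c(1.5, 1.5, 0.5, 0.5), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(mean_effect(toy, Xt)), c(0.75, 0.25))

  # single-descriptor model normalizes to exactly 1
  f1 <- qsar_mlr(X[, "a", drop = FALSE], y)
  expect_equal(unname(mean_effect(f1, X)), 1)
})

test_that("the full validation report is internally consistent", {
  set.seed(56)
  d <- gen_descriptor_data(n_compounds = 80, n_descriptors = 10,
                           n_informative = 3, beta = 1.5, sigma = 0.3,
                           seed = 56)
  sp <- kennard_stone(d$X, 60)
  Xtr <- d$X[sp$train, ]; Xte <- d$X[sp$test, ]
  ytr <- d$y[sp$train]; yte <- d$y[sp$test]
  fit <- qsar_pls(Xtr, ytr, 4)
  rep <- validation_report(fit, Xtr, ytr, Xte, yte)
  expect_equal(rep$rmsep, rmse(yte, predict(fit, Xte)), tolerance = 1e-12)
  expect_equal(rep$q2_ext, q2_external(yte, predict(fit, Xte), mean(ytr)),
               tolerance = 1e-12)
  expect_gt(rep$r2_train, 0.6)
  expect_s3_class(rep$tropsha, "tropsha")
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_csv(rep, path)
  back <- read.csv(path)
  expect_equal(back$value[back$metric == "rmsep"], rep$rmsep,
               tolerance = 1e-6)
})
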