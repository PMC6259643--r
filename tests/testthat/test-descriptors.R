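# Autocorrelation and Burden-eigenvalue kernels, matrix assembly, prefilter.

test_that("Moran autocorrelation matches hand values and conventions", {
  path3 <- make_graph(c("C", "C", "C"),
                      data.frame(i = c(0, 1), j = c(1, 2)))
  # uniform weights: zero variance convention
  expect_equal(moran_autocorrelation(path3, c(1, 1, 1), 1), 0)
  # hand evaluation: deviations (-1, 0, 1); both lag-1 products are 0
  expect_equal(moran_autocorrelation(path3, c(1, 2, 3), 1), 0)
  # lag beyond diameter
  expect_equal(moran_autocorrelation(path3, c(1, 2, 3), 5), 0)
  expect_error(moran_autocorrelation(path3, c(1, 2, 3), 0), "lag")
})

test_that("Geary autocorrelation matches the 2-atom closed form", {
  pair <- make_graph(c("C", "C"), data.frame(i = 0, j = 1))
  # hand evaluation: ordered pairs at lag 1: (1,2) and (2,1), Delta = 2;
  # numerator (2*2)^-1 * ((1-3)^2 + (3-1)^2) = 8/4 = 2;
  # denominator (2-1)^-1 * ((1-2)^2 + (3-2)^2) = 2; c = 1
  expect_equal(geary_autocorrelation(pair, c(1, 3), 1), 1)
  expect_equal(geary_autocorrelation(pair, c(2, 2), 1), 0)
})

test_that("Broto-Moreau autocorrelation counts weighted adjacent pairs", {
  path3 <- make_graph(c("C", "C", "C"),
                      data.frame(i = c(0, 1), j = c(1, 2)))
  expect_equal(broto_moreau_autocorrelation(path3, c(1, 1, 1), 1), 2)
  expect_equal(broto_moreau_autocorrelation(path3, c(1, 1, 1), 9), 0)
})

test_that("autocorrelation kernels match brute-force oracles on random graphs", {
  set.seed(202)
  for (t in 1:200) {
    n <- sample(2:12, 1)
    g <- random_tree_graph(n, ring = t %% 3 == 0)
    D <- topological_distances(g)
    w <- runif(n, 0.5, 3)
    lag <- sample(1:5, 1)
    expect_equal(moran_autocorrelation(g, w, lag, D),
                 oracle_moran(D, w, lag), tolerance = 1e-12)
    expect_equal(geary_autocorrelation(g, w, lag, D),
                 oracle_geary(D, w, lag), tolerance = 1e-12)
    expect_equal(broto_moreau_autocorrelation(g, w, lag, D),
                 oracle_ats(D, w, lag), tolerance = 1e-12)
  }
})

test_that("descriptors are invariant under atom relabelling", {
  set.seed(77)
  for (t in 1:20) {
    n <- sample(4:10, 1)
    g <- random_tree_graph(n)
    w <- runif(n, 0.5, 3)
    D <- topological_distances(g)
    perm <- sample(n)
    # relabel: atom k becomes perm[k]
    gp <- g
    gp$atoms <- g$atoms[order(perm), , drop = FALSE]
    rownames(gp$atoms) <- NULL
    gp$bonds$i <- perm[g$bonds$i + 1L] - 1L
    gp$bonds$j <- perm[g$bonds$j + 1L] - 1L
    wp <- w[order(perm)]
    Dp <- topological_distances(gp)
    for (lag in 1:3) {
      expect_equal(moran_autocorrelation(g, w, lag, D),
                   moran_autocorrelation(gp, wp, lag, Dp), tolerance = 1e-12)
      expect_equal(broto_moreau_autocorrelation(g, w, lag, D),
                   broto_moreau_autocorrelation(gp, wp, lag, Dp),
                   tolerance = 1e-12)
    }
    expect_equal(burden_eigenvalues(g, w, 1), burden_eigenvalues(gp, wp, 1),
                 tolerance = 1e-10)
  }
})

test_that("Burden eigenvalues obey closed forms and the trace identity", {
  single <- make_graph("C")
  expect_equal(burden_eigenvalues(single, 2.5, 1), 2.5)

  pair <- make_graph(c("C", "C"), data.frame(i = 0, j = 1))
  expect_equal(burden_eigenvalues(pair, c(1, 1), 1), 1.1)
  expect_equal(burden_eigenvalues(pair, c(1, 1), 2), 0.9)
  expect_error(burden_eigenvalues(pair, c(1, 1), 3), "out of range")

  set.seed(303)
  for (t in 1:20) {
    n <- sample(2:10, 1)
    g <- random_tree_graph(n, ring = TRUE)
    w <- runif(n, 0.5, 2)
    ev <- vapply(seq_len(n), function(k) burden_eigenvalues(g, w, k),
                 numeric(1))
    expect_equal(sum(ev), sum(w), tolerance = 1e-10)  # trace identity
    expect_true(all(diff(ev) <= 1e-12))               # BEH monotonicity
  }
})

test_that("aromatic bonds enter the Burden matrix with order 1.5", {
  bz <- parse_smiles("c1ccccc1", "benzene")
  B <- burden_matrix(bz, rep(1, 6))
  bonded <- B[cbind(bz$bonds$i + 1L, bz$bonds$j + 1L)]
  expect_equal(bonded, rep(0.1 * 1.5, 6))
  expect_true(all(B[1, setdiff(1:6, c(1, 2, 6))] == 0.001))
})

test_that("descriptor matrix assembly follows the naming grammar", {
  mols <- list(parse_smiles("CCO", "a"), parse_smiles("c1ccccc1C", "b"))
  spec <- c("MATS2m", "GATS8p", "MATS5v", "BEHp2")
  X <- compute_descriptor_matrix(mols, spec)
  expect_equal(colnames(X), spec)
  expect_equal(rownames(X), c("a", "b"))
  expect_equal(attr(X, "provenance"), "computed")

  expect_error(compute_descriptor_matrix(list(), spec), "empty")
  expect_error(compute_descriptor_matrix(mols, c("nAT", "nAT")), "duplicate")
  expect_error(compute_descriptor_matrix(mols, "RDF030m"), "CSV")
  expect_error(parse_descriptor_name("MATS0m"), "lag")
})

test_that("constitutional counts are correct", {
  g <- parse_smiles("OC(=O)c1ccc(Cl)cc1", "acid")
  X <- compute_descriptor_matrix(list(g),
                                 c("nAT", "nBT", "nC", "nO", "nX", "nCIC"))
  expect_equal(unname(X[1, ]), c(10, 10, 7, 2, 1, 1))
})

test_that("prefilter removes constants and correlated columns deterministically", {
  set.seed(9)
  n <- 60
  base <- rnorm(n)
  X <- cbind(a = base, b = rnorm(n), const = rep(2, n), dup = base)
  out <- prefilter(X)
  expect_equal(colnames(out$X), c("a", "b"))
  expect_equal(out$removed$name, c("const", "dup"))
  expect_equal(out$removed$reason, c("near_constant", "correlated"))
  expect_equal(out$removed$partner[2], "a")

  # correlation right at the boundary: r ~ 0.96 via Cholesky mixing
  r <- 0.96
  z <- rnorm(n)
  v <- r * scale(base)[, 1] + sqrt(1 - r^2) * scale(z)[, 1]
  Xc <- cbind(x1 = scale(base)[, 1], x2 = v)
  rr <- abs(cor(Xc))[1, 2]
  kept95 <- prefilter(Xc, corr_cutoff = 0.95)$X
  kept99 <- prefilter(Xc, corr_cutoff = 0.99)$X
  if (rr > 0.95) expect_equal(ncol(kept95), 1) else expect_equal(ncol(kept95), 2)
  expect_equal(ncol(kept99), 2)

  # idempotence
  again <- prefilter(out$X)
  expect_equal(again$X, out$X)
  expect_equal(nrow(again$removed), 0)

  expect_error(prefilter(matrix(1, 5, 2)), "all columns")
})

test_that("descriptor CSVs round-trip at full precision", {
  X <- matrix(c(pi, exp(1), sqrt(2), 1 / 3), 2, 2,
              dimnames = list(c("m1", "m2"), c("MATS2m", "BEHp2")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(X, path)
  X2 <- read_descriptor_csv(path)
  expect_equal(unclass(X2), unclass(X), ignore_attr = TRUE,
               tolerance = 1e-15)
  expect_equal(attr(X2, "provenance"), "imported")
})
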