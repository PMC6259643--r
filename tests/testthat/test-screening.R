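# Candidate enumeration by scaffold substitution and AD-filtered screening.

spec_text <- c(
  "# diphenyl scaffold with two substitution sites",
  "[scaffold]",
  "c1cc([*:1])ccc1Nc1ccc([*:2])cc1",
  "[site 1]",
  "H -",
  "Br Br",
  "Me C",
  "[site 2]",
  "H -",
  "Cl Cl",
  "OMe OC",
  "Et CC",
  "[mode]",
  "cross-product")

test_that("cross-product enumeration yields the full combination grid", {
  path <- withr::local_tempfile(fileext = ".spec")
  writeLines(spec_text, path)
  spec <- read_substitution_spec(path)
  cand <- enumerate_candidates(spec)
  expect_length(cand$molecules, 3 * 4)
  expect_equal(nrow(cand$rejected), 0)
  expect_true(all(grepl("_", names(cand$molecules))))
  # hydrogen sites really remove the branch
  hh <- cand$smiles[["H_H"]]
  expect_false(grepl("*", hh, fixed = TRUE))
})

test_that("explicit pair lists reproduce a fixed candidate series", {
  # eleven X/Y pairs on a two-site ring, as in a staged screening campaign
  pairs <- list(c("H", "Cl"), c("H", "OMe"), c("H", "Et"), c("Br", "H"),
                c("Br", "Cl"), c("Br", "OMe"), c("Br", "Et"), c("Me", "Cl"),
                c("Me", "OMe"), c("Me", "Et"), c("H", "H"))
  spec <- substitution_spec(
    "c1cc([*:1])ccc1Nc1ccc([*:2])cc1",
    sites = list(`1` = c(H = "-", Br = "Br", Me = "C"),
                 `2` = c(H = "-", Cl = "Cl", OMe = "OC", Et = "CC")),
    mode = "explicit", pairs = pairs)
  cand <- enumerate_candidates(spec)
  expect_length(cand$molecules, 11)
  expect_equal(names(cand$molecules)[1], "H_Cl")
  # unknown substituent names are reported, not silently mis-indexed
  spec_bad <- spec; spec_bad$pairs <- list(c("H", "Zz"))
  expect_error(enumerate_candidates(spec_bad), "unknown substituent")
})

test_that("specification validation catches structural mistakes", {
  expect_error(substitution_spec("c1ccccc1", list(`1` = c(H = "-"))),
               "attachment")
  expect_error(substitution_spec("c1cc([*:1])ccc1", list()), "match")
  expect_error(substitution_spec("c1cc([*:1])ccc1",
                                 list(`1` = character(0))), "empty")
})

test_that("invalid grafts are rejected with a logged reason", {
  spec <- substitution_spec("C([*:1])", list(`1` = c(ok = "O", bad = ")(")))
  cand <- enumerate_candidates(spec)
  expect_length(cand$molecules, 1)
  expect_equal(cand$rejected$id, "bad")
  expect_match(cand$rejected$reason, "SMILES")
})

test_that("screening ranks by prediction, flags by leverage, and is order-invariant", {
  set.seed(71)
  gen <- gen_molecules(n = 25, size_range = c(6, 14), seed = 71)
  spec_names <- c("MATS1m", "MATS2m", "GATS1e", "BEHm1", "BEHm2", "nAT",
                  "MW", "nBT")
  X <- compute_descriptor_matrix(gen$molecules, spec_names)
  X <- prefilter(X)$X
  # planted linear model on computed descriptors, tiny noise
  b_true <- seq_len(ncol(X)) / ncol(X)
  y <- drop(scale(X) %*% b_true) + rnorm(25, 0, 0.01)
  names(y) <- rownames(X)
  fit <- qsar_mlr(X, y)
  # candidates = a fresh batch from the same generator family
  cand_gen <- gen_molecules(n = 10, size_range = c(6, 14), seed = 72)
  scr <- screen_candidates(cand_gen, fit, X, space = "descriptor")
  expect_s3_class(scr, "screening_result")
  expect_equal(nrow(scr), 10)
  # ranking covers exactly the in-domain candidates, best first
  ranked <- scr[!is.na(scr$rank), ]
  expect_true(all(ranked$in_domain))
  expect_true(all(diff(ranked$predicted_pic50[order(ranked$rank)]) <= 1e-12))
  expect_true(all(is.na(scr$rank[!scr$in_domain])))

  # permutation invariance of scores and flags
  perm <- sample(length(cand_gen$molecules))
  scr2 <- screen_candidates(list(molecules = cand_gen$molecules[perm],
                                 smiles = cand_gen$smiles[perm]),
                            fit, X, space = "descriptor")
  m <- match(scr$candidate_id, scr2$candidate_id)
  expect_equal(scr2$predicted_pic50[m], scr$predicted_pic50)
  expect_equal(scr2$in_domain[m], scr$in_domain)
})

test_that("a candidate identical to a training compound reproduces its fit", {
  set.seed(73)
  gen <- gen_molecules(n = 15, size_range = c(5, 12), seed = 73)
  spec_names <- c("MATS1m", "BEHm1", "nAT", "MW")
  X <- compute_descriptor_matrix(gen$molecules, spec_names)
  X <- prefilter(X)$X
  y <- drop(scale(X) %*% rep(1, ncol(X))) + rnorm(15, 0, 0.05)
  fit <- qsar_mlr(X, y)
  first <- gen$molecules[[1]]
  scr <- screen_candidates(list(molecules = stats::setNames(list(first),
                                                            first$id),
                                smiles = gen$smiles[1]),
                           fit, X, space = "descriptor")
  expect_equal(scr$predicted_pic50, unname(fit$fitted[1]), tolerance = 1e-10)
  Xs <- autoscale(X[, fit$descriptors, drop = FALSE])
  expect_equal(scr$leverage, unname(leverage(Xs)[1]), tolerance = 1e-10)
})
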