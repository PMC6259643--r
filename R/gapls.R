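# Genetic-algorithm descriptor selection wrapped around PLS. Chromosomes are
# binary inclusion vectors over descriptor columns; fitness is a
# cross-validated PLS prediction score. The defaults reproduce the published
# configuration of the method: population 64, per-bit mutation rate 0.003,
# random-subset cross-validation with 4 subsets, 20% initial term density,
# at most 100 generations, double (two-point) crossover, convergence when
# 80% of the population shares the best fitness.

#' GA configuration for descriptor selection
#'
#' @param pop_size population size (must be even).
#' @param mutation_rate per-bit mutation probability.
#' @param max_generations generation cap.
#' @param initial_term_frac probability that a bit is set in the initial
#'   population.
#' @param crossover `"double"` (two-point) or `"single"`.
#' @param convergence fraction of the population sharing the best fitness at
#'   which evolution stops early.
#' @param n_subsets number of random cross-validation subsets used inside the
#'   fitness function (re-randomized each generation).
#' @param window_width carried for configuration completeness; the mutation
#'   operator here is plain per-bit flipping, so this knob is documentation
#'   only (see the methods vignette).
#' @param max_lv cap on latent variables tried inside a fitness evaluation;
#'   the LV count actually used is chosen by inner RMSECV.
#' @param elitism number of best chromosomes copied unchanged (1 gives the
#'   monotone best-fitness guarantee).
#' @return list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 64, mutation_rate = 0.003,
                       max_generations = 100, initial_term_frac = 0.2,
                       crossover = c("double", "single"), convergence = 0.8,
                       n_subsets = 4, window_width = 2, max_lv = 10,
                       elitism = 1) {
  crossover <- match.arg(crossover)
  stopifnot(pop_size %% 2 == 0, mutation_rate >= 0, mutation_rate <= 1,
            initial_term_frac > 0, initial_term_frac <= 1,
            convergence > 0, convergence <= 1)
  structure(list(pop_size = pop_size, mutation_rate = mutation_rate,
                 max_generations = max_generations,
                 initial_term_frac = initial_term_frac,
                 crossover = crossover, convergence = convergence,
                 n_subsets = n_subsets, window_width = window_width,
                 max_lv = max_lv, elitism = elitism),
            class = "ga_control")
}

#' GA fitness of a descriptor subset
#'
#' Cross-validated PLS prediction score
#' \deqn{100 - \frac{\sum_i (y_i-\hat y_i)^2 / n}{\sum_i (y_i-\bar y)^2 / k}
#'       \times 100, \qquad k = n - 1,}
#' where the \eqn{\hat y_i} are out-of-fold cross-validation predictions.
#' Equivalently \eqn{100\,[1 - \frac{n-1}{n}\,SSE_{cv}/SS_y]}; perfect CV
#' prediction scores 100, the constant mean predictor scores
#' \eqn{100/n}, and worse-than-mean prediction goes negative. An empty
#' chromosome returns `-Inf` and is never selected.
#'
#' @param chrom logical/0-1 inclusion vector over the columns of `X`.
#' @param X autoscaled, prefiltered descriptor matrix.
#' @param y activity vector.
#' @param folds fold labels or a fold count (see [pls_cv_predict()]).
#' @param max_lv latent-variable cap; the LV count is picked by the RMSECV
#'   minimum over 1..min(max_lv, #bits).
#' @return list with `fitness`, `ncomp`, `rmsecv` (at the chosen LV count).
#' @export
ga_fitness <- function(chrom, X, y, folds, max_lv = 10) {
  k <- sum(chrom)
  if (k == 0) return(list(fitness = -Inf, ncomp = 0L, rmsecv = Inf))
  Xs <- X[, as.logical(chrom), drop = FALSE]
  nc <- min(max_lv, k)
  pred <- pls_cv_predict(Xs, y, nc, folds = folds, scale = FALSE)
  sse <- colSums((pred - y)^2)
  best <- which.min(sse)
  n <- length(y)
  ssy <- sum((y - mean(y))^2)
  fit <- 100 - (sse[best] / n) / (ssy / (n - 1)) * 100
  list(fitness = unname(fit), ncomp = as.integer(best),
       rmsecv = sqrt(sse[best] / n))
}

#' Initialize a GA population
#'
#' Each bit is set independently with probability `initial_term_frac`;
#' chromosomes that come out empty are redrawn.
#'
#' @param control a [ga_control()].
#' @param n_descriptors chromosome length.
#' @return `pop_size` x `n_descriptors` 0/1 integer matrix.
#' @export
ga_initialize <- function(control, n_descriptors) {
  pop <- matrix(as.integer(stats::runif(control$pop_size * n_descriptors) <
                           control$initial_term_frac),
                control$pop_size, n_descriptors)
  for (r in which(rowSums(pop) == 0))
    while (sum(pop[r, ]) == 0)
      pop[r, ] <- as.integer(stats::runif(n_descriptors) <
                             control$initial_term_frac)
  pop
}

.ga_select_parents <- function(fitness, n_pairs) {
  f <- fitness
  w <- if (any(!is.finite(f)) || min(f) <= 0) rank(f) else f
  idx <- sample(length(f), 2 * n_pairs, replace = TRUE, prob = w / sum(w))
  matrix(idx, ncol = 2)
}

.ga_crossover <- function(a, b, kind) {
  n <- length(a)
  if (n < 2) return(rbind(a, b))
  if (kind == "double" && n >= 3) {
    pts <- sort(sample(seq_len(n - 1), 2))
    seg <- seq.int(pts[1] + 1, pts[2])
  } else {
    pt <- sample(seq_len(n - 1), 1)
    seg <- seq.int(pt + 1, n)
  }
  c1 <- a; c2 <- b
  if (length(seg)) { c1[seg] <- b[seg]; c2[seg] <- a[seg] }
  rbind(c1, c2)
}

#' Genetic-algorithm descriptor selection around PLS
#'
#' Generational GA: fitness-proportional (roulette) selection with a
#' rank-based fallback when fitnesses are non-positive, single/double-point
#' crossover, per-bit mutation, elitism of the best chromosome, and an early
#' stop when the configured fraction of the population reaches the best
#' fitness. Cross-validation subsets inside the fitness function are
#' re-randomized each generation. The best chromosome is refit as a PLS model
#' with a CV-chosen latent-variable count.
#'
#' @param X prefiltered descriptor matrix (raw scale; autoscaling is applied
#'   internally, the conventional preprocessing for GA-PLS).
#' @param y activity vector.
#' @param control a [ga_control()].
#' @param seed integer RNG seed; omit for a randomly drawn (and reported)
#'   seed.
#' @param scale autoscale descriptor columns before the GA (default TRUE;
#'   harmless on an already-autoscaled matrix). The returned model always
#'   predicts from raw descriptor values.
#' @return object of class `c("qsar_gapls", "qsar_model")` with the refit
#'   `model` (a `qsar_pls` on the selected columns), `chromosome`, `selected`
#'   (descriptor names), `history` (per generation: best/mean fitness, bits
#'   of the best), `fitness`, `control`, `seed`. Prediction, coefficients and
#'   residuals delegate to the refit PLS model.
#' @export
qsar_gapls <- function(X, y, control = ga_control(), seed = NULL,
                       scale = TRUE) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("qsar_gapls: using generated seed ", seed)
  }
  set.seed(seed)
  X <- as.matrix(X)
  Xga <- if (scale) autoscale(X) else X
  n <- nrow(X); p <- ncol(X)
  pop <- ga_initialize(control, p)
  history <- data.frame(generation = integer(), best = numeric(),
                        mean = numeric(), bits_best = integer())
  best_chrom <- NULL; best_fit <- -Inf
  fit_cache <- new.env(hash = TRUE, parent = emptyenv())
  for (gen in seq_len(control$max_generations)) {
    folds <- sample(rep_len(seq_len(control$n_subsets), n))
    fits <- numeric(control$pop_size)
    for (r in seq_len(control$pop_size)) {
      key <- paste(pop[r, ], collapse = "")
      hit <- get0(key, envir = fit_cache)
      if (is.null(hit)) {
        hit <- ga_fitness(pop[r, ], Xga, y, folds, control$max_lv)$fitness
        assign(key, hit, envir = fit_cache)
      }
      fits[r] <- hit
    }
    gi <- which.max(fits)
    if (fits[gi] > best_fit) { best_fit <- fits[gi]; best_chrom <- pop[gi, ] }
    history[nrow(history) + 1L, ] <-
      list(gen, best_fit, mean(fits[is.finite(fits)]), sum(best_chrom))
    share <- mean(fits >= best_fit - 1e-9)
    if (share >= control$convergence) break
    if (gen == control$max_generations) break
    # next generation
    n_children <- control$pop_size - control$elitism
    parents <- .ga_select_parents(fits, ceiling(n_children / 2))
    children <- matrix(0L, 0, p)
    for (pr in seq_len(nrow(parents))) {
      off <- .ga_crossover(pop[parents[pr, 1], ], pop[parents[pr, 2], ],
                           control$crossover)
      children <- rbind(children, off)
    }
    children <- children[seq_len(n_children), , drop = FALSE]
    if (control$mutation_rate > 0) {
      flip <- matrix(stats::runif(length(children)) < control$mutation_rate,
                     nrow(children), p)
      children[flip] <- 1L - children[flip]
    }
    for (r in which(rowSums(children) == 0)) {
      children[r, sample(p, 1)] <- 1L
    }
    elite <- pop[order(fits, decreasing = TRUE)[seq_len(control$elitism)], ,
                 drop = FALSE]
    pop <- rbind(elite, children)
    # fitness cache is per-CV-split; clear since folds change per generation
    rm(list = ls(envir = fit_cache), envir = fit_cache)
  }
  sel <- colnames(X)[as.logical(best_chrom)]
  Xsel <- Xga[, sel, drop = FALSE]
  lv <- select_lv(Xsel, y,
                  max_lv = min(control$max_lv, length(sel),
                               qr(base::scale(Xsel, scale = FALSE))$rank),
                  folds = sample(rep_len(seq_len(control$n_subsets), n)),
                  scale = FALSE)
  # refit on the raw columns so prediction is affine in raw descriptors
  model <- qsar_pls(X[, sel, drop = FALSE], y, lv$ncomp, scale = scale)
  structure(list(
    kind = "GA-PLS",
    model = model,
    coefficients = model$coefficients,
    descriptors = model$descriptors,
    weights = model$weights, loadings = model$loadings,
    center = model$center, scale = model$scale, y_mean = model$y_mean,
    ncomp = model$ncomp,
    fitted = model$fitted,
    residuals = model$residuals,
    r_squared = model$r_squared,
    chromosome = best_chrom,
    selected = sel,
    fitness = best_fit,
    history = history,
    rmsecv = lv$rmsecv,
    control = control,
    seed = seed,
    n = n, p = length(sel)),
    class = c("qsar_gapls", "qsar_model"))
}

#' @export
print.qsar_gapls <- function(x, ...) {
  cat("GA-PLS model: selected", length(x$selected), "of",
      length(x$chromosome), "descriptors in",
      nrow(x$history), "generation(s)\n")
  cat("  best fitness =", format(x$fitness, digits = 4),
      "| LVs =", x$ncomp,
      "| R2 =", format(x$r_squared, digits = 4), "\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
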