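# Synthetic-data generators. These give every pipeline stage inputs with the
# statistical structure the analysis assumes - descriptor matrices whose
# activity is a sparse linear function of a known descriptor subset plus
# Gaussian noise, with factor-induced collinearity emulating real descriptor
# blocks - and valence-respecting random molecular graphs for the structural
# stages. Truth (support, coefficients) is returned for recovery scoring.

#' Generate a synthetic descriptor/activity data set with planted signal
#'
#' Descriptor columns are built by mixing shared latent factors with
#' independent noise, so that columns loading on the same factor correlate at
#' about `corr` (the collinearity that motivates PLS and GA selection).
#' Activity is a sparse linear function of `n_informative` randomly chosen
#' columns plus Gaussian noise:
#' \eqn{y = X_{S}\beta + \epsilon,\ \epsilon \sim N(0, \sigma^2)}.
#'
#' @param n_compounds number of rows.
#' @param n_descriptors number of columns.
#' @param n_informative size of the true support.
#' @param beta coefficient magnitude (scalar, or vector of length
#'   `n_informative`).
#' @param sigma activity noise SD.
#' @param corr pairwise correlation level induced within factor blocks,
#'   in [0, 1).
#' @param seed integer RNG seed (mandatory: generators are pure functions of
#'   their spec).
#' @return list with `X` (matrix, columns `D001`... and rows `c001`...),
#'   `y`, `support` (informative column names), `beta` (named), `sigma`,
#'   `seed`.
#' @export
gen_descriptor_data <- function(n_compounds = 120, n_descriptors = 50,
                                n_informative = 5, beta = 2, sigma = 0.3,
                                corr = 0.3, seed) {
  stopifnot(n_informative <= n_descriptors, sigma >= 0,
            corr >= 0, corr < 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n_factors <- max(2L, round(n_descriptors / 10))
  Fm <- matrix(stats::rnorm(n_compounds * n_factors), n_compounds)
  assign_f <- sample(n_factors, n_descriptors, replace = TRUE)
  X <- sqrt(corr) * Fm[, assign_f] +
    sqrt(1 - corr) * matrix(stats::rnorm(n_compounds * n_descriptors),
                            n_compounds)
  colnames(X) <- sprintf("D%03d", seq_len(n_descriptors))
  rownames(X) <- sprintf("c%03d", seq_len(n_compounds))
  support <- sort(sample(colnames(X), n_informative))
  b <- rep_len(beta, n_informative)
  names(b) <- support
  y <- drop(X[, support, drop = FALSE] %*% b) +
    stats::rnorm(n_compounds, 0, sigma)
  names(y) <- rownames(X)
  list(X = X, y = y, support = support, beta = b, sigma = sigma, seed = seed)
}

.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L)

#' Generate random valence-respecting molecules
#'
#' Grows random trees over heavy atoms (single bonds), optionally closing one
#' ring per molecule, and writes each graph as SMILES. Element draws follow
#' `element_weights`; a halogen is replaced by carbon whenever picking it
#' would leave no free valence to finish growing. Deterministic per seed.
#'
#' @param n number of molecules.
#' @param size_range integer vector `c(min, max)` heavy-atom count.
#' @param element_weights named sampling weights over C, N, O, S, F, Cl, Br.
#' @param ring_prob probability of attempting one ring closure.
#' @param seed integer RNG seed (mandatory).
#' @return list with `molecules` (named list of `molgraph`, ids `m001`...)
#'   and `smiles` (named character vector).
#' @export
gen_molecules <- function(n = 20, size_range = c(5, 30),
                          element_weights = c(C = 10, N = 2, O = 2, S = 1,
                                              F = 1, Cl = 1, Br = 1),
                          ring_prob = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(size_range[1] >= 2, size_range[2] >= size_range[1])
  set.seed(seed)
  els <- names(element_weights)
  stopifnot(all(els %in% names(.VALENCE)))
  mols <- list(); smi <- character()
  for (m in seq_len(n)) {
    size <- if (size_range[1] == size_range[2]) size_range[1]
            else sample(seq.int(size_range[1], size_range[2]), 1)
    el <- character(size)
    free <- integer(size)
    edges <- matrix(integer(), 0, 2)
    el[1] <- "C"  # root always carbon so growth can never stall
    free[1] <- .VALENCE[el[1]]
    for (a in seq.int(2, size)) {
      cand <- which(free[seq_len(a - 1)] > 0)
      at <- if (length(cand) == 1) cand else sample(cand, 1)
      e <- sample(els, 1, prob = element_weights)
      # don't let a terminal atom strand the growth
      if (a < size && sum(free[seq_len(a - 1)]) - 1 + .VALENCE[e] - 1 < 1)
        e <- "C"
      el[a] <- e
      free[a] <- .VALENCE[e] - 1L
      free[at] <- free[at] - 1L
      edges <- rbind(edges, c(at, a))
    }
    g <- structure(list(
      atoms = data.frame(element = el, charge = 0L,
                         stringsAsFactors = FALSE),
      bonds = data.frame(i = edges[, 1] - 1L, j = edges[, 2] - 1L,
                         order = 1, aromatic = FALSE),
      id = sprintf("m%03d", m)), class = "molgraph")
    if (stats::runif(1) < ring_prob) {
      D <- topological_distances(g)
      open <- which(free > 0)
      if (length(open) >= 2) {
        prs <- which(D[open, open, drop = FALSE] >= 2, arr.ind = TRUE)
        prs <- prs[prs[, 1] < prs[, 2], , drop = FALSE]
        if (nrow(prs)) {
          pk <- prs[sample(nrow(prs), 1), ]
          i <- open[pk[1]]; j <- open[pk[2]]
          g$bonds <- rbind(g$bonds,
                           data.frame(i = i - 1L, j = j - 1L, order = 1,
                                      aromatic = FALSE))
        }
      }
    }
    mols[[g$id]] <- g
    smi[g$id] <- write_smiles(g)
  }
  list(molecules = mols, smiles = smi)
}

#' Write a molecular graph as SMILES
#'
#' Depth-first spanning-tree writer with ring-closure digits; covers
#' single/double/triple bonds and neutral organic-subset atoms, which is all
#' the synthetic generator produces.
#'
#' @param g a connected `molgraph`.
#' @return SMILES string.
#' @export
write_smiles <- function(g) {
  n <- n_atoms(g)
  el <- g$atoms$element
  bsym <- c(`1` = "", `2` = "=", `3` = "#")
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b] + 1L; j <- g$bonds$j[b] + 1L
    o <- as.character(g$bonds$order[b])
    adj[[i]] <- c(adj[[i]], list(list(to = j, sym = bsym[[o]])))
    adj[[j]] <- c(adj[[j]], list(list(to = i, sym = bsym[[o]])))
  }
  visited <- rep(FALSE, n)
  closures <- vector("list", n)  # per atom: list of (digit, bond symbol)
  next_digit <- 0L
  order_seen <- integer(0)
  # first pass: find DFS tree and ring-closure bonds (iterative DFS)
  parent <- rep(NA_integer_, n)
  stack <- 1L; visited[1] <- TRUE
  closed <- matrix(integer(), 0, 2)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_seen <- c(order_seen, v)
    for (nb in adj[[v]]) {
      u <- nb$to
      if (!visited[u]) {
        visited[u] <- TRUE; parent[u] <- v; stack <- c(stack, u)
      }
    }
  }
  if (!all(visited)) stop("cannot write SMILES of a disconnected graph")
  tree_edge <- function(a, b) (!is.na(parent[b]) && parent[b] == a) ||
                              (!is.na(parent[a]) && parent[a] == b)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b] + 1L; j <- g$bonds$j[b] + 1L
    if (!tree_edge(i, j)) {
      next_digit <- next_digit + 1L
      if (next_digit > 9) stop("more than 9 ring closures unsupported")
      o <- as.character(g$bonds$order[b])
      closures[[i]] <- c(closures[[i]],
                         list(list(d = next_digit, sym = bsym[[o]])))
      closures[[j]] <- c(closures[[j]], list(list(d = next_digit, sym = "")))
    }
  }
  atom_token <- function(v) {
    tok <- el[v]
    for (cl in closures[[v]]) tok <- paste0(tok, cl$sym, cl$d)
    tok
  }
  emit <- function(v, from) {
    out <- atom_token(v)
    kids <- Filter(function(nb) !is.na(parent[nb$to]) &&
                     parent[nb$to] == v, adj[[v]])
    # deduplicate (parallel adjacency entries cannot occur; keep order)
    seen <- integer(0)
    kids <- Filter(function(nb) {
      if (nb$to %in% seen) FALSE else { seen <<- c(seen, nb$to); TRUE }
    }, kids)
    nk <- length(kids)
    for (ki in seq_along(kids)) {
      sub <- paste0(kids[[ki]]$sym, emit(kids[[ki]]$to, v))
      out <- paste0(out, if (ki < nk) paste0("(", sub, ")") else sub)
    }
    out
  }
  emit(1L, NA_integer_)
}
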