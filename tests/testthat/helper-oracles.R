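# Independent brute-force oracles and graph builders used across the suite.
# Oracles are deliberately written as naive double loops, independent of the
# package's vectorized kernels.

# Build a molgraph directly (no SMILES round trip): atoms is a character
# vector of elements, bonds a data frame with 0-based i, j and optional
# order/aromatic.
make_graph <- function(atoms, bonds = NULL, id = "g") {
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                        aromatic = logical())
  if (is.null(bonds$order)) bonds$order <- 1
  if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
  structure(list(atoms = data.frame(element = atoms, charge = 0L,
                                    stringsAsFactors = FALSE),
                 bonds = bonds, id = id),
            class = "molgraph")
}

# Random connected tree (plus optional extra ring edge) on n atoms.
random_tree_graph <- function(n, elements = c("C", "N", "O"),
                              ring = FALSE) {
  atoms <- sample(elements, n, replace = TRUE)
  bonds <- if (n > 1)
    data.frame(i = vapply(seq.int(2, n),
                          function(a) sample.int(a - 1, 1), integer(1)) - 1L,
               j = seq.int(2, n) - 1L)
  else data.frame(i = integer(), j = integer())
  g <- make_graph(atoms, bonds)
  if (ring && n >= 4) {
    D <- topological_distances(g)
    prs <- which(D >= 3, arr.ind = TRUE)
    prs <- prs[prs[, 1] < prs[, 2], , drop = FALSE]
    if (nrow(prs)) {
      pk <- prs[sample(nrow(prs), 1), ]
      g$bonds <- rbind(g$bonds, data.frame(i = pk[1] - 1L, j = pk[2] - 1L,
                                           order = 1, aromatic = FALSE))
    }
  }
  g
}

# Floyd-Warshall all-pairs shortest paths oracle.
floyd_warshall <- function(g) {
  n <- nrow(g$atoms)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b] + 1L; j <- g$bonds$j[b] + 1L
    D[i, j] <- D[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Naive pair-enumeration autocorrelation oracles.
oracle_moran <- function(D, w, lag) {
  n <- length(w); wb <- mean(w)
  num <- 0; cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && D[i, j] == lag) {
      num <- num + (w[i] - wb) * (w[j] - wb); cnt <- cnt + 1
    }
  den <- sum((w - wb)^2) / n
  if (cnt == 0 || den == 0) return(0)
  (num / cnt) / den
}

oracle_geary <- function(D, w, lag) {
  n <- length(w); wb <- mean(w)
  num <- 0; cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && D[i, j] == lag) {
      num <- num + (w[i] - w[j])^2; cnt <- cnt + 1
    }
  den <- sum((w - wb)^2) / (n - 1)
  if (cnt == 0 || den == 0) return(0)
  (num / (2 * cnt)) / den
}

oracle_ats <- function(D, w, lag) {
  n <- length(w); s <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    if (D[i, j] == lag) s <- s + w[i] * w[j]
  s
}

# Normal-equations OLS oracle.
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  drop(solve(crossprod(Xi), crossprod(Xi, y)))
}

# Kennard-Stone maximin property checker: every selected point after the
# seed pair must attain the maximal minimum distance to the already-selected
# set (re-evaluated exhaustively).
ks_is_maximin <- function(X, split, scale = TRUE) {
  ids <- rownames(X)
  Xs <- if (scale) {
    sds <- apply(X, 2, sd)
    base::scale(X[, sds > 0, drop = FALSE])
  } else X
  D <- as.matrix(dist(Xs))
  sel_idx <- match(split$order, ids)
  all_idx <- seq_len(nrow(X))
  for (k in seq.int(3, length(sel_idx))) {
    chosen <- sel_idx[seq_len(k - 1)]
    cand <- setdiff(all_idx, chosen)
    mind <- vapply(cand, function(c) min(D[c, chosen]), numeric(1))
    if (min(abs(D[sel_idx[k], chosen])) < max(mind) - 1e-12 &&
        min(D[sel_idx[k], chosen]) < max(mind) - 1e-12)
      return(FALSE)
  }
  TRUE
}
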