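# Topological descriptor kernels: Broto-Moreau (ATS), Moran (MATS) and Geary
# (GATS) 2D autocorrelations, Burden-matrix eigenvalues (BEH/BEL) and a few
# constitutional counts; plus the descriptor-matrix assembler and prefilter.
#
# The autocorrelation kernels operate on the topological distance matrix with
# atom weights w (carbon-scaled atomic properties). Conventions, fixed here
# and relied on throughout: a lag with no atom pair, or a zero-variance weight
# vector, yields 0 (not NaN) for MATS/GATS, so matrix assembly is total and
# constant columns are left for the prefilter to drop.

.pair_mask <- function(D, lag) D == lag

#' Moran topological autocorrelation (MATS)
#'
#' Moran's I over the molecular graph at a given topological lag:
#' \deqn{I(d) = \frac{\sum_{i,j: d_{ij}=d} (w_i-\bar w)(w_j-\bar w) / \Delta}
#'                   {\sum_i (w_i-\bar w)^2 / A}}
#' with \eqn{\Delta} the number of ordered pairs at distance d and A the atom
#' count. Returns 0 when no pair sits at the lag or the weights are constant.
#'
#' @param g a `molgraph`.
#' @param w numeric weight vector, one value per atom.
#' @param lag positive integer topological distance.
#' @param D optional precomputed distance matrix.
#' @return a finite scalar.
#' @export
moran_autocorrelation <- function(g, w, lag, D = topological_distances(g)) {
  stopifnot(length(w) == n_atoms(g))
  if (lag < 1) stop("lag must be a positive integer")
  m <- .pair_mask(D, lag)
  n_pairs <- sum(m)                      # ordered pairs (matrix is symmetric)
  dev <- w - mean(w)
  denom <- sum(dev^2) / length(w)
  if (n_pairs == 0 || denom == 0) return(0)
  num <- sum(outer(dev, dev) * m) / n_pairs
  num / denom
}

#' Geary topological autocorrelation (GATS)
#'
#' Geary's c at a topological lag:
#' \deqn{c(d) = \frac{\sum_{i,j: d_{ij}=d} (w_i-w_j)^2 / (2\Delta)}
#'                   {\sum_i (w_i-\bar w)^2 / (A-1)}}
#' Same empty-lag / zero-variance conventions as
#' [moran_autocorrelation()].
#'
#' @inheritParams moran_autocorrelation
#' @return a finite scalar (non-negative).
#' @export
geary_autocorrelation <- function(g, w, lag, D = topological_distances(g)) {
  stopifnot(length(w) == n_atoms(g))
  if (lag < 1) stop("lag must be a positive integer")
  m <- .pair_mask(D, lag)
  n_pairs <- sum(m)
  denom <- sum((w - mean(w))^2) / (length(w) - 1)
  if (n_pairs == 0 || denom == 0) return(0)
  num <- sum(outer(w, w, `-`)^2 * m) / (2 * n_pairs)
  num / denom
}

#' Broto-Moreau topological autocorrelation (ATS)
#'
#' Sum of weight products over unordered atom pairs at the lag:
#' \eqn{ATS(d) = \sum_{i<j: d_{ij}=d} w_i w_j}. Empty lag gives 0.
#'
#' @inheritParams moran_autocorrelation
#' @return a finite scalar.
#' @export
broto_moreau_autocorrelation <- function(g, w, lag,
                                         D = topological_distances(g)) {
  stopifnot(length(w) == n_atoms(g))
  if (lag < 1) stop("lag must be a positive integer")
  m <- .pair_mask(D, lag)
  sum(outer(w, w) * m) / 2
}

#' Burden matrix of a molecular graph
#'
#' The modified connectivity matrix B: diagonal entries are the atomic
#' weights; for bonded pairs the off-diagonal entry is 0.1 times the
#' conventional bond order (1, 2, 3; 1.5 for aromatic); all non-bonded pairs
#' carry 0.001.
#'
#' @inheritParams moran_autocorrelation
#' @return symmetric numeric matrix.
#' @export
burden_matrix <- function(g, w) {
  n <- n_atoms(g)
  stopifnot(length(w) == n)
  B <- matrix(0.001, n, n)
  diag(B) <- w
  if (nrow(g$bonds)) {
    ord <- ifelse(g$bonds$aromatic, 1.5, g$bonds$order)
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[b] + 1L; j <- g$bonds$j[b] + 1L
      B[i, j] <- B[j, i] <- 0.1 * ord[b]
    }
  }
  B
}

#' Burden eigenvalue descriptor (BEH / BEL)
#'
#' The k-th largest (`which = "highest"`, BEH) or k-th smallest
#' (`which = "lowest"`, BEL) eigenvalue of the Burden matrix.
#'
#' @inheritParams moran_autocorrelation
#' @param k eigenvalue rank, 1..n_atoms.
#' @param which `"highest"` or `"lowest"`.
#' @return a real eigenvalue.
#' @export
burden_eigenvalues <- function(g, w, k, which = c("highest", "lowest")) {
  which <- match.arg(which)
  n <- n_atoms(g)
  if (k < 1 || k > n) stop("eigenvalue rank k = ", k,
                           " out of range 1..", n)
  ev <- eigen(burden_matrix(g, w), symmetric = TRUE,
              only.values = TRUE)$values   # descending
  if (which == "highest") ev[k] else ev[n - k + 1L]
}

# --- constitutional counts ------------------------------------------------

.CONSTITUTIONAL <- c("nAT", "nBT", "nC", "nN", "nO", "nS", "nX", "MW", "nCIC")

.constitutional <- function(g, name, table) {
  el <- g$atoms$element
  switch(name,
    nAT = n_atoms(g),
    nBT = nrow(g$bonds),
    nC = sum(el == "C"),
    nN = sum(el == "N"),
    nO = sum(el == "O"),
    nS = sum(el == "S"),
    nX = sum(el %in% c("F", "Cl", "Br", "I")),
    MW = sum(.ATOM_PROPS_RAW$mass[match(el, .ATOM_PROPS_RAW$element)]),
    nCIC = nrow(g$bonds) - n_atoms(g) + 1L,
    stop("unknown constitutional descriptor: ", name))
}

# --- descriptor naming grammar -------------------------------------------

.WEIGHT_PROPERTY <- c(m = "mass", v = "volume", e = "electronegativity",
                      p = "polarizability", u = "unit")

#' Parse a descriptor name
#'
#' Descriptor names follow the Dragon naming grammar: autocorrelations are
#' family + lag + weight letter (`ATS3m`, `MATS5v`, `GATS8p`), Burden
#' eigenvalues are family + weight letter + rank (`BEHp2`, `BELm1`), and
#' constitutional counts are literal (`nAT`, `MW`, ...). Weight letters:
#' m mass, v van der Waals volume, e Sanderson electronegativity,
#' p polarizability, u unweighted.
#'
#' @param name descriptor name string.
#' @return list with `family`, and for autocorrelations `lag` and `property`,
#'   for Burden descriptors `rank`, `property` and `which`.
#' @export
parse_descriptor_name <- function(name) {
  if (name %in% .CONSTITUTIONAL)
    return(list(family = "constitutional", name = name))
  m <- regmatches(name, regexec("^(ATS|MATS|GATS)([0-9]+)([mvepu])$", name))[[1]]
  if (length(m)) {
    lag <- as.integer(m[3])
    if (lag < 1) stop("descriptor '", name, "': lag must be >= 1")
    return(list(family = m[2], lag = lag,
                property = unname(.WEIGHT_PROPERTY[m[4]])))
  }
  m <- regmatches(name, regexec("^(BEH|BEL)([mvepu])([0-9]+)$", name))[[1]]
  if (length(m)) {
    return(list(family = m[2], rank = as.integer(m[4]),
                property = unname(.WEIGHT_PROPERTY[m[3]]),
                which = if (m[2] == "BEH") "highest" else "lowest"))
  }
  stop("cannot parse descriptor name '", name, "'. Implemented families: ",
       "ATS/MATS/GATS<lag><mvepu>, BEH/BEL<mvepu><rank>, and constitutional ",
       "counts (", paste(.CONSTITUTIONAL, collapse = ", "), "). ",
       "Other descriptor families (3D, charge, ...) must be imported from a ",
       "precomputed CSV via read_descriptor_csv().", call. = FALSE)
}

.compute_descriptor <- function(g, parsed, table, D) {
  if (parsed$family == "constitutional")
    return(.constitutional(g, parsed$name, table))
  w <- atom_weights(g, parsed$property, table)
  switch(parsed$family,
    ATS = broto_moreau_autocorrelation(g, w, parsed$lag, D),
    MATS = moran_autocorrelation(g, w, parsed$lag, D),
    GATS = geary_autocorrelation(g, w, parsed$lag, D),
    BEH = ,
    BEL = {
      if (parsed$rank > n_atoms(g)) return(0)  # rank beyond size: pad with 0
      burden_eigenvalues(g, w, parsed$rank, parsed$which)
    })
}

#' Compute a descriptor matrix for a set of molecules
#'
#' @param molecules a list of `molgraph` objects (names become compound ids
#'   when the graphs carry no ids).
#' @param spec character vector of descriptor names (see
#'   [parse_descriptor_name()]); column order follows `spec`.
#' @param table atomic property table.
#' @return numeric matrix, compounds x descriptors, with compound ids as row
#'   names and attribute `provenance = "computed"`.
#' @examples
#' g <- parse_smiles("CCO", "ethanol")
#' compute_descriptor_matrix(list(g), c("MATS1m", "BEHm1", "nAT"))
#' @export
compute_descriptor_matrix <- function(molecules, spec,
                                      table = atom_property_table()) {
  if (length(molecules) == 0) stop("empty molecule list")
  if (anyDuplicated(spec)) stop("duplicate descriptor names in spec: ",
                                paste(unique(spec[duplicated(spec)]),
                                      collapse = ", "))
  parsed <- lapply(spec, parse_descriptor_name)
  ids <- vapply(molecules, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate compound ids")
  X <- matrix(NA_real_, length(molecules), length(spec),
              dimnames = list(ids, spec))
  for (r in seq_along(molecules)) {
    g <- molecules[[r]]
    D <- topological_distances(g)
    for (c in seq_along(spec))
      X[r, c] <- .compute_descriptor(g, parsed[[c]], table, D)
  }
  attr(X, "provenance") <- "computed"
  X
}

#' Prefilter a descriptor matrix
#'
#' Drops near-constant columns (raw-scale SD at or below
#' `near_constant_tol`), then scans column pairs in fixed column order and,
#' for every pair with |Pearson r| above `corr_cutoff`, drops the
#' later column. The removal log records each drop and its cause.
#'
#' @param X numeric descriptor matrix with column names.
#' @param near_constant_tol SD threshold for the constancy filter.
#' @param corr_cutoff absolute-correlation threshold in (0, 1].
#' @return list with `X` (filtered matrix) and `removed` (data frame:
#'   `name`, `reason`, `partner`).
#' @export
prefilter <- function(X, near_constant_tol = 1e-8, corr_cutoff = 0.95) {
  stopifnot(corr_cutoff > 0, corr_cutoff <= 1)
  removed <- data.frame(name = character(), reason = character(),
                        partner = character(), stringsAsFactors = FALSE)
  sds <- apply(X, 2, stats::sd)
  const <- sds <= near_constant_tol
  for (nm in colnames(X)[const])
    removed[nrow(removed) + 1L, ] <- c(nm, "near_constant", NA)
  X <- X[, !const, drop = FALSE]
  if (ncol(X) == 0) stop("prefilter removed all columns")
  keep <- rep(TRUE, ncol(X))
  if (ncol(X) >= 2) {
    R <- abs(stats::cor(X))
    for (a in seq_len(ncol(X) - 1L)) {
      if (!keep[a]) next
      for (b in seq.int(a + 1L, ncol(X))) {
        if (keep[b] && R[a, b] > corr_cutoff) {
          keep[b] <- FALSE
          removed[nrow(removed) + 1L, ] <-
            c(colnames(X)[b], "correlated", colnames(X)[a])
        }
      }
    }
  }
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("prefilter removed all columns")
  list(X = X, removed = removed)
}

#' Write / read a descriptor CSV
#'
#' Plain CSV with header `compound_id,<name>,...`, one row per compound, full
#' double precision. The import path is how precomputed descriptor families
#' not computed natively (3D, charge, ...) enter the pipeline.
#'
#' @param X descriptor matrix with row names.
#' @param path file path.
#' @return `read_descriptor_csv` returns the matrix with
#'   `provenance = "imported"`.
#' @export
write_descriptor_csv <- function(X, path) {
  df <- data.frame(compound_id = rownames(X), check.names = FALSE)
  for (nm in colnames(X))   # 17 significant digits: lossless double repr
    df[[nm]] <- formatC(X[, nm], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "compound_id")
    stop("descriptor CSV must start with a compound_id column")
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$compound_id
  attr(X, "provenance") <- "imported"
  X
}
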