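# Hydrogen-depleted molecular graphs: SMILES ingestion, topological distances
# and atomic weight vectors. Chemistry (SMILES grammar, ring/aromaticity
# perception, formal charges) is delegated to OpenBabel through
# ChemmineR/ChemmineOB; this file only reshapes its output into a light graph
# structure that the descriptor kernels consume.

# MDL charge codes as used in SDF atom blocks (column C6 of ChemmineR's
# atomblock): 0 none, 1 +3, 2 +2, 3 +1, 5 -1, 6 -2, 7 -3 (4 = radical).
.MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

#' Parse a SMILES string into a molecular graph
#'
#' Builds the hydrogen-depleted labelled graph of a single connected molecule.
#' Atom elements, bond orders and formal charges come from OpenBabel's SMILES
#' parser; aromatic bonds are flagged using OpenBabel's aromaticity perception
#' (via MOL2 export) rather than the kekulized SDF orders.
#'
#' @param text a SMILES string for one connected molecule.
#' @param id compound identifier attached to the graph.
#' @return An object of class `molgraph`: a list with `atoms` (data frame with
#'   `element`, `charge`), `bonds` (data frame with 0-based `i`, `j`, numeric
#'   `order` 1/2/3, logical `aromatic`) and `id`.
#' @examples
#' g <- parse_smiles("CCO", "ethanol")
#' n_atoms(g)  # 3
#' @export
parse_smiles <- function(text, id = "mol") {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  if (grepl(".", text, fixed = TRUE))
    stop("disconnected molecule (dot-separated SMILES) is not supported: ",
         text, call. = FALSE)
  # single-atom molecules: SDF round-tripping is degenerate, parse directly
  m <- regmatches(text,
                  regexec("^\\[?([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*)?\\]?$",
                          text))[[1]]
  if (length(m) && m[2] %in% .ATOM_PROPS_RAW$element) {
    chg <- if (nzchar(m[4])) {
      mag <- sub("^[+-]", "", m[4])
      as.integer(paste0(substr(m[4], 1, 1), if (nzchar(mag)) mag else "1"))
    } else 0L
    return(structure(list(
      atoms = data.frame(element = m[2], charge = chg,
                         stringsAsFactors = FALSE),
      bonds = data.frame(i = integer(), j = integer(), order = numeric(),
                         aromatic = logical()),
      id = id), class = "molgraph"))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(text)),
    error = function(e) stop("invalid SMILES '", text, "': ",
                             conditionMessage(e), call. = FALSE))
  parts <- tryCatch({
    mol <- sdf[[1]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elements <- sub("_\\d+$", "", rownames(ab))
    charges <- unname(.MDL_CHARGE[as.character(ab[, "C6"])])
    charges[is.na(charges)] <- 0L
    bonds <- if (nrow(bb) > 0)
      data.frame(i = as.integer(bb[, 1]) - 1L,
                 j = as.integer(bb[, 2]) - 1L,
                 order = as.numeric(bb[, 3]))
    else data.frame(i = integer(), j = integer(), order = numeric())
    list(elements = elements, charges = charges, bonds = bonds)
  }, error = function(e) stop("invalid SMILES '", text,
                              "': malformed structure record",
                              call. = FALSE))
  elements <- parts$elements; charges <- parts$charges; bonds <- parts$bonds
  bonds$aromatic <- .aromatic_flags(text, nrow(bonds), bonds)
  g <- structure(list(
    atoms = data.frame(element = elements, charge = charges,
                       stringsAsFactors = FALSE),
    bonds = bonds,
    id = id), class = "molgraph")
  if (n_atoms(g) > 1 && !.is_connected(g))
    stop("SMILES '", text, "' parsed to a disconnected graph", call. = FALSE)
  g
}

# Aromatic bond flags from OpenBabel's MOL2 export (bond type "ar").
.aromatic_flags <- function(smiles, n_bonds, bonds) {
  if (n_bonds == 0L) return(logical(0))
  mol2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, "\n")),
    error = function(e) NULL)
  flags <- rep(FALSE, n_bonds)
  if (is.null(mol2)) return(flags)
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  start <- which(lines == "@<TRIPOS>BOND")
  if (length(start) != 1L) return(flags)
  rec <- lines[seq(start + 1L, length.out = n_bonds)]
  ar <- lapply(strsplit(trimws(rec), "\\s+"), function(f) {
    if (length(f) >= 4 && f[4] == "ar") as.integer(f[2:3]) - 1L else NULL
  })
  ar <- ar[!vapply(ar, is.null, logical(1))]
  for (pr in ar) {
    hit <- (bonds$i == pr[1] & bonds$j == pr[2]) |
           (bonds$i == pr[2] & bonds$j == pr[1])
    flags[hit] <- TRUE
  }
  flags
}

.is_connected <- function(g) {
  ig <- .as_igraph(g)
  igraph::is_connected(ig)
}

.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = data.frame(from = g$bonds$i + 1L, to = g$bonds$j + 1L),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$id, ": ", n_atoms(x), " heavy atoms, ",
      nrow(x$bonds), " bonds (", sum(x$bonds$aromatic), " aromatic)\n",
      sep = "")
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a `molgraph`.
#' @return integer atom count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Topological distance matrix
#'
#' All-pairs shortest-path distances in bond counts (every bond counts as one
#' edge regardless of order). This is the lag metric of the 2D autocorrelation
#' descriptors.
#'
#' @param g a connected `molgraph`.
#' @return A symmetric integer matrix with zero diagonal and attribute
#'   `diameter` (the largest distance).
#' @export
topological_distances <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) {
    D <- matrix(0L, 1, 1)
  } else {
    if (!.is_connected(g)) stop("graph is disconnected; distances undefined")
    D <- igraph::distances(.as_igraph(g))
    storage.mode(D) <- "integer"
    dimnames(D) <- NULL
  }
  attr(D, "diameter") <- max(D)
  D
}

#' Atomic weight vector for a molecular graph
#'
#' Looks up the chosen atomic property for every heavy atom. Under a
#' carbon-scaled table (the default convention) all-carbon skeletons get unit
#' weights.
#'
#' @param g a `molgraph`.
#' @param property one of `"mass"`, `"volume"`, `"electronegativity"`,
#'   `"polarizability"`, or `"unit"` for unweighted (all ones).
#' @param table an atomic property table from [atom_property_table()].
#' @return numeric vector of length `n_atoms(g)`.
#' @export
atom_weights <- function(g,
                         property = c("mass", "volume", "electronegativity",
                                      "polarizability", "unit"),
                         table = atom_property_table()) {
  property <- match.arg(property)
  if (property == "unit") return(rep(1, n_atoms(g)))
  unknown <- setdiff(unique(g$atoms$element), table$element)
  if (length(unknown))
    stop("element(s) not in the atom property table: ",
         paste(unknown, collapse = ", "),
         " (available: ", paste(table$element, collapse = ", "), ")",
         call. = FALSE)
  unname(table[g$atoms$element, property])
}

#' Read a SMILES file
#'
#' One record per line, whitespace-separated columns: identifier, SMILES and
#' an optional numeric activity. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A list with `molecules` (list of `molgraph`) and `activity`
#'   (named numeric vector, `NA` where absent).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mols <- list()
  act <- numeric(0)
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 2) stop("malformed SMILES record: '", ln, "'")
    mols[[f[1]]] <- parse_smiles(f[2], id = f[1])
    act[f[1]] <- if (length(f) >= 3) as.numeric(f[3]) else NA_real_
  }
  list(molecules = mols, activity = act)
}
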