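# In silico screening: enumerate candidate molecules by substituent
# substitution on a scaffold, predict their activity with a fitted model and
# filter by the leverage applicability domain.
#
# Attachment points are numbered dummy atoms written as [*:1], [*:2], ... in
# the scaffold SMILES (the common fragment-replacement convention). A
# substituent fragment is a SMILES snippet grafted textually in place of the
# placeholder; the empty fragment (or "H") removes the attachment branch.

#' Read a substitution specification file
#'
#' Plain-text sections: `[scaffold]` (one SMILES line with `[*:N]`
#' placeholders), `[site N]` (lines of `name SMILES`, one substituent per
#' line; SMILES `-` or `H` means hydrogen / no substituent), and `[mode]`
#' (`cross-product` or `explicit`; explicit mode takes `[pairs]` lines of
#' whitespace-separated substituent names, one tuple per candidate).
#'
#' @param path file path.
#' @return list of class `substitution_spec` with `scaffold`, `sites` (named
#'   list of name->fragment vectors), `mode`, `pairs`.
#' @export
read_substitution_spec <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  scaffold <- NULL; sites <- list(); mode <- "cross-product"; pairs <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    if (is.na(section)) stop("content before first section header: ", ln)
    if (section == "scaffold") {
      scaffold <- ln
    } else if (grepl("^site ", section)) {
      idx <- sub("^site ", "", section)
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) != 2) stop("bad substituent line: ", ln)
      sites[[idx]] <- c(sites[[idx]], stats::setNames(f[2], f[1]))
    } else if (section == "mode") {
      mode <- ln
    } else if (section == "pairs") {
      pairs[[length(pairs) + 1L]] <- strsplit(ln, "\\s+")[[1]]
    } else stop("unknown section [", section, "]")
  }
  substitution_spec(scaffold, sites, mode, pairs)
}

#' Construct a substitution specification
#'
#' @param scaffold SMILES with `[*:N]` attachment placeholders.
#' @param sites named list: names are the placeholder numbers, values are
#'   named character vectors of substituent SMILES fragments.
#' @param mode `"cross-product"` or `"explicit"`.
#' @param pairs for explicit mode, a list of character vectors of substituent
#'   names, one per candidate.
#' @return list of class `substitution_spec`.
#' @export
substitution_spec <- function(scaffold, sites, mode = "cross-product",
                              pairs = list()) {
  if (is.null(scaffold)) stop("no scaffold given")
  found <- regmatches(scaffold,
                      gregexpr("\\[\\*:([0-9]+)\\]", scaffold))[[1]]
  nums <- sort(as.integer(gsub("\\D", "", found)))
  if (!length(nums)) stop("scaffold has no [*:N] attachment points")
  if (!setequal(as.character(nums), names(sites)))
    stop("sites (", paste(names(sites), collapse = ","),
         ") do not match scaffold placeholders (",
         paste(nums, collapse = ","), ")")
  for (s in names(sites))
    if (!length(sites[[s]])) stop("empty substituent list at site ", s)
  if (!mode %in% c("cross-product", "explicit"))
    stop("mode must be cross-product or explicit")
  if (mode == "explicit" && !length(pairs))
    stop("explicit mode requires a pairs list")
  structure(list(scaffold = scaffold, sites = sites, mode = mode,
                 pairs = pairs), class = "substitution_spec")
}

.graft <- function(scaffold, site, fragment) {
  ph <- paste0("[*:", site, "]")
  if (fragment %in% c("", "-", "H", "[H]")) {
    # drop the whole branch "([*:N])" when parenthesized, else the bare atom
    out <- sub(paste0("(", ph, ")"), "", scaffold, fixed = TRUE)
    if (identical(out, scaffold)) out <- sub(ph, "", scaffold, fixed = TRUE)
    return(out)
  }
  sub(ph, fragment, scaffold, fixed = TRUE)
}

#' Enumerate candidate molecules from a substitution specification
#'
#' Cross-product mode yields one candidate per combination of substituents;
#' explicit mode one per listed name tuple. Candidate ids are formed from the
#' substituent names. Grafts whose SMILES fail to parse (valence violations
#' and the like) are rejected and logged, never silently dropped.
#'
#' @param spec a `substitution_spec`.
#' @return list with `molecules` (named list of `molgraph`), `smiles` (named
#'   character vector) and `rejected` (data frame: id, smiles, reason).
#' @export
enumerate_candidates <- function(spec) {
  site_ids <- names(spec$sites)
  combos <- if (spec$mode == "cross-product") {
    grid <- expand.grid(lapply(spec$sites, names),
                        stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(r) unlist(grid[r, , drop = FALSE]))
  } else {
    lapply(spec$pairs, function(p) stats::setNames(p, site_ids))
  }
  mols <- list(); smi <- character(); rej <- data.frame(
    id = character(), smiles = character(), reason = character(),
    stringsAsFactors = FALSE)
  for (cmb in combos) {
    id <- paste(cmb, collapse = "_")
    s <- spec$scaffold
    for (site in site_ids) {
      if (!cmb[[site]] %in% names(spec$sites[[site]]))
        stop("unknown substituent '", cmb[[site]], "' at site ", site,
             " (available: ", paste(names(spec$sites[[site]]),
                                    collapse = ", "), ")")
      s <- .graft(s, site, spec$sites[[site]][[cmb[[site]]]])
    }
    g <- tryCatch(parse_smiles(s, id = id), error = function(e) e)
    if (inherits(g, "error")) {
      rej[nrow(rej) + 1L, ] <- c(id, s, conditionMessage(g))
    } else {
      mols[[id]] <- g
      smi[id] <- s
    }
  }
  list(molecules = mols, smiles = smi, rejected = rej)
}

#' Screen candidate molecules through a fitted model with AD filtering
#'
#' Computes the model's descriptors for every candidate, predicts activity,
#' computes the leverage of each candidate against the training compounds in
#' the model's space, flags candidates above the warning leverage, and ranks
#' the in-domain candidates by predicted activity (best first).
#' Out-of-domain candidates are retained and flagged, never dropped.
#'
#' @param candidates output of [enumerate_candidates()], or a named list of
#'   `molgraph` objects.
#' @param model a fitted `qsar_model`.
#' @param X_train raw training descriptor matrix used to fit the model.
#' @param table atomic property table for descriptor computation.
#' @param space passed to the leverage computation (see [williams()]).
#' @return data frame of class `screening_result`: `candidate_id`, `smiles`,
#'   `predicted_pic50`, `leverage`, `in_domain`, `rank` (NA outside the
#'   domain); attribute `h_star`.
#' @export
screen_candidates <- function(candidates, model, X_train,
                              table = atom_property_table(),
                              space = c("auto", "score", "descriptor")) {
  space <- match.arg(space)
  if (space == "auto")
    space <- if (!is.null(model$weights)) "score" else "descriptor"
  mols <- if (is.list(candidates) && !is.null(candidates$molecules))
    candidates$molecules else candidates
  smi <- if (!is.null(candidates$smiles)) candidates$smiles else
    stats::setNames(rep(NA_character_, length(mols)), names(mols))
  if (!length(mols)) stop("no candidate molecules to screen")
  Xc <- compute_descriptor_matrix(mols, model$descriptors, table)
  Xtr <- as.matrix(X_train)[, model$descriptors, drop = FALSE]
  pred <- predict(model, Xc)
  if (space == "score") {
    proj <- function(M) {
      Mc <- sweep(sweep(M, 2, model$center), 2, model$scale, `/`)
      Mc %*% model$weights %*%
        solve(crossprod(model$loadings, model$weights))
    }
    Ttr <- proj(Xtr); Tpr <- proj(Xc)
  } else {
    Ttr <- autoscale(Xtr); Tpr <- apply_scaling(Xc, Ttr)
  }
  h_star <- warning_leverage(nrow(Ttr), ncol(Ttr))
  h <- leverage(Ttr, Tpr)
  in_dom <- h <= h_star
  out <- data.frame(candidate_id = names(mols),
                    smiles = unname(smi[names(mols)]),
                    predicted_pic50 = unname(pred),
                    leverage = unname(h),
                    in_domain = in_dom,
                    rank = NA_integer_,
                    stringsAsFactors = FALSE)
  out$rank[in_dom] <- rank(-out$predicted_pic50[in_dom],
                           ties.method = "first")
  out <- out[order(!out$in_domain, out$rank), ]
  rownames(out) <- NULL
  attr(out, "h_star") <- h_star
  class(out) <- c("screening_result", "data.frame")
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening result:", nrow(x), "candidates,",
      sum(x$in_domain), "in-domain (h* =",
      format(attr(x, "h_star"), digits = 4), ")\n")
  NextMethod()
}
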