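# Atomic property table used to weight topological descriptors.
#
# The four weighting schemes (atomic mass m, van der Waals volume v, Sanderson
# electronegativity e, atomic polarizability p) follow the convention of the
# Dragon/Todeschini-Consonni descriptor literature: property values are divided
# by the carbon value, so every weight is expressed relative to carbon and a
# pure-carbon skeleton gets unit weights.
#
# Sources of the literal values:
#   mass  - IUPAC 2021 standard atomic weights (u)
#   vdw   - Bondi (1964) van der Waals radii (Angstrom); volumes 4/3*pi*r^3
#   sand  - Sanderson electronegativities (Sanderson 1983)
#   polar - atomic polarizabilities (Angstrom^3), Miller (1990) compilation

.ATOM_RADII <- c(C = 1.70, H = 1.20, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10)

.ATOM_PROPS_RAW <- data.frame(
  element = c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si"),
  mass = c(12.011, 1.008, 14.007, 15.999, 32.06, 30.974,
           18.998, 35.45, 79.904, 126.904, 10.81, 28.085),
  electronegativity = c(2.746, 2.592, 3.194, 3.654, 2.957, 2.515,
                        4.000, 3.475, 3.219, 2.778, 2.275, 2.138),
  polarizability = c(1.76, 0.67, 1.10, 0.80, 2.90, 3.63,
                     0.56, 2.18, 3.05, 5.35, 3.03, 5.38),
  stringsAsFactors = FALSE
)
.ATOM_PROPS_RAW$volume <- 4 / 3 * pi * .ATOM_RADII[.ATOM_PROPS_RAW$element]^3

#' Atomic property table for descriptor weighting
#'
#' Returns the per-element property table used to weight autocorrelation and
#' Burden-eigenvalue descriptors: atomic mass (u), van der Waals volume
#' (A^3, from Bondi radii), Sanderson electronegativity (dimensionless) and
#' atomic polarizability (A^3). With `carbon_scaled = TRUE` (the default, and
#' the convention of the Dragon descriptor family) every property is divided
#' by its carbon value, so carbon has weight exactly 1 under every scheme.
#'
#' @param carbon_scaled logical; divide each property column by its carbon
#'   entry.
#' @return A data frame with one row per element (C, H, N, O, S, P, F, Cl, Br,
#'   I, B, Si) and columns `element`, `mass`, `volume`, `electronegativity`,
#'   `polarizability`, with attribute `carbon_scaled`.
#' @examples
#' tab <- atom_property_table()
#' tab[tab$element == "C", ]  # all ones
#' @export
atom_property_table <- function(carbon_scaled = TRUE) {
  tab <- .ATOM_PROPS_RAW[, c("element", "mass", "volume",
                             "electronegativity", "polarizability")]
  if (carbon_scaled) {
    crow <- tab[tab$element == "C", -1]
    for (p in names(crow)) tab[[p]] <- tab[[p]] / crow[[p]]
  }
  rownames(tab) <- tab$element
  attr(tab, "carbon_scaled") <- carbon_scaled
  tab
}
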