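## Element reference data: symbols, covalent radii, periodic-table position.
##
## Covalent radii are the Cordero et al. (2008) single-bond radii, in
## Angstrom (sp3 value for carbon).  The table is pinned here as package data
## so that graph featurization is reproducible: representations built from
## path lengths depend directly on these numbers.

.element_table <- local({
  tab <- data.frame(
    symbol = c("H",  "He",
               "Li", "Be", "B",  "C",  "N",  "O",  "F",  "Ne",
               "Na", "Mg", "Al", "Si", "P",  "S",  "Cl", "Ar",
               "K",  "Ca", "Ga", "Ge", "As", "Se", "Br", "Kr",
               "Rb", "Sr", "In", "Sn", "Sb", "Te", "I",  "Xe",
               "Cs", "Ba", "Tl", "Pb", "Bi"),
    z      = c(1, 2,
               3, 4, 5, 6, 7, 8, 9, 10,
               11, 12, 13, 14, 15, 16, 17, 18,
               19, 20, 31, 32, 33, 34, 35, 36,
               37, 38, 49, 50, 51, 52, 53, 54,
               55, 56, 81, 82, 83),
    radius = c(0.31, 0.28,
               1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
               1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06,
               2.03, 1.76, 1.22, 1.20, 1.19, 1.20, 1.20, 1.16,
               2.20, 1.95, 1.42, 1.39, 1.39, 1.38, 1.39, 1.40,
               2.44, 2.15, 1.45, 1.46, 1.48),
    period = c(1, 1,
               2, 2, 2, 2, 2, 2, 2, 2,
               3, 3, 3, 3, 3, 3, 3, 3,
               4, 4, 4, 4, 4, 4, 4, 4,
               5, 5, 5, 5, 5, 5, 5, 5,
               6, 6, 6, 6, 6),
    ## number of s+p valence electrons (main-group column)
    valence_electrons = c(1, 2,
                          1, 2, 3, 4, 5, 6, 7, 8,
                          1, 2, 3, 4, 5, 6, 7, 8,
                          1, 2, 3, 4, 5, 6, 7, 8,
                          1, 2, 3, 4, 5, 6, 7, 8,
                          1, 2, 3, 4, 5),
    stringsAsFactors = FALSE)
  ## standard bonding valence used for graph generation / saturation checks
  tab$valence <- c(1, 0,
                   1, 2, 3, 4, 3, 2, 1, 0,
                   1, 2, 3, 4, 3, 2, 1, 0,
                   1, 2, 3, 4, 3, 2, 1, 0,
                   1, 2, 3, 4, 3, 2, 1, 0,
                   1, 2, 3, 4, 3)
  tab
})

#' Covalent radii table
#'
#' Returns the pinned single-bond covalent radii (Cordero et al. 2008)
#' used throughout the package, as a named numeric vector in Angstrom
#' indexed by nuclear charge.
#'
#' @return Named numeric vector; names are nuclear charges as strings.
#' @export
#' @examples
#' covalent_radii()[["6"]]  # carbon, 0.76
covalent_radii <- function() {
  r <- .element_table$radius
  names(r) <- as.character(.element_table$z)
  r
}

#' Covalent radius of an element
#'
#' @param z Nuclear charge(s).
#' @return Radius (Angstrom).
#' @export
covalent_radius <- function(z) {
  i <- match(z, .element_table$z)
  if (anyNA(i)) {
    stop("no covalent radius tabulated for Z = ",
         paste(z[is.na(i)], collapse = ", "))
  }
  .element_table$radius[i]
}

#' Convert element symbols to nuclear charges
#' @param symbol Character vector of element symbols.
#' @return Integer vector of nuclear charges.
#' @export
element_number <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol: ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .element_table$z[i]
}

#' Convert nuclear charges to element symbols
#' @param z Integer vector of nuclear charges.
#' @return Character vector of symbols.
#' @export
element_symbol <- function(z) {
  i <- match(z, .element_table$z)
  if (anyNA(i)) stop("unknown nuclear charge: ",
                     paste(unique(z[is.na(i)]), collapse = ", "))
  .element_table$symbol[i]
}

## period and valence-electron count (used by the FLLA crystal representation)
.periodic_position <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) stop("element outside the tabulated main group: ",
                     paste(symbol[is.na(i)], collapse = ", "))
  cbind(period = .element_table$period[i],
        valence = .element_table$valence_electrons[i])
}

.standard_valence <- function(z) {
  i <- match(z, .element_table$z)
  if (anyNA(i)) stop("no standard valence for Z = ",
                     paste(z[is.na(i)], collapse = ", "))
  .element_table$valence[i]
}
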