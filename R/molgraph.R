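## Core data model: molecular graphs, geometry records, crystal records.
##
## A molecular graph holds nuclear charges plus an integer bond-order matrix
## (0 none, 1 single, 2 double, 3 triple).  Hydrogens are explicit; each must
## be attached by exactly one single bond.  Under-valent heavy atoms (e.g.
## singlet carbene carbons) are allowed and flagged, never rejected: graphs
## without a conventional closed-shell Lewis structure are legitimate inputs.

#' Construct a molecular graph
#'
#' @param nuclear_charges Integer vector of nuclear charges, one per atom
#'   (hydrogens explicit).
#' @param bond_order_matrix Square symmetric integer matrix with entries in
#'   \code{0:3} and zero diagonal.
#' @return An object of class \code{molgraph} with fields
#'   \code{nuclear_charges}, \code{bond_order_matrix}, \code{heavy_indices},
#'   \code{hydrogen_attachments} (named integer vector mapping hydrogen index
#'   to its bonded heavy atom) and \code{undervalent} (indices of heavy atoms
#'   whose total bond order is below the standard valence).
#' @export
molecular_graph <- function(nuclear_charges, bond_order_matrix) {
  z <- as.integer(nuclear_charges)
  B <- as.matrix(bond_order_matrix)
  storage.mode(B) <- "integer"
  n <- length(z)
  if (!all(dim(B) == c(n, n)))
    stop("bond_order_matrix must be ", n, "x", n)
  if (!isTRUE(all.equal(B, t(B), check.attributes = FALSE)))
    stop("bond_order_matrix must be symmetric")
  if (any(diag(B) != 0L)) stop("bond_order_matrix must have zero diagonal")
  if (any(!B %in% 0:3))
    stop("bond orders must be in {0,1,2,3}; aromatic/query orders must be ",
         "kekulized before graph construction")
  if (any(z < 1L)) stop("nuclear charges must be positive")

  heavy <- which(z > 1L)
  if (length(heavy) == 0L) stop("graph must contain at least one heavy atom")
  hyd <- which(z == 1L)
  att <- integer(0)
  if (length(hyd)) {
    att <- vapply(hyd, function(h) {
      nb <- which(B[h, ] > 0L)
      if (length(nb) != 1L || B[h, nb] != 1L)
        stop("hydrogen atom ", h,
             " must have exactly one single bond (found ", length(nb), ")")
      if (z[nb] == 1L) stop("hydrogen atom ", h, " bonded to hydrogen")
      nb
    }, integer(1))
    names(att) <- as.character(hyd)
  }
  deg <- rowSums(B)
  under <- heavy[deg[heavy] < .standard_valence(z[heavy])]

  structure(list(nuclear_charges = z,
                 bond_order_matrix = B,
                 heavy_indices = heavy,
                 hydrogen_attachments = att,
                 undervalent = under),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  z <- x$nuclear_charges
  tab <- table(element_symbol(z))
  formula <- paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = "")
  cat("<molgraph> ", formula, ": ", length(x$heavy_indices), " heavy atoms, ",
      sum(z == 1L), " hydrogens, ",
      sum(x$bond_order_matrix > 0) / 2, " bonds",
      if (length(x$undervalent)) paste0(" [under-valent: ",
                                        paste(x$undervalent, collapse = ","),
                                        "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a graph
#' @param g A \code{molgraph}.
#' @return Integer count of atoms with Z > 1.
#' @export
n_heavy <- function(g) length(g$heavy_indices)

## heavy-atom bond-order submatrix
.heavy_bonds <- function(g) {
  h <- g$heavy_indices
  g$bond_order_matrix[h, h, drop = FALSE]
}

#' Construct a geometry record
#'
#' Element identities plus Cartesian coordinates in Angstrom, in the same
#' atom order as the associated molecular graph.
#'
#' @param nuclear_charges Integer vector.
#' @param coordinates n x 3 numeric matrix (Angstrom).
#' @param check_clash Reject geometries with any interatomic distance below
#'   0.3 Angstrom (default TRUE).
#' @return Object of class \code{geometry_record}.
#' @export
geometry_record <- function(nuclear_charges, coordinates, check_clash = TRUE) {
  z <- as.integer(nuclear_charges)
  xyz <- as.matrix(coordinates)
  if (ncol(xyz) != 3L || nrow(xyz) != length(z))
    stop("coordinates must be ", length(z), " x 3")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  dimnames(xyz) <- NULL
  if (check_clash && length(z) > 1L) {
    dmin <- min(dist(xyz))
    if (dmin < 0.3)
      stop(sprintf("atoms closer than 0.3 Angstrom (min distance %.3f)", dmin))
  }
  structure(list(nuclear_charges = z, coordinates = xyz),
            class = "geometry_record")
}

#' @export
print.geometry_record <- function(x, ...) {
  cat("<geometry_record> ", length(x$nuclear_charges), " atoms (",
      sum(x$nuclear_charges > 1), " heavy)\n", sep = "")
  invisible(x)
}

#' Pairwise distance matrix of a geometry
#'
#' @param geom A \code{geometry_record}.
#' @param heavy_only Restrict to heavy atoms (default FALSE).
#' @return Symmetric matrix of Euclidean distances (Angstrom).
#' @export
distance_matrix <- function(geom, heavy_only = FALSE) {
  xyz <- geom$coordinates
  if (heavy_only) xyz <- xyz[geom$nuclear_charges > 1L, , drop = FALSE]
  as.matrix(dist(xyz))
}

## ideal elpasolite (ABC2D6) representative fractional sites, fixed Wyckoff
## sequence A, B, C, D.  The D (halide) site position along <100> is the one
## internal degree of freedom; 0.24 is a typical relaxed value.
.elpasolite_template <- function(x_d = 0.24) {
  rbind(A = c(0, 0, 0),
        B = c(0.5, 0.5, 0.5),
        C = c(0.25, 0.25, 0.25),
        D = c(x_d, 0, 0))
}

#' Construct an elpasolite crystal record
#'
#' Quaternary ABC2D6 crystal described by its four site elements (fixed
#' Wyckoff sequence A, B, C, D), the cubic lattice constant, and fractional
#' coordinates of the representative sites.
#'
#' @param site_elements Character vector of length 4 (A, B, C, D elements).
#' @param lattice_constant Cubic cell length in Angstrom (> 0).
#' @param fractional_coords m x 3 matrix with entries in [0, 1); defaults to
#'   the ideal elpasolite template.
#' @return Object of class \code{crystal_record}.
#' @export
crystal_record <- function(site_elements, lattice_constant,
                           fractional_coords = .elpasolite_template()) {
  if (length(site_elements) != 4L)
    stop("site_elements must have length 4 (ABC2D6)")
  element_number(site_elements)  # validates symbols
  if (!is.numeric(lattice_constant) || length(lattice_constant) != 1L ||
      lattice_constant <= 0)
    stop("lattice_constant must be a positive scalar")
  fc <- as.matrix(fractional_coords)
  if (ncol(fc) != 3L) stop("fractional_coords must have 3 columns")
  if (any(fc < 0 | fc >= 1)) stop("fractional coordinates must lie in [0, 1)")
  structure(list(site_elements = as.character(site_elements),
                 lattice_constant = as.numeric(lattice_constant),
                 fractional_coords = fc),
            class = "crystal_record")
}

#' @export
print.crystal_record <- function(x, ...) {
  e <- x$site_elements
  cat(sprintf("<crystal_record> %s%s%s2%s6, a = %.4f A, %d sites\n",
              e[1], e[2], e[3], e[4], x$lattice_constant,
              nrow(x$fractional_coords)))
  invisible(x)
}
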