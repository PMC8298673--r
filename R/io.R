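## Readers and writers for the standard chemical exchange formats used here:
## XYZ (geometries), SDF V2000 (graph + geometry) and SMILES (graph input).
## SMILES and SDF perception is delegated to OpenBabel via ChemmineOB /
## ChemmineR; the functions below adapt those objects to the package's data
## model and enforce its contracts (kekulized orders, explicit hydrogens,
## closed-shell inputs).

#' Read an XYZ file
#'
#' Standard XYZ dialect: atom-count line, comment line, then one
#' \code{symbol x y z} line per atom (Angstrom).
#'
#' @param path Path to an XYZ file.
#' @return A \code{geometry_record}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("malformed XYZ count line: '", lines[1], "'")
  if (length(lines) < n + 2L)
    stop("XYZ count line announces ", n, " atoms but only ",
         length(lines) - 2L, " atom lines present")
  body <- lines[3:(n + 2L)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(lengths(toks) < 4L)
  if (length(bad)) stop("malformed XYZ atom line ", bad[1] + 2L)
  sym <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinate in XYZ file")
  geometry_record(element_number(sym), xyz, check_clash = FALSE)
}

#' Write an XYZ file
#'
#' @param geom A \code{geometry_record}.
#' @param path Output path.
#' @param comment Comment line (default empty).
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(geom, path, comment = "") {
  sym <- element_symbol(geom$nuclear_charges)
  lines <- c(as.character(length(sym)), comment,
             sprintf("%-3s %17.9f %17.9f %17.9f", sym,
                     geom$coordinates[, 1], geom$coordinates[, 2],
                     geom$coordinates[, 3]))
  writeLines(lines, path)
  invisible(path)
}

## molgraph + geometry from a ChemmineR SDF object
.sdf_to_graph <- function(sdf, source = "SDF") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(as.matrix(bb)) == 0L)
    stop(source, ": missing bond block")
  sym <- sub("_.*$", "", rownames(ab))
  z <- element_number(sym)
  n <- length(z)
  B <- matrix(0L, n, n)
  bb <- as.matrix(bb)
  ord <- as.integer(bb[, 3])
  if (any(ord > 3L))
    stop(source, ": aromatic/query bond order ", max(ord),
         " present; kekulize the input first")
  i <- as.integer(bb[, 1]); j <- as.integer(bb[, 2])
  B[cbind(i, j)] <- ord
  B[cbind(j, i)] <- ord
  g <- molecular_graph(z, B)
  geom <- geometry_record(z, ab[, 1:3, drop = FALSE], check_clash = FALSE)
  list(graph = g, geometry = geom)
}

#' Read an SDF (V2000) file
#'
#' Each record yields the molecular graph (from the bond block) and the
#' geometry (from the atom block).
#'
#' @param path Path to an SDF file.
#' @return List of \code{list(graph, geometry)} pairs, one per record.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such SDF file: ", path)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  lapply(seq_along(sdfs), function(k) .sdf_to_graph(sdfs[[k]], source = path))
}

#' Write molecules to an SDF (V2000) file
#'
#' @param dataset List of \code{list(graph, geometry)} pairs.
#' @param path Output path.
#' @param titles Optional record titles.
#' @return \code{path}, invisibly.
#' @export
write_sdf <- function(dataset, path, titles = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(dataset)) {
    g <- dataset[[i]]$graph; geom <- dataset[[i]]$geometry
    z <- g$nuclear_charges
    B <- g$bond_order_matrix
    bonds <- which(upper.tri(B) & B > 0L, arr.ind = TRUE)
    title <- if (!is.null(titles)) titles[i] else sprintf("mol_%d", i)
    writeLines(c(title, "  g2s", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         length(z), nrow(bonds)),
                 sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         geom$coordinates[, 1], geom$coordinates[, 2],
                         geom$coordinates[, 3], element_symbol(z)),
                 sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2],
                         B[bonds]),
                 "M  END", "$$$$"), con)
  }
  invisible(path)
}

## light SMILES lexer: catches structural errors OpenBabel silently repairs
.check_smiles_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L; bracket <- FALSE
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (bracket) {
      if (ch == "]") bracket <- FALSE
      next
    }
    if (ch == "[") { bracket <- TRUE; next }
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unparsable SMILES '", smiles,
                           "': unmatched ')' at position ", k)
    } else if (!grepl("[]A-Za-z0-9@+=#:/\\\\%.*$[-]", ch)) {
      stop("unparsable SMILES '", smiles, "': invalid token '", ch,
           "' at position ", k)
    }
  }
  if (depth != 0L) stop("unparsable SMILES '", smiles, "': unmatched '('")
  if (bracket) stop("unparsable SMILES '", smiles, "': unmatched '['")
  invisible(TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Hydrogens are made explicit (saturating standard valences) and aromatic
#' systems are kekulized, so all bond orders are in \{1, 2, 3\}.  Charged and
#' open-shell (radical) species are rejected; under-valent closed-shell atoms
#' such as singlet carbene carbons are accepted and flagged on the returned
#' graph.  Atom order in the result carries no meaning: representations
#' canonicalize it downstream.
#'
#' @param smiles A SMILES string.
#' @return A \code{molgraph}.
#' @export
#' @examples
#' g <- parse_smiles("CC")   # ethane: 2 heavy atoms, 6 hydrogens
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .check_smiles_tokens(smiles)
  txt <- ChemmineOB::convertFormat(
    "SMI", "SDF", smiles,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))
  if (!nzchar(txt)) stop("unparsable SMILES '", smiles, "'")
  if (grepl("M  CHG", txt, fixed = TRUE))
    stop("charged species are not supported: '", smiles, "'")
  if (grepl("M  RAD", txt, fixed = TRUE))
    stop("open-shell (radical) species are not supported: '", smiles, "'")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
  res <- .sdf_to_graph(sdfs[[1]], source = paste0("SMILES '", smiles, "'"))
  g <- res$graph
  ## neutral species with an odd electron count are necessarily open-shell
  if (sum(g$nuclear_charges) %% 2L == 1L)
    stop("open-shell (radical) species are not supported: '", smiles, "'")
  g
}
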