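## Graph-based molecular representations.
##
## Every scheme turns a molecular graph into a fixed-length feature vector
## built from a symmetric heavy-atom matrix:
##   bond_order  -- the bond-order matrix itself ({0,1,2,3})
##   bond_hop    -- shortest-path bond counts
##   bond_length -- shortest-path lengths weighted by covalent radii sums
##   graph_cm    -- Coulomb-matrix analogue, 0.5 Z^2.4 diagonal and
##                  Z_i Z_j / l_ij off-diagonal with l_ij the bond_length
##   graph_bob   -- graph_cm entries binned into element(-pair) bags
## plus flla for crystals (periodic-table row / valence-electron count per
## site).  Atoms are canonically sorted by non-decreasing row norm so that
## the vector (and the paired distance labels) are invariant to the input
## atom order.

REP_SCHEMES <- c("bond_order", "bond_hop", "bond_length",
                 "graph_cm", "graph_bob", "flla")

## heavy-atom bond-order matrix, with pseudo-edges added for disconnected
## graphs (transition-state inputs): every atom of a detached fragment is
## connected with order 1 to every reaction-center atom, which must be
## supplied as attr(g, "reaction_centers") (heavy-atom positions).
.effective_heavy_bonds <- function(g) {
  Bh <- .heavy_bonds(g)
  gi <- igraph::graph_from_adjacency_matrix(Bh > 0L, mode = "undirected")
  comp <- igraph::components(gi)
  if (comp$no == 1L) return(Bh)
  rc <- attr(g, "reaction_centers")
  if (is.null(rc))
    stop("disconnected heavy-atom graph: supply reaction-center atoms as ",
         "attr(g, 'reaction_centers') (positions among heavy atoms)")
  rc <- as.integer(rc)
  core <- comp$membership[rc[1]]
  if (any(comp$membership[rc] != core))
    stop("reaction-center atoms must lie in a single fragment")
  frag <- which(comp$membership != core)
  for (a in frag) for (b in rc) if (Bh[a, b] == 0L) {
    Bh[a, b] <- Bh[b, a] <- 1L
  }
  Bh
}

## per-scheme heavy-atom representation matrix (unsorted)
.rep_matrix <- function(g, scheme) {
  zh <- g$nuclear_charges[g$heavy_indices]
  Bh <- .effective_heavy_bonds(g)
  n <- nrow(Bh)
  if (scheme == "bond_order") {
    M <- Bh
    storage.mode(M) <- "double"
    return(M)
  }
  gi <- igraph::graph_from_adjacency_matrix(Bh > 0L, mode = "undirected")
  if (scheme == "bond_hop")
    return(igraph::distances(gi))
  ## weighted shortest paths: edge weight = sum of covalent radii.  Radii
  ## are tabulated to 0.01 A, so weights are integers in centi-Angstrom:
  ## path sums are then exact and bit-identical under any atom permutation
  ## (no last-ulp drift from tie-broken equal-weight paths).
  el <- igraph::as_edgelist(gi)
  r <- covalent_radius(zh)
  w <- round(100 * (r[el[, 1]] + r[el[, 2]]))
  L <- igraph::distances(gi, weights = w) / 100
  if (scheme == "bond_length") return(L)
  CM <- outer(zh, zh) / L
  diag(CM) <- 0.5 * zh^2.4
  if (scheme %in% c("graph_cm", "graph_bob")) return(CM)
  stop("unknown representation scheme: ", scheme)
}

## permutation-stable row norm: Euclidean, accumulated over sorted entries so
## the float result is bit-identical under any input atom permutation
.row_norms <- function(M) {
  vapply(seq_len(nrow(M)), function(i) sqrt(sum(sort(M[i, ]^2))), numeric(1))
}

## Canonical atom order: non-decreasing row norm, ties broken by nuclear
## charge, then by canonical labeling of the weighted matrix via
## individualization-refinement: Weisfeiler-Lehman-style colour refinement
## over (entry, colour) multisets, and -- where classes of equivalent atoms
## remain -- branching on each member and keeping the permutation whose
## sorted matrix is lexicographically smallest.  The result depends only on
## the matrix content, never on the input atom order; remaining degenerate
## branches are exact matrix automorphisms, for which all choices coincide.
.canonical_order <- function(M, z, primary = NULL) {
  n <- nrow(M)
  if (n == 1L) return(1L)
  norms <- .row_norms(M)
  fmt <- function(x) sprintf("%.14e", x)
  if (is.null(primary)) primary <- rep(0L, n)

  wl <- function(rank) {
    repeat {
      sig <- vapply(seq_len(n), function(i) {
        pairs <- paste0(fmt(M[i, -i]), ":", sprintf("%06d", rank[-i]))
        paste(sprintf("%06d", rank[i]), paste(sort(pairs), collapse = "|"))
      }, character(1))
      new_rank <- match(sig, sort(unique(sig)))
      stable <- length(unique(new_rank)) == length(unique(rank))
      rank <- new_rank
      if (stable) return(rank)
    }
  }
  matrix_key <- function(p) {
    Mp <- M[p, p, drop = FALSE]
    paste(fmt(Mp[upper.tri(Mp, diag = TRUE)]), collapse = ",")
  }
  rec <- function(rank) {
    rank <- wl(rank)
    ord <- order(rank)
    cls <- rank[ord]
    dup <- which(duplicated(cls) | duplicated(cls, fromLast = TRUE))
    if (!length(dup)) return(ord)
    members <- which(rank == cls[dup[1]])
    best <- NULL; best_key <- NULL
    for (m in members) {
      r2 <- rank - (seq_len(n) == m) * 0.5
      p <- rec(match(r2, sort(unique(r2))))
      key <- matrix_key(p)
      if (is.null(best_key) || key < best_key) {
        best_key <- key; best <- p
      }
    }
    best
  }

  ## initial colours ordered numerically by (primary, row norm, Z)
  ord0 <- order(primary, norms, z)
  tup <- paste(primary, fmt(norms), z)
  rank0 <- integer(n)
  rank0[ord0] <- cumsum(!duplicated(tup[ord0]))
  rec(rank0)
}

#' Canonically sort a representation matrix and its distance labels
#'
#' Reorders atoms by non-decreasing representation row norm (ties broken
#' deterministically and permutation-invariantly) and applies the SAME
#' permutation to the rows/columns of the distance matrix, so features and
#' regression labels stay aligned.
#'
#' @param rep_matrix Square symmetric representation matrix (heavy atoms).
#' @param distance_matrix Optional square distance matrix of equal dimension.
#' @param z Optional nuclear charges used in tie-breaking.
#' @return List with \code{rep_matrix}, \code{distance_matrix} (or NULL) and
#'   \code{permutation} (original indices in canonical order).
#' @export
canonical_sort <- function(rep_matrix, distance_matrix = NULL, z = NULL) {
  M <- as.matrix(rep_matrix)
  n <- nrow(M)
  if (ncol(M) != n) stop("rep_matrix must be square")
  if (is.null(z)) z <- rep(0L, n)
  if (!is.null(distance_matrix) && !all(dim(distance_matrix) == c(n, n)))
    stop("distance_matrix dimension mismatch")
  p <- .canonical_order(M, z)
  list(rep_matrix = M[p, p, drop = FALSE],
       distance_matrix = if (!is.null(distance_matrix))
         as.matrix(distance_matrix)[p, p, drop = FALSE] else NULL,
       permutation = p)
}

.pad_matrix <- function(M, n_max) {
  n <- nrow(M)
  if (n > n_max) stop("molecule has ", n, " heavy atoms, exceeding n_max = ",
                      n_max)
  out <- matrix(0, n_max, n_max)
  out[seq_len(n), seq_len(n)] <- M
  out
}

.flatten_upper <- function(M, diag = TRUE) M[upper.tri(M, diag = diag)]

.new_rep <- function(values, scheme, n_max, permutation, matrix = NULL) {
  structure(list(values = as.numeric(values), scheme = scheme,
                 n_max = n_max, permutation = permutation,
                 matrix = matrix),
            class = "g2s_rep")
}

#' @export
print.g2s_rep <- function(x, ...) {
  cat("<g2s_rep> scheme=", x$scheme, ", length=", length(x$values),
      ", n_max=", x$n_max, "\n", sep = "")
  invisible(x)
}

## shared worker for the matrix-valued schemes
.matrix_rep <- function(g, scheme, n_max) {
  zh <- g$nuclear_charges[g$heavy_indices]
  M <- .rep_matrix(g, scheme)
  cs <- canonical_sort(M, z = zh)
  padded <- .pad_matrix(cs$rep_matrix, n_max)
  .new_rep(.flatten_upper(padded), scheme, n_max, cs$permutation,
           cs$rep_matrix)
}

#' Bond-order representation
#'
#' Flattened upper triangle (diagonal included, zero) of the canonically
#' sorted heavy-atom bond-order matrix, zero-padded to \code{n_max} atoms.
#'
#' @param g A \code{molgraph}.
#' @param n_max Padding size (maximum heavy-atom count of the model).
#' @return A \code{g2s_rep}.
#' @export
bond_order_rep <- function(g, n_max) .matrix_rep(g, "bond_order", n_max)

#' Bond-hop representation
#'
#' Number of bonds along the shortest connecting path between every heavy
#' atom pair, canonically sorted and padded.
#'
#' @inheritParams bond_order_rep
#' @return A \code{g2s_rep}.
#' @export
bond_hop_rep <- function(g, n_max) .matrix_rep(g, "bond_hop", n_max)

#' Bond-length representation
#'
#' Total idealized bond length along the minimum-weight path between heavy
#' atoms, each edge weighted by the sum of the two covalent radii; paths
#' minimize the weighted sum, making the matrix a true metric.
#'
#' @inheritParams bond_order_rep
#' @return A \code{g2s_rep}.
#' @export
bond_length_rep <- function(g, n_max) .matrix_rep(g, "bond_length", n_max)

#' Graph Coulomb-matrix representation
#'
#' Coulomb-matrix analogue on the graph: diagonal \eqn{0.5 Z^{2.4}},
#' off-diagonal \eqn{Z_i Z_j / l_{ij}} with \eqn{l_{ij}} the bond-length
#' path metric, canonically sorted and padded.
#'
#' @inheritParams bond_order_rep
#' @return A \code{g2s_rep}.
#' @export
graph_cm_rep <- function(g, n_max) .matrix_rep(g, "graph_cm", n_max)

## bag keys of a molecule: diagonal -> element, off-diagonal -> element pair
.bob_entries <- function(g) {
  zh <- g$nuclear_charges[g$heavy_indices]
  CM <- .rep_matrix(g, "graph_cm")
  sym <- element_symbol(zh)
  n <- length(zh)
  keys <- character(0); vals <- numeric(0)
  for (i in seq_len(n)) {
    keys <- c(keys, sym[i]); vals <- c(vals, CM[i, i])
    if (i < n) for (j in (i + 1):n) {
      pair <- paste(sort(c(sym[i], sym[j])), collapse = "-")
      keys <- c(keys, pair); vals <- c(vals, CM[i, j])
    }
  }
  split(vals, keys)
}

#' Bag sizes of a training set for the graph Bag-of-Bonds representation
#'
#' Bag sizes (maximum per-bag entry counts over the training graphs) are part
#' of the fitted model state: they fix the representation length.
#'
#' @param graphs List of \code{molgraph}s.
#' @return Named integer vector of bag sizes, keys sorted alphabetically.
#' @export
bob_bag_sizes <- function(graphs) {
  sizes <- list()
  for (g in graphs) {
    b <- lengths(.bob_entries(g))
    for (k in names(b)) sizes[[k]] <- max(sizes[[k]] %||% 0L, b[[k]])
  }
  out <- unlist(sizes[order(names(sizes))])
  storage.mode(out) <- "integer"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Graph Bag-of-Bonds representation
#'
#' Graph Coulomb-matrix entries grouped into bags keyed by element (diagonal)
#' and element pair (off-diagonal), sorted descending within each bag and
#' zero-padded to the training bag sizes.
#'
#' @param g A \code{molgraph}.
#' @param bag_sizes Named integer vector from \code{\link{bob_bag_sizes}};
#'   if NULL, the molecule's own bag sizes are used.
#' @return A \code{g2s_rep} (field \code{bag_sizes} attached).
#' @export
graph_bob_rep <- function(g, bag_sizes = NULL) {
  entries <- .bob_entries(g)
  if (is.null(bag_sizes))
    bag_sizes <- bob_bag_sizes(list(g))
  oov <- setdiff(names(entries), names(bag_sizes))
  if (length(oov))
    stop("element (pair) bag(s) absent from training vocabulary: ",
         paste(oov, collapse = ", "))
  vals <- unlist(lapply(names(bag_sizes), function(k) {
    v <- sort(entries[[k]] %||% numeric(0), decreasing = TRUE)
    if (length(v) > bag_sizes[[k]]) {
      warning("bag '", k, "' overflows its training size (",
              length(v), " > ", bag_sizes[[k]], "); smallest entries dropped")
      v <- v[seq_len(bag_sizes[[k]])]
    }
    c(v, rep(0, bag_sizes[[k]] - length(v)))
  }))
  ## atom order for the paired distance labels: element-binned, then row norm
  zh <- g$nuclear_charges[g$heavy_indices]
  CM <- .rep_matrix(g, "graph_cm")
  p <- .canonical_order(CM, zh, primary = zh)
  out <- .new_rep(vals, "graph_bob", NA_integer_, p, CM[p, p, drop = FALSE])
  out$bag_sizes <- bag_sizes
  out
}

#' FLLA stoichiometry representation for elpasolite crystals
#'
#' Each representative site (fixed Wyckoff sequence A, B, C, D) is encoded by
#' its element's periodic-table row (principal quantum number) and number of
#' valence electrons, giving an 8-vector for ABC2D6.
#'
#' @param crystal A \code{crystal_record}.
#' @return A \code{g2s_rep} of length 8.
#' @export
flla_rep <- function(crystal) {
  pos <- .periodic_position(crystal$site_elements)
  vals <- as.numeric(t(pos))  # (period, valence) per site in Wyckoff order
  .new_rep(vals, "flla", NA_integer_, seq_len(4))
}

#' Featurize a molecular graph under a named scheme
#'
#' Dispatcher over the scheme enum used throughout the package
#' (\code{bond_order | bond_hop | bond_length | graph_cm | graph_bob}).
#'
#' @param g A \code{molgraph}.
#' @param scheme Scheme name.
#' @param n_max Padding size (matrix schemes).
#' @param bag_sizes Training bag sizes (graph_bob only).
#' @return A \code{g2s_rep}.
#' @export
represent <- function(g, scheme, n_max, bag_sizes = NULL) {
  scheme <- match.arg(scheme, setdiff(REP_SCHEMES, "flla"))
  if (scheme == "graph_bob") graph_bob_rep(g, bag_sizes)
  else .matrix_rep(g, scheme, n_max)
}

#' Heavy-atom distance targets in canonical order
#'
#' Upper-triangle heavy-atom pairwise distances of a geometry, reordered by
#' the SAME canonical permutation as the representation and zero-padded to
#' length \code{n_max (n_max - 1) / 2}.
#'
#' @param geom A \code{geometry_record} (atom order matching the graph).
#' @param g The \code{molgraph}.
#' @param rep The \code{g2s_rep} whose permutation is applied.
#' @param n_max Padding size.
#' @return Numeric vector of distances (Angstrom), padded entries zero.
#' @export
distance_targets <- function(geom, g, rep, n_max) {
  D <- distance_matrix(geom, heavy_only = FALSE)
  h <- g$heavy_indices
  Dh <- D[h, h, drop = FALSE]
  p <- rep$permutation
  Dp <- .pad_matrix(Dh[p, p, drop = FALSE], n_max)
  .flatten_upper(Dp, diag = FALSE)
}
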