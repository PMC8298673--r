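## Distance-geometry stage: recover Cartesian coordinates from (possibly
## noisy) pairwise distances, place hydrogens on a spherical grid, superpose
## and score structures, and convert fractional to Cartesian coordinates.
##
## The solver is a native two-stage scheme: classical metric embedding
## (double-centering, top-3 spectral components) for the initial guess,
## followed by SMACOF stress majorization of
##   stress(X) = sum_{i<j} (|r_i - r_j| - D_ij)^2 ,
## whose Guttman transform never increases the stress between iterations.

#' Embed a distance matrix into 3D coordinates
#'
#' @param D Symmetric matrix with zero diagonal and positive off-diagonals.
#' @param tol Relative stress-change convergence threshold (default 1e-10).
#' @param max_iter Maximum majorization iterations (default 500).
#' @return Object of class \code{embedding_result}: \code{coordinates}
#'   (n x 3), \code{stress}, \code{converged}, \code{n_iterations} and
#'   \code{stress_trace}.
#' @export
embed_distances <- function(D, tol = 1e-10, max_iter = 500) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 points to embed")
  if (ncol(D) != n || max(abs(D - t(D))) > 1e-8)
    stop("D must be a symmetric square matrix")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D[upper.tri(D)] <= 0)) stop("off-diagonal distances must be > 0")

  ## stage 1: classical MDS start
  X <- suppressWarnings(stats::cmdscale(D, k = 3))
  if (ncol(X) < 3L) X <- cbind(X, matrix(0, n, 3L - ncol(X)))

  stress_of <- function(X) {
    d <- as.matrix(dist(X))
    sum((d[upper.tri(d)] - D[upper.tri(D)])^2)
  }

  ## stage 2: SMACOF majorization
  s <- stress_of(X)
  trace <- s
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d <- as.matrix(dist(X))
    ratio <- matrix(0, n, n)
    nz <- d > 1e-12
    ratio[nz] <- D[nz] / d[nz]
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    sn <- stress_of(Xn)
    trace <- c(trace, sn)
    if (s - sn <= tol * max(s, .Machine$double.eps)) {
      X <- Xn; s <- sn; converged <- TRUE
      break
    }
    X <- Xn; s <- sn
  }
  structure(list(coordinates = unname(X), stress = s, converged = converged,
                 n_iterations = it, stress_trace = trace),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d points, stress %.3e, %s after %d iters\n",
              nrow(x$coordinates), x$stress,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Optimal superposition of two point sets (Kabsch algorithm)
#'
#' Finds the rigid motion (optionally including reflection) of \code{P} onto
#' \code{Q} minimizing the RMSD, with correspondence by row index.  Distance
#' matrices cannot fix handedness, so evaluation of embedded structures
#' should minimize over both enantiomers (\code{allow_reflection = TRUE});
#' reports flag which hand was used.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3).
#' @param allow_reflection Also consider the mirror image of \code{P}.
#' @return Object of class \code{superposition_report}: \code{rmsd},
#'   \code{rotation} (3 x 3, det +1 or -1), \code{reflection_used},
#'   \code{aligned} (transformed copy of P).
#' @export
kabsch_superpose <- function(P, Q, allow_reflection = FALSE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must both be n x 3")
  if (nrow(P) < 3L) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  ## best proper rotation: flip the smallest singular direction if needed
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  if (S[3, 3] == 0) S[3, 3] <- 1
  Rp <- sv$v %*% S %*% t(sv$u)
  Ap <- P0 %*% t(Rp)
  res <- list(rmsd = sqrt(mean(rowSums((Ap - Q0)^2))), rotation = Rp,
              reflection_used = FALSE,
              aligned = sweep(Ap, 2, cq, `+`))
  if (allow_reflection) {
    ## mirror P through the xy-plane, then best proper rotation of the mirror
    Pm <- P0 %*% diag(c(1, 1, -1))
    Hm <- crossprod(Pm, Q0)
    svm <- svd(Hm)
    Sm <- diag(c(1, 1, sign(det(svm$v %*% t(svm$u)))))
    if (Sm[3, 3] == 0) Sm[3, 3] <- 1
    Rm <- svm$v %*% Sm %*% t(svm$u)
    Am <- Pm %*% t(Rm)
    rmsd_m <- sqrt(mean(rowSums((Am - Q0)^2)))
    if (rmsd_m < res$rmsd) {
      res <- list(rmsd = rmsd_m,
                  rotation = Rm %*% diag(c(1, 1, -1)),  # net improper map
                  reflection_used = TRUE,
                  aligned = sweep(Am, 2, cq, `+`))
    }
  }
  structure(res, class = "superposition_report")
}

#' @export
print.superposition_report <- function(x, ...) {
  cat(sprintf("<superposition_report> RMSD %.6f A%s\n", x$rmsd,
              if (x$reflection_used) " (mirror image used)" else ""))
  invisible(x)
}

## tetrahedron volume of 4 points
.tetra_volume <- function(p) {
  abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6
}

#' Select the four anchor heavy atoms of each hydrogen
#'
#' The four closest heavy atoms are chosen, with the constraint that they
#' must not be (nearly) coplanar: if the tetrahedron they span has volume
#' below 0.1 cubic Angstrom, the farthest anchor is swapped for the nearest
#' non-coplanar replacement.  If no non-coplanar quadruple exists (e.g. a
#' linear scaffold) the coplanar set is kept and flagged.
#'
#' Two distance references are supported: \code{mode = "hydrogen"} measures
#' from the hydrogen itself (requires its coordinates, training-time rule);
#' \code{mode = "scaffold"} measures from the bonded heavy atom, which is
#' available both at training and at prediction time and is what the G2S
#' model uses so that target definitions match between the two.
#'
#' @param g A \code{molgraph}.
#' @param geom Geometry; with \code{mode = "hydrogen"} it must contain the
#'   hydrogens, with \code{mode = "scaffold"} heavy-atom coordinates suffice
#'   (n_heavy x 3 matrix in heavy-atom order is also accepted).
#' @param mode Anchor distance reference (see above).
#' @return Integer matrix (one row per hydrogen, in hydrogen index order) of
#'   up to 4 heavy-atom positions (indices into \code{g$heavy_indices});
#'   fewer columns if the molecule has fewer than 4 heavy atoms (with a
#'   warning).  Attribute \code{coplanar_flagged} lists rows where no
#'   non-coplanar quadruple exists.
#' @export
select_hydrogen_anchors <- function(g, geom, mode = c("scaffold", "hydrogen")) {
  mode <- match.arg(mode)
  heavy <- g$heavy_indices
  nh <- length(heavy)
  att <- g$hydrogen_attachments
  if (length(att) == 0L)
    return(matrix(integer(0), 0, min(4L, nh)))
  if (is.matrix(geom)) {
    if (mode == "hydrogen") stop("mode='hydrogen' needs a full geometry")
    Xh <- geom
  } else {
    Xh <- geom$coordinates[heavy, , drop = FALSE]
  }
  if (nrow(Xh) != nh) stop("scaffold coordinate count mismatch")
  k <- min(4L, nh)
  if (nh < 4L)
    warning("fewer than 4 heavy atoms: falling back to ", nh, "-anchor ",
            "hydrogen placement")
  flagged <- integer(0)
  out <- matrix(NA_integer_, length(att), k)
  for (r in seq_along(att)) {
    b <- match(att[r], heavy)             # bonded heavy, heavy-atom position
    ref <- if (mode == "hydrogen")
      geom$coordinates[as.integer(names(att))[r], ] else Xh[b, ]
    ## round before ordering so exact distance ties (common in idealized
    ## geometries) break by index, stably under numerical noise
    d <- round(sqrt(rowSums(sweep(Xh, 2, ref)^2)), 6)
    ord <- order(d, seq_len(nh))
    if (mode == "scaffold") ord <- c(b, setdiff(ord, b))  # bonded atom first
    sel <- ord[seq_len(k)]
    if (k == 4L) {
      vol <- .tetra_volume(Xh[sel, , drop = FALSE])
      if (vol < 0.1) {
        fixed <- FALSE
        for (cand in setdiff(ord, sel)) {
          trial <- c(sel[1:3], cand)
          if (.tetra_volume(Xh[trial, , drop = FALSE]) >= 0.1) {
            sel <- trial; fixed <- TRUE; break
          }
        }
        if (!fixed) flagged <- c(flagged, r)
      }
    }
    out[r, ] <- sel
  }
  rownames(out) <- names(att)
  attr(out, "coplanar_flagged") <- flagged
  out
}

#' Deterministic spherical grid (generalized spiral)
#'
#' Near-uniform unit-sphere covering used as the candidate set for hydrogen
#' placement; any fixed deterministic grid serves, since placement is an
#' argmin over grid points rather than a quadrature.
#'
#' @param n Number of points (default 4096).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_grid <- function(n = 4096) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Place hydrogens on spherical grids around their bonded heavy atoms
#'
#' Each hydrogen is placed at the point of a deterministic spherical grid --
#' centered on its bonded heavy atom, radius equal to the predicted bond
#' distance -- that minimizes the squared error to the remaining anchor
#' distances plus a clash penalty against already-placed hydrogens.
#' Hydrogens are placed sequentially in index order; exact ties fall to the
#' smallest grid index.
#'
#' @param scaffold n_heavy x 3 matrix of heavy-atom coordinates (heavy-atom
#'   order of \code{g}).
#' @param g A \code{molgraph}.
#' @param h_distances Matrix (one row per hydrogen, in hydrogen index order)
#'   of predicted distances to the anchors; column 1 is the bond distance to
#'   the bonded heavy atom.
#' @param anchors Anchor index matrix from
#'   \code{\link{select_hydrogen_anchors}} (defaults to the scaffold rule).
#' @param grid_size Number of spherical grid points (default 4096).
#' @param clash_distance Hydrogen-hydrogen distance (Angstrom) below which
#'   the clash penalty applies (default 1.0).
#' @return Full n x 3 coordinate matrix in the atom order of \code{g}.
#' @export
place_hydrogens <- function(scaffold, g, h_distances, anchors = NULL,
                            grid_size = 4096, clash_distance = 1.0) {
  heavy <- g$heavy_indices
  att <- g$hydrogen_attachments
  n <- length(g$nuclear_charges)
  X <- matrix(NA_real_, n, 3)
  X[heavy, ] <- as.matrix(scaffold)
  if (length(att) == 0L) return(X)
  if (is.null(anchors))
    anchors <- select_hydrogen_anchors(g, as.matrix(scaffold),
                                       mode = "scaffold")
  h_distances <- as.matrix(h_distances)
  if (nrow(h_distances) != length(att))
    stop("h_distances must have one row per hydrogen")
  grid <- sphere_grid(grid_size)
  placed_h <- matrix(numeric(0), 0, 3)
  for (r in seq_along(att)) {
    h_idx <- as.integer(names(att))[r]
    b <- match(att[r], heavy)
    radius <- h_distances[r, 1]
    center <- X[heavy[b], ]
    ks <- seq_len(min(ncol(anchors), ncol(h_distances)))
    point_obj <- function(P) {
      o <- numeric(nrow(P))
      for (k in ks[-1]) {
        a <- anchors[r, k]
        da <- sqrt(rowSums(sweep(P, 2, X[heavy[a], ])^2))
        o <- o + (da - h_distances[r, k])^2
      }
      if (nrow(placed_h)) for (q in seq_len(nrow(placed_h))) {
        dq <- sqrt(rowSums(sweep(P, 2, placed_h[q, ])^2))
        o <- o + 10 * pmax(0, clash_distance - dq)^2
      }
      o
    }
    cand <- sweep(grid * radius, 2, center, `+`)
    obj <- point_obj(cand)
    best <- which.min(obj)       # ties: smallest grid index
    ## continuous on-sphere refinement from the best grid point and from the
    ## best point of the opposite basin (> 45 deg away), so near-coplanar
    ## anchor sets cannot trap the argmin on the wrong mirror side
    refine <- function(start_idx) {
      u0 <- grid[start_idx, ]
      th0 <- acos(max(-1, min(1, u0[3]))); ph0 <- atan2(u0[2], u0[1])
      o <- stats::optim(c(th0, ph0), function(p) {
        u <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
        point_obj(matrix(center + radius * u, 1))
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 400))
      u <- c(sin(o$par[1]) * cos(o$par[2]), sin(o$par[1]) * sin(o$par[2]),
             cos(o$par[1]))
      list(p = center + radius * u, value = o$value)
    }
    r1 <- refine(best)
    far <- which(grid %*% grid[best, ] < cos(pi / 4))
    sol <- r1
    if (length(far)) {
      alt <- far[which.min(obj[far])]
      r2 <- refine(alt)
      if (r2$value < r1$value - 1e-12) sol <- r2
    }
    X[h_idx, ] <- sol$p
    placed_h <- rbind(placed_h, sol$p)
  }
  X
}

#' Convert fractional to Cartesian coordinates (cubic cell)
#'
#' @param crystal A \code{crystal_record}.
#' @return m x 3 matrix of Cartesian coordinates in Angstrom,
#'   \eqn{r = a \cdot r_{frac}}.
#' @export
frac_to_cartesian <- function(crystal) {
  crystal$lattice_constant * crystal$fractional_coords
}
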