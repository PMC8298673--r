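## Synthetic fixture generator.
##
## The generator emulates a family of constitutional isomers: a fixed heavy-
## atom stoichiometry, varying bonding connectivity (trees and single rings,
## all single bonds), with every graph mapped to EXACTLY ONE deterministic
## minimum-like geometry.  Geometries are built from idealized internal
## coordinates -- bond lengths equal to sums of covalent radii, ideal
## hybridization angles, canonical anti torsions, hydrogens completed
## geometrically -- so the graph -> geometry map is a pure function with no
## conformational ambiguity and no chemistry-engine dependency.

## run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

## hybridization of each heavy atom from its bond orders:
## triple or two doubles -> sp, one double -> sp2, else sp3
.hybridization <- function(Bh) {
  vapply(seq_len(nrow(Bh)), function(i) {
    ord <- Bh[i, ]
    if (any(ord == 3L) || sum(ord == 2L) >= 2L) "sp"
    else if (any(ord == 2L)) "sp2"
    else "sp3"
  }, character(1))
}

.TETRA_ANGLE <- acos(-1 / 3)  # 109.4712 deg

## ideal direction set in a canonical orientation (used for unplaced roots)
.ideal_set <- function(hyb) {
  switch(hyb,
    sp3 = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3),
    sp2 = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)),
    sp  = rbind(c(1, 0, 0), c(-1, 0, 0)))
}

## free bonding directions at atom p given unit vectors U (rows) toward its
## already-placed neighbors.  ref is an optional reference point defining the
## torsion zero (the anti rule); deterministic in all branches.
.free_directions <- function(U, hyb, ref_vec = NULL) {
  m <- nrow(U)
  if (m == 0L) return(.ideal_set(hyb))
  if (m == 1L) {
    e1 <- .unit(U[1, ])
    v <- if (!is.null(ref_vec)) ref_vec else c(0, 0, 1)
    v <- v - sum(v * e1) * e1
    if (sqrt(sum(v^2)) < 1e-8) {
      v <- c(0, 1, 0) - sum(c(0, 1, 0) * e1) * e1
      if (sqrt(sum(v^2)) < 1e-8) v <- c(0, 0, 1) - sum(c(0, 0, 1) * e1) * e1
    }
    e2 <- .unit(v)
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    spec <- switch(hyb,
      sp3 = list(theta = .TETRA_ANGLE, phi = c(180, 60, -60) * pi / 180),
      sp2 = list(theta = 2 * pi / 3, phi = c(180, 0) * pi / 180),
      sp  = list(theta = pi, phi = 0))
    t(vapply(spec$phi, function(phi) {
      cos(spec$theta) * e1 +
        sin(spec$theta) * (cos(phi) * e2 + sin(phi) * e3)
    }, numeric(3)))
  } else if (m == 2L) {
    s <- U[1, ] + U[2, ]
    b <- if (sqrt(sum(s^2)) < 1e-8) {
      ## nearly linear neighbors: any perpendicular, chosen canonically
      e1 <- .unit(U[1, ])
      p <- c(0, 0, 1) - sum(c(0, 0, 1) * e1) * e1
      if (sqrt(sum(p^2)) < 1e-8) p <- c(0, 1, 0) - sum(c(0, 1, 0) * e1) * e1
      .unit(p)
    } else .unit(-s)
    if (hyb == "sp2" || hyb == "sp") return(rbind(b))
    nrm <- c(U[1, 2] * U[2, 3] - U[1, 3] * U[2, 2],
             U[1, 3] * U[2, 1] - U[1, 1] * U[2, 3],
             U[1, 1] * U[2, 2] - U[1, 2] * U[2, 1])
    if (sqrt(sum(nrm^2)) < 1e-8) {
      e1 <- .unit(U[1, ])
      nrm <- c(e1[2] * b[3] - e1[3] * b[2],
               e1[3] * b[1] - e1[1] * b[3],
               e1[1] * b[2] - e1[2] * b[1])
    }
    nrm <- .unit(nrm)
    beta <- .TETRA_ANGLE / 2
    rbind(.unit(cos(beta) * b + sin(beta) * nrm),
          .unit(cos(beta) * b - sin(beta) * nrm))
  } else {
    rbind(.unit(-colSums(U)))
  }
}

## cyclic-polygon coordinates for a ring with given edge lengths, planar (xy)
.ring_coordinates <- function(lengths) {
  k <- length(lengths)
  f <- function(R) sum(2 * asin(pmin(1, lengths / (2 * R)))) - 2 * pi
  Rmin <- max(lengths) / 2 * (1 + 1e-12)
  if (f(Rmin) < 0)
    stop("ring with edge lengths ", paste(round(lengths, 2), collapse = ","),
         " is not realizable as a cyclic polygon")
  R <- stats::uniroot(f, c(Rmin, sum(lengths)), tol = 1e-14)$root
  ang <- cumsum(c(0, 2 * asin(lengths[-k] / (2 * R))))
  cbind(R * cos(ang), R * sin(ang), 0)
}

#' Build the deterministic idealized geometry of a molecular graph
#'
#' Constructs one minimum-like 3D structure from connectivity alone: bond
#' lengths are sums of the pinned covalent radii, bond angles follow the
#' atom's hybridization (tetrahedral / trigonal / linear), torsions follow a
#' canonical anti rule, rings are laid out as planar cyclic polygons, and
#' hydrogens fill the remaining coordination slots geometrically.  The map
#' graph -> geometry is a pure function: repeated calls are bit-identical.
#' Heavy-atom subgraphs must be connected trees or single-ring graphs.
#'
#' @param g A \code{molgraph}.
#' @return A \code{geometry_record} in the same atom order as \code{g}.
#' @export
build_ideal_geometry <- function(g) {
  z <- g$nuclear_charges
  heavy <- g$heavy_indices
  nh <- length(heavy)
  Bh <- .heavy_bonds(g)
  r <- covalent_radius(z)
  hyb <- .hybridization(Bh)

  nedge <- sum(Bh > 0L) / 2
  coords_h <- matrix(NA_real_, nh, 3)

  if (nh == 1L) {
    coords_h[1, ] <- 0
  } else {
    gi <- igraph::graph_from_adjacency_matrix(Bh > 0L, mode = "undirected")
    if (!igraph::is_connected(gi))
      stop("heavy-atom subgraph must be connected")
    if (nedge > nh)
      stop("only trees and single-ring graphs are supported")

    if (nedge == nh) {  # exactly one cycle
      cyc <- igraph::girth(gi)$circle
      cyc <- as.integer(cyc)
      ## canonical ring orientation: start at smallest index, walk toward its
      ## smaller-indexed ring neighbor
      s <- which.min(cyc)
      cyc <- c(cyc[s:length(cyc)], cyc[seq_len(s - 1L)])
      if (length(cyc) > 2L && cyc[2] > cyc[length(cyc)])
        cyc <- c(cyc[1], rev(cyc[-1]))
      k <- length(cyc)
      lens <- r[heavy[cyc]] + r[heavy[c(cyc[-1], cyc[1])]]
      coords_h[cyc, ] <- .ring_coordinates(lens)
      queue <- cyc
    } else {
      root <- 1L
      nb <- which(Bh[root, ] > 0L)[1]
      coords_h[root, ] <- 0
      coords_h[nb, ] <- c(r[heavy[root]] + r[heavy[nb]], 0, 0)
      queue <- c(root, nb)
    }

    placed <- !is.na(coords_h[, 1])
    qi <- 1L
    while (qi <= length(queue)) {
      p <- queue[qi]; qi <- qi + 1L
      nbs <- which(Bh[p, ] > 0L)
      todo <- nbs[!placed[nbs]]
      if (length(todo)) {
        done <- nbs[placed[nbs]]
        U <- t(vapply(done, function(q) .unit(coords_h[q, ] - coords_h[p, ]),
                      numeric(3)))
        ref_vec <- NULL
        if (length(done) == 1L) {
          ## anti-torsion reference: a placed neighbor of the parent
          gp <- done[1]
          cand <- setdiff(which(Bh[gp, ] > 0L & placed), p)
          if (length(cand))
            ref_vec <- coords_h[min(cand), ] - coords_h[gp, ]
        }
        dirs <- .free_directions(U, hyb[p], ref_vec)
        if (nrow(dirs) < length(todo))
          stop("atom ", p, " has more neighbors than coordination slots")
        todo <- sort(todo)
        for (k in seq_along(todo)) {
          c_ <- todo[k]
          coords_h[c_, ] <- coords_h[p, ] +
            (r[heavy[p]] + r[heavy[c_]]) * dirs[k, ]
          placed[c_] <- TRUE
          queue <- c(queue, c_)
        }
      }
    }
    if (any(!placed)) stop("internal error: unplaced heavy atoms")
  }

  ## hydrogens: fill remaining coordination slots, atoms in index order
  n <- length(z)
  coords <- matrix(NA_real_, n, 3)
  coords[heavy, ] <- coords_h
  att <- g$hydrogen_attachments
  if (length(att)) {
    for (p in sort(unique(att))) {
      hp <- match(p, heavy)
      hs <- as.integer(names(att))[att == p]
      done <- which(g$bond_order_matrix[p, ] > 0L & z > 1L)
      U <- if (length(done))
        t(vapply(done, function(q) .unit(coords[q, ] - coords[p, ]),
                 numeric(3)))
      else matrix(numeric(0), 0, 3)
      ref_vec <- NULL
      if (length(done) == 1L) {
        gp <- done[1]
        cand <- setdiff(which(g$bond_order_matrix[gp, ] > 0L & z > 1L), p)
        if (length(cand)) ref_vec <- coords[min(cand), ] - coords[gp, ]
      }
      dirs <- .free_directions(U, hyb[hp], ref_vec)
      if (nrow(dirs) < length(hs))
        stop("atom ", p, " cannot host ", length(hs), " hydrogens")
      bl <- r[p] + r[hs[1]]
      for (k in seq_along(hs))
        coords[sort(hs)[k], ] <- coords[p, ] + bl * dirs[k, ]
    }
  }
  geometry_record(z, coords, check_clash = FALSE)
}

## canonical isomorphism key of a heavy-atom graph (BLISS via igraph)
.canonical_heavy_order <- function(zh, Bh) {
  gi <- igraph::graph_from_adjacency_matrix(Bh > 0L, mode = "undirected")
  colors <- match(zh, sort(unique(zh)))
  cp <- igraph::canonical_permutation(gi, colors = colors)$labeling
  order(cp)  # ord[k] = original index of the k-th canonical vertex
}

.graph_key <- function(zh, Bh) {
  ord <- .canonical_heavy_order(zh, Bh)
  Bc <- Bh[ord, ord, drop = FALSE]
  paste(c(zh[ord], Bc[upper.tri(Bc)]), collapse = ",")
}

## expand a heavy graph (zh, Bh) into a full molgraph with explicit hydrogens
## saturating standard valences; heavy atoms first, hydrogens grouped by atom
.saturate_graph <- function(zh, Bh) {
  nh <- length(zh)
  deg <- rowSums(Bh)
  n_h_per <- .standard_valence(zh) - deg
  if (any(n_h_per < 0)) stop("valence exceeded")
  n <- nh + sum(n_h_per)
  z <- c(zh, rep(1L, sum(n_h_per)))
  B <- matrix(0L, n, n)
  B[seq_len(nh), seq_len(nh)] <- Bh
  hidx <- nh
  for (p in seq_len(nh)) {
    if (n_h_per[p] > 0) for (k in seq_len(n_h_per[p])) {
      hidx <- hidx + 1L
      B[p, hidx] <- B[hidx, p] <- 1L
    }
  }
  molecular_graph(z, B)
}

## Prufer decode: edges of the labeled tree for sequence a over n nodes
.prufer_tree <- function(a, n) {
  degree <- rep(1L, n)
  for (v in a) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2)
  ptr <- 0L
  leaf_set <- which(degree == 1L)
  for (k in seq_along(a)) {
    leaf <- min(leaf_set)
    v <- a[k]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, v)
    leaf_set <- setdiff(leaf_set, leaf)
    degree[v] <- degree[v] - 1L
    if (degree[v] == 1L) leaf_set <- c(leaf_set, v)
  }
  u <- leaf_set
  edges[n - 1L, ] <- c(min(u), max(u))
  edges
}

#' Generate a family of constitutional-isomer fixtures
#'
#' Emits \code{count} distinct heavy-atom connectivities (trees and single
#' rings, all single bonds) over a fixed stoichiometry, each paired with its
#' unique deterministic idealized geometry (see
#' \code{\link{build_ideal_geometry}}).  Graphs are emitted in a canonical
#' atom order; two isomorphic graphs can never appear twice.  The same
#' \code{(stoichiometry, seed)} always yields a bit-identical fixture set.
#'
#' @param n_heavy Number of heavy atoms (4 to 9).
#' @param stoichiometry Named integer vector of heavy-element counts, e.g.
#'   \code{c(C = 7, O = 2)}; must sum to \code{n_heavy}.
#' @param count Number of distinct connectivities requested.
#' @param seed Integer seed; the only source of randomness.
#' @param ring_fraction Probability of attempting a ring closure on each
#'   sampled tree (default 0.4).
#' @return List of \code{list(graph, geometry)} pairs of length \code{count}.
#' @export
generate_fixture_family <- function(n_heavy, stoichiometry, count, seed,
                                    ring_fraction = 0.4) {
  stopifnot(n_heavy >= 4L, n_heavy <= 9L, count >= 1L)
  sto <- stoichiometry
  if (is.null(names(sto)) || any(!nzchar(names(sto))))
    stop("stoichiometry must be a named vector, e.g. c(C = 7, O = 2)")
  if (sum(sto) != n_heavy)
    stop("stoichiometry sums to ", sum(sto), ", not n_heavy = ", n_heavy)
  zh <- as.integer(element_number(rep(names(sto), times = sto)))
  val <- .standard_valence(zh)
  if (sum(val) < 2 * (n_heavy - 1L))
    stop("stoichiometry not realizable with standard valences")

  .with_seed(seed, function() {
    seen <- new.env(parent = emptyenv())
    out <- vector("list", count)
    found <- 0L
    stale <- 0L
    stale_limit <- max(2000L, 50L * count)
    while (found < count) {
      if (stale >= stale_limit)
        stop("requested ", count, " distinct connectivities but only ",
             found, " are realizable for this stoichiometry")
      stale <- stale + 1L
      edges <- if (n_heavy == 2L) matrix(c(1L, 2L), 1) else
        .prufer_tree(sample.int(n_heavy, n_heavy - 2L, replace = TRUE),
                     n_heavy)
      B <- matrix(0L, n_heavy, n_heavy)
      B[edges] <- 1L; B[edges[, 2:1, drop = FALSE]] <- 1L
      if (any(rowSums(B) > val)) next
      if (stats::runif(1) < ring_fraction) {
        free <- which(rowSums(B) < val)
        if (length(free) >= 2L) {
          cand <- which(upper.tri(B) & !B, arr.ind = TRUE)
          cand <- cand[cand[, 1] %in% free & cand[, 2] %in% free, ,
                       drop = FALSE]
          if (nrow(cand)) {
            pick <- cand[sample.int(nrow(cand), 1L), ]
            B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1L
          }
        }
      }
      key <- .graph_key(zh, B)
      if (!is.null(seen[[key]])) next
      ord <- .canonical_heavy_order(zh, B)
      g <- try(.saturate_graph(zh[ord], B[ord, ord, drop = FALSE]),
               silent = TRUE)
      if (inherits(g, "try-error")) { seen[[key]] <- TRUE; next }
      geom <- try(build_ideal_geometry(g), silent = TRUE)
      if (inherits(geom, "try-error") ||
          min(dist(geom$coordinates)) < 0.7) {
        ## geometry sterically clashed at ideal angles (not minimum-like):
        ## the connectivity is excluded from the family, deterministically
        seen[[key]] <- TRUE
        next
      }
      seen[[key]] <- TRUE
      found <- found + 1L
      stale <- 0L
      out[[found]] <- list(graph = g, geometry = geom)
    }
    out
  })
}

#' Generate synthetic elpasolite crystal fixtures
#'
#' Emits distinct ABC2D6 stoichiometries with ideal elpasolite fractional
#' sites.  The lattice constant is a smooth, strictly increasing function of
#' the covalent-radius size proxies of the four site elements,
#' \deqn{a_0 = 2 r_A + 2 r_B + 0.4 r_C + 4 r_D,}
#' plus seeded Gaussian noise of scale \code{noise_sd} emulating relaxation
#' scatter.  The halide-site coordinate is set from the A--D bond length,
#' \eqn{x_D = (r_A + r_D) / a_0}.
#'
#' @param element_pool Named list with character vectors \code{A}, \code{B},
#'   \code{C}, \code{D} of candidate main-group elements per site.
#' @param count Number of distinct stoichiometries.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of lattice-constant noise in Angstrom
#'   (default 0.1).
#' @return List of \code{crystal_record}s; attributes \code{noise_sd} and
#'   \code{clean_lattice} record the generator's noise scale and noise-free
#'   lattice constants.
#' @export
generate_crystal_fixtures <- function(element_pool = list(
                                        A = c("B", "Al", "Ga", "In", "Tl"),
                                        B = c("Li", "Na", "K", "Rb", "Cs"),
                                        C = c("Li", "Na", "K", "Rb", "Cs"),
                                        D = c("F", "Cl", "Br", "I")),
                                      count, seed, noise_sd = 0.1) {
  stopifnot(all(c("A", "B", "C", "D") %in% names(element_pool)))
  combos <- expand.grid(A = element_pool$A, B = element_pool$B,
                        C = element_pool$C, D = element_pool$D,
                        stringsAsFactors = FALSE)
  ## B and C are both monovalent cation sites; identical (B, C) pairs swapped
  ## describe different site occupations and are kept distinct.
  if (count > nrow(combos))
    stop("requested ", count, " distinct stoichiometries but the pool only ",
         "admits ", nrow(combos))
  .with_seed(seed, function() {
    idx <- sample.int(nrow(combos), count)
    noise <- stats::rnorm(count, 0, noise_sd)
    clean <- numeric(count)
    recs <- vector("list", count)
    for (k in seq_len(count)) {
      e <- as.character(combos[idx[k], ])
      r <- covalent_radius(element_number(e))
      a0 <- 2 * r[1] + 2 * r[2] + 0.4 * r[3] + 4 * r[4]
      clean[k] <- a0
      x_d <- (r[1] + r[4]) / a0
      recs[[k]] <- crystal_record(e, a0 + noise[k],
                                  .elpasolite_template(x_d))
    }
    attr(recs, "noise_sd") <- noise_sd
    attr(recs, "clean_lattice") <- clean
    recs
  })
}

#' Closed-form noise-free lattice constant of the crystal fixture generator
#'
#' Exposed so tests can verify monotonicity of the generator against its own
#' closed form.
#'
#' @param site_elements Character vector of length 4.
#' @return Lattice constant in Angstrom (noise-free).
#' @export
fixture_lattice_form <- function(site_elements) {
  r <- covalent_radius(element_number(site_elements))
  unname(2 * r[1] + 2 * r[2] + 0.4 * r[3] + 4 * r[4])
}
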