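## Distance-geometry embedding, superposition, hydrogen placement.

test_that("the unit square embeds exactly", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  D <- as.matrix(dist(P))
  emb <- embed_distances(D)
  Dhat <- as.matrix(dist(emb$coordinates))
  expect_lt(max(abs(Dhat - D)), 1e-8)
  expect_true(emb$converged)
})

test_that("exact distances from random point sets are recovered below 1e-6", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:9, 1)
    P <- matrix(rnorm(3 * n), n) * 2
    emb <- embed_distances(as.matrix(dist(P)))
    sup <- kabsch_superpose(emb$coordinates, P, allow_reflection = TRUE)
    expect_lt(sup$rmsd, 1e-6)
    expect_true(all(diff(emb$stress_trace) <= 1e-12))
  }
})

test_that("fixture geometries are self-consistently embeddable", {
  for (f in fixture_family(10)[c(1, 5, 9)]) {
    D <- distance_matrix(f$geometry, heavy_only = TRUE)
    emb <- embed_distances(D)
    ref <- f$geometry$coordinates[f$graph$heavy_indices, ]
    expect_lt(kabsch_superpose(emb$coordinates, ref,
                               allow_reflection = TRUE)$rmsd, 1e-6)
  }
})

test_that("noisy distances embed with bounded stress and drift", {
  set.seed(17)
  ## a rigid cage: cube corners plus center
  P <- rbind(expand.grid(c(0, 1.5), c(0, 1.5), c(0, 1.5)),
             c(0.75, 0.75, 0.75))
  P <- as.matrix(P)
  D <- as.matrix(dist(P))
  for (k in 1:5) {
    noise <- matrix(rnorm(length(D), 0, 0.01), nrow(D))
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    Dn <- D * (1 + noise)
    emb <- embed_distances(Dn)
    expect_lt(emb$stress, sum((Dn - D)^2))  # bounded by the injected noise
    expect_lt(kabsch_superpose(emb$coordinates, P,
                               allow_reflection = TRUE)$rmsd, 0.1)
  }
})

test_that("embed_distances validates its input", {
  expect_error(embed_distances(matrix(0, 2, 2)), "at least 3")
  M <- matrix(runif(9), 3); diag(M) <- 0
  expect_error(embed_distances(M), "symmetric")
  D <- matrix(1, 3, 3); diag(D) <- 2
  expect_error(embed_distances(D), "zero diagonal")
})

test_that("kabsch superposition recovers rigid motions and flags mirrors", {
  set.seed(23)
  for (k in 1:10) {
    P <- matrix(rnorm(18), 6)
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0),
                c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    Q <- P %*% t(Rz %*% Rx) + matrix(runif(3), 6, 3, byrow = TRUE)
    s <- kabsch_superpose(P, Q)
    expect_lt(s$rmsd, 1e-10)
    expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-10)
  }
  ## chirality: a mirrored chiral set only superposes with reflection
  P <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.2, 0), c(0, 0, 1.1),
             c(0.9, 0.8, 0.7))
  Pm <- P %*% diag(c(1, 1, -1))
  expect_gt(kabsch_superpose(Pm, P, allow_reflection = FALSE)$rmsd, 0.1)
  s2 <- kabsch_superpose(Pm, P, allow_reflection = TRUE)
  expect_lt(s2$rmsd, 1e-10)
  expect_true(s2$reflection_used)
  ## reflection-minimized RMSD never exceeds the rotation-only RMSD
  for (k in 1:5) {
    A <- matrix(rnorm(15), 5); B <- matrix(rnorm(15), 5)
    expect_lte(kabsch_superpose(A, B, TRUE)$rmsd,
               kabsch_superpose(A, B, FALSE)$rmsd + 1e-12)
  }
})

test_that("kabsch RMSD matches a rotation-grid search oracle", {
  P <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.3, 1.2, 0), c(0.5, 0.4, 1.3))
  Q <- rbind(c(0.1, 0, 0), c(1.5, 0.2, 0), c(0.2, 1.3, 0.1),
             c(0.4, 0.5, 1.2))
  rmsd_of <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    R <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  ## coarse exhaustive grid over Euler angles, then local polish
  grid <- as.matrix(expand.grid(seq(0, 2 * pi, length.out = 19)[-19],
                                seq(0, pi, length.out = 10),
                                seq(0, 2 * pi, length.out = 19)[-19]))
  vals <- apply(grid, 1, rmsd_of)
  start <- grid[which.min(vals), ]
  oracle <- stats::optim(start, rmsd_of,
                         control = list(reltol = 1e-14, maxit = 2000))$value
  expect_equal(kabsch_superpose(P, Q)$rmsd, oracle, tolerance = 1e-3)
})

test_that("hydrogen anchors are the nearest non-coplanar heavy quadruple", {
  f <- fixture_family(10)[[1]]
  g <- f$graph
  anch <- select_hydrogen_anchors(g, f$geometry, mode = "hydrogen")
  att <- g$hydrogen_attachments
  Xh <- f$geometry$coordinates[g$heavy_indices, ]
  flagged <- attr(anch, "coplanar_flagged")
  for (r in seq_along(att)) {
    hx <- f$geometry$coordinates[as.integer(names(att))[r], ]
    d <- sqrt(rowSums(sweep(Xh, 2, hx)^2))
    ## anchors always include the bonded atom; where a non-coplanar
    ## quadruple exists the set spans volume >= 0.1 A^3, otherwise the row
    ## is flagged and keeps the four nearest atoms
    expect_true(match(att[r], g$heavy_indices) %in% anch[r, ])
    if (r %in% flagged) {
      expect_setequal(anch[r, ], order(round(d, 6), seq_along(d))[1:4])
    } else {
      expect_gte(g2s:::.tetra_volume(Xh[anch[r, ], ]), 0.1)
    }
  }
  ## methanol has 2 heavy atoms: falls back with a warning
  meoh <- parse_smiles("CO")
  geo <- build_ideal_geometry(meoh)
  expect_warning(a2 <- select_hydrogen_anchors(meoh, geo, mode = "hydrogen"),
                 "fewer than 4")
  expect_equal(ncol(a2), 2)

  ## a linear 4-heavy chain is coplanar: the swap cannot succeed, flagged
  but_g <- parse_smiles("C#CC#C")  # strictly linear by hybridization
  but_geo <- build_ideal_geometry(but_g)
  a3 <- suppressWarnings(select_hydrogen_anchors(but_g, but_geo,
                                                 mode = "hydrogen"))
  expect_true(length(attr(a3, "coplanar_flagged")) > 0)

  ## invariance: anchors track atoms, not input order
  set.seed(31)
  p <- sample(length(g$nuclear_charges))
  gp <- molecular_graph(g$nuclear_charges[p], g$bond_order_matrix[p, p])
  gpm <- geometry_record(g$nuclear_charges[p], f$geometry$coordinates[p, ],
                         check_clash = FALSE)
  ap <- select_hydrogen_anchors(gp, gpm, mode = "hydrogen")
  ## map back: anchor atoms (as original ids) must match per hydrogen
  orig_h <- as.integer(names(g$hydrogen_attachments))
  perm_h <- as.integer(names(gp$hydrogen_attachments))
  for (r in seq_along(orig_h)) {
    rp <- which(p[perm_h] == orig_h[r])
    orig_atoms <- sort(g$heavy_indices[anch[r, ]])
    perm_atoms <- sort(p[gp$heavy_indices[ap[rp, ]]])
    expect_equal(perm_atoms, orig_atoms)
  }
})

test_that("hydrogens are placed on-radius and recover exact fixtures", {
  f <- fixture_family(10)[[6]]
  g <- f$graph
  att <- g$hydrogen_attachments
  scaf <- f$geometry$coordinates[g$heavy_indices, ]
  anch <- select_hydrogen_anchors(g, scaf)
  hd <- t(vapply(seq_along(att), function(r) {
    hx <- f$geometry$coordinates[as.integer(names(att))[r], ]
    vapply(seq_len(ncol(anch)), function(k)
      sqrt(sum((hx - scaf[anch[r, k], ])^2)), numeric(1))
  }, numeric(ncol(anch))))
  X <- place_hydrogens(scaf, g, hd, anchors = anch)
  herr <- sqrt(rowSums((X[as.integer(names(att)), ] -
                        f$geometry$coordinates[as.integer(names(att)), ])^2))
  expect_lt(max(herr), 0.05)
  ## the bond radius is honored exactly up to float rounding
  for (r in seq_along(att)) {
    b <- att[r]
    got <- sqrt(sum((X[as.integer(names(att))[r], ] - X[b, ])^2))
    expect_equal(got, hd[r, 1], tolerance = 1e-9)
  }
})

test_that("fractional to Cartesian conversion is a pure scaling", {
  cr <- crystal_record(c("Al", "Na", "K", "F"), 1)
  expect_equal(frac_to_cartesian(cr), cr$fractional_coords)
  cr8 <- crystal_record(c("Al", "Na", "K", "F"), 8,
                        fractional_coords = rbind(c(0.5, 0.5, 0.5)))
  expect_equal(frac_to_cartesian(cr8)[1, ], c(4, 4, 4))
  cr2 <- crystal_record(c("Al", "Na", "K", "F"), 2 * 8,
                        fractional_coords = rbind(c(0.5, 0.5, 0.5),
                                                  c(0.25, 0, 0)))
  expect_equal(as.matrix(dist(frac_to_cartesian(cr2)))[1, 2],
               2 * as.matrix(dist(8 * cr2$fractional_coords))[1, 2])
})
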