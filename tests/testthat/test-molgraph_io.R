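## Data model, file formats and the synthetic fixture generators.

test_that("molecular_graph enforces its invariants", {
  B <- matrix(0L, 2, 2); B[1, 2] <- B[2, 1] <- 1L
  g <- molecular_graph(c(6, 1), B)
  expect_equal(g$heavy_indices, 1L)
  expect_equal(unname(g$hydrogen_attachments), 1L)

  expect_error(molecular_graph(c(6, 1), matrix(c(0L, 1L, 0L, 0L), 2)),
               "symmetric")
  B4 <- matrix(0L, 2, 2); B4[1, 2] <- B4[2, 1] <- 4L
  expect_error(molecular_graph(c(6, 6), B4), "kekulized")
  Bh2 <- matrix(c(0L, 2L, 2L, 0L), 2)
  expect_error(molecular_graph(c(6, 1), Bh2), "single bond")
})

test_that("XYZ files round-trip and malformed inputs are rejected", {
  tf <- tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule",
               "H 0 0 0", "H 0 0 0.74"), tf)
  geom <- read_xyz(tf)
  expect_equal(geom$nuclear_charges, c(1L, 1L))
  expect_equal(distance_matrix(geom)[1, 2], 0.74)

  f <- fixture_family(10)[[4]]
  out <- tempfile(fileext = ".xyz")
  write_xyz(f$geometry, out, comment = "fixture")
  back <- read_xyz(out)
  expect_equal(back$nuclear_charges, f$geometry$nuclear_charges)
  expect_lt(max(abs(back$coordinates - f$geometry$coordinates)), 1e-6)
  ## second round trip is exact
  out2 <- tempfile(fileext = ".xyz")
  write_xyz(back, out2)
  expect_identical(readLines(out)[-2], readLines(out2)[-2])

  bad <- tempfile(fileext = ".xyz")
  writeLines(c("not_a_count", "x", "H 0 0 0"), bad)
  expect_error(read_xyz(bad), "count line")
  short <- tempfile(fileext = ".xyz")
  writeLines(c("5", "x", "H 0 0 0"), short)
  expect_error(read_xyz(short), "announces")
})

test_that("SDF write/read preserves graphs and geometries", {
  fx <- fixture_family(10)[1:3]
  tf <- tempfile(fileext = ".sdf")
  write_sdf(fx, tf)
  back <- read_sdf(tf)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$graph$bond_order_matrix,
                 fx[[i]]$graph$bond_order_matrix)
    expect_equal(back[[i]]$graph$nuclear_charges,
                 fx[[i]]$graph$nuclear_charges)
    ## coordinates to the 1e-4 precision of the V2000 atom block
    expect_lt(max(abs(back[[i]]$geometry$coordinates -
                      fx[[i]]$geometry$coordinates)), 1e-4)
  }
  ## distances derived from the SDF geometry match the XYZ route
  xf <- tempfile(fileext = ".xyz")
  write_xyz(fx[[1]]$geometry, xf)
  Dx <- distance_matrix(read_xyz(xf))
  Ds <- distance_matrix(back[[1]]$geometry)
  expect_lt(max(abs(Dx - Ds)), 1e-3)
})

test_that("parse_smiles builds kekulized, hydrogen-saturated graphs", {
  g <- parse_smiles("CC")
  expect_equal(n_heavy(g), 2)
  expect_equal(sum(g$nuclear_charges == 1L), 6)
  h <- g$heavy_indices
  expect_equal(g$bond_order_matrix[h[1], h[2]], 1L)

  g2 <- parse_smiles("C=O")
  h2 <- g2$heavy_indices
  expect_equal(g2$bond_order_matrix[h2[1], h2[2]], 2L)
  carbon <- h2[g2$nuclear_charges[h2] == 6L]
  expect_equal(sum(g2$hydrogen_attachments == carbon), 2)

  ## aromatic input comes out kekulized (orders 1/2 alternating)
  gb <- parse_smiles("c1ccccc1")
  orders <- gb$bond_order_matrix[gb$heavy_indices, gb$heavy_indices]
  expect_setequal(unique(orders[orders > 0]), c(1L, 2L))
})

test_that("parse_smiles heavy-atom counts match a lexical oracle", {
  smiles <- c("CC", "CCC", "CCO", "C=O", "C#N", "CC(C)C", "OCC(O)CO",
              "C1CCCCC1", "c1ccccc1", "O=C1OC(C)(C)C1", "CC(=O)OC",
              "N#CC1CC1", "OC(=O)CN", "CCOC(C)=O", "C1CC1C#C",
              "CNC", "CON", "C=CC=C", "CC#CC", "OC1CCOC1")
  ## oracle: count element tokens in the string, independent of any parser
  count_heavy <- function(s) {
    s <- gsub("\\[[^]]*\\]", "X", s)  # bracket atom = one heavy atom
    length(gregexpr("Cl|Br|[BCNOFPSIX]|[cnos]", s)[[1]])
  }
  for (s in smiles)
    expect_equal(n_heavy(parse_smiles(s)), count_heavy(s), label = s)
})

test_that("parse_smiles rejects what it cannot represent", {
  expect_error(parse_smiles("C((C"), "unmatched")
  expect_error(parse_smiles("C{}"), "invalid token")
  expect_error(parse_smiles("[NH4+]"), "charged")
  expect_error(parse_smiles("[CH3]"), "radical|open-shell")
  ## singlet-carbene-like under-valent carbon is accepted and flagged
  g <- parse_smiles("[CH2]")
  expect_length(g$undervalent, 1)
})

test_that("fixture families: the C4 case, determinism, and saturation", {
  fx <- generate_fixture_family(4, c(C = 4), 2, seed = 1, ring_fraction = 0)
  expect_length(fx, 2)
  ## the only two C4 alkane skeletons: n-butane and isobutane
  degs <- lapply(fx, function(f) {
    h <- f$graph$heavy_indices
    sort(rowSums(f$graph$bond_order_matrix[h, h] > 0))
  })
  expect_true(!identical(degs[[1]], degs[[2]]))
  D1 <- distance_matrix(fx[[1]]$geometry, heavy_only = TRUE)
  D2 <- distance_matrix(fx[[2]]$geometry, heavy_only = TRUE)
  expect_gt(max(abs(sort(D1[upper.tri(D1)]) - sort(D2[upper.tri(D2)]))), 0.1)

  ## requesting more skeletons than exist reports the realizable maximum
  expect_error(generate_fixture_family(4, c(C = 4), 10, seed = 1,
                                       ring_fraction = 0),
               "only 2 are realizable")

  ## same seed, bit-identical output
  expect_identical(generate_fixture_family(4, c(C = 4), 2, seed = 1),
                   generate_fixture_family(4, c(C = 4), 2, seed = 1))
})

test_that("rebuilt bond lengths equal covalent-radius sums exactly", {
  fx <- fixture_family(10)
  for (f in fx[1:5]) {
    g <- f$graph
    D <- distance_matrix(f$geometry)
    r <- covalent_radius(g$nuclear_charges)
    bonds <- which(upper.tri(g$bond_order_matrix) & g$bond_order_matrix > 0,
                   arr.ind = TRUE)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      expect_equal(D[i, j], r[i] + r[j], tolerance = 1e-9,
                   label = sprintf("bond %d-%d", i, j))
    }
  }
})

test_that("the graph->geometry map is deterministic and injective on distance matrices", {
  fam <- fixture_family(50)
  ## determinism: rebuilding from the graph reproduces coordinates exactly
  f <- fam[[7]]
  expect_identical(build_ideal_geometry(f$graph)$coordinates,
                   f$geometry$coordinates)
  ## injectivity over the family: distinct connectivities give distinct
  ## heavy-atom distance matrices
  sigs <- vapply(fam, function(f) {
    D <- distance_matrix(f$geometry, heavy_only = TRUE)
    paste(sprintf("%.6f", sort(D[upper.tri(D)])), collapse = ",")
  }, character(1))
  expect_equal(anyDuplicated(sigs), 0L)
})

test_that("crystal fixtures are reproducible, valid and monotone in size", {
  crs <- fixture_crystals(50, seed = 4)
  expect_identical(crs, fixture_crystals(50, seed = 4))
  for (cr in crs) {
    expect_true(all(cr$fractional_coords >= 0 & cr$fractional_coords < 1))
    expect_gt(cr$lattice_constant, 0)
  }
  ## lattice constant strictly increasing in the anion size proxy at fixed
  ## other elements, per the generator's own closed form
  a_F <- fixture_lattice_form(c("Al", "Na", "K", "F"))
  a_Cl <- fixture_lattice_form(c("Al", "Na", "K", "Cl"))
  a_Br <- fixture_lattice_form(c("Al", "Na", "K", "Br"))
  a_I <- fixture_lattice_form(c("Al", "Na", "K", "I"))
  expect_true(all(diff(c(a_F, a_Cl, a_Br, a_I)) > 0))
  ## and in the A-site proxy
  expect_lt(fixture_lattice_form(c("B", "Na", "K", "F")),
            fixture_lattice_form(c("Al", "Na", "K", "F")))
  ## over-requesting distinct stoichiometries errors
  expect_error(generate_crystal_fixtures(
    element_pool = list(A = "Al", B = "Na", C = "K", D = c("F", "Cl")),
    count = 3, seed = 1), "pool only admits")
})
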