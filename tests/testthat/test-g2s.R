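## End-to-end model training, prediction, evaluation, persistence, crystals.

interp_model <- function(dataset, scheme = "bond_length") {
  g2s_train(dataset, scheme = scheme, search = "none",
            hyper = list(family = "laplacian", sigma = 5, lambda = 1e-12))
}

test_that("training molecules are reconstructed at lambda -> 0", {
  fam <- fixture_family(10)
  m <- interp_model(fam)
  for (f in fam[c(1, 4, 8)]) {
    g <- f$graph
    ## distance interpolation
    Dg <- g2s:::predict_distances(m, g)
    Dref <- distance_matrix(f$geometry)[g$heavy_indices, g$heavy_indices]
    expect_lt(mean(abs(Dg[upper.tri(Dg)] - Dref[upper.tri(Dref)])), 1e-6)
    ## full reconstruction: heavy-atom RMSD below 1e-3
    ps <- predict_structure(m, g)
    expect_true(attr(ps, "embedding")$converged)
    sup <- kabsch_superpose(ps$coordinates[g$heavy_indices, ],
                            f$geometry$coordinates[g$heavy_indices, ],
                            allow_reflection = TRUE)
    expect_lt(sup$rmsd, 1e-3)
    ## contract: predicted distance matrix symmetric and positive
    expect_equal(Dg, t(Dg))
    expect_true(all(Dg[upper.tri(Dg)] > 0))
  }
})

test_that("duplicate training graphs are rejected", {
  fam <- fixture_family(10)
  expect_error(g2s_train(c(fam[1:3], fam[2]), search = "none",
                         hyper = list(family = "laplacian", sigma = 5,
                                      lambda = 1e-10)),
               "duplicate graphs")
})

test_that("n-butane and isobutane predictions are clearly separated", {
  skel <- generate_fixture_family(4, c(C = 4), 2, seed = 1,
                                  ring_fraction = 0)
  fam <- fixture_family(10)
  m <- interp_model(c(fam, skel))
  D1 <- g2s:::predict_distances(m, skel[[1]]$graph)
  D2 <- g2s:::predict_distances(m, skel[[2]]$graph)
  expect_gt(max(abs(sort(D1[upper.tri(D1)]) - sort(D2[upper.tri(D2)]))), 0.5)
})

test_that("evaluation aggregates match recomputation and spot overlap", {
  fam <- fixture_family(40)
  m <- g2s_train(fam[1:25], scheme = "bond_length", search = "cv", seed = 2,
                 hydrogens = FALSE,
                 grid = hyper_grid(lambda_values = 10^c(-8, -6, -4)))
  ev <- g2s_evaluate(m, fam[26:40])
  expect_equal(ev$n, 15)
  expect_equal(ev$rmsd, mean(ev$per_molecule$rmsd))
  ## pooled MAE equals the per-pair recomputation from the table: all
  ## molecules here have 9 heavy atoms, so pooling equals the mean
  expect_equal(ev$mae, weighted.mean(ev$per_molecule$mae,
                                     choose(ev$per_molecule$n_heavy, 2)))
  ## perfect predictions give zero errors: evaluate the model on a training
  ## molecule through the interpolating model
  mi <- interp_model(fam[1:10])
  evi <- g2s_evaluate(mi, fam[1:2], allow_overlap = TRUE)
  expect_lt(evi$mae, 1e-6)
  expect_lt(evi$rmsd, 1e-3)
  ## test/train overlap is rejected unless explicitly allowed
  expect_error(g2s_evaluate(m, fam[25:26]), "overlaps")
})

test_that("models survive a JSON save/load round trip", {
  fam <- fixture_family(10)
  m <- interp_model(fam[1:8])
  tf <- tempfile(fileext = ".json")
  g2s_save(m, tf)
  m2 <- g2s_load(tf)
  g <- fam[[2]]$graph
  expect_equal(g2s:::predict_distances(m2, g),
               g2s:::predict_distances(m, g), tolerance = 1e-12)
  ## schema version is enforced
  bad <- jsonlite::read_json(tf)
  bad$schema_version <- "g2s-model-99"
  tf2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, tf2, auto_unbox = TRUE, digits = NA)
  expect_error(g2s_load(tf2), "schema version")
})

test_that("graph_bob queries outside the training vocabulary fail cleanly", {
  fam <- fixture_family(10)
  m <- g2s_train(fam, scheme = "graph_bob", search = "none", n_max = 9,
                 hydrogens = FALSE,
                 hyper = list(family = "laplacian", sigma = 50,
                              lambda = 1e-8))
  expect_error(g2s:::predict_distances(m, parse_smiles("CCN")),
               "vocabulary")
})

test_that("crystal models interpolate and predict sensible structures", {
  crs <- fixture_crystals(60, seed = 4)
  cm <- g2s_train_crystal(crs, search = "none",
                          hyper = list(family = "laplacian", sigma = 2,
                                       lambda = 1e-12))
  ## training stoichiometry queried back at lambda -> 0
  pr <- g2s_predict_crystal(cm, crs[[5]]$site_elements)
  expect_equal(pr$lattice_constant, crs[[5]]$lattice_constant,
               tolerance = 1e-6)
  ## predicted fractional distances within the geometric bound (0, sqrt(3))
  x <- matrix(flla_rep(pr)$values, 1)
  dhat <- krr_predict(cm$site_distance_model, x)[1, ]
  expect_true(all(dhat > 0 & dhat < sqrt(3)))
  expect_true(all(pr$fractional_coords >= 0 & pr$fractional_coords < 1))
  ## conflicting anion/cation roles are rejected
  bad <- crystal_record(c("F", "Na", "K", "F"), 8)
  expect_error(g2s_train_crystal(list(bad)), "conflicting")
})

test_that("benchmark metadata matches the published protocol sizes", {
  expect_equal(benchmark_info("C7NOH11")$n_train, 4687L)
  expect_equal(benchmark_info("C7NOH11")$n_test, 1172L)
  expect_equal(benchmark_info("C7O2H10")$n_train, 4876L)
  expect_equal(benchmark_info("C7O2H10")$n_test, 1219L)
  expect_error(benchmark_info("nope"), "unknown subset")
  ## a missing dataset produces an actionable message carrying the DOI
  expect_error(run_qm9_benchmark(tempfile(), "C7O2H10"),
               "10.6084/m9.figshare")
})

test_that("training is invariant to dataset shuffling given a fixed seed", {
  fam <- fixture_family(30)
  grid <- hyper_grid(sigma_values = c(2, 8, 32),
                     lambda_values = c(1e-8, 1e-5))
  m1 <- g2s_train(fam, scheme = "bond_hop", search = "cv", seed = 5,
                  hydrogens = FALSE, grid = grid)
  set.seed(99)
  m2 <- g2s_train(fam[sample(30)], scheme = "bond_hop", search = "cv",
                  seed = 5, hydrogens = FALSE, grid = grid)
  expect_identical(m1$metadata$hyper, m2$metadata$hyper)
  expect_identical(m1$scaffold_model$coefficients,
                   m2$scaffold_model$coefficients)
})
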