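test_that("endpoint activity is substrate removed, with clipping", {
  p <- assay_params(2.25, 40)
  expect_equal(endpoint_activity(2.25, p), 0)
  expect_equal(endpoint_activity(0, p), 2.25)
  expect_equal(endpoint_activity(1.25, p), 1.0)
  expect_equal(endpoint_activity(1.25, p, as_rate = TRUE), 0.025)
  expect_warning(a <- endpoint_activity(c(2.5, 1), p), "clipped")
  expect_equal(a, c(0, 1.25))
  expect_error(endpoint_activity(-0.1, p), "negative")
  expect_error(assay_params(0), "c0")
  # mass conservation: activity + remaining = c0
  rem <- seq(0, 2.25, length.out = 10)
  expect_equal(endpoint_activity(rem, p) + rem, rep(2.25, 10))
})

test_that("SEC calibration fits log10(mass) on elution volume", {
  # points exactly on a log-line: perfect fit, parameters recovered
  vols <- c(8, 10, 12, 14, 16, 18)
  std <- data.frame(mass_kda = 10^(-0.2 * vols + 4), volume_ml = vols)
  curve <- sec_calibrate(std)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$slope, -0.2)
  expect_equal(curve$intercept, 4)
  # round-trip: apparent mass at each standard's volume returns its mass
  expect_equal(apparent_mass(curve, vols), std$mass_kda, tolerance = 1e-9)
  expect_error(sec_calibrate(std[1:2, ]), "3 calibration")
  expect_error(sec_calibrate(data.frame(mass_kda = c(1, 2, 3),
                                        volume_ml = c(1, 1, 2))),
               "distinct")
  # noisy standards from a known line: slope recovered approximately
  set.seed(2)
  noisy <- data.frame(volume_ml = vols,
                      mass_kda = 10^(-0.2 * vols + 4 + rnorm(6, 0, 0.02)))
  expect_lt(abs(sec_calibrate(noisy)$slope + 0.2), 0.02)
})

test_that("apparent mass inverts the calibration", {
  curve <- structure(list(slope = -0.2, intercept = 4, r_squared = 1,
                          volume_range = c(8, 18)),
                     class = "sec_calibration")
  expect_equal(apparent_mass(curve, 10), 100)
  expect_warning(m <- apparent_mass(curve, 25), "outside")
  expect_equal(m, 10^(-0.2 * 25 + 4))
})

test_that("oligomer candidates are ranked integer multiples", {
  call <- oligomer_candidates(57, 200, n_max = 6, tolerance = 0.2)
  expect_setequal(call$candidates$n_subunits, c(3, 4))
  expect_equal(call$candidates$predicted_mass[call$candidates$n_subunits == 3],
               171)
  expect_equal(call$candidates$predicted_mass[call$candidates$n_subunits == 4],
               228)
  expect_equal(call$candidates$abs_deviation,
               sort(call$candidates$abs_deviation))
  expect_equal(oligomer_candidates(57, 57, 6, 0.01)$candidates$n_subunits, 1)
  expect_equal(nrow(oligomer_candidates(57, 1000, 6, 0.2)$candidates), 0)
  # predicted masses are exact integer multiples of the monomer
  set.seed(3)
  for (i in 1:10) {
    mono <- runif(1, 20, 120)
    app <- runif(1, 50, 600)
    cand <- oligomer_candidates(mono, app, 8, 0.3)$candidates
    if (nrow(cand))
      expect_equal(cand$predicted_mass / mono, cand$n_subunits,
                   tolerance = 1e-12)
  }
})

test_that("correlation clustering recovers planted proteins", {
  params <- clustering_params(top_n = 200, similarity_threshold = 75)
  # noise-free planted profile is in the >75% set
  ex0 <- simulate_sec(30, 60, 3, 0, 2.25, 4)
  act0 <- endpoint_activity(ex0$remaining_substrate, assay_params(2.25))
  cl0 <- correlation_cluster(act0, ex0$abundance,
                             clustering_params(top_n = 60))
  expect_true(all(ex0$planted_ids %in% cl0$members))
  sims <- cl0$similarity
  expect_equal(
    sims$similarity_to_activity[sims$protein_id %in% ex0$planted_ids],
    rep(100, 3), tolerance = 1e-9)
  # a background protein peaking far from the activity peak is excluded
  far <- sims$protein_id[!(sims$protein_id %in% ex0$planted_ids)]
  expect_false(any(far %in% cl0$members))
  # 5% noise, full-size experiment: exactly the planted set recovered
  ex <- simulate_sec(30, 200, 5, 0.05, 2.25, 9)
  act <- endpoint_activity(ex$remaining_substrate, assay_params(2.25))
  cl <- correlation_cluster(act, ex$abundance, params)
  expect_setequal(cl$members, ex$planted_ids)
  # constant profiles are excluded with a warning
  ab <- ex$abundance
  ab["prot0100", ] <- 5
  expect_warning(correlation_cluster(act, ab, params), "constant")
  expect_error(correlation_cluster(rep(1, 30), ex$abundance, params),
               "zero variance")
  expect_error(correlation_cluster(act[1:3], ex$abundance[, 1:3], params),
               "5 fractions")
})

test_that("dendrograms serialise to Newick with all leaves", {
  ex <- simulate_sec(20, 30, 2, 0.02, 2.25, 6)
  act <- endpoint_activity(ex$remaining_substrate, assay_params(2.25))
  cl <- correlation_cluster(act, ex$abundance,
                            clustering_params(top_n = 30))
  path <- tempfile(fileext = ".nwk")
  write_dendrogram(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("activity", rownames(ex$abundance)))
})

test_that("stoichiometry check compares removal and formation", {
  expect_true(stoichiometry_check(1.0, 1.0, 0.1))
  expect_false(stoichiometry_check(1.0, 0.0, 0.1))
  expect_false(stoichiometry_check(1.0, 0.85, 0.1))
  expect_true(stoichiometry_check(1.0, 0.95, 0.1))
  expect_true(stoichiometry_check(0, 0, 0.1))  # no-enzyme control
  expect_error(stoichiometry_check(-1, 0), ">= 0")
})
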