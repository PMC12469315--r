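test_that("strong acid alone gives pH = pKw/2 at the equivalence point", {
  # 1e-3 M HNO3 in 30 mL, 0.2 M NaOH: equivalence at 0.15 mL
  m <- build_model(list(component("X", role = "ligand"),
                        component("H", role = "proton")),
                   list(species_def("HX", c(X = 1, H = 1), 1)),
                   pKw = 13.78)
  p <- titration_protocol(c(X = 0), acid_mmol = 0.03, v_max_mL = 0.3,
                          n_points = 3L)
  crv <- simulate_titration(m, p, volumes = c(0.0999, 0.15, 0.2001))
  expect_equal(crv$points$pH[2], 13.78 / 2, tolerance = 1e-6)
  expect_true(all(diff(crv$points$pH) > 0))
})

test_that("monoprotic half-neutralization matches the proton-balance oracle", {
  m <- monoprotic_model(logK = 10.28)
  # 0.06 mmol ligand delivered fully protonated; half-neutralized at 0.15 mL
  p <- titration_protocol(c(L = 0.06), acid_mmol = 0, v_max_mL = 0.25,
                          n_points = 2L, ligand_protons = c(L = 1))
  v <- 0.15
  crv <- simulate_titration(m, p, volumes = c(0.01, v))
  TH <- (0.06 - 0.2 * v) / (30 + v)
  pH_oracle <- oracle_titration_pH(m, c(L = 0.06 / (30 + v)), TH)
  expect_equal(crv$points$pH[2], pH_oracle, tolerance = 1e-8)
  # close to, but not exactly at, log K (buffer approximation degrades
  # near pKw)
  expect_equal(crv$points$pH[2], 10.28, tolerance = 0.02)
})

test_that("pH is strictly nondecreasing in titrant volume on all fixtures", {
  for (s in bundled_systems()) {
    crv <- simulate_titration(bundled_model(s), design_protocol(s))
    expect_true(all(diff(crv$points$pH) > 0), label = s)
    expect_true(all(crv$points$pH > 0 & crv$points$pH < 13.78), label = s)
  }
})

test_that("titration points are consistent with the fixed-pH solver", {
  m <- bundled_model("Cu_Tyr")
  p <- design_protocol("Cu_Tyr", n_points = 25L)
  crv <- simulate_titration(m, p)
  H0 <- p$acid_mmol + sum(p$ligand_protons * p$component_mmol)
  for (i in c(1L, 8L, 15L, 25L)) {
    v <- crv$points$v_mL[i]
    totals <- p$component_mmol / (p$v0_mL + v)
    st <- solve_speciation(m, totals, crv$points$pH[i])
    # mass conservation of every component at the simulated point
    expect_equal(recovered_totals(m, st)[names(totals)], totals,
                 tolerance = 1e-10)
    # the full proton condition is met by the fixed-pH re-solve
    h <- 10^(-crv$points$pH[i])
    TH_implied <- sum(m$stoich[, "H"] * st$species_conc) + h - 10^(-m$pKw) / h
    TH <- (H0 - p$titrant_conc_M * v) / (p$v0_mL + v)
    expect_equal(TH_implied, TH, tolerance = 1e-8)
    # and the species concentrations match the full solve
    full <- betafit:::.solve_full(m, totals, TH)
    expect_equal(full$species_conc, st$species_conc, tolerance = 1e-9)
  }
})

test_that("complexation shifts the curve only above pH about 3", {
  m <- bundled_model("Cu_Tyr")
  p <- design_protocol("Cu_Tyr")
  cu_curve <- simulate_titration(m, p)
  ligand_only <- drop_component(m, "Cu")
  p0 <- design_protocol(ligand_only, component_mmol = c(Tyr = 0.06))
  p0 <- titration_protocol(c(Tyr = 0.06), acid_mmol = p0$acid_mmol,
                           v_max_mL = p$v_max_mL, n_points = p$n_points,
                           ligand_protons = c(Tyr = 2))
  free_curve <- simulate_titration(ligand_only, p0)
  cmp <- compare_curves(cu_curve, free_curve, threshold = 0.05)
  expect_false(is.null(cmp$first_divergence))
  expect_gt(cmp$first_divergence$pH, 3.0)
  expect_lt(cmp$first_divergence$pH, 4.5)
  expect_gt(cmp$max_abs_dpH, 1)
})

test_that("curve comparison is exact on self and validates ranges", {
  crv <- simulate_titration(toy_ML_model(),
                            titration_protocol(c(M = 0.03, L = 0.03),
                                               acid_mmol = 0.06,
                                               v_max_mL = 0.5, n_points = 20L))
  expect_identical(compare_curves(crv, crv)$max_abs_dpH, 0)
  shifted <- crv
  shifted$points$v_mL <- shifted$points$v_mL + 10
  expect_error(compare_curves(crv, shifted), "disjoint")
})

test_that("noisy replicates differ by no more than the calibrated bound", {
  m <- bundled_model("Cu_Tyr")
  p <- design_protocol("Cu_Tyr")
  sigma <- 0.005
  a <- generate_curve(m, p, noise_model(sigma, 1))
  b <- generate_curve(m, p, noise_model(sigma, 2))
  cmp <- compare_curves(a, b)
  # difference of two noisy replicates is N(0, 2 sigma^2); for 250 points
  # the maximum stays below 5 * sigma * sqrt(2) with high probability
  expect_lt(cmp$max_abs_dpH, 5 * sigma * sqrt(2))
})
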