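test_that("free component only: solver returns the analytical total", {
  m <- build_model(list(component("M", role = "metal"),
                        component("H", role = "proton")),
                   list(species_def("MOH", c(M = 1, H = -1), -20)))
  s <- solve_speciation(m, c(M = 1e-3), pH = 3)
  expect_equal(s$free[["M"]], 1e-3, tolerance = 1e-9)
})

test_that("M + L = ML toy matches the closed-form quadratic root", {
  # with equal totals T the free concentration solves beta f^2 + f - T = 0
  beta <- 1e3; T0 <- 1e-3
  f_exact <- (-1 + sqrt(1 + 4 * beta * T0)) / (2 * beta)
  m <- toy_ML_model(log_beta = 3)
  s <- solve_speciation(m, c(M = T0, L = T0), pH = 7)
  expect_equal(s$free[["M"]], f_exact, tolerance = 1e-10)
  expect_equal(s$free[["L"]], f_exact, tolerance = 1e-10)
  expect_equal(s$species_conc[["ML"]], T0 - f_exact, tolerance = 1e-10)
  expect_equal(s$free[["M"]], 6.1803e-4, tolerance = 1e-4)
})

test_that("Newton solver agrees with the bisection oracle on random toys", {
  set.seed(42)
  for (rep in 1:8) {
    lbML <- runif(1, 2, 6); lbHL <- runif(1, 4, 9); lbMHL <- lbML + lbHL - runif(1, 0, 2)
    m <- build_model(
      list(component("M", role = "metal"), component("L", role = "ligand"),
           component("H", role = "proton")),
      list(species_def("ML", c(M = 1, L = 1), lbML),
           species_def("HL", c(L = 1, H = 1), lbHL),
           species_def("MHL", c(M = 1, L = 1, H = 1), lbMHL)))
    totals <- c(M = 10^runif(1, -4, -2.5), L = 10^runif(1, -4, -2.5))
    pH <- runif(1, 3, 9)
    s <- solve_speciation(m, totals, pH)
    f_oracle <- oracle_free(m, totals, pH)
    expect_equal(s$free[["M"]], f_oracle[["M"]], tolerance = 1e-8)
    expect_equal(s$free[["L"]], f_oracle[["L"]], tolerance = 1e-8)
  }
})

test_that("mass conservation holds at every converged state", {
  m <- bundled_model("Cu_Tyr_ADP")
  totals <- c(Cu = 1e-3, Tyr = 1e-3, ADP = 1e-3)
  for (pH in c(2.5, 4.0, 6.5, 9.0, 10.8)) {
    s <- solve_speciation(m, totals, pH)
    rec <- recovered_totals(m, s)
    expect_equal(rec[names(totals)], totals, tolerance = 1e-10)
  }
})

test_that("mole fractions of a 1:1 mononuclear toy are scale-equivariant", {
  m <- toy_ML_model(log_beta = 4)
  base <- solve_speciation(m, c(M = 1e-3, L = 1e-3), pH = 7)
  # the quadratic's mole fractions do shift with scale for ML; equivariance
  # holds for first-order response: compare fraction of a strictly
  # mononuclear protonation toy instead
  mp <- monoprotic_model(logK = 6)
  s1 <- solve_speciation(mp, c(L = 1e-4), pH = 6.3)
  s2 <- solve_speciation(mp, c(L = 1e-2), pH = 6.3)
  expect_equal(s1$species_conc[["HL"]] / 1e-4,
               s2$species_conc[["HL"]] / 1e-2, tolerance = 1e-9)
  expect_true(base$converged)
})

test_that("complex concentration is nondecreasing in log beta", {
  prev <- -Inf
  for (lb in seq(2, 6, by = 0.5)) {
    s <- solve_speciation(toy_ML_model(lb), c(M = 1e-3, L = 1e-3), pH = 7)
    expect_gte(s$species_conc[["ML"]], prev)
    prev <- s$species_conc[["ML"]]
  }
})

test_that("distribution percentages account for all of the reference", {
  m <- bundled_model("Cu_Tyr")
  d <- distribution(m, c(Cu = 1e-3, Tyr = 2e-3), 2.5, 11, step = 0.05)
  sums <- rowSums(d$percent)
  expect_equal(sums, rep(100, length(sums)), tolerance = 1e-6)
  expect_true(all(d$percent >= 0 & d$percent <= 100 + 1e-9))
})

test_that("distribution values are independent of the grid step", {
  m <- bundled_model("Cu_Tyr")
  totals <- c(Cu = 1e-3, Tyr = 2e-3)
  d1 <- distribution(m, totals, 2.5, 11, step = 0.01)
  d2 <- distribution(m, totals, 2.5, 11, step = 0.05)
  shared <- match(round(d2$pH, 9), round(d1$pH, 9))
  expect_false(anyNA(shared))
  expect_equal(d1$percent[shared, colnames(d2$percent)], d2$percent,
               tolerance = 1e-9)
})

test_that("binary Cu/Tyr distribution reproduces the dominance pattern", {
  m <- bundled_model("Cu_Tyr")
  d <- distribution(m, c(Cu = 1e-3, Tyr = 2e-3), 2.5, 11, step = 0.01)
  expect_identical(dominant_species(d, 3.0), "CuH2(Tyr)")
  expect_identical(dominant_species(d, 10.2), "CuH(Tyr)2")
  pk <- peak(d, "CuH(Tyr)")
  expect_gt(pk$max_percent, 70)
  expect_true(pk$pH_at_max > 4.0 && pk$pH_at_max < 5.7)
  expect_equal(peak(d, "CuH2(Tyr)")$pH_at_max, 3.0, tolerance = 0.1)
})

test_that("species excluded by a zero total stay identically zero", {
  m <- bundled_model("Cu_Tyr_ADP")
  d <- distribution(m, c(Cu = 1e-3, Tyr = 2e-3, ADP = 0), 2.5, 11,
                    step = 0.1)
  pk <- peak(d, "Cu(Tyr)H2(ADP)")
  expect_identical(pk$max_percent, 0)
  expect_identical(pk$pH_at_max, 2.5)
  # the remaining binary speciation is unaffected
  expect_identical(dominant_species(d, 3.0), "CuH2(Tyr)")
})

test_that("diagram accessors validate their inputs", {
  m <- toy_ML_model()
  d <- distribution(m, c(M = 1e-3, L = 1e-3), 4, 9, step = 0.5)
  expect_identical(dominant_species(d, 7), "ML")
  expect_error(dominant_species(d, 12), "outside")
  expect_error(peak(d, "nope"), "unknown species")
  expect_error(distribution(m, c(L = 1e-3), 4, 9, step = 0.5,
                            reference = "M"), "positive total")
  expect_error(solve_speciation(m, c(M = 1e-3, L = 1e-3), pH = 15), "pKw")
  expect_error(solve_speciation(m, c(M = 0, L = 0), pH = 7), "positive")
})
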