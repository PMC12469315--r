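toy_curve <- function(log_beta = 3, n = 60L) {
  m <- build_model(list(component("M", role = "metal"),
                        component("L", role = "ligand"),
                        component("H", role = "proton")),
                   list(species_def("ML", c(M = 1, L = 1), log_beta),
                        species_def("HL", c(L = 1, H = 1), 6)))
  p <- titration_protocol(c(M = 0.03, L = 0.03), acid_mmol = 0.08,
                          v_max_mL = 1.2, n_points = n,
                          ligand_protons = c(L = 1))
  list(model = m, curve = simulate_titration(m, p))
}

test_that("a noiseless toy constant is recovered from a perturbed start", {
  tc <- toy_curve()
  fit <- refine(set_log_beta(tc$model, c(ML = 3.5)), list(tc$curve), "ML")
  expect_true(fit$converged)
  expect_equal(unname(fit$log_beta_hat[["ML"]]), 3, tolerance = 1e-4)
  expect_lt(fit$Sigma_stat, 1e-12)
  expect_identical(fit$rejected_species, character(0))
})

test_that("an empty free set is a pure evaluation", {
  tc <- toy_curve()
  fit <- refine(tc$model, list(tc$curve), character(0))
  expect_identical(fit$n_iterations, 0L)
  expect_true(fit$converged)
  expect_identical(fit$log_beta_hat[["ML"]], 3)
  expect_lt(fit$Sigma_stat, 1e-18)
})

test_that("Sigma never increases from start to optimum", {
  tc <- toy_curve()
  noisy <- tc$curve
  noisy$points$pH <- noisy$points$pH +
    betafit:::.with_seed(4, rnorm(nrow(noisy$points), 0, 0.01))
  start <- set_log_beta(tc$model, c(ML = 3.4))
  S0 <- sum((noisy$points$pH -
               simulate_titration(start, noisy$protocol,
                                  volumes = noisy$points$v_mL)$points$pH)^2)
  fit <- refine(start, list(noisy), "ML")
  expect_lte(fit$Sigma_stat, S0)
  # reported uncertainty is of the right order for sigma_pH = 0.01
  expect_gt(fit$sigma[["ML"]], 1e-4)
  expect_lt(fit$sigma[["ML"]], 0.1)
})

test_that("the optimizer agrees with an independent Levenberg-Marquardt", {
  library(minpack.lm)
  tc <- toy_curve()
  noisy <- tc$curve
  noisy$points$pH <- noisy$points$pH +
    betafit:::.with_seed(5, rnorm(nrow(noisy$points), 0, 0.005))
  fit <- refine(set_log_beta(tc$model, c(ML = 3.3)), list(noisy), "ML")
  resid_fn <- function(par) {
    mm <- set_log_beta(tc$model, c(ML = par))
    noisy$points$pH -
      simulate_titration(mm, noisy$protocol,
                         volumes = noisy$points$v_mL)$points$pH
  }
  ref <- minpack.lm::nls.lm(par = 3.3, fn = resid_fn)
  expect_equal(unname(fit$log_beta_hat[["ML"]]), unname(coef(ref)),
               tolerance = 1e-5)
})

test_that("sigma_pH weighting rescales Sigma but not the optimum", {
  tc <- toy_curve()
  noisy <- tc$curve
  noisy$points$pH <- noisy$points$pH +
    betafit:::.with_seed(6, rnorm(nrow(noisy$points), 0, 0.005))
  noisy$noise_sigma_pH <- 0.005
  fu <- refine(set_log_beta(tc$model, c(ML = 3.2)), list(noisy), "ML")
  fw <- refine(set_log_beta(tc$model, c(ML = 3.2)), list(noisy), "ML",
               weighting = "sigma_pH")
  expect_equal(unname(fu$log_beta_hat[["ML"]]), unname(fw$log_beta_hat[["ML"]]),
               tolerance = 1e-6)
  expect_equal(fw$Sigma_stat, fu$Sigma_stat / 0.005^2, tolerance = 1e-4)
  clean <- tc$curve
  expect_error(refine(tc$model, list(clean), "ML", weighting = "sigma_pH"),
               "positive noise_sigma_pH")
})

test_that("refine validates its inputs", {
  tc <- toy_curve()
  expect_error(refine(tc$model, list(tc$curve), "XY"), "not in model")
  expect_error(refine(tc$model, list(), "ML"))
  one_pt <- tc$curve
  one_pt$points <- one_pt$points[1, ]
  expect_error(refine(tc$model, list(one_pt), "ML"), "at least 2 points")
})

test_that("model selection ranks the true species set first", {
  m <- bundled_model("Cu_Tyr")
  p <- design_protocol("Cu_Tyr", n_points = 80L)
  st <- generate_study("Cu_Tyr", 2L, noise_model(0.005, 3), protocol = p)
  free_full <- c("CuH2(Tyr)", "CuH(Tyr)", "CuH2(Tyr)2", "CuH(Tyr)2")
  start_full <- setNames(
    m$species$log_beta[match(free_full, m$species$name)] + 0.2, free_full)
  reduced <- drop_species <- "CuH2(Tyr)2"
  m_red <- build_model(
    lapply(seq_len(nrow(m$components)), function(i)
      do.call(component, as.list(m$components[i, ]))),
    lapply(setdiff(m$species$name, drop_species), function(nm) {
      i <- match(nm, m$species$name)
      st_ <- m$stoich[i, ]
      species_def(nm, st_[st_ != 0], m$species$log_beta[i])
    }))
  cands <- list(
    list(model = m, free_species = free_full, init = start_full),
    list(model = m_red, free_species = setdiff(free_full, drop_species),
         init = start_full[setdiff(free_full, drop_species)]))
  sel <- select_model(cands, st$curves, sigma_max = 0.1)
  expect_identical(sel[[1]]$spec$free_species, free_full)
  expect_identical(sel[[1]]$result$rejected_species, character(0))
  expect_gte(sel[[1]]$n_accepted, sel[[2]]$n_accepted)
})

test_that("a spurious added species is flagged as rejected", {
  m <- bundled_model("Cu_Tyr")
  p <- design_protocol("Cu_Tyr", n_points = 80L)
  st <- generate_study("Cu_Tyr", 2L, noise_model(0.005, 3), protocol = p)
  # the ML-type complex Cu(Tyr) is not formed in this system; adding it as
  # a candidate species must not survive selection
  m_plus <- build_model(
    lapply(seq_len(nrow(m$components)), function(i)
      do.call(component, as.list(m$components[i, ]))),
    c(lapply(m$species$name, function(nm) {
      i <- match(nm, m$species$name)
      st_ <- m$stoich[i, ]
      species_def(nm, st_[st_ != 0], m$species$log_beta[i])
    }), list(species_def("Cu(Tyr)", c(Cu = 1, Tyr = 1), 11))))
  free <- c("CuH2(Tyr)", "CuH(Tyr)", "CuH2(Tyr)2", "CuH(Tyr)2", "Cu(Tyr)")
  init <- setNames(
    m_plus$species$log_beta[match(free, m_plus$species$name)], free)
  init[1:4] <- init[1:4] + 0.2
  sel <- select_model(list(list(model = m_plus, free_species = free,
                                init = init)),
                      st$curves, sigma_max = 0.1)
  expect_true("Cu(Tyr)" %in% sel[[1]]$result$rejected_species)
})
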