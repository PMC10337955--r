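make_eq2_tc <- function(A, k, times = seq(0, 10, by = 0.25), t0 = 5) {
  y <- ifelse(times <= t0, 0, A * (1 - exp(-k * (times - t0))))
  timecourse(times = times, conc = y, scenario = "eq2", t_stim = t0)
}

test_that("initial-velocity estimator is exact on noiseless exponential
           rises", {
  set.seed(41)
  for (i in 1:15) {
    A <- runif(1, 0.01, 10); k <- runif(1, 0.05, 5)
    fit <- fit_initial_velocity(make_eq2_tc(A, k))
    expect_equal(fit$A, A, tolerance = 1e-5)
    expect_equal(fit$k, k, tolerance = 1e-5)
    expect_equal(fit$v0, A * k, tolerance = 1e-5)
    expect_identical(fit$v0, fit$A * fit$k)  # v0 is A*k by construction
  }
})

test_that("initial-velocity estimator handles degenerate inputs", {
  flat <- timecourse(seq(0, 10, 0.5), rep(0, 21), t_stim = 5)
  expect_equal(fit_initial_velocity(flat)$v0, 0)
  expect_error(fit_initial_velocity(make_eq2_tc(2, 0.5), window = 6),
               "at most 5")
  few <- timecourse(c(0, 5.5, 6), c(0, 1, 1.5), t_stim = 5)
  expect_error(fit_initial_velocity(few), "at least 4")
})

test_that("ecto-ATPase constant is recovered from simulated decay curves", {
  k_true <- 1.70
  p <- quiet_parameters(k_ATPase = k_true, M_cell = 0.2)
  decays <- lapply(c(0.2, 1.2, 4.2, 7), function(c0)
    simulate_protocol(plain_protocol(nucleotide_state(eATP = c0),
                                     times = seq(0, 6, by = 0.1)), p))
  est <- fit_ectoatpase_constant(decays)
  expect_equal(est$slope, k_true, tolerance = 0.05)
  expect_lt(abs(est$slope - k_true), max(2 * est$se, 0.05 * k_true))
  # all-zero decays give slope 0
  zero <- lapply(c(1, 2, 3), function(c0)
    timecourse(seq(0, 6, 0.1), rep(c0, 61), t_stim = 0))
  expect_equal(fit_ectoatpase_constant(zero)$slope, 0, tolerance = 1e-10)
  expect_error(fit_ectoatpase_constant(decays[1:2]), "3 distinct")
})

test_that("global fit has near-zero objective at the truth on noiseless
           data", {
  p <- default_parameters()
  protos <- list(build_scenario("hypotonic_180"))
  sim <- simulate_protocol(protos[[1]], p)
  data <- list(list(timecourse(sim$times, tc_species(sim, "eATP"),
                               scenario = sim$scenario,
                               protein_mg = p$M_cell,
                               t_stim = sim$t_stim)))
  fit <- fit_global(protos, data,
                    free = c(k_ATPase = 0.1, A_NL.180 = 1.2), p = p,
                    maxiter = 5)
  expect_lt(fit$objective, 1e-8)
  expect_equal(unname(fit$par[["k_ATPase"]]), 0.1, tolerance = 1e-3)
})

test_that("free parameters are recovered from the seeded synthetic suite", {
  suite <- make_recovery_suite(seed = 101,
                               scenarios = c("hypotonic_180", "adp_12",
                                             "ndpk_ctp100_adp12"),
                               n_replicates = 3)
  truth <- default_parameters()
  free_names <- c("k_ATPase", "Vmax_NDPK", "A_NL.180", "Ftr_AK")
  start <- setNames(vapply(free_names, function(nm)
    param_get(truth, nm), numeric(1)) * c(1.4, 0.7, 0.75, 1.3),
    free_names)
  fit <- fit_global(lapply(suite$scenarios, `[[`, "protocol"),
                    lapply(suite$scenarios, `[[`, "data"),
                    free = start, p = truth, maxiter = 40)
  rel <- abs(fit$par / vapply(free_names, function(nm)
    param_get(truth, nm), numeric(1)) - 1)
  expect_lt(rel[["k_ATPase"]], 0.15)
  expect_lt(rel[["Vmax_NDPK"]], 0.15)
  expect_lt(rel[["A_NL.180"]], 0.15)
  expect_lt(rel[["Ftr_AK"]], 0.30)   # AK weakly identified at low eADP
  expect_true(all(is.finite(fit$objective)))
  expect_true(all(fit$se[c("k_ATPase", "Vmax_NDPK")] >= 0, na.rm = TRUE))
})

test_that("recovery is stable: median relative error over seeded
           replicates stays inside the identifiability bounds", {
  truth <- default_parameters()
  free_names <- c("k_ATPase", "Vmax_NDPK", "A_NL.180", "Ftr_AK")
  truth_vals <- vapply(free_names, function(nm) param_get(truth, nm),
                       numeric(1))
  rel_errs <- sapply(1:20, function(r) {
    suite <- make_recovery_suite(seed = 200 + r,
                                 scenarios = c("hypotonic_180", "adp_12",
                                               "ndpk_ctp100_adp12"),
                                 n_replicates = 2)
    set.seed(300 + r)
    start <- setNames(truth_vals * exp(runif(4, -0.3, 0.3)), free_names)
    fit <- fit_global(lapply(suite$scenarios, `[[`, "protocol"),
                      lapply(suite$scenarios, `[[`, "data"),
                      free = start, p = truth, maxiter = 25)
    abs(fit$par / truth_vals - 1)
  })
  med <- apply(rel_errs, 1, stats::median)
  expect_lt(med[["k_ATPase"]], 0.15)
  expect_lt(med[["Vmax_NDPK"]], 0.15)
  expect_lt(med[["A_NL.180"]], 0.15)
  expect_lt(med[["Ftr_AK"]], 0.30)
})

test_that("objective is non-increasing across refinement stages", {
  p <- default_parameters()
  proto <- build_scenario("adp_12")
  data <- generate_timecourses(proto, p, n_replicates = 2, seed = 7)
  fit <- fit_global(list(proto), list(data),
                    free = c(Ftr_AK = 1.6), p = p, strategy = "global",
                    seed = 13, n_starts = 4, maxiter = 20)
  expect_true(all(diff(fit$trace) <= 1e-9))
})

test_that("apical/basolateral AK ordering is recovered from data
           synthesized with that ordering", {
  p_ap <- default_parameters("apical")
  p_ba <- default_parameters("basolateral")
  fit_one <- function(scenario, p_true) {
    proto <- build_scenario(scenario)
    data <- generate_timecourses(proto, p_true, n_replicates = 2,
                                 seed = 17)
    fit_global(list(proto), list(data), free = c(Ftr_AK = 1.0),
               p = p_true, maxiter = 25)
  }
  f_ap <- fit_one("polarized_apical_adp12", p_ap)
  f_ba <- fit_one("polarized_basolateral_adp12", p_ba)
  vmax_ap <- vmax_ak_from_scheme(f_ap$par[["Ftr_AK"]], p_ap$k1,
                                 p_ap$k_minus2)
  vmax_ba <- vmax_ak_from_scheme(f_ba$par[["Ftr_AK"]], p_ba$k1,
                                 p_ba$k_minus2)
  expect_gt(vmax_ap, vmax_ba)
})

test_that("unknown free parameters are rejected up front", {
  p <- default_parameters()
  proto <- build_scenario("adp_6")
  expect_error(fit_global(list(proto), list(list()),
                          free = c(not_a_param = 1), p = p),
               "unknown parameter")
})
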