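test_that("an empty system stays identically zero", {
  p <- quiet_parameters()
  tc <- simulate_protocol(plain_protocol(nucleotide_state()), p)
  expect_true(all(tc$conc == 0))
})

test_that("isolated linear eATP decay matches the closed-form exponential", {
  p <- quiet_parameters(k_ATPase = 0.5, M_cell = 0.2)  # k_eff = 0.1 /min
  tc <- simulate_protocol(plain_protocol(nucleotide_state(eATP = 1)), p)
  expect_equal(tc_species(tc, "eATP"), exp(-0.1 * tc$times),
               tolerance = 1e-6)
})

test_that("conservation invariants hold along simulated trajectories", {
  p <- default_parameters()
  for (name in c("ndpk_ctp100_adp12", "utp_100", "hypotonic_180")) {
    tc <- simulate_protocol(build_scenario(name), p)
    utot <- tc_species(tc, "eUTP") + tc_species(tc, "eUDP")
    ctot <- tc_species(tc, "eCTP") + tc_species(tc, "eCDP")
    # piecewise-constant (addition events step the totals; the reported
    # value at the event time itself is the pre-event state)
    ev <- build_scenario(name)$events
    keep <- !(tc$times %in% ev$time)
    segs <- split(seq_along(tc$times)[keep],
                  findInterval(tc$times[keep], sort(unique(ev$time))))
    for (idx in segs) {
      expect_lt(diff(range(utot[idx])), 1e-5)
      expect_lt(diff(range(ctot[idx])), 1e-5)
    }
  }
})

test_that("addition events apply as instantaneous concentration jumps", {
  p <- quiet_parameters()
  proto <- protocol(name = "jump", t_stim = 5,
                    events = data.frame(time = 5, species = "eADP",
                                        amount = 12),
                    init = nucleotide_state(eADP = 0.22),
                    times = seq(0, 20, by = 0.5))
  tc <- simulate_protocol(proto, p)
  v <- tc_species(tc, "eADP")
  expect_equal(v[tc$times < 5], rep(0.22, sum(tc$times < 5)))
  expect_equal(v[tc$times > 5], rep(12.22, sum(tc$times > 5)),
               tolerance = 1e-8)
})

test_that("tightening tolerances 10x leaves trajectories unchanged to 0.1%", {
  p <- default_parameters()
  for (name in c("hypotonic_180", "ndpk_ctp100_adp12")) {
    proto <- build_scenario(name)
    a <- simulate_protocol(proto, p, solver_settings())
    b <- simulate_protocol(proto, p,
                           solver_settings(rtol = 1e-7, atol = 1e-13))
    scale <- max(abs(a$conc))
    expect_lt(max(abs(a$conc - b$conc)) / scale, 1e-3)
  }
})

test_that("splitting a simulation at an interior time is consistent", {
  p <- default_parameters()
  proto <- build_scenario("hypotonic_180")
  full <- simulate_protocol(proto, p)
  t_split <- 10
  first <- proto; first$times <- proto$times[proto$times <= t_split]
  leg1 <- simulate_protocol(first, p)
  second <- proto
  second$times <- proto$times[proto$times >= t_split]
  second$init <- as_nucleotide_state(leg1$conc[nrow(leg1$conc), ])
  leg2 <- simulate_protocol(second, p)
  joined <- rbind(leg1$conc[-nrow(leg1$conc), ], leg2$conc)
  expect_equal(joined, full$conc, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("activity scaling re-simulates with only the target changed", {
  p <- default_parameters()
  proto <- build_scenario("hypotonic_180")
  sc <- compare_activity_scaling(proto, p, "k_ATPase", c(0.2, 1, 5))
  base <- simulate_protocol(proto, p)
  expect_equal(sc$x1$conc, base$conc)
  peaks <- vapply(sc, function(tc) max(tc_species(tc, "eATP")),
                  numeric(1))
  # more ecto-ATPase, faster decay: peak ordering is monotone decreasing
  expect_gt(peaks[["x0.2"]], peaks[["x1"]])
  expect_gt(peaks[["x1"]], peaks[["x5"]])
})

test_that("parameter scans run 4^n simulations and bracket the best fit", {
  p <- default_parameters()
  proto <- build_scenario("hypotonic_180")
  fit <- list(par = c(k_ATPase = 0.1), se = c(k_ATPase = 0.02))
  env <- scan_uncertainty(proto, fit, "k_ATPase", p)
  expect_identical(env$n_sim, 4L)
  expect_true(all(env$lower <= env$best + 1e-12))
  expect_true(all(env$best <= env$upper + 1e-12))
  # grid: two endpoints at +/- SE, two interior at +/- SE/3
  expect_equal(env$grids$k_ATPase,
               0.1 + c(-1, -1/3, 1/3, 1) * 0.02)
  # zero standard errors collapse the envelope onto the best fit
  fit0 <- list(par = c(k_ATPase = 0.1), se = c(k_ATPase = 0))
  env0 <- scan_uncertainty(proto, fit0, "k_ATPase", p)
  expect_equal(env0$lower, env0$best)
  expect_equal(env0$upper, env0$best)
  # combinatorial guard
  fitn <- list(par = setNames(rep(0.1, 7), paste0("p", 1:7)),
               se = setNames(rep(0.01, 7), paste0("p", 1:7)))
  expect_error(scan_uncertainty(proto, fitn, paste0("p", 1:7), p),
               "4\\^n")
  expect_error(scan_uncertainty(proto, list(par = c(k_ATPase = 0.1),
                                            se = NULL), "k_ATPase", p),
               "standard error")
})

test_that("integration failures carry the protocol name", {
  p <- default_parameters()
  proto <- build_scenario("adp_12")
  # an absurd stiffness blow-up: gigantic Vmax with tiny Km
  p_bad <- param_set(param_set(p, "Vmax_NDPK", 1e12), "Km_AD", 1e-10)
  expect_error(
    suppressWarnings(simulate_protocol(build_scenario("ndpk_ctp100_adp12"),
                                       p_bad,
                                       solver_settings(maxsteps = 10))),
    "ndpk_ctp100_adp12")
  expect_s3_class(simulate_protocol(proto, p), "timecourse")
})
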