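test_that("linear hydrolase laws match hand-computed per-mg rates", {
  p <- default_parameters()
  expect_equal(flux_ecto_atpase(nucleotide_state(eATP = 1.5), p,
                                per_mg = TRUE), 0.15)
  expect_equal(flux_ecto_atpase(nucleotide_state(), p), 0)
  p_ap <- default_parameters("apical")
  expect_equal(flux_ecto_atpase(nucleotide_state(eATP = 4.2), p_ap,
                                per_mg = TRUE), 4.2 * 1.70)
  expect_equal(flux_ecto_adpase(nucleotide_state(eADP = 6), p,
                                per_mg = TRUE), 6 * 0.008)
  expect_equal(flux_ecto_adpase(nucleotide_state(eADP = 6),
                                default_parameters("basolateral")), 0)
  p_u <- parameter_set(k_NTPase = c(UTP = 0.01, CTP = 0, GTP = 0.01))
  expect_equal(flux_ecto_ntpase(nucleotide_state(eUTP = 100), p_u, "UTP",
                                per_mg = TRUE), 1.0)
  expect_equal(flux_ecto_ntpase(nucleotide_state(eUTP = 100), p_u, "CTP"), 0)
  # absolute flux is the per-mg rate scaled by the protein mass
  expect_equal(flux_ecto_atpase(nucleotide_state(eATP = 1.5), p),
               0.15 * p$M_cell)
})

test_that("linear laws are homogeneous of degree one in their substrate", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_parameters()
    s1 <- random_state()
    s2 <- as_nucleotide_state(unclass(s1) * 2)
    expect_equal(flux_ecto_atpase(s2, p), 2 * flux_ecto_atpase(s1, p))
    expect_equal(flux_ecto_adpase(s2, p), 2 * flux_ecto_adpase(s1, p))
    expect_equal(flux_ecto_ntpase(s2, p, "UTP"),
                 2 * flux_ecto_ntpase(s1, p, "UTP"))
  }
})

test_that("negative or malformed states are rejected", {
  p <- default_parameters()
  expect_error(flux_ecto_atpase(c(eATP = -1), p), "negative")
  expect_error(purinome_rhs(0, c(eATP = NaN), build_scenario("adp_6"), p))
  expect_error(as_nucleotide_state(c(eXTP = 1)), "unknown species")
})

test_that("ecto-AMPase follows Michaelis-Menten saturation", {
  p <- default_parameters()
  half <- flux_ecto_ampase(nucleotide_state(eAMP = p$Km_AMPase), p,
                           per_mg = TRUE)
  expect_equal(half, p$Vmax_AMPase / 2)
  expect_equal(flux_ecto_ampase(nucleotide_state(), p), 0)
  sat <- flux_ecto_ampase(nucleotide_state(eAMP = 1e9), p, per_mg = TRUE)
  expect_equal(sat, p$Vmax_AMPase, tolerance = 1e-6)
})

test_that("AK maximal velocity derives from the scheme constants", {
  expect_equal(vmax_ak_from_scheme(2, 1, 3), 1.5)
  expect_equal(vmax_ak_from_scheme(0, 1, 3), 0)
  k <- 0.7
  expect_equal(vmax_ak_from_scheme(1.3, k, k), 1.3 * k / 2)
  expect_error(vmax_ak_from_scheme(1, 0, 0), "denominator")
})

test_that("ecto-AK is null at equilibrium, blocked by Ap5A, sigmoidal", {
  p <- default_parameters()
  vmax <- vmax_ak_from_scheme(p$Ftr_AK, p$k1, p$k_minus2)
  # equilibrium: [eADP]^2 = [eATP][eAMP]/Keq
  Tt <- 3; Mm <- 2
  Dd <- sqrt(Tt * Mm / p$Keq_AK)
  eq <- nucleotide_state(eATP = Tt, eAMP = Mm, eADP = Dd)
  expect_equal(flux_ecto_ak(eq, p), 0)
  set.seed(21)
  for (i in 1:10) {
    pr <- random_parameters()
    Tt <- runif(1, 0.1, 10); Mm <- runif(1, 0.1, 10)
    eq <- nucleotide_state(eATP = Tt, eAMP = Mm,
                           eADP = sqrt(Tt * Mm / pr$Keq_AK))
    expect_equal(flux_ecto_ak(eq, pr), 0, tolerance = 1e-12)
  }
  # Ap5A switch
  expect_identical(flux_ecto_ak(random_state(), p, ap5a_blocked = TRUE), 0)
  # half-saturation of the synthesis branch
  hs <- nucleotide_state(eADP = p$K_AK_half)
  expect_equal(flux_ecto_ak(hs, p, per_mg = TRUE), -vmax / 2)
  # synthesis is very low below 3 uM eADP relative to above it
  r1 <- abs(flux_ecto_ak(nucleotide_state(eADP = 1), p))
  r3 <- abs(flux_ecto_ak(nucleotide_state(eADP = 3), p))
  expect_lt(r1, r3 / 4)
})

test_that("ecto-NDPK is reversible ping-pong with the committed form", {
  p <- default_parameters()
  # equilibrium null: [eATP][eNDP] = Keq * [eADP][eNTP]
  st <- nucleotide_state(eATP = 4, eADP = 2, eUTP = 10,
                         eUDP = p$Keq_NDPK * 2 * 10 / 4)
  expect_equal(flux_ecto_ndpk(st, p, "UTP"), 0)
  # saturating substrates, no products: synthesis at -Vmax per mg
  sat <- nucleotide_state(eADP = 1e8, eUTP = 1e8)
  expect_equal(flux_ecto_ndpk(sat, p, "UTP", per_mg = TRUE),
               -p$Vmax_NDPK, tolerance = 1e-5)
  # interior evaluation against an independently written expression
  pi <- parameter_set(Vmax_NDPK = 5, Km_AD = 5, Km_AT = 5,
                      Km_NTP = c(UTP = 5, CTP = 5, GTP = 5),
                      Ki_NDP = 5, Ki_ADP = 5, Keq_NDPK = 1)
  s <- nucleotide_state(eATP = 10, eADP = 10, eAMP = 10, eUTP = 10,
                        eUDP = 10, eCTP = 10, eCDP = 10)
  A <- 10; B <- 10; P <- 10; Q <- 10; Qpool <- 10 + 10
  D <- 5 * B * (1 + Qpool / 5) + 5 * A * (1 + P / 5) + A * B +
    (5 * Q + 5 * P + P * Q) / 1
  expected <- -5 * (A * B - P * Q / 1) / D * pi$M_cell
  expect_equal(flux_ecto_ndpk(s, pi, "UTP"), expected)
  # a large NDP excess drives the flux into eATP consumption
  udp <- nucleotide_state(eATP = 1, eADP = 12, eUDP = 5000, eUTP = 0)
  expect_gt(flux_ecto_ndpk(udp, p, "UTP"), 0)
})

test_that("release flux is leakage before the stimulus, then a decaying
           transient plus lysis only at 100 mOsm", {
  p <- default_parameters()
  proto <- build_scenario("hypotonic_180")
  ts <- proto$t_stim
  expect_equal(flux_release(ts - 1, proto, p, per_mg = TRUE), p$J_leakage)
  expect_equal(flux_release(ts, proto, p, per_mg = TRUE),
               p$J_leakage + p$A_NL[["180"]])
  # half-life of the non-lytic component
  th <- ts + log(2) / p$k_obs
  expect_equal(flux_release(th, proto, p, per_mg = TRUE) - p$J_leakage,
               p$A_NL[["180"]] / 2)
  # lytic term at 100 mOsm only
  p100 <- build_scenario("hypotonic_100")
  expect_equal(flux_release(p100$t_stim, p100, p, per_mg = TRUE),
               p$J_leakage + p$A_NL[["100"]] + p$k_L)
  expect_equal(flux_release(ts, proto, p),
               (p$J_leakage + p$A_NL[["180"]]) * p$M_cell)
})

test_that("rhs conserves adenine total release and pyrimidine pairs", {
  proto <- build_scenario("ndpk_ctp100_adp12")
  proto_u <- build_scenario("utp_100")
  set.seed(31)
  for (i in 1:25) {
    p <- random_parameters()
    s <- random_state()
    t <- runif(1, 0, 35)
    for (pr in list(proto, proto_u)) {
      d <- purinome_rhs(t, s, pr, p)
      adenine <- sum(d[c("eATP", "eADP", "eAMP", "eADO")])
      expect_equal(adenine, flux_release(t, pr, p), tolerance = 1e-12)
      expect_equal(d[["eUTP"]] + d[["eUDP"]], 0)
      expect_equal(d[["eCTP"]] + d[["eCDP"]], 0)
    }
  }
})

test_that("rhs is the zero vector when every flux is off", {
  p <- quiet_parameters()
  d <- purinome_rhs(1, nucleotide_state(), plain_protocol(nucleotide_state()), p)
  expect_equal(unname(d), rep(0, 8))
})

test_that("apical eCTP hydrolysis enters the eCTP/eCDP pair only", {
  p <- default_parameters("apical")
  s <- nucleotide_state(eCTP = 50)
  d <- purinome_rhs(1, s, build_scenario("polarized_apical_shock180"), p)
  expect_lt(d[["eCTP"]], 0)
  expect_equal(d[["eCTP"]] + d[["eCDP"]], 0)
  # basolateral constant is zero
  pb <- default_parameters("basolateral")
  expect_equal(flux_ecto_ntpase(s, pb, "CTP"), 0)
})
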