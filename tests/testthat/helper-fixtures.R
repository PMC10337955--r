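# Shared fixtures: random states/parameters for property-style tests and
# a parameter set with everything switched off except chosen fluxes.

random_state <- function() {
  nucleotide_state(eATP = runif(1, 0, 10), eADP = runif(1, 0, 10),
                   eAMP = runif(1, 0, 10), eADO = runif(1, 0, 10),
                   eUTP = runif(1, 0, 100), eUDP = runif(1, 0, 100),
                   eCTP = runif(1, 0, 100), eCDP = runif(1, 0, 100))
}

random_parameters <- function() {
  parameter_set(k_ATPase = runif(1, 0, 2), k_ADPase = runif(1, 0, 0.1),
                Vmax_AMPase = runif(1, 0, 1), Km_AMPase = runif(1, 1, 50),
                Ftr_AK = runif(1, 0, 3), k1 = runif(1, 0.1, 2),
                k_minus2 = runif(1, 0.1, 2), K_AK_half = runif(1, 1, 20),
                Keq_AK = runif(1, 0.1, 3), Vmax_NDPK = runif(1, 0, 10),
                Km_AD = runif(1, 5, 200), Km_AT = runif(1, 5, 500),
                Km_NTP = c(UTP = runif(1, 5, 500), CTP = runif(1, 5, 500),
                           GTP = runif(1, 5, 500)),
                Ki_NDP = runif(1, 10, 1000), Ki_ADP = runif(1, 10, 1000),
                Keq_NDPK = runif(1, 0.2, 5),
                k_NTPase = c(UTP = runif(1, 0, 0.1),
                             CTP = runif(1, 0, 0.1),
                             GTP = runif(1, 0, 0.1)),
                J_leakage = runif(1, 0, 0.05),
                A_NL = c("300" = 0.02, "180" = runif(1, 0.5, 2),
                         "150" = 2.4, "100" = 3.6),
                k_obs = runif(1, 0.1, 2), k_L = runif(1, 0, 0.2),
                M_cell = runif(1, 0.1, 0.5))
}

# all fluxes off except those re-enabled through ...
quiet_parameters <- function(...) {
  off <- list(k_ATPase = 0, k_ADPase = 0, Vmax_AMPase = 0, Ftr_AK = 0,
              Vmax_NDPK = 0, k_NTPase = c(UTP = 0, CTP = 0, GTP = 0),
              J_leakage = 0,
              A_NL = c("300" = 0, "180" = 0, "150" = 0, "100" = 0),
              k_L = 0)
  do.call(default_parameters, utils::modifyList(off, list(...)))
}

# protocol with no stimulus and no events
plain_protocol <- function(init, times = seq(0, 30, by = 0.5), ...) {
  protocol(name = "plain", init = init, times = times, ...)
}
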