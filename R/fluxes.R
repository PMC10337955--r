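#' Ecto-enzyme flux laws
#'
#' The five ecto-enzyme rate laws of the extracellular purinome model.
#' Fluxes are returned in uM/min referred to the assay volume
#' (per-mg rate multiplied by `p$M_cell`); pass `per_mg = TRUE` for the
#' per-mg-protein rate (uM/min/mg) that luminometry assays report.
#'
#' Sign convention: the two ecto-kinase fluxes ([flux_ecto_ak()] and
#' [flux_ecto_ndpk()]) are signed in the eATP-*consuming* direction, so
#' a negative value means net eATP synthesis.
#'
#' @param state A [nucleotide_state()] (or coercible named vector).
#' @param p A [parameter_set()].
#' @param per_mg If `TRUE`, return the per-mg-protein rate.
#' @return Flux in uM/min (or uM/min/mg).
#' @name fluxes
NULL

#' @describeIn fluxes Linear ecto-ATPase law `k_ATPase * [eATP]`.
#' @export
flux_ecto_atpase <- function(state, p, per_mg = FALSE) {
  s <- as_nucleotide_state(state)
  rate <- p$k_ATPase * s[["eATP"]]
  if (per_mg) rate else rate * p$M_cell
}

#' @describeIn fluxes Linear ecto-ADPase law `k_ADPase * [eADP]`.
#' @export
flux_ecto_adpase <- function(state, p, per_mg = FALSE) {
  s <- as_nucleotide_state(state)
  rate <- p$k_ADPase * s[["eADP"]]
  if (per_mg) rate else rate * p$M_cell
}

#' @describeIn fluxes Michaelis-Menten ecto-5'-nucleotidase law
#'   `Vmax_AMPase * [eAMP] / (Km_AMPase + [eAMP])`.
#' @export
flux_ecto_ampase <- function(state, p, per_mg = FALSE) {
  s <- as_nucleotide_state(state)
  if (p$Km_AMPase <= 0) stop("Km_AMPase must be strictly positive")
  rate <- p$Vmax_AMPase * s[["eAMP"]] / (p$Km_AMPase + s[["eAMP"]])
  if (per_mg) rate else rate * p$M_cell
}

#' @describeIn fluxes Reversible sigmoidal ecto-adenylate-kinase law.
#'   In the eATP-consuming direction (eATP + eAMP -> 2 eADP):
#'   `Vmax_AK * (T*M/Keq_AK - D^2) / (K_AK_half^2 + D^2 + T*M/Keq_AK)`
#'   with `T = [eATP]`, `M = [eAMP]`, `D = [eADP]` and `Vmax_AK` from
#'   [vmax_ak_from_scheme()]. The net rate vanishes at the equilibrium
#'   condition `D^2 = T*M/Keq_AK`; the synthesis branch is sigmoidal
#'   (Hill 2) in eADP with half-saturation `K_AK_half`. Ap5A abolishes
#'   the flux.
#' @param ap5a_blocked If `TRUE` (Ap5A present) the AK flux is exactly 0.
#' @export
flux_ecto_ak <- function(state, p, ap5a_blocked = FALSE, per_mg = FALSE) {
  s <- as_nucleotide_state(state)
  if (isTRUE(ap5a_blocked)) return(0)
  Tt <- s[["eATP"]]; Mm <- s[["eAMP"]]; Dd <- s[["eADP"]]
  q <- Tt * Mm / p$Keq_AK
  rate <- vmax_ak(p) * (q - Dd^2) / (p$K_AK_half^2 + Dd^2 + q)
  if (per_mg) rate else rate * p$M_cell
}

#' @describeIn fluxes Reversible ping-pong bi-bi ecto-NDP-kinase law for
#'   one donor pair. With substrates `A = [eADP]`, `B = [eNTP]` and
#'   products `P = [eATP]`, `Q = [eNDP]` of the synthesis direction, the
#'   net flux in the eATP-consuming direction is
#'   `-Vmax_NDPK * (A*B - P*Q/Keq_NDPK) / D` with
#'   `D = Km_AD*B*(1 + Qpool/Ki_NDP) + Km_NTP*A*(1 + P/Ki_ADP) + A*B +
#'   (Km_AT*Q + Km_NTP*P + P*Q)/Keq_NDPK`, where `Qpool` is the pooled
#'   non-adenine NDP concentration (the donor pairs share one enzyme).
#'   Zero exactly when the mass-action ratio `P*Q/(A*B)` equals
#'   `Keq_NDPK`; tends to `-Vmax_NDPK` (synthesis) at saturating
#'   substrates with no products.
#' @param donor Donor NTP species: `"UTP"`, `"CTP"` or `"GTP"`. GTP uses
#'   the eUTP/eUDP state slots.
#' @export
flux_ecto_ndpk <- function(state, p, donor = c("UTP", "CTP", "GTP"),
                           per_mg = FALSE) {
  donor <- match.arg(donor)
  s <- as_nucleotide_state(state)
  slots <- if (donor == "CTP") c("eCTP", "eCDP") else c("eUTP", "eUDP")
  A <- s[["eADP"]]; B <- s[[slots[1]]]
  P <- s[["eATP"]]; Q <- s[[slots[2]]]
  Qpool <- s[["eUDP"]] + s[["eCDP"]]
  KmN <- p$Km_NTP[[donor]]
  denom <- p$Km_AD * B * (1 + Qpool / p$Ki_NDP) +
    KmN * A * (1 + P / p$Ki_ADP) +
    A * B +
    (p$Km_AT * Q + KmN * P + P * Q) / p$Keq_NDPK
  if (denom <= 0) return(0)
  rate <- -p$Vmax_NDPK * (A * B - P * Q / p$Keq_NDPK) / denom
  if (per_mg) rate else rate * p$M_cell
}

#' @describeIn fluxes Linear hydrolysis of a non-adenine NTP,
#'   `k_NTPase[species] * [eNTP]`; the per-species constant may be 0
#'   (e.g. eCTP outside the apical compartment).
#' @param species Non-adenine NTP species: `"UTP"`, `"CTP"` or `"GTP"`.
#' @export
flux_ecto_ntpase <- function(state, p, species = c("UTP", "CTP", "GTP"),
                             per_mg = FALSE) {
  species <- match.arg(species)
  s <- as_nucleotide_state(state)
  slot <- if (species == "CTP") "eCTP" else "eUTP"
  rate <- p$k_NTPase[[species]] * s[[slot]]
  if (per_mg) rate else rate * p$M_cell
}

a_nl_amplitude <- function(osmolarity, p) {
  osm <- as.numeric(names(p$A_NL))
  o <- order(osm)
  if (length(osm) == 1L) return(unname(p$A_NL[[1]]))
  stats::approx(osm[o], as.numeric(p$A_NL)[o], xout = osmolarity,
                rule = 2)$y
}

#' Intracellular ATP release flux
#'
#' Total ATP release `J_ATP = J_leakage + J_NL(t) + J_L(t)`. Before the
#' stimulus only the constant basal leakage is active. At the stimulus
#' the non-lytic component rises instantaneously to its
#' osmolarity-specific amplitude `A_NL` and inactivates first-order with
#' rate `k_obs`. The lytic component `J_L` is a constant `k_L` from the
#' stimulus onward, active only for the 100 mOsm stimulus.
#'
#' @param t Time in min.
#' @param protocol A [protocol()].
#' @param p A [parameter_set()].
#' @param per_mg If `TRUE`, return uM/min/mg instead of uM/min.
#' @return Release flux J_ATP.
#' @export
flux_release <- function(t, protocol, p, per_mg = FALSE) {
  rate <- p$J_leakage
  if (!is.null(protocol$osmolarity) && t >= protocol$t_stim) {
    rate <- rate +
      a_nl_amplitude(protocol$osmolarity, p) *
        exp(-p$k_obs * (t - protocol$t_stim))
    if (protocol$osmolarity <= 100) rate <- rate + p$k_L
  }
  if (per_mg) rate else rate * p$M_cell
}

#' Time derivatives of the eight extracellular species
#'
#' The right-hand side of the purinome ODE system. With the ecto-kinase
#' fluxes signed in the eATP-consuming direction:
#' \deqn{d\,eATP/dt = J_{ATP} - (J_{ATPase} + J_{AK} + J_{NDPK})}
#' \deqn{d\,eADP/dt = J_{ATPase} - J_{ADPase} + 2 J_{AK} + J_{NDPK}}
#' \deqn{d\,eAMP/dt = J_{ADPase} - (J_{AK} + J_{AMPase})}
#' \deqn{d\,eADO/dt = J_{AMPase}}
#' and, per donor pair, \eqn{d\,eNTP/dt = J_{NDPK} - J_{NTPase}},
#' \eqn{d\,eNDP/dt = -J_{NDPK} + J_{NTPase}}. Both NDPK instances
#' (eUTP/eUDP-slot pair and eCTP/eCDP pair) are evaluated; an instance is
#' identically zero when its pair is absent. eCTP hydrolysis is active
#' only where `k_NTPase["CTP"] > 0` (the apical compartment variant).
#'
#' The enzymatic fluxes cancel in the sum of the four adenine
#' derivatives, which therefore equals [flux_release()]; each NTP/NDP
#' pair sum is conserved.
#'
#' @inheritParams flux_release
#' @param state A [nucleotide_state()].
#' @return Named numeric vector of derivatives, uM/min.
#' @export
purinome_rhs <- function(t, state, protocol, p) {
  s <- as_nucleotide_state(state)
  if (!is.finite(t)) stop("non-finite time in rhs")
  J_rel    <- flux_release(t, protocol, p)
  J_atpase <- flux_ecto_atpase(s, p)
  J_adpase <- flux_ecto_adpase(s, p)
  J_ampase <- flux_ecto_ampase(s, p)
  J_ak     <- flux_ecto_ak(s, p, ap5a_blocked = protocol$ap5a)
  J_ndpk_u <- flux_ecto_ndpk(s, p, donor = protocol$utp_species)
  J_ndpk_c <- flux_ecto_ndpk(s, p, donor = "CTP")
  J_ntp_u  <- flux_ecto_ntpase(s, p, species = protocol$utp_species)
  J_ntp_c  <- flux_ecto_ntpase(s, p, species = "CTP")
  c(eATP = J_rel - (J_atpase + J_ak + J_ndpk_u + J_ndpk_c),
    eADP = J_atpase - J_adpase + 2 * J_ak + J_ndpk_u + J_ndpk_c,
    eAMP = J_adpase - (J_ak + J_ampase),
    eADO = J_ampase,
    eUTP = J_ndpk_u - J_ntp_u,
    eUDP = -J_ndpk_u + J_ntp_u,
    eCTP = J_ndpk_c - J_ntp_c,
    eCDP = -J_ndpk_c + J_ntp_c)
}
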