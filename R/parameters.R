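#' Kinetic parameter set of the extracellular purinome model
#'
#' Bundles every kinetic constant, release parameter and the
#' protein-mass normaliser used by the flux laws. All rate constants are
#' stored per mg of cell protein and are multiplied by `M_cell` inside
#' flux evaluation, so per-mg constants reported by luminometry assays
#' can be used verbatim.
#'
#' @param k_ATPase Linear ecto-ATPase constant,
#'   (uM eATP hydrolysed)/(mg prot * uM eATP * min).
#' @param k_ADPase Linear ecto-ADPase constant, same unit family for eADP.
#' @param Vmax_AMPase,Km_AMPase Michaelis-Menten parameters of
#'   ecto-5'-nucleotidase, uM/(mg min) and uM.
#' @param Ftr_AK,k1,k_minus2 Adenylate-kinase scheme parameters; the
#'   maximal velocity is derived as [vmax_ak_from_scheme()].
#' @param K_AK_half Half-saturation eADP concentration of the sigmoidal
#'   AK synthesis branch, uM.
#' @param Keq_AK Equilibrium constant of 2 eADP <-> eATP + eAMP
#'   (\[eATP\]\[eAMP\]/\[eADP\]^2 at equilibrium), dimensionless.
#' @param Vmax_NDPK Maximal NDP-kinase velocity, uM/(mg min).
#' @param Km_AD Michaelis constant for eADP, uM.
#' @param Km_AT Michaelis constant for eATP (product side), uM.
#' @param Km_NTP Named vector of Michaelis constants per donor NTP
#'   (`UTP`, `CTP`, `GTP`), uM.
#' @param Ki_NDP,Ki_ADP Product-inhibition constants, uM. `Ki_NDP` acts
#'   on the pooled non-adenine NDP concentration because all donor pairs
#'   share a single enzyme.
#' @param Keq_NDPK Equilibrium constant of eADP + eNTP <-> eATP + eNDP,
#'   dimensionless.
#' @param k_NTPase Named vector of linear hydrolysis constants per
#'   non-adenine NTP (`UTP`, `CTP`, `GTP`); a zero disables the flux
#'   (e.g. eCTP hydrolysis outside the apical compartment).
#' @param J_leakage Constant basal ATP release, uM/(mg min).
#' @param A_NL Named vector of peak non-lytic release amplitudes per
#'   stimulus osmolarity (`"300"`, `"180"`, `"150"`, `"100"` mOsm),
#'   uM/(mg min). Other osmolarities are interpolated.
#' @param k_obs First-order inactivation rate of non-lytic release, 1/min.
#' @param k_L Lytic release rate (100 mOsm protocols only), uM/(mg min).
#' @param M_cell Protein mass in the assay, mg.
#' @return Object of class `parameter_set` (a named list).
#' @seealso [default_parameters()] for the calibrated per-compartment
#'   defaults, [vmax_ak_from_scheme()].
#' @export
parameter_set <- function(k_ATPase = 0.1,
                          k_ADPase = 0.008,
                          Vmax_AMPase = 0.1,
                          Km_AMPase = 14,
                          Ftr_AK = 0.8,
                          k1 = 1,
                          k_minus2 = 1,
                          K_AK_half = 6,
                          Keq_AK = 0.44,
                          Vmax_NDPK = 5,
                          Km_AD = 50,
                          Km_AT = 170,
                          Km_NTP = c(UTP = 100, CTP = 100, GTP = 100),
                          Ki_NDP = 300,
                          Ki_ADP = 100,
                          Keq_NDPK = 1,
                          k_NTPase = c(UTP = 0.01, CTP = 0, GTP = 0.01),
                          J_leakage = 0.004,
                          A_NL = c("300" = 0.02, "180" = 1.2,
                                   "150" = 2.4, "100" = 3.6),
                          k_obs = 0.5,
                          k_L = 0.1,
                          M_cell = 0.2) {
  p <- list(k_ATPase = k_ATPase, k_ADPase = k_ADPase,
            Vmax_AMPase = Vmax_AMPase, Km_AMPase = Km_AMPase,
            Ftr_AK = Ftr_AK, k1 = k1, k_minus2 = k_minus2,
            K_AK_half = K_AK_half, Keq_AK = Keq_AK,
            Vmax_NDPK = Vmax_NDPK, Km_AD = Km_AD, Km_AT = Km_AT,
            Km_NTP = Km_NTP, Ki_NDP = Ki_NDP, Ki_ADP = Ki_ADP,
            Keq_NDPK = Keq_NDPK, k_NTPase = k_NTPase,
            J_leakage = J_leakage, A_NL = A_NL, k_obs = k_obs,
            k_L = k_L, M_cell = M_cell)
  validate_parameters(p)
  structure(p, class = "parameter_set")
}

validate_parameters <- function(p) {
  num <- unlist(p)
  if (anyNA(num) || any(!is.finite(num)))
    stop("parameter set contains NA or non-finite values")
  if (any(num < 0))
    stop("negative parameter value: ",
         paste(names(num)[num < 0], collapse = ", "))
  strictly_pos <- c("Km_AMPase", "K_AK_half", "Keq_AK", "Km_AD", "Km_AT",
                    "Ki_NDP", "Ki_ADP", "Keq_NDPK", "M_cell")
  for (nm in strictly_pos)
    if (any(p[[nm]] <= 0))
      stop(nm, " must be strictly positive")
  if (any(p$Km_NTP <= 0)) stop("Km_NTP entries must be strictly positive")
  for (nm in c("Km_NTP", "k_NTPase"))
    if (!all(c("UTP", "CTP", "GTP") %in% names(p[[nm]])))
      stop(nm, " must be named for UTP, CTP and GTP")
  if (is.null(names(p$A_NL)) || anyNA(suppressWarnings(as.numeric(names(p$A_NL)))))
    stop("A_NL must be named by stimulus osmolarity in mOsm")
  invisible(p)
}

#' Calibrated default parameter sets per compartment
#'
#' Returns the package's calibrated [parameter_set()] for non-polarized
#' cells or for the apical or basolateral domain of a polarized
#' monolayer. The compartments differ in the measured ecto-ATPase
#' constant (0.1, 1.70 and 0.36 per mg for non-polarized, apical and
#' basolateral), in the ecto-ADPase and eCTP-hydrolysis constants (both
#' negligible basolaterally, eCTP hydrolysis active only apically), in
#' the ecto-kinase maximal velocities (apical > non-polarized >
#' basolateral) and in the non-lytic release amplitude; the inactivation
#' rate `k_obs` is shared.
#'
#' @param compartment One of `"non_polarized"`, `"apical"`,
#'   `"basolateral"`.
#' @param ... Overrides passed on to [parameter_set()].
#' @return A `parameter_set`.
#' @examples
#' default_parameters()$k_ATPase        # 0.1
#' default_parameters("apical")$k_ATPase  # 1.70
#' @export
default_parameters <- function(compartment = c("non_polarized", "apical",
                                               "basolateral"), ...) {
  compartment <- match.arg(compartment)
  base <- switch(compartment,
    non_polarized = list(),
    apical = list(k_ATPase = 1.70,
                  k_ADPase = 0.008,
                  Ftr_AK = 2.4,
                  Vmax_NDPK = 6,
                  k_NTPase = c(UTP = 0.01, CTP = 0.01, GTP = 0.01),
                  A_NL = c("300" = 0.02, "180" = 2.0,
                           "150" = 4.0, "100" = 6.0)),
    basolateral = list(k_ATPase = 0.36,
                       k_ADPase = 0,
                       Ftr_AK = 0.4,
                       Vmax_NDPK = 2.5,
                       k_NTPase = c(UTP = 0.01, CTP = 0, GTP = 0.01),
                       A_NL = c("300" = 0.02, "180" = 1.0,
                                "150" = 2.0, "100" = 3.0)))
  over <- list(...)
  do.call(parameter_set, utils::modifyList(base, over))
}

#' Maximal adenylate-kinase velocity from the kinetic scheme
#'
#' The AK maximal velocity is not a free parameter but is derived from
#' the fitted transfer factor and the two elementary rate constants of
#' the kinetic scheme as `Ftr_AK * k_minus2 * k1 / (k_minus2 + k1)`.
#'
#' @param Ftr_AK Transfer factor (uM/mg).
#' @param k1,k_minus2 Elementary rate constants (1/min); their sum must
#'   be positive.
#' @return Vmax_AK in uM/(mg min).
#' @examples
#' vmax_ak_from_scheme(2, 1, 3)  # 1.5
#' @export
vmax_ak_from_scheme <- function(Ftr_AK, k1, k_minus2) {
  stopifnot(is.numeric(Ftr_AK), is.numeric(k1), is.numeric(k_minus2))
  if (k1 + k_minus2 <= 0)
    stop("k1 + k_minus2 must be positive (zero denominator)")
  Ftr_AK * k_minus2 * k1 / (k_minus2 + k1)
}

vmax_ak <- function(p) vmax_ak_from_scheme(p$Ftr_AK, p$k1, p$k_minus2)

#' Get or set a parameter by name
#'
#' Parameters living inside named vectors are addressed with a dotted
#' path, e.g. `"A_NL.180"`, `"k_NTPase.UTP"`, `"Km_NTP.CTP"`.
#'
#' @param p A [parameter_set()].
#' @param name Parameter name (dotted path for vector components).
#' @param value Replacement value (non-negative).
#' @return `param_get` the numeric value; `param_set` the modified set.
#' @export
param_get <- function(p, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (!parts[1] %in% names(p)) stop("unknown parameter: ", name)
  v <- p[[parts[1]]]
  if (length(parts) == 1L) {
    if (length(v) != 1L) stop(name, " is a vector; use a dotted component")
    return(unname(v))
  }
  if (!parts[2] %in% names(v)) stop("unknown parameter component: ", name)
  unname(v[[parts[2]]])
}

#' @rdname param_get
#' @export
param_set <- function(p, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (!parts[1] %in% names(p)) stop("unknown parameter: ", name)
  if (length(parts) == 1L) {
    p[[parts[1]]] <- value
  } else {
    v <- p[[parts[1]]]
    if (!parts[2] %in% names(v)) stop("unknown parameter component: ", name)
    v[[parts[2]]] <- value
    p[[parts[1]]] <- v
  }
  validate_parameters(p)
  structure(p, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> (per-mg rate constants; M_cell =", x$M_cell, "mg)\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
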