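#' Stiff ODE solver settings
#'
#' Tolerances and step limit for the LSODA integrator. Defaults follow
#' the model's reference configuration: relative tolerance 1e-6,
#' absolute tolerance 1e-12, at most 1e5 internal steps.
#'
#' @param rtol Relative tolerance (> 0).
#' @param atol Absolute tolerance (> 0).
#' @param maxsteps Maximum internal steps per output interval.
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-6, atol = 1e-12, maxsteps = 1e5) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  structure(list(rtol = rtol, atol = atol, maxsteps = maxsteps),
            class = "solver_settings")
}

#' Simulate a protocol
#'
#' Integrates the eight-species purinome ODE system over a protocol's
#' observation grid with LSODA (automatic stiff/non-stiff switching;
#' release transients of seconds coexist with enzymatic decays of tens
#' of minutes). Addition events are applied as instantaneous
#' concentration jumps (amount over the assay volume) with an integrator
#' restart; the stimulus time is also forced as a restart point so the
#' release discontinuity is resolved cleanly.
#'
#' Tiny negative excursions produced by the integrator (bounded by
#' 1e6 times the absolute tolerance) are clipped to zero; anything
#' larger aborts with a diagnostic naming the protocol and time.
#'
#' @param protocol A [protocol()].
#' @param p A [parameter_set()].
#' @param settings A [solver_settings()].
#' @return A [timecourse()] with all 8 species on the observation grid.
#' @examples
#' tc <- simulate_protocol(build_scenario("hypotonic_180"),
#'                         default_parameters())
#' max(tc_species(tc, "eATP"))
#' @export
simulate_protocol <- function(protocol, p, settings = solver_settings()) {
  stopifnot(inherits(protocol, "protocol"))
  validate_parameters(p)
  y0 <- as_nucleotide_state(protocol$init)
  times <- protocol$times

  ev_times <- unique(protocol$events$time)
  if (!is.null(protocol$osmolarity)) ev_times <- c(ev_times, protocol$t_stim)
  # discontinuities before the window (resumed run) need no restart point
  ev_times <- sort(unique(ev_times))
  ev_times <- ev_times[ev_times >= times[1] & ev_times <= times[length(times)]]

  events <- NULL
  if (length(ev_times)) {
    evdf <- protocol$events
    # zero-amount marker events force an integrator restart at each
    # discontinuity (stimulus onset included)
    marker <- data.frame(time = ev_times, species = "eATP", amount = 0)
    evdf <- rbind(evdf[c("time", "species", "amount")], marker)
    events <- list(data = data.frame(var = evdf$species,
                                     time = evdf$time,
                                     value = evdf$amount,
                                     method = "add"))
  }
  solve_times <- sort(unique(c(times, ev_times)))

  rhs_fn <- function(t, y, parms) {
    y[y < 0 & y > -1e6 * settings$atol] <- 0
    list(unname(purinome_rhs(t, y, protocol, p)))
  }
  out <- try(deSolve::lsoda(y = stats::setNames(as.numeric(y0),
                                                PURINOME_SPECIES),
                            times = solve_times, func = rhs_fn,
                            parms = NULL, rtol = settings$rtol,
                            atol = settings$atol,
                            maxsteps = settings$maxsteps,
                            events = events),
             silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integration failed for protocol '", protocol$name, "': ",
         attr(out, "condition")$message)
  if (nrow(out) < length(solve_times))
    stop("integration of protocol '", protocol$name,
         "' stopped early at t = ", out[nrow(out), 1], " min")

  conc <- out[match(times, out[, 1]), PURINOME_SPECIES, drop = FALSE]
  neg <- conc < 0
  if (any(neg)) {
    worst <- min(conc[neg])
    if (worst < -1e6 * settings$atol)
      stop("negative concentration excursion (", signif(worst, 3),
           " uM) in protocol '", protocol$name, "'")
    conc[neg] <- 0
  }
  timecourse(times = times, conc = conc, scenario = protocol$name,
             protein_mg = p$M_cell,
             t_stim = if (length(ev_times)) min(c(protocol$t_stim,
                                                  ev_times)) else NA_real_,
             provenance = "simulated")
}

#' Parameter-scan uncertainty envelope
#'
#' Propagates parameter uncertainty into a prediction band the way a
#' grid parameter scan does: each scanned parameter takes exactly 4
#' values evenly spanning best-fit +/- one standard error (the two
#' endpoints plus two interior points at +/- SE/3), all 4^n combinations
#' are simulated, and the pointwise minimum/maximum of the observable
#' over all runs forms the envelope.
#'
#' @param protocol A [protocol()].
#' @param fit A [fit_global()] result, or a list with elements `par`
#'   (named best values) and `se` (named standard errors).
#' @param scanned Character vector of parameter names to scan (dotted
#'   paths allowed, see [param_get()]); each must have a standard error.
#' @param p Baseline [parameter_set()] supplying non-scanned parameters.
#' @param settings A [solver_settings()].
#' @param observable Species to envelope (default `"eATP"`).
#' @param force Allow more than 6 scanned parameters (4^n explosion).
#' @return Object of class `uncertainty_envelope` with elements `times`,
#'   `lower`, `upper`, `best`, `n_sim`, `grids`.
#' @export
scan_uncertainty <- function(protocol, fit, scanned, p,
                             settings = solver_settings(),
                             observable = "eATP", force = FALSE) {
  if (length(scanned) > 6 && !force)
    stop("refusing to scan ", length(scanned),
         " parameters (4^n explosion); set force = TRUE to override")
  best <- fit$par; se <- fit$se
  se_vals <- if (is.null(se)) rep(NA_real_, length(scanned)) else
    unlist(se)[scanned]
  missing_se <- scanned[is.na(se_vals)]
  if (length(missing_se))
    stop("no standard error for scanned parameter(s): ",
         paste(missing_se, collapse = ", "))
  p_best <- p
  for (nm in names(best)) p_best <- param_set(p_best, nm, best[[nm]])

  grids <- lapply(scanned, function(nm) {
    b <- best[[nm]]; s <- se[[nm]]
    vals <- b + c(-1, -1/3, 1/3, 1) * s
    pmax(vals, 0)  # rate constants cannot go negative
  })
  names(grids) <- scanned
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)

  best_tc <- simulate_protocol(protocol, p_best, settings)
  obs_best <- tc_species(best_tc, observable)
  lower <- upper <- obs_best
  for (i in seq_len(nrow(combos))) {
    pi <- p_best
    for (nm in scanned) pi <- param_set(pi, nm, combos[i, nm])
    tc <- simulate_protocol(protocol, pi, settings)
    v <- tc_species(tc, observable)
    lower <- pmin(lower, v)
    upper <- pmax(upper, v)
  }
  structure(list(times = best_tc$times, lower = lower, upper = upper,
                 best = obs_best, n_sim = nrow(combos), grids = grids,
                 observable = observable, scenario = protocol$name),
            class = "uncertainty_envelope")
}

#' @export
print.uncertainty_envelope <- function(x, ...) {
  cat("<uncertainty_envelope>", x$scenario, "/", x$observable, "\n")
  cat("  ", length(x$grids), "scanned parameter(s),", x$n_sim,
      "simulations\n")
  cat(sprintf("  band width (max): %.4g uM\n", max(x$upper - x$lower)))
  invisible(x)
}

#' Export an uncertainty envelope as a data frame / CSV
#'
#' @param env An [scan_uncertainty()] result.
#' @param path Optional CSV path; when given the table is also written.
#' @return `data.frame` with columns `time`, `lower`, `upper`, `best`.
#' @export
envelope_to_csv <- function(env, path = NULL) {
  df <- data.frame(time = env$times, lower = env$lower,
                   upper = env$upper, best = env$best)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Re-simulate a protocol under scaled enzyme activity
#'
#' Multiplies one flux constant by each of a set of factors and
#' re-simulates, leaving every other parameter untouched; this is the
#' in-silico "what if the enzyme amount changed" experiment (e.g.
#' 5-fold more or less ecto-ATPase, or 5- and 12-fold more ecto-ADPase).
#'
#' @param protocol A [protocol()].
#' @param p A [parameter_set()].
#' @param target Name of the scaled parameter (dotted path allowed),
#'   e.g. `"k_ATPase"` or `"k_ADPase"`.
#' @param factors Numeric scale factors.
#' @param settings A [solver_settings()].
#' @return Named list of [timecourse()]s, one per factor.
#' @export
compare_activity_scaling <- function(protocol, p, target, factors,
                                     settings = solver_settings()) {
  stopifnot(is.numeric(factors), all(factors >= 0))
  base <- param_get(p, target)
  out <- lapply(factors, function(f) {
    simulate_protocol(protocol, param_set(p, target, base * f), settings)
  })
  names(out) <- paste0("x", factors)
  out
}
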