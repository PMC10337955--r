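#' Initial-velocity estimate from a single-exponential rise
#'
#' Fits `eATP(t) = A * (1 - exp(-k t))` to the first minutes of an eATP
#' synthesis time course (time re-zeroed at substrate addition, baseline
#' subtracted) and reports the initial velocity `v0 = A * k`, the value
#' of the analytic derivative at t = 0.
#'
#' @param tc A [timecourse()]; its recorded `t_stim` marks the substrate
#'   addition unless `t0` is given.
#' @param window Fitting window after addition, min (<= 5).
#' @param t0 Substrate-addition time override, min.
#' @param species Fitted species (default `"eATP"`).
#' @return Object of class `initial_velocity_fit` with fields `A` (uM),
#'   `k` (1/min), `v0 = A*k` (uM/min), `window`, `residual_norm`,
#'   `negative_A` flag.
#' @export
fit_initial_velocity <- function(tc, window = 5, t0 = NULL,
                                 species = "eATP") {
  if (window > 5) stop("window must be at most 5 min")
  if (is.null(t0)) t0 <- tc$t_stim
  if (is.na(t0)) stop("no substrate-addition time available")
  v <- tc_species(tc, species)
  sel <- tc$times > t0 & tc$times <= t0 + window
  if (sum(sel) < 4) stop("need at least 4 points in the fitting window")
  tt <- tc$times[sel] - t0
  base_idx <- which(tc$times <= t0)
  base_val <- if (length(base_idx)) v[max(base_idx)] else 0
  y <- v[sel] - base_val

  if (all(abs(y) < .Machine$double.eps^0.5)) {
    fit <- list(A = 0, k = 0, v0 = 0, window = window,
                residual_norm = 0, negative_A = FALSE)
    return(structure(fit, class = "initial_velocity_fit"))
  }
  A0 <- y[length(y)]
  if (A0 == 0) A0 <- max(abs(y))
  nls_fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * tt)),
                               start = list(A = A0, k = 1),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
  co <- stats::coef(nls_fit)
  if (!all(is.finite(co))) stop("initial-velocity fit did not converge")
  neg <- co[["A"]] < 0
  if (neg) warning("negative fitted amplitude A; check the data window")
  structure(list(A = co[["A"]], k = co[["k"]],
                 v0 = co[["A"]] * co[["k"]], window = window,
                 residual_norm = sqrt(sum(stats::resid(nls_fit)^2)),
                 negative_A = neg),
            class = "initial_velocity_fit")
}

#' @export
print.initial_velocity_fit <- function(x, ...) {
  cat(sprintf(
    "<initial_velocity_fit> A = %.4g uM, k = %.4g /min, v0 = %.4g uM/min\n",
    x$A, x$k, x$v0))
  invisible(x)
}

#' Ecto-ATPase kinetic constant from eATP decay curves
#'
#' Estimates the linear ecto-ATPase constant from decay time courses
#' recorded at several initial eATP levels: the initial decay velocity
#' of each curve (single-exponential fit to the consumed eATP, per mg
#' protein) is regressed linearly on the starting concentration; the
#' slope is `k_ATPase` in (uM eATP)/(mg prot uM eATP min).
#'
#' @param decays List of [timecourse()]s, each an eATP decay from a
#'   different starting level; at least 3 distinct levels required.
#' @param window Initial-velocity window, min.
#' @return List with `slope`, `se`, `intercept`, `velocities`
#'   (data.frame of per-level initial concentrations and decay
#'   velocities) and the underlying `lm` fit.
#' @export
fit_ectoatpase_constant <- function(decays, window = 5) {
  lv <- lapply(decays, function(tc) {
    t0 <- tc$t_stim
    if (is.na(t0)) t0 <- tc$times[1]
    v <- tc_species(tc, "eATP")
    i0 <- which(tc$times >= t0)[1]
    c0 <- v[i0]
    sel <- tc$times > tc$times[i0]
    consumed <- timecourse(times = tc$times[sel] - tc$times[i0],
                           conc = pmax(c0 - v[sel], 0),
                           scenario = tc$scenario, t_stim = 0,
                           protein_mg = tc$protein_mg)
    iv <- fit_initial_velocity(consumed, window = window, t0 = 0)
    c(conc0 = c0, v0_per_mg = iv$v0 / tc$protein_mg)
  })
  tab <- as.data.frame(do.call(rbind, lv))
  if (length(unique(round(tab$conc0, 6))) < 3)
    stop("need at least 3 distinct initial eATP levels")
  fit <- stats::lm(v0_per_mg ~ conc0, data = tab)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["conc0", "Estimate"]),
       se = unname(sm["conc0", "Std. Error"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       velocities = tab, fit = fit)
}

#' Simultaneous multi-experiment parameter estimation
#'
#' Fits free parameters of the purinome model to several experiments at
#' once by weighted least squares: for every protocol/data pairing the
#' model is simulated on the data's time grid (with the replicate's own
#' recorded protein mass) and residuals on the measured species are
#' normalized by the scenario's maximum observed concentration, so
#' micromolar NDPK assays do not dominate nanomolar basal data. The
#' summed weighted SSR is minimized with Levenberg-Marquardt on
#' log-transformed parameters, optionally preceded by a random
#' multistart stage (`strategy = "global"`). Standard errors come from
#' the Gauss-Newton approximation at the optimum (delta method back to
#' the natural scale).
#'
#' @param protocols List of [protocol()]s.
#' @param data List parallel to `protocols`; element i is a list of
#'   [timecourse()] replicates observed under protocol i.
#' @param free Named numeric vector of starting values for the free
#'   parameters (dotted paths allowed, see [param_get()]), or a
#'   character vector of names (starting values then taken from `p`).
#' @param p Baseline [parameter_set()] holding every frozen parameter.
#' @param strategy `"local"` (Levenberg-Marquardt from `free`) or
#'   `"global"` (randomized multistart refinement, then LM).
#' @param seed Seed for the multistart draw (mandatory when
#'   `strategy = "global"`).
#' @param settings A [solver_settings()].
#' @param species Measured species (default `"eATP"`).
#' @param n_starts Multistart candidates for `strategy = "global"`.
#' @param maxiter LM iteration cap for the final refinement.
#' @return Object of class `fit_result`: `par` (best values), `se`,
#'   `objective` (weighted SSR), `trace` (objective per stage,
#'   non-increasing), `frozen`, `unidentifiable` (names with
#'   SE > 10 x value), `seed`, `strategy`.
#' @export
fit_global <- function(protocols, data, free, p,
                       strategy = c("local", "global"), seed = NULL,
                       settings = solver_settings(), species = "eATP",
                       n_starts = 8, maxiter = 60) {
  strategy <- match.arg(strategy)
  if (is.character(free))
    free <- stats::setNames(vapply(free, function(nm) param_get(p, nm),
                                   numeric(1)), free)
  if (any(free <= 0))
    stop("free parameters must start strictly positive (log-scale fit)")
  for (nm in names(free)) param_get(p, nm)  # every free param must exist
  stopifnot(length(protocols) == length(data))
  data <- lapply(data, function(d) if (inherits(d, "timecourse")) list(d) else d)

  weights <- vapply(data, function(reps) {
    m <- max(vapply(reps, function(tc) max(tc_species(tc, species)),
                    numeric(1)))
    if (m <= 0) 1 else m
  }, numeric(1))
  n_res_total <- sum(vapply(data, function(reps)
    sum(vapply(reps, function(tc) length(tc$times), integer(1))),
    integer(1)))

  residuals_fn <- function(logpar) {
    pi <- p
    for (j in seq_along(logpar))
      pi <- param_set(pi, names(free)[j], exp(logpar[j]))
    res <- numeric(0)
    for (i in seq_along(protocols)) {
      proto <- protocols[[i]]
      for (tc in data[[i]]) {
        proto_i <- proto
        proto_i$times <- sort(unique(c(tc$times, proto$t_stim)))
        p_rep <- param_set(pi, "M_cell", tc$protein_mg)
        sim <- try(simulate_protocol(proto_i, p_rep, settings),
                   silent = TRUE)
        if (inherits(sim, "try-error"))
          return(rep(1e4, n_res_total))  # pathological parameter point
        pred <- tc_species(sim, species)[match(tc$times, sim$times)]
        res <- c(res, (pred - tc_species(tc, species)) / weights[i])
      }
    }
    res
  }
  objective <- function(logpar) sum(residuals_fn(logpar)^2)

  start <- log(free)
  trace <- c(start = objective(start))

  if (strategy == "global") {
    if (is.null(seed)) stop("seed is mandatory for the global strategy")
    set.seed(seed)
    starts <- replicate(n_starts,
                        start + stats::runif(length(start), -0.7, 0.7),
                        simplify = FALSE)
    starts <- c(list(start), starts)
    objs <- vapply(starts, objective, numeric(1))
    keep <- starts[order(objs)[seq_len(min(3, length(starts)))]]
    refined <- lapply(keep, function(s0) {
      f <- minpack.lm::nls.lm(par = s0, fn = residuals_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 10))
      list(par = f$par, obj = f$deviance)
    })
    best_stage <- refined[[which.min(vapply(refined, `[[`, numeric(1),
                                            "obj"))]]
    start <- best_stage$par
    trace <- c(trace, multistart = min(min(objs), best_stage$obj))
  }

  fit <- minpack.lm::nls.lm(par = start, fn = residuals_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter))
  trace <- c(trace, final = fit$deviance)
  # the final stage starts from the best point so far; keep whichever won
  if (fit$deviance > trace[length(trace) - 1] + 1e-12) {
    fit$par <- start
    fit$deviance <- objective(start)
    trace[length(trace)] <- fit$deviance
  }

  best_log <- unlist(fit$par)
  best <- stats::setNames(exp(best_log), names(free))

  se <- rep(NA_real_, length(free)); names(se) <- names(free)
  J <- try(fit$hessian, silent = TRUE)
  nres <- length(residuals_fn(best_log))
  dof <- max(nres - length(free), 1)
  if (!inherits(J, "try-error") && !is.null(J)) {
    s2 <- fit$deviance / dof
    cv <- try(solve(J) * 2 * s2, silent = TRUE)  # hessian ~ 2 J'J
    if (!inherits(cv, "try-error")) {
      se_log <- sqrt(pmax(diag(cv), 0))
      se <- best * se_log  # delta method from log scale
    }
  }
  unident <- names(free)[!is.na(se) & se > 10 * best]
  if (length(unident))
    warning("weakly identified parameter(s): ",
            paste(unident, collapse = ", "))

  structure(list(par = best, se = se, objective = fit$deviance,
                 trace = trace, frozen = p, unidentifiable = unident,
                 seed = seed, strategy = strategy,
                 convergence = fit$info),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective =", format(x$objective, digits = 6),
      sprintf("(%s strategy)\n", x$strategy))
  tab <- data.frame(best = x$par, se = x$se)
  print(tab)
  if (length(x$unidentifiable))
    cat("weakly identified:", paste(x$unidentifiable, collapse = ", "),
        "\n")
  invisible(x)
}
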