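#' Define an experimental protocol
#'
#' A protocol bundles everything that defines one luminometry
#' experiment: the compartment variant, an optional hypotonic (or
#' isotonic, 300 mOsm) stimulus, timed nucleotide addition events,
#' inhibitor flags, the initial extracellular state and the observation
#' grid.
#'
#' @param name Scenario identifier (free text).
#' @param compartment `"non_polarized"`, `"apical"` or `"basolateral"`.
#' @param osmolarity Stimulus osmolarity in mOsm (any positive value;
#'   the standard protocols use 300, 180, 150 or 100), or `NULL` for no
#'   osmotic stimulus.
#' @param t_stim Stimulus / substrate-addition time in min (default 5
#'   min of baseline before any event).
#' @param events `data.frame` with columns `time` (min), `species` (one
#'   of [PURINOME_SPECIES]) and `amount` (uM added to the assay volume),
#'   or `NULL`.
#' @param ap5a If `TRUE`, 10 uM Ap5A is present and the ecto-AK flux is
#'   hard-blocked.
#' @param utp_species Species carried by the eUTP/eUDP state slots:
#'   `"UTP"` (default) or `"GTP"` for guanine-donor protocols.
#' @param init Initial [nucleotide_state()].
#' @param times Observation grid in min, strictly increasing, spanning
#'   all event times.
#' @return Object of class `protocol`.
#' @export
protocol <- function(name = "custom",
                     compartment = c("non_polarized", "apical", "basolateral"),
                     osmolarity = NULL,
                     t_stim = 5,
                     events = NULL,
                     ap5a = FALSE,
                     utp_species = c("UTP", "GTP"),
                     init = nucleotide_state(),
                     times = seq(0, 35, by = 0.25)) {
  compartment <- match.arg(compartment)
  utp_species <- match.arg(utp_species)
  if (!is.null(osmolarity)) {
    stopifnot(is.numeric(osmolarity), length(osmolarity) == 1L)
    if (osmolarity <= 0) stop("osmolarity must be positive")
  }
  if (is.null(events))
    events <- data.frame(time = numeric(), species = character(),
                         amount = numeric())
  stopifnot(all(c("time", "species", "amount") %in% names(events)))
  if (nrow(events)) {
    bad <- setdiff(events$species, PURINOME_SPECIES)
    if (length(bad)) stop("unknown species in events: ",
                          paste(bad, collapse = ", "))
    if (any(events$amount < 0)) stop("event amounts must be non-negative")
  }
  if (is.unsorted(times, strictly = TRUE))
    stop("observation times must be strictly increasing")
  tmin <- times[1]; tmax <- times[length(times)]
  if (nrow(events) && (any(events$time < tmin) || any(events$time > tmax)))
    stop("event times must lie within the observation window")
  # t_stim may precede the window (resuming mid-experiment) but never
  # follow it
  if ((!is.null(osmolarity) || nrow(events)) && t_stim > tmax)
    stop("stimulus time must not exceed the observation window")
  structure(list(name = name, compartment = compartment,
                 osmolarity = osmolarity, t_stim = t_stim,
                 events = events, ap5a = ap5a,
                 utp_species = utp_species,
                 init = as_nucleotide_state(init), times = times),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>", x$name, "\n")
  cat("  compartment:", x$compartment,
      if (x$ap5a) "| Ap5A present (AK blocked)" else "", "\n")
  if (!is.null(x$osmolarity))
    cat("  stimulus:", x$osmolarity, "mOsm at t =", x$t_stim, "min\n")
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    t=%g min: +%g uM %s\n", x$events$time[i],
                  x$events$amount[i], x$events$species[i]))
  }
  cat(sprintf("  window: [%g, %g] min, %d points\n", x$times[1],
              x$times[length(x$times)], length(x$times)))
  invisible(x)
}
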