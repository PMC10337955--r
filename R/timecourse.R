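#' Sampled concentration-versus-time series
#'
#' A `timecourse` holds one sampled trajectory: observation times, a
#' concentration matrix (one column per species, uM in the assay
#' volume), and the metadata the estimators need (replicate id, protein
#' mass, scenario id, stimulus time, provenance).
#'
#' @param times Observation times (min), strictly increasing.
#' @param conc Numeric matrix (length(times) rows) or vector; columns
#'   named by species.
#' @param scenario Scenario id.
#' @param replicate Replicate id.
#' @param protein_mg Protein mass in the assay, mg.
#' @param t_stim Stimulus / substrate addition time (min), or `NA`.
#' @param provenance `"observed"`, `"simulated"` or `"synthetic"`.
#' @param truth Optional list recording the generating truth for
#'   synthetic data.
#' @return Object of class `timecourse`.
#' @export
timecourse <- function(times, conc, scenario = "custom", replicate = 1L,
                       protein_mg = 0.2, t_stim = NA_real_,
                       provenance = c("simulated", "observed", "synthetic"),
                       truth = NULL) {
  provenance <- match.arg(provenance)
  if (is.null(dim(conc))) conc <- matrix(conc, ncol = 1,
                                         dimnames = list(NULL, "eATP"))
  conc <- as.matrix(conc)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (nrow(conc) != length(times))
    stop("series length must equal times length")
  if (any(conc < 0, na.rm = TRUE))
    stop("negative concentration in timecourse")
  structure(list(times = times, conc = conc, scenario = scenario,
                 replicate = replicate, protein_mg = protein_mg,
                 t_stim = t_stim, provenance = provenance, truth = truth),
            class = "timecourse")
}

#' Extract one species series from a timecourse
#'
#' @param tc A [timecourse()].
#' @param species Species name (default `"eATP"`, the measured species).
#' @param per_mg If `TRUE`, divide by the recorded protein mass to
#'   report uM/mg protein.
#' @return Numeric vector along `tc$times`.
#' @export
tc_species <- function(tc, species = "eATP", per_mg = FALSE) {
  if (!species %in% colnames(tc$conc))
    stop("species not present in timecourse: ", species)
  v <- tc$conc[, species]
  if (per_mg) v / tc$protein_mg else v
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse>", x$scenario, sprintf("(replicate %s, %s)\n",
      x$replicate, x$provenance))
  cat(sprintf("  %d points over [%g, %g] min; species: %s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              paste(colnames(x$conc), collapse = ", ")))
  cat(sprintf("  protein mass %.3g mg; stimulus at t = %s min\n",
              x$protein_mg, format(x$t_stim)))
  invisible(x)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  sp <- colnames(x$conc)
  data.frame(scenario = x$scenario,
             replicate = x$replicate,
             time_min = rep(x$times, times = length(sp)),
             species = rep(sp, each = length(x$times)),
             conc_uM = as.vector(x$conc),
             protein_mg = x$protein_mg,
             stringsAsFactors = FALSE)
}
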