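#' Read and write time-course CSV files
#'
#' The on-disk dialect is a long-format CSV with header
#' `scenario,replicate,time_min,species,conc_uM,protein_mg`.
#' Concentrations are always stored in uM referred to the assay volume;
#' per-mg normalization is a view ([tc_species()] with `per_mg = TRUE`),
#' never stored. The reader validates the header, monotone time within
#' each scenario/replicate/species series and non-negative
#' concentrations; the writer round-trips losslessly.
#'
#' @param tcs A [timecourse()] or list of them (for writing).
#' @param path File path.
#' @return `read_timecourse_csv`: list of [timecourse()]s;
#'   `write_timecourse_csv`: `path`, invisibly.
#' @export
write_timecourse_csv <- function(tcs, path) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  df <- do.call(rbind, lapply(tcs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- c("scenario", "replicate", "time_min", "species", "conc_uM",
              "protein_mg")
  if (!identical(sort(names(df)), sort(wanted)))
    stop("malformed header: expected columns ",
         paste(wanted, collapse = ","))
  if (any(df$conc_uM < 0))
    stop("negative concentration in ", path)
  key <- interaction(df$scenario, df$replicate, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    sp <- unique(d$species)
    times <- sort(unique(d$time_min))
    conc <- matrix(NA_real_, length(times), length(sp),
                   dimnames = list(NULL, sp))
    for (s in sp) {
      ds <- d[d$species == s, ]
      if (is.unsorted(ds$time_min, strictly = TRUE))
        stop("non-monotone time for scenario '", d$scenario[1],
             "' replicate ", d$replicate[1], " species ", s)
      conc[match(ds$time_min, times), s] <- ds$conc_uM
    }
    timecourse(times = times, conc = conc, scenario = d$scenario[1],
               replicate = d$replicate[1], protein_mg = d$protein_mg[1],
               provenance = "observed")
  })
  unname(out)
}

#' Serialize and restore a parameter set as structured config
#'
#' Parameters are stored as a YAML key-value tree with a provenance tag
#' per parameter (`literature`, `fitted` or `default`), mirroring the
#' split between literature-sourced and fitted constants.
#'
#' @param p A [parameter_set()].
#' @param path YAML file path.
#' @param provenance Optional named character vector tagging parameters.
#' @return `write_parameters`: `path` invisibly; `read_parameters`: a
#'   [parameter_set()] with a `provenance` attribute.
#' @export
write_parameters <- function(p, path, provenance = NULL) {
  obj <- lapply(unclass(p), function(v)
    if (length(v) > 1) as.list(v) else unname(v))
  if (!is.null(provenance)) obj$.provenance <- as.list(provenance)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- yaml::read_yaml(path)
  prov <- obj$.provenance
  obj$.provenance <- NULL
  for (nm in c("Km_NTP", "k_NTPase", "A_NL"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- unlist(obj[[nm]])
  p <- do.call(parameter_set, obj)
  if (!is.null(prov)) attr(p, "provenance") <- unlist(prov)
  p
}
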