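#' Extracellular nucleotide species tracked by the model
#'
#' The eight species of the extracellular purinome state, in canonical
#' order: the adenine ladder (eATP, eADP, eAMP, eADO) plus two
#' triphosphate/diphosphate donor pairs (eUTP/eUDP and eCTP/eCDP).
#' In protocols that use eGTP as the phosphate donor the eUTP/eUDP slots
#' carry the guanine pair (see [protocol()]).
#'
#' @format Character vector of length 8.
#' @export
PURINOME_SPECIES <- c("eATP", "eADP", "eAMP", "eADO",
                      "eUTP", "eUDP", "eCTP", "eCDP")

#' Construct an extracellular nucleotide state
#'
#' A `nucleotide_state` holds the instantaneous concentration of each of
#' the eight extracellular species, in micromolar referred to the assay
#' volume.
#'
#' @param eATP,eADP,eAMP,eADO,eUTP,eUDP,eCTP,eCDP Concentrations in uM;
#'   all must be finite and non-negative.
#' @return Named numeric vector of length 8 with class `nucleotide_state`.
#' @examples
#' nucleotide_state(eATP = 0.04, eADP = 0.22)
#' @export
nucleotide_state <- function(eATP = 0, eADP = 0, eAMP = 0, eADO = 0,
                             eUTP = 0, eUDP = 0, eCTP = 0, eCDP = 0) {
  s <- c(eATP = eATP, eADP = eADP, eAMP = eAMP, eADO = eADO,
         eUTP = eUTP, eUDP = eUDP, eCTP = eCTP, eCDP = eCDP)
  validate_state(s)
  structure(s, class = "nucleotide_state")
}

#' @rdname nucleotide_state
#' @param x Object to coerce / validate.
#' @export
as_nucleotide_state <- function(x) {
  if (inherits(x, "nucleotide_state")) return(x)
  x <- unlist(x)
  if (is.null(names(x))) {
    stopifnot(length(x) == 8L)
    names(x) <- PURINOME_SPECIES
  }
  s <- stats::setNames(numeric(8L), PURINOME_SPECIES)
  bad <- setdiff(names(x), PURINOME_SPECIES)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  s[names(x)] <- x
  validate_state(s)
  structure(s, class = "nucleotide_state")
}

validate_state <- function(s) {
  if (!is.numeric(s) || length(s) != 8L)
    stop("state must be a numeric vector of 8 species concentrations")
  if (anyNA(s) || any(!is.finite(s)))
    stop("state contains NA or non-finite concentrations")
  if (any(s < 0))
    stop("negative concentration in state: ",
         paste(names(s)[s < 0], collapse = ", "))
  invisible(s)
}

#' @export
print.nucleotide_state <- function(x, ...) {
  cat("<nucleotide_state> (uM)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
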