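#' 1D reduced SAXS curve
#'
#' A reduced one-dimensional scattering curve: momentum transfer `q`
#' (nm^-1, strictly increasing, all positive), intensity `I(q)`
#' (non-negative, arbitrary units), optional per-point uncertainty
#' (positive, same units as the intensity), and free-form metadata tags
#' (sample name, N/P ratio, frame index, ...).
#'
#' @param q strictly increasing numeric vector of momentum-transfer values,
#'   nm^-1, length >= 2, all > 0.
#' @param intensity numeric vector of non-negative intensities, same length.
#' @param uncertainty optional numeric vector of positive uncertainties,
#'   same length, or `NULL`.
#' @param metadata named list of free-form tags.
#' @return object of class `saxs_curve`.
#' @export
saxs_curve <- function(q, intensity, uncertainty = NULL, metadata = list()) {
  stopifnot(is.numeric(q), is.numeric(intensity),
            length(q) == length(intensity), length(q) >= 2,
            all(is.finite(q)), all(q > 0), all(diff(q) > 0),
            all(is.finite(intensity)), all(intensity >= 0))
  if (!is.null(uncertainty)) {
    stopifnot(is.numeric(uncertainty), length(uncertainty) == length(q),
              all(is.finite(uncertainty)), all(uncertainty > 0))
  }
  stopifnot(is.list(metadata))
  structure(list(q = q, intensity = intensity, uncertainty = uncertainty,
                 metadata = metadata),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("SAXS curve: %d points, q in [%.4g, %.4g] nm^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$uncertainty)) "" else ", with uncertainties"))
  if (length(x$metadata)) {
    cat("  metadata:",
        paste(names(x$metadata), unlist(x$metadata), sep = " = ",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.saxs_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$uncertainty)) d$uncertainty <- x$uncertainty
  d
}

#' @export
length.saxs_curve <- function(x) length(x$q)
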