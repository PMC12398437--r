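#' Construct a raw spectrum record
#'
#' One channel's detector counts versus wavelength together with the
#' acquisition metadata needed downstream.
#'
#' @param wavelength Strictly increasing wavelength vector in nm.
#' @param counts Nonnegative counts, same length as `wavelength`.
#' @param channel_id One of `CHANNEL_IDS`.
#' @param integration_time_s Positive integration time in seconds.
#' @param metadata Named list (patient_id, sample_id, side, position, ...).
#' @return Object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(wavelength, counts, channel_id, integration_time_s,
                         metadata = list()) {
  if (length(wavelength) != length(counts))
    stop("wavelength and counts lengths differ (",
         length(wavelength), " vs ", length(counts), ")")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing; first violation at row ",
         which(diff(wavelength) <= 0)[1] + 1L)
  if (any(counts < 0)) stop("negative counts")
  if (!is.numeric(integration_time_s) || integration_time_s <= 0)
    stop("integration_time_s must be positive")
  channel_id <- match.arg(channel_id, CHANNEL_IDS)
  structure(list(
    wavelength = as.numeric(wavelength),
    counts = as.numeric(counts),
    channel_id = channel_id,
    integration_time_s = as.numeric(integration_time_s),
    metadata = metadata
  ), class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum %s: %d points %g-%g nm, t=%gs%s>\n",
              x$channel_id, length(x$wavelength),
              min(x$wavelength), max(x$wavelength), x$integration_time_s,
              if (length(x$metadata))
                paste0(", ", paste(names(x$metadata),
                                   unlist(x$metadata, use.names = FALSE),
                                   sep = "=", collapse = " "))
              else ""))
  invisible(x)
}

#' @export
plot.raw_spectrum <- function(x, ...) {
  plot(x$wavelength, x$counts, type = "l",
       xlab = "wavelength (nm)", ylab = "counts",
       main = x$channel_id, ...)
  invisible(x)
}
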