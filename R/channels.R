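#' Channel identifiers of the six-channel DRS-IFS probe
#'
#' Four diffuse-reflectance channels at source-detector separations of
#' 0.5, 0.8, 1.6 and 2.8 mm, and two intrinsic-fluorescence channels
#' excited at 375 and 405 nm.
#'
#' @format Character vector of length 6.
#' @export
CHANNEL_IDS <- c("DRS05", "DRS08", "DRS16", "DRS28", "IFS375", "IFS405")

DRS_SDS_MM <- c(DRS05 = 0.5, DRS08 = 0.8, DRS16 = 1.6, DRS28 = 2.8)
IFS_EXCITATION_NM <- c(IFS375 = 375, IFS405 = 405)

#' Native spectrometer wavelength grid
#'
#' The simulated spectrometers record on a 2 nm pitch over 400--900 nm,
#' comfortably covering the 425--850 nm analysis range so that canonical
#' resampling never extrapolates.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_native_grid <- function() seq(400, 900, by = 2)

#' Canonical analysis wavelength grid
#'
#' All processed spectra live on integer wavelengths 425..850 nm
#' (step 1 nm, 426 points).
#'
#' @return Integer-valued numeric vector of length 426.
#' @export
canonical_grid <- function() seq(425, 850, by = 1)

#' Construct a single channel specification
#'
#' @param channel_id One of `CHANNEL_IDS`.
#' @param native_grid Strictly increasing wavelength vector (nm) the
#'   channel's spectrometer records on; must span at least 425--850 nm.
#' @return An object of class `channel_spec` with fields `channel_id`,
#'   `mode` (`"reflectance"` or `"fluorescence"`), `sds_mm` (DRS only),
#'   `excitation_nm` (IFS only) and `native_grid`.
#' @export
channel_spec <- function(channel_id, native_grid = default_native_grid()) {
  channel_id <- match.arg(channel_id, CHANNEL_IDS)
  stopifnot(is.numeric(native_grid), length(native_grid) >= 4L,
            all(diff(native_grid) > 0))
  if (min(native_grid) > 425 || max(native_grid) < 850)
    stop("native_grid must span at least 425-850 nm")
  drs <- channel_id %in% names(DRS_SDS_MM)
  structure(list(
    channel_id    = channel_id,
    mode          = if (drs) "reflectance" else "fluorescence",
    sds_mm        = if (drs) unname(DRS_SDS_MM[channel_id]) else NULL,
    excitation_nm = if (drs) NULL else unname(IFS_EXCITATION_NM[channel_id]),
    native_grid   = native_grid
  ), class = "channel_spec")
}

#' The full six-channel instrument
#'
#' @inheritParams channel_spec
#' @return Named list of six `channel_spec` objects (4 DRS + 2 IFS).
#' @export
drsifs_instrument <- function(native_grid = default_native_grid()) {
  chs <- lapply(CHANNEL_IDS, channel_spec, native_grid = native_grid)
  names(chs) <- CHANNEL_IDS
  structure(chs, class = "drsifs_instrument")
}

is_drs_channel <- function(channel) {
  inherits(channel, "channel_spec") && channel$mode == "reflectance"
}

is_ifs_channel <- function(channel) {
  inherits(channel, "channel_spec") && channel$mode == "fluorescence"
}

#' @export
print.channel_spec <- function(x, ...) {
  extra <- if (x$mode == "reflectance")
    sprintf("SDS %.1f mm", x$sds_mm)
  else
    sprintf("excitation %d nm", x$excitation_nm)
  cat(sprintf("<channel %s: %s, %s, %d native points %g-%g nm>\n",
              x$channel_id, x$mode, extra, length(x$native_grid),
              min(x$native_grid), max(x$native_grid)))
  invisible(x)
}

#' @export
print.drsifs_instrument <- function(x, ...) {
  cat("Six-channel DRS-IFS instrument:\n")
  for (ch in x) print(ch)
  invisible(x)
}
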