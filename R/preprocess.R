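#' Preprocessing parameters
#'
#' @param snr_min SNR gate threshold (spectra below it are flagged).
#' @param sg_window Savitzky-Golay window length (odd).
#' @param sg_order Savitzky-Golay polynomial order (< window).
#' @param reference_floor_frac Calibration-reference floor as a fraction
#'   of the reference maximum; bins below it are flagged invalid.
#' @return Named list of class `preprocess_params`.
#' @export
preprocess_params <- function(snr_min = 5, sg_window = 11, sg_order = 3,
                              reference_floor_frac = 1e-3) {
  stopifnot(snr_min >= 0, sg_window %% 2 == 1, sg_window > sg_order,
            sg_order >= 1, reference_floor_frac > 0)
  structure(list(snr_min = snr_min, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 reference_floor_frac = reference_floor_frac),
            class = "preprocess_params")
}

SNR_SENTINEL <- 1e6

#' Integration-time (and dark) correction
#'
#' Converts counts to count rates: `(counts - dark) / integration_time`.
#'
#' @param raw A `raw_spectrum`.
#' @param dark Optional dark `raw_spectrum` on the same grid (zeros if
#'   absent); dark counts are subtracted before dividing by the
#'   spectrum's integration time (darks are acquired at the channel's
#'   own integration time).
#' @return A list of class `rate_spectrum` with fields `wavelength`,
#'   `rate`, `channel_id`, `metadata`.
#' @export
correct_integration_time <- function(raw, dark = NULL) {
  stopifnot(inherits(raw, "raw_spectrum"))
  dark_counts <- 0
  if (!is.null(dark)) {
    stopifnot(inherits(dark, "raw_spectrum"))
    if (length(dark$wavelength) != length(raw$wavelength) ||
        any(dark$wavelength != raw$wavelength))
      stop("dark spectrum grid mismatch")
    dark_counts <- dark$counts
  }
  structure(list(
    wavelength = raw$wavelength,
    rate = (raw$counts - dark_counts) / raw$integration_time_s,
    channel_id = raw$channel_id,
    metadata = raw$metadata
  ), class = "rate_spectrum")
}

#' Spectral shape calibration
#'
#' Divides a tissue count-rate spectrum by the matching calibration
#' reference rate (white standard for DRS, fluorescence reference for
#' IFS), cancelling the system response. Reference bins below
#' `floor_frac * max(reference)` are flagged invalid and excluded from
#' downstream window statistics.
#'
#' @param rate A tissue `rate_spectrum`.
#' @param reference The matching reference `rate_spectrum`.
#' @param floor_frac Reference floor fraction.
#' @return A `rate_spectrum` with an additional logical `valid` field.
#' @export
calibrate_shape <- function(rate, reference, floor_frac = 1e-3) {
  stopifnot(inherits(rate, "rate_spectrum"),
            inherits(reference, "rate_spectrum"))
  if (rate$channel_id != reference$channel_id)
    stop("calibration channel mismatch: spectrum ", rate$channel_id,
         " vs reference ", reference$channel_id)
  if (length(rate$wavelength) != length(reference$wavelength) ||
      any(rate$wavelength != reference$wavelength))
    stop("calibration grid mismatch")
  floor <- floor_frac * max(reference$rate)
  if (floor <= 0 || all(reference$rate < floor))
    stop("calibration reference entirely below floor")
  valid <- reference$rate >= floor
  out <- rate$rate
  out[valid] <- out[valid] / reference$rate[valid]
  out[!valid] <- NA_real_
  structure(list(wavelength = rate$wavelength, rate = out,
                 channel_id = rate$channel_id, metadata = rate$metadata,
                 valid = valid), class = "rate_spectrum")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing via `signal::sgolayfilt`;
#' edge points use polynomial fits over windows anchored at the spectrum
#' ends. Length is preserved.
#'
#' @param x Numeric vector.
#' @param window Odd window length, greater than `order`.
#' @param order Polynomial order.
#' @return Smoothed vector of the same length.
#' @export
smooth_savitzky_golay <- function(x, window = 11, order = 3) {
  if (window %% 2 != 1 || window <= order || order < 1)
    stop("need odd window > order >= 1")
  if (length(x) < window)
    stop("spectrum shorter than the smoothing window")
  signal::sgolayfilt(x, p = sg_filter_matrix(order, window))
}

# the SG projection matrix is expensive to build; cache per (order, window)
.sg_cache <- new.env(parent = emptyenv())
sg_filter_matrix <- function(order, window) {
  key <- paste(order, window)
  f <- .sg_cache[[key]]
  if (is.null(f)) {
    f <- signal::sgolay(p = order, n = window)
    .sg_cache[[key]] <- f
  }
  f
}

#' Signal-to-noise ratio of a spectrum
#'
#' `SNR = (max(smoothed) - baseline) / sigma_hat`, with the smoothed
#' curve from Savitzky-Golay filtering, `baseline` the 5th percentile of
#' the smoothed curve, and `sigma_hat` the noise SD estimated from the
#' smoothing residuals `x - smoothed`. Because the residual of a linear
#' smoother under white noise has variance `sigma^2 (1 - 2 h0 + sum h^2)`
#' (`h` the central filter row), the raw residual SD is rescaled by that
#' factor so `sigma_hat` is unbiased for the detector noise. A noise-free
#' spectrum returns a large sentinel (the SNR is also capped there), so
#' it always passes the gate. Invalid (NA) bins are ignored.
#'
#' @param x Numeric vector (count rate or calibrated intensity).
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param smoothed Optional precomputed Savitzky-Golay smoothing of `x`
#'   (with the same parameters), to avoid filtering twice.
#' @return Nonnegative scalar.
#' @export
compute_snr <- function(x, sg_window = 11, sg_order = 3, smoothed = NULL) {
  ok <- is.finite(x)
  x <- x[ok]
  if (length(x) < sg_window)
    stop("spectrum shorter than the smoothing window")
  sm <- if (is.null(smoothed)) smooth_savitzky_golay(x, sg_window, sg_order)
        else smoothed[ok]
  h <- sg_filter_matrix(sg_order, sg_window)[(sg_window + 1) / 2, ]
  shrink <- sqrt(1 - 2 * h[(sg_window + 1) / 2] + sum(h^2))
  sigma_hat <- stats::sd(x - sm) / shrink
  signal <- max(sm) - stats::quantile(sm, 0.05, names = FALSE)
  if (sigma_hat == 0) return(SNR_SENTINEL)
  min(max(signal / sigma_hat, 0), SNR_SENTINEL)
}

#' Resample a spectrum to the canonical grid
#'
#' Cubic-spline interpolation onto integer wavelengths 425..850 nm
#' (426 points). Canonical points outside the native range, or backed by
#' no nearby valid native point, come back `NA` and invalid.
#'
#' @param wavelength Native wavelength vector (nm), strictly increasing.
#' @param x Intensities on the native grid (may contain NA for invalid
#'   bins; those are dropped before fitting).
#' @return List with `intensities` (length 426) and logical `valid`.
#' @export
resample_to_canonical <- function(wavelength, x) {
  grid <- canonical_grid()
  ok <- is.finite(x)
  if (sum(ok) < 4) stop("fewer than 4 valid native points")
  wl <- wavelength[ok]; xv <- x[ok]
  fit <- stats::spline(wl, xv, xout = grid, method = "fmm")
  out <- fit$y
  # no extrapolation: kill canonical points outside the valid native span
  # or farther than two native steps from any valid native point
  step <- stats::median(diff(wavelength))
  pos <- findInterval(grid, wl)
  lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(wl))
  near <- pmin(abs(grid - wl[lo]), abs(grid - wl[hi])) <= 2 * step
  valid <- grid >= min(wl) & grid <= max(wl) & near
  out[!valid] <- NA_real_
  list(intensities = out, valid = valid)
}

#' Preprocess a single raw spectrum
#'
#' Applies, in order: integration-time correction (with dark
#' subtraction), spectral shape calibration, SNR computation and gate,
#' Savitzky-Golay smoothing, canonical resampling. A failed gate never
#' raises; the record comes back flagged `passed_qc = FALSE`.
#'
#' @param raw A `raw_spectrum`.
#' @param calibration A `calibration_set` covering the channel.
#' @param params A `preprocess_params`.
#' @return List of class `processed_spectrum`: `intensities` (426),
#'   `valid`, `snr`, `passed_qc`, `channel_id`, `metadata`.
#' @export
preprocess_spectrum <- function(raw, calibration,
                                params = preprocess_params()) {
  preprocess_one(raw, reference_rate(calibration, raw$channel_id),
                 calibration$dark[[raw$channel_id]], params)
}

# count-rate reference (white standard or fluorescence film) for a channel
reference_rate <- function(calibration, ch) {
  ref_raw <- if (ch %in% names(calibration$white)) calibration$white[[ch]]
             else calibration$reference[[ch]]
  if (is.null(ref_raw))
    stop("calibration set is missing channel ", ch)
  correct_integration_time(ref_raw, calibration$dark[[ch]])
}

preprocess_one <- function(raw, ref_rate, dark, params) {
  rate <- correct_integration_time(raw, dark)
  cal <- calibrate_shape(rate, ref_rate, params$reference_floor_frac)
  ok <- is.finite(cal$rate)
  sm <- cal$rate
  sm[ok] <- smooth_savitzky_golay(cal$rate[ok], params$sg_window,
                                  params$sg_order)
  snr <- compute_snr(cal$rate, params$sg_window, params$sg_order,
                     smoothed = sm)
  passed <- snr >= params$snr_min
  res <- resample_to_canonical(cal$wavelength, sm)
  structure(list(intensities = res$intensities, valid = res$valid,
                 snr = snr, passed_qc = passed,
                 channel_id = raw$channel_id,
                 metadata = raw$metadata), class = "processed_spectrum")
}

#' Preprocess a full dataset
#'
#' Runs [preprocess_spectrum()] over every spectrum of every acquisition
#' set and collects the results into a spectra-by-wavelength matrix with
#' per-spectrum metadata (sample class and quality grade joined from the
#' sample table).
#'
#' @param dataset A `drsifs_dataset` (or a list with `sets`,
#'   `calibration`, `samples`).
#' @param params A `preprocess_params`.
#' @return Object of class `processed_spectra`: `meta` (data.frame, one
#'   row per spectrum), `intensities` and `valid` (matrices, 426
#'   columns), `grid`, `params`.
#' @export
preprocess_dataset <- function(dataset, params = preprocess_params()) {
  sets <- dataset$sets
  n <- length(sets) * 6L
  grid <- canonical_grid()
  intens <- matrix(NA_real_, n, length(grid))
  valid <- matrix(FALSE, n, length(grid))
  cls <- stats::setNames(dataset$samples$tissue_class,
                         dataset$samples$sample_id)
  grd <- stats::setNames(dataset$samples$quality_grade,
                         dataset$samples$sample_id)
  refs <- lapply(stats::setNames(nm = CHANNEL_IDS), function(ch)
    reference_rate(dataset$calibration, ch))
  set_id <- patient_id <- sample_id <- side <- channel_id <- character(n)
  position <- integer(n)
  snr <- numeric(n)
  passed_qc <- logical(n)
  i <- 0L
  for (st in sets) {
    for (sp in st$spectra) {
      i <- i + 1L
      ps <- preprocess_one(sp, refs[[sp$channel_id]],
                           dataset$calibration$dark[[sp$channel_id]], params)
      intens[i, ] <- ps$intensities
      valid[i, ] <- ps$valid
      set_id[i] <- st$set_id; patient_id[i] <- st$patient_id
      sample_id[i] <- st$sample_id; side[i] <- st$side
      position[i] <- st$position; channel_id[i] <- sp$channel_id
      snr[i] <- ps$snr; passed_qc[i] <- ps$passed_qc
    }
  }
  meta <- data.frame(
    set_id = set_id, patient_id = patient_id, sample_id = sample_id,
    side = side, position = position, channel_id = channel_id,
    tissue_class = unname(cls[sample_id]),
    quality_grade = unname(grd[sample_id]),
    snr = snr, passed_qc = passed_qc, stringsAsFactors = FALSE)
  structure(list(meta = meta, intensities = intens,
                 valid = valid, grid = grid, params = params),
            class = "processed_spectra")
}

#' @export
print.processed_spectra <- function(x, ...) {
  cat(sprintf(
    "<processed_spectra: %d spectra x %d wavelengths, %d (%.1f%%) passed the SNR >= %g gate>\n",
    nrow(x$meta), length(x$grid), sum(x$meta$passed_qc),
    100 * mean(x$meta$passed_qc), x$params$snr_min))
  invisible(x)
}
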