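#' Instrument noise parameters
#'
#' @param shot_scale Scale of the signal-proportional (shot) noise
#'   variance: `var_shot = shot_scale * expected_counts`.
#' @param read_sd Gaussian read-noise standard deviation in counts.
#' @param dark_offset Constant dark level in counts.
#' @return Named list of class `noise_params`.
#' @export
noise_params <- function(shot_scale = 1, read_sd = 8, dark_offset = 120) {
  stopifnot(shot_scale >= 0, read_sd >= 0, dark_offset >= 0)
  structure(list(shot_scale = shot_scale, read_sd = read_sd,
                 dark_offset = dark_offset), class = "noise_params")
}

#' Default per-channel integration times (seconds)
#'
#' Longer times at larger source-detector separations compensate the
#' weaker diffuse signal, mimicking the auto-exposure of the real system.
#'
#' @return Named numeric vector over the six channels.
#' @export
default_integration_times <- function() {
  c(DRS05 = 0.10, DRS08 = 0.15, DRS16 = 0.25, DRS28 = 0.40,
    IFS375 = 0.50, IFS405 = 0.50)
}

#' Spectral system response of a channel
#'
#' Combined lamp/fibre/spectrometer throughput in counts per second per
#' unit ideal intensity: a broad smooth bell over the visible range with
#' a channel-class gain.
#'
#' @param wavelength Wavelengths in nm.
#' @param channel A `channel_spec`.
#' @return Positive response vector.
#' @export
system_response <- function(wavelength, channel) {
  gain <- if (is_drs_channel(channel)) 3e4 else 1e4
  gain * exp(-0.5 * ((wavelength - 640) / 180)^2)
}

#' Push an ideal spectrum through the simulated instrument
#'
#' `counts = ideal * response * t + dark_offset + shot + read`, where the
#' shot term has variance `shot_scale * expected_counts` and the read term
#' is Gaussian with SD `read_sd`; counts are clipped at zero. Uses the
#' current RNG state.
#'
#' @param ideal Ideal (noise-free, response-free) spectrum on the
#'   channel's native grid.
#' @param channel A `channel_spec`.
#' @param integration_time_s Positive integration time in seconds.
#' @param noise A `noise_params` object.
#' @param response System response vector; defaults to
#'   [system_response()] on the channel grid. Pass `rep(1, n)` for an
#'   ideal detector.
#' @param metadata Metadata list attached to the output record.
#' @return A `raw_spectrum`.
#' @export
instrument_apply <- function(ideal, channel, integration_time_s,
                             noise = noise_params(),
                             response = system_response(channel$native_grid,
                                                        channel),
                             metadata = list()) {
  if (!is.numeric(integration_time_s) || integration_time_s <= 0)
    stop("integration_time_s must be positive")
  stopifnot(length(ideal) == length(channel$native_grid),
            length(response) == length(ideal))
  mean_counts <- ideal * response * integration_time_s + noise$dark_offset
  n <- length(mean_counts)
  counts <- mean_counts
  if (noise$shot_scale > 0)
    counts <- counts +
      stats::rnorm(n, 0, sqrt(noise$shot_scale * pmax(mean_counts, 0)))
  if (noise$read_sd > 0)
    counts <- counts + stats::rnorm(n, 0, noise$read_sd)
  raw_spectrum(channel$native_grid, pmax(counts, 0), channel$channel_id,
               integration_time_s, metadata)
}

#' Generate a calibration set
#'
#' One white-standard measurement per DRS channel (Spectralon-like flat
#' 99% reflector), one fluorescence-reference measurement per IFS channel
#' (spectrally flat white fluorescent film), and one dark measurement per
#' channel, all pushed through the same instrument model. Uses the
#' current RNG state.
#'
#' @param instrument A `drsifs_instrument`.
#' @param noise A `noise_params` object.
#' @param integration_times Named vector of per-channel times (seconds).
#' @return Object of class `calibration_set` with fields `white`,
#'   `reference` and `dark` (named lists of `raw_spectrum`).
#' @export
generate_calibration_set <- function(instrument = drsifs_instrument(),
                                     noise = noise_params(),
                                     integration_times =
                                       default_integration_times()) {
  white <- list(); reference <- list(); dark <- list()
  for (ch in instrument) {
    n <- length(ch$native_grid)
    t_ch <- unname(integration_times[ch$channel_id])
    if (is_drs_channel(ch)) {
      white[[ch$channel_id]] <- instrument_apply(
        rep(0.99, n), ch, t_ch, noise,
        metadata = list(kind = "white_standard"))
    } else {
      reference[[ch$channel_id]] <- instrument_apply(
        rep(1, n), ch, t_ch, noise,
        metadata = list(kind = "fluorescence_reference"))
    }
    dark[[ch$channel_id]] <- instrument_apply(
      rep(0, n), ch, t_ch, noise, metadata = list(kind = "dark"))
  }
  structure(list(white = white, reference = reference, dark = dark,
                 integration_times = integration_times),
            class = "calibration_set")
}

#' Grade sample quality from size and dye contamination
#'
#' Grade 3 ("poor") if the maximum dimension is below 3 mm or the sample
#' is heavily dye-contaminated; grade 2 ("mediocre") if the dimension lies
#' in [3, 4] mm or dye is partially present; grade 1 ("good") otherwise
#' (> 4 mm, dye-free). The worst applicable grade wins.
#'
#' @param max_dimension_mm Nonnegative sample dimension(s) in mm.
#' @param dye_contamination One of `"none"`, `"partial"`, `"heavy"`
#'   (recycled against `max_dimension_mm`).
#' @return Integer grade(s) in 1..3.
#' @export
grade_quality <- function(max_dimension_mm, dye_contamination) {
  if (any(max_dimension_mm < 0)) stop("negative sample dimension")
  dye <- match.arg(dye_contamination, c("none", "partial", "heavy"),
                   several.ok = TRUE)
  n <- max(length(max_dimension_mm), length(dye))
  d <- rep_len(max_dimension_mm, n)
  dye <- rep_len(dye, n)
  ifelse(d < 3 | dye == "heavy", 3L,
         ifelse(d <= 4 | dye == "partial", 2L, 1L))
}

DYE_CONC <- c(none = 0, partial = 0.05, heavy = 0.25)

#' Simulation configuration
#'
#' Defaults emulate the ex-vivo study design: a patient, sample, side,
#' rotation-position hierarchy with 8--10 positions per side and six
#' spectra per acquisition set (96--120 spectra per sample), a class mix
#' matching the study cohort (62/46/46/21/6 of 181 samples), and
#' shot-plus-read detector noise.
#'
#' @param n_patients Number of simulated patients.
#' @param class_mix Named probability vector over `TISSUE_CLASSES`
#'   (must sum to 1).
#' @param samples_per_patient Named probability vector; names are sample
#'   counts (default 70% one sample, 30% two).
#' @param positions_per_side Candidate rotation-position counts per side.
#' @param class_contrast Nonnegative scalar scaling between-class
#'   parameter differences; 0 makes all classes identically distributed.
#' @param spectra_noise A `noise_params` object.
#' @param integration_times Named per-channel integration times (s).
#' @param native_grid Spectrometer wavelength grid.
#' @param dye_probs Probabilities of none/partial/heavy dye contamination.
#' @param rng_seed Integer seed; the generated dataset is a deterministic
#'   function of the full configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 10,
                       class_mix = c(healthy = 62, IDC = 46, ILC = 46,
                                     DCIS = 21, pCR = 6) / 181,
                       samples_per_patient = c(`1` = 0.7, `2` = 0.3),
                       positions_per_side = 8:10,
                       class_contrast = 1,
                       spectra_noise = noise_params(),
                       integration_times = default_integration_times(),
                       native_grid = default_native_grid(),
                       dye_probs = c(none = 0.45, partial = 0.40,
                                     heavy = 0.15),
                       rng_seed = 1L) {
  stopifnot(n_patients >= 1,
            all(TISSUE_CLASSES %in% names(class_mix)),
            all(class_mix >= 0),
            abs(sum(class_mix) - 1) < 1e-8,
            all(positions_per_side >= 1),
            class_contrast >= 0,
            inherits(spectra_noise, "noise_params"),
            abs(sum(dye_probs) - 1) < 1e-8)
  structure(list(
    n_patients = as.integer(n_patients),
    class_mix = class_mix[TISSUE_CLASSES],
    samples_per_patient = samples_per_patient,
    positions_per_side = positions_per_side,
    class_contrast = class_contrast,
    spectra_noise = spectra_noise,
    integration_times = integration_times,
    native_grid = native_grid,
    dye_probs = dye_probs[c("none", "partial", "heavy")],
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Generate a full synthetic DRS-IFS dataset
#'
#' Simulates the patient / sample / side / rotation-position hierarchy:
#' each sample gets a class-conditional tissue model (with shared
#' patient-level variability), is measured from both sides at 8--10
#' rotation positions, six spectra per acquisition set, and is assigned a
#' quality grade from its simulated size and dye contamination (dye also
#' enters the optics as an additive absorber). A matching calibration set
#' is generated with the same instrument and noise model.
#'
#' @param config A `sim_config`.
#' @return Object of class `drsifs_dataset` with fields `samples`
#'   (data.frame of sample records), `sets` (list of acquisition sets,
#'   each with six `raw_spectrum` records), `calibration`
#'   (a `calibration_set`) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  instrument <- drsifs_instrument(config$native_grid)
  calibration <- generate_calibration_set(instrument, config$spectra_noise,
                                          config$integration_times)
  samples <- list(); sets <- list()
  sidx <- 0L
  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("P%03d", p)
    n_samp <- as.integer(sample(names(config$samples_per_patient), 1,
                                prob = config$samples_per_patient))
    patient_effect <- list(thb = stats::rlnorm(1, 0, 0.12),
                           scatter = stats::rlnorm(1, 0, 0.08),
                           fluor = stats::rlnorm(1, 0, 0.15))
    for (s in seq_len(n_samp)) {
      sidx <- sidx + 1L
      sample_id <- sprintf("S%04d", sidx)
      tissue_class <- sample(names(config$class_mix), 1,
                             prob = config$class_mix)
      max_dim <- min(max(exp(stats::rnorm(1, log(9), 0.45)), 2), 27)
      dye <- sample(names(config$dye_probs), 1, prob = config$dye_probs)
      grade <- grade_quality(max_dim, dye)
      model <- sample_tissue_model(tissue_class, config, patient_effect)
      model$dye_conc <- unname(DYE_CONC[dye])
      ideals <- lapply(instrument, function(ch)
        if (is_drs_channel(ch)) drs_forward(model, ch)
        else ifs_forward(model, ch))
      npos <- if (length(config$positions_per_side) > 1)
        sample(config$positions_per_side, 1) else config$positions_per_side
      n_spec <- 0L
      for (side in c("anterior", "posterior")) {
        for (pos in seq_len(npos)) {
          contact_scale <- stats::rlnorm(1, 0, 0.03)
          meta <- list(patient_id = patient_id, sample_id = sample_id,
                       side = side, position = pos)
          spectra <- lapply(instrument, function(ch)
            instrument_apply(ideals[[ch$channel_id]] * contact_scale, ch,
                             unname(config$integration_times[ch$channel_id]),
                             config$spectra_noise, metadata = meta))
          names(spectra) <- CHANNEL_IDS
          sets[[length(sets) + 1L]] <- list(
            set_id = sprintf("%s_%s_%02d", sample_id, side, pos),
            patient_id = patient_id, sample_id = sample_id,
            side = side, position = pos, spectra = spectra)
          n_spec <- n_spec + 6L
        }
      }
      samples[[sidx]] <- data.frame(
        sample_id = sample_id, patient_id = patient_id,
        tissue_class = tissue_class, max_dimension_mm = max_dim,
        dye_contamination = dye, quality_grade = grade,
        n_spectra = n_spec, stringsAsFactors = FALSE)
    }
  }
  structure(list(samples = do.call(rbind, samples), sets = sets,
                 calibration = calibration, config = config),
            class = "drsifs_dataset")
}

#' @export
print.drsifs_dataset <- function(x, ...) {
  cat(sprintf(
    "<drsifs_dataset: %d patients, %d samples, %d acquisition sets (%d spectra)>\n",
    length(unique(x$samples$patient_id)), nrow(x$samples),
    length(x$sets), sum(x$samples$n_spectra)))
  print(table(x$samples$tissue_class))
  invisible(x)
}
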