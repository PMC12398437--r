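#' @name optics
#' @title Tissue optical model
#'
#' @description
#' The simulator describes each tissue sample by a small set of optical
#' parameters: chromophore concentrations driving absorption, a power-law
#' reduced-scattering spectrum, and fluorophore weights per excitation
#' wavelength. Absorption mixes linearly over five chromophores relevant
#' to breast tissue (oxy-/deoxy-haemoglobin, lipid, water, beta-carotene);
#' scattering follows the usual Mie-type power law
#' \eqn{\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b}} referenced at
#' \eqn{\lambda_0 = 786} nm.
#'
#' The extinction and emission basis curves are smooth synthetic analogues
#' (Gaussian mixtures placed at the literature peak positions: haemoglobin
#' Soret/Q bands, the 760 nm deoxy-Hb and lipid bands, the NIR water band,
#' carotenoid absorption below ~550 nm), not digitised literature tables.
#' Their shapes give the simulated classes realistic spectral contrast;
#' absolute units are arbitrary apart from the healthy-adipose anchor
#' (0.041 cm^-1 absorption, 8.5 cm^-1 reduced scattering at 786 nm).
NULL

CHROMOPHORES <- c("oxyHb", "deoxyHb", "lipid", "water", "betaCarotene")
FLUOROPHORES <- c("NADH", "FAD", "collagen", "elastin", "lipopigment")

MUSP_REFERENCE_NM <- 786

gauss <- function(lambda, mu, sd) exp(-0.5 * ((lambda - mu) / sd)^2)

#' Chromophore extinction basis
#'
#' Synthetic smooth extinction curves, one column per chromophore, in
#' cm^-1 per unit concentration. Valid over 400--900 nm.
#'
#' @param wavelength Numeric vector of wavelengths in nm.
#' @return Matrix `length(wavelength) x 5` with columns
#'   `oxyHb, deoxyHb, lipid, water, betaCarotene`.
#' @export
extinction_basis <- function(wavelength) {
  l <- wavelength
  if (any(l < 400 | l > 900))
    stop("wavelength outside the bundled extinction basis range (400-900 nm)")
  cbind(
    oxyHb = 55 * gauss(l, 415, 26) + 6.5 * gauss(l, 542, 14) +
      7.5 * gauss(l, 577, 12) + 0.02 + 0.06 * stats::plogis((l - 700) / 60),
    deoxyHb = 60 * gauss(l, 430, 28) + 9 * gauss(l, 556, 20) +
      1.8 * gauss(l, 757, 22) + 0.04,
    lipid = 3e-4 + 6e-3 * gauss(l, 760, 28) + 1e-2 * gauss(l, 830, 50),
    water = 5e-4 + 4.5e-3 * gauss(l, 740, 28) + 3e-2 * gauss(l, 840, 45),
    betaCarotene = 0.30 * gauss(l, 462, 42)
  )
}

# Patent-blue-like histological dye; additive absorber used for simulated
# grade-2/3 samples (broad band centred near 640 nm).
dye_extinction <- function(wavelength) gauss(wavelength, 640, 45)

#' Fluorophore emission basis
#'
#' Synthetic unimodal emission curves (unit peak height), one column per
#' endogenous fluorophore, at the literature emission maxima.
#'
#' @param wavelength Numeric vector of wavelengths in nm.
#' @return Matrix `length(wavelength) x 5` with columns
#'   `NADH, FAD, collagen, elastin, lipopigment`.
#' @export
emission_basis <- function(wavelength) {
  l <- wavelength
  cbind(
    NADH        = gauss(l, 460, 38),
    FAD         = gauss(l, 530, 42),
    collagen    = gauss(l, 450, 35),
    elastin     = gauss(l, 475, 40),
    lipopigment = gauss(l, 570, 52)
  )
}

#' Construct a tissue optical model
#'
#' @param class_label One of `healthy, IDC, ILC, DCIS, pCR`.
#' @param chromophore_conc Named nonnegative vector over
#'   `oxyHb, deoxyHb, lipid, water, betaCarotene` (arbitrary units scaled
#'   so that absorption comes out in cm^-1).
#' @param scatter_amplitude_a Reduced scattering at 786 nm, cm^-1.
#' @param scatter_power_b Dimensionless scattering power.
#' @param fluor_weights Named list with elements `"375"` and `"405"`,
#'   each a named nonnegative vector over the five fluorophores.
#' @param mua_floor Constant background absorption, cm^-1.
#' @param dye_conc Nonnegative concentration of histological dye
#'   (additive absorber; 0 for uncontaminated tissue).
#' @return Object of class `tissue_optical_model`.
#' @export
tissue_optical_model <- function(class_label, chromophore_conc,
                                 scatter_amplitude_a, scatter_power_b,
                                 fluor_weights,
                                 mua_floor = 0.002, dye_conc = 0) {
  class_label <- match.arg(class_label, TISSUE_CLASSES)
  stopifnot(all(CHROMOPHORES %in% names(chromophore_conc)),
            all(chromophore_conc >= 0),
            scatter_amplitude_a > 0, scatter_power_b >= 0,
            all(c("375", "405") %in% names(fluor_weights)),
            mua_floor >= 0, dye_conc >= 0)
  for (w in fluor_weights)
    stopifnot(all(FLUOROPHORES %in% names(w)), all(w >= 0))
  structure(list(
    class_label = class_label,
    chromophore_conc = chromophore_conc[CHROMOPHORES],
    scatter_amplitude_a = scatter_amplitude_a,
    scatter_power_b = scatter_power_b,
    fluor_weights = lapply(fluor_weights, function(w) w[FLUOROPHORES]),
    mua_floor = mua_floor,
    dye_conc = dye_conc
  ), class = "tissue_optical_model")
}

#' Absorption coefficient of a tissue model
#'
#' Linear chromophore mixing plus the constant floor and, if present,
#' the histological-dye term:
#' \eqn{\mu_a(\lambda) = \sum_c conc_c \epsilon_c(\lambda) + floor + dye}.
#'
#' @param model A `tissue_optical_model`.
#' @param wavelength Wavelengths in nm (within the basis range).
#' @return Strictly positive vector of \eqn{\mu_a} in cm^-1.
#' @export
absorption_mu_a <- function(model, wavelength) {
  stopifnot(inherits(model, "tissue_optical_model"))
  eps <- extinction_basis(wavelength)
  mua <- drop(eps %*% model$chromophore_conc) + model$mua_floor +
    model$dye_conc * dye_extinction(wavelength)
  unname(mua)
}

#' Reduced scattering coefficient of a tissue model
#'
#' @inheritParams absorption_mu_a
#' @return Vector of \eqn{\mu_s'} in cm^-1.
#' @export
reduced_scattering <- function(model, wavelength) {
  stopifnot(inherits(model, "tissue_optical_model"))
  model$scatter_amplitude_a *
    (wavelength / MUSP_REFERENCE_NM)^(-model$scatter_power_b)
}

# Steady-state diffusion-dipole (extrapolated boundary) spatially resolved
# reflectance from a semi-infinite homogeneous medium, in cm^-2 up to a
# constant collection factor. rho, mua, musp in cm / cm^-1.
# Internal reflection handled through the Groenhuis empirical formula for
# relative refractive index n_rel.
farrell_reflectance <- function(rho_cm, mua, musp, n_rel = 1.4) {
  mut <- mua + musp
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  mueff <- sqrt(3 * mua * mut)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  A <- (1 + rd) / (1 - rd)
  zb <- 2 * A * D
  r1 <- sqrt(z0^2 + rho_cm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_cm^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

#' Ideal diffuse reflectance spectrum of a DRS channel
#'
#' Evaluates the diffusion-dipole closed form for spatially resolved
#' reflectance of a semi-infinite medium at the channel's source-detector
#' separation. A warning is raised where the diffusion validity condition
#' \eqn{\mu_s' > \mu_a} fails.
#'
#' @param model A `tissue_optical_model`.
#' @param channel A DRS `channel_spec`.
#' @param wavelength Wavelengths in nm; defaults to the channel grid.
#' @return Positive dimensionless reflectance vector.
#' @export
drs_forward <- function(model, channel, wavelength = channel$native_grid) {
  if (!is_drs_channel(channel))
    stop("drs_forward requires a reflectance channel, got ",
         channel$channel_id)
  mua <- absorption_mu_a(model, wavelength)
  musp <- reduced_scattering(model, wavelength)
  if (any(musp <= mua))
    warning("diffusion approximation invalid (mu_s' <= mu_a) at some wavelengths")
  farrell_reflectance(channel$sds_mm / 10, mua, musp)
}

#' Ideal intrinsic fluorescence emission spectrum of an IFS channel
#'
#' Weighted sum of fluorophore emission bases (weights specific to the
#' channel's excitation wavelength), attenuated by tissue absorption over
#' an effective escape path, and cut to zero below the 425 nm long-pass
#' filter edge.
#'
#' @inheritParams drs_forward
#' @param channel An IFS `channel_spec`.
#' @param escape_path_cm Effective emission escape path length in cm.
#' @return Nonnegative emission vector (arbitrary units).
#' @export
ifs_forward <- function(model, channel, wavelength = channel$native_grid,
                        escape_path_cm = 0.03) {
  if (!is_ifs_channel(channel))
    stop("ifs_forward requires a fluorescence channel, got ",
         channel$channel_id)
  w <- model$fluor_weights[[as.character(channel$excitation_nm)]]
  emi <- drop(emission_basis(wavelength) %*% w)
  emi <- emi * exp(-absorption_mu_a(model, wavelength) * escape_path_cm)
  emi[wavelength < 425] <- 0
  pmax(emi, 0)
}

#' @export
print.tissue_optical_model <- function(x, ...) {
  cat(sprintf("<tissue_optical_model: %s>\n", x$class_label))
  cat("  chromophores:",
      paste(sprintf("%s=%.4g", names(x$chromophore_conc),
                    x$chromophore_conc), collapse = ", "), "\n")
  cat(sprintf("  scattering: a=%.3g cm^-1 @786nm, b=%.3g\n",
              x$scatter_amplitude_a, x$scatter_power_b))
  if (x$dye_conc > 0) cat(sprintf("  dye_conc=%.3g\n", x$dye_conc))
  invisible(x)
}
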