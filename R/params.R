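#' Tissue class labels
#'
#' Healthy tissue, invasive ductal carcinoma (IDC), invasive lobular
#' carcinoma (ILC), ductal carcinoma in situ (DCIS) and pathological
#' complete response after neoadjuvant chemotherapy (pCR).
#'
#' @format Character vector of length 5.
#' @export
TISSUE_CLASSES <- c("healthy", "IDC", "ILC", "DCIS", "pCR")

# Healthy (predominantly adipose) reference parameters. The haemoglobin
# concentration is solved so that the model reproduces the fatty-breast
# literature anchor mu_a = 0.041 cm^-1 at 786 nm exactly; reduced
# scattering is anchored at 8.5 cm^-1 (a-parameter, reference 786 nm).
healthy_reference_params <- function() {
  sat <- 0.55
  lipid <- 0.6; water <- 0.3; bcar <- 0.01; floor <- 0.002
  eps <- extinction_basis(MUSP_REFERENCE_NM)
  fixed <- drop(lipid * eps[, "lipid"] + water * eps[, "water"] +
                  bcar * eps[, "betaCarotene"]) + floor
  per_thb <- drop(sat * eps[, "oxyHb"] + (1 - sat) * eps[, "deoxyHb"])
  thb <- unname((0.041 - fixed) / per_thb)
  list(
    thb = thb, sat = sat, lipid = lipid, water = water,
    betaCarotene = bcar, mua_floor = floor,
    scatter_a = 8.5, scatter_b = 0.7,
    fluor = list(
      `375` = c(NADH = 1.00, FAD = 0.30, collagen = 0.80,
                elastin = 0.40, lipopigment = 0.15),
      `405` = c(NADH = 0.50, FAD = 0.80, collagen = 0.60,
                elastin = 0.35, lipopigment = 0.25)
    )
  )
}

#' Class-contrast parameter table
#'
#' Mean multiplicative offsets of each tissue class relative to the healthy
#' reference, applied geometrically scaled by the simulator's
#' `class_contrast` (ratio^contrast), so that contrast 0 collapses all
#' classes onto identical parameter distributions. Tumour classes carry
#' more haemoglobin, water, collagen fluorescence and scattering and less
#' lipid/beta-carotene than healthy adipose tissue; pCR is modelled as
#' fibrotic (collagen-rich) but nearly normally perfused. Oxygen
#' saturation is interpolated additively (it is a fraction, not a scale).
#'
#' @return Named list, one entry per tissue class, each with multiplier
#'   fields `thb, lipid, water, betaCarotene, scatter_a, scatter_b`,
#'   per-fluorophore multipliers, and a target saturation `sat`.
#' @export
tissue_class_table <- function() {
  list(
    healthy = list(thb = 1, lipid = 1, water = 1, betaCarotene = 1,
                   scatter_a = 1, scatter_b = 1, sat = 0.55,
                   fluor = c(NADH = 1, FAD = 1, collagen = 1,
                             elastin = 1, lipopigment = 1)),
    IDC = list(thb = 2.2, lipid = 0.45, water = 1.5, betaCarotene = 0.4,
               scatter_a = 1.5, scatter_b = 1.35, sat = 0.45,
               fluor = c(NADH = 1.8, FAD = 1.25, collagen = 1.6,
                         elastin = 1.1, lipopigment = 0.8)),
    ILC = list(thb = 1.8, lipid = 0.5, water = 1.4, betaCarotene = 0.5,
               scatter_a = 1.4, scatter_b = 1.25, sat = 0.47,
               fluor = c(NADH = 1.5, FAD = 1.15, collagen = 1.9,
                         elastin = 1.15, lipopigment = 0.85)),
    DCIS = list(thb = 1.5, lipid = 0.65, water = 1.25, betaCarotene = 0.6,
                scatter_a = 1.25, scatter_b = 1.15, sat = 0.50,
                fluor = c(NADH = 1.4, FAD = 1.2, collagen = 1.3,
                          elastin = 1.05, lipopigment = 0.9)),
    pCR = list(thb = 1.1, lipid = 0.75, water = 1.1, betaCarotene = 0.8,
               scatter_a = 1.2, scatter_b = 1.1, sat = 0.53,
               fluor = c(NADH = 0.9, FAD = 0.95, collagen = 2.2,
                         elastin = 1.2, lipopigment = 1.1))
  )
}

#' Default healthy tissue model
#'
#' The class-mean healthy model (no sampling variability); reproduces the
#' adipose-breast anchor \eqn{\mu_a(786) = 0.041} cm^-1,
#' \eqn{\mu_s'(786) = 8.5} cm^-1.
#'
#' @return A `tissue_optical_model`.
#' @export
default_healthy_model <- function() {
  p <- healthy_reference_params()
  tissue_optical_model(
    "healthy",
    c(oxyHb = p$sat * p$thb, deoxyHb = (1 - p$sat) * p$thb,
      lipid = p$lipid, water = p$water, betaCarotene = p$betaCarotene),
    scatter_amplitude_a = p$scatter_a, scatter_power_b = p$scatter_b,
    fluor_weights = p$fluor, mua_floor = p$mua_floor
  )
}

#' Draw a class-conditional tissue optical model
#'
#' Parameters are drawn log-normally around class means obtained from the
#' healthy reference and the class-contrast table; `class_contrast = 0`
#' makes all classes identically distributed. Uses the current RNG state.
#'
#' @param class_label One of `TISSUE_CLASSES`.
#' @param config A `sim_config` (only `class_contrast` is used).
#' @param patient_effect Optional named list of shared patient-level
#'   multipliers (`thb`, `scatter`, `fluor`) as produced by the dataset
#'   generator; defaults to no effect.
#' @return A `tissue_optical_model`.
#' @export
sample_tissue_model <- function(class_label, config = sim_config(),
                                patient_effect = NULL) {
  class_label <- match.arg(class_label, TISSUE_CLASSES)
  contrast <- config$class_contrast
  stopifnot(contrast >= 0)
  ref <- healthy_reference_params()
  mult <- tissue_class_table()[[class_label]]
  if (is.null(patient_effect))
    patient_effect <- list(thb = 1, scatter = 1, fluor = 1)
  gscale <- function(x, ratio) x * ratio^contrast
  # within-class biological variability (lognormal, CVs chosen to mimic
  # the spread of published breast optical-property compilations)
  thb <- gscale(ref$thb, mult$thb) * patient_effect$thb *
    stats::rlnorm(1, 0, 0.25)
  sat <- min(max(ref$sat + contrast * (mult$sat - ref$sat) +
                   stats::rnorm(1, 0, 0.04), 0.05), 0.98)
  lipid <- gscale(ref$lipid, mult$lipid) * stats::rlnorm(1, 0, 0.15)
  water <- gscale(ref$water, mult$water) * stats::rlnorm(1, 0, 0.15)
  bcar <- gscale(ref$betaCarotene, mult$betaCarotene) *
    stats::rlnorm(1, 0, 0.30)
  a <- gscale(ref$scatter_a, mult$scatter_a) * patient_effect$scatter *
    stats::rlnorm(1, 0, 0.12)
  b <- gscale(ref$scatter_b, mult$scatter_b) * stats::rlnorm(1, 0, 0.08)
  fluor <- lapply(ref$fluor, function(w)
    gscale(w, mult$fluor) * patient_effect$fluor *
      stats::rlnorm(length(w), 0, 0.20))
  tissue_optical_model(
    class_label,
    c(oxyHb = sat * thb, deoxyHb = (1 - sat) * thb,
      lipid = lipid, water = water, betaCarotene = bcar),
    scatter_amplitude_a = a, scatter_power_b = b,
    fluor_weights = fluor, mua_floor = ref$mua_floor
  )
}
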