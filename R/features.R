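#' The 20 fixed spectral windows
#'
#' Twenty contiguous 20 nm windows covering 450--850 nm. Windows are
#' half-open `[start, end)` except the last, which is closed at 850 nm,
#' so every canonical grid point in 450--850 belongs to exactly one
#' window.
#'
#' @return data.frame with columns `index`, `start_nm`, `end_nm`,
#'   `closed_right`.
#' @export
make_windows <- function() {
  start <- 450 + 20 * (0:19)
  data.frame(index = 1:20, start_nm = start, end_nm = start + 20,
             closed_right = c(rep(FALSE, 19), TRUE))
}

# window index (1..20, NA outside 450-850) for each canonical grid point
window_index <- function(wavelength) {
  idx <- findInterval(wavelength, 450 + 20 * (0:20),
                      rightmost.closed = TRUE)
  idx[idx < 1 | idx > 20] <- NA_integer_
  idx
}

WINDOW_STATS <- c("mean", "max", "min", "argmax_nm", "argmin_nm")

#' Fixed-window features of one processed spectrum
#'
#' For each of the 20 windows: mean, maximum and minimum intensity, and
#' the wavelengths at which the maximum and minimum occur (ties broken
#' towards the smallest wavelength) -- 100 features per spectrum.
#' Invalid bins are excluded; a window with no valid bin yields `NA`
#' features.
#'
#' @param intensities Vector on the canonical grid (426 points), or a
#'   `processed_spectrum`.
#' @param valid Optional logical mask of valid bins.
#' @return Named numeric vector of length 100
#'   (`W01_mean ... W20_argmin_nm`).
#' @export
extract_fixed_window_features <- function(intensities, valid = NULL) {
  if (inherits(intensities, "processed_spectrum")) {
    valid <- intensities$valid
    intensities <- intensities$intensities
  }
  grid <- canonical_grid()
  stopifnot(length(intensities) == length(grid))
  if (is.null(valid)) valid <- rep(TRUE, length(grid))
  valid <- valid & is.finite(intensities)
  widx <- window_index(grid)
  out <- numeric(0)
  for (w in 1:20) {
    in_w <- which(!is.na(widx) & widx == w & valid)
    if (length(in_w) == 0) {
      vals <- rep(NA_real_, 5)
    } else {
      y <- intensities[in_w]; wl <- grid[in_w]
      vals <- c(mean(y), max(y), min(y),
                wl[which.max(y)], wl[which.min(y)])
    }
    names(vals) <- sprintf("W%02d_%s", w, WINDOW_STATS)
    out <- c(out, vals)
  }
  out
}

#' Build the per-acquisition-set feature table for a channel combination
#'
#' Extracts fixed-window features for every spectrum that passed QC and
#' concatenates them per acquisition set in the combination's order
#' (column names `CHANNEL_Wkk_stat`; `100 * m` feature columns for `m`
#' channels). Acquisition sets missing any required channel (failed QC)
#' are dropped; the dropped count is attached as attribute `n_dropped`.
#'
#' @param processed A `processed_spectra` object.
#' @param combination Character vector of channel ids (subset of
#'   `CHANNEL_IDS`, no duplicates).
#' @return data.frame: metadata columns (`set_id`, `patient_id`,
#'   `sample_id`, `side`, `position`, `tissue_class`, `quality_grade`)
#'   followed by the feature columns.
#' @export
featurize <- function(processed, combination = c("IFS405", "DRS08", "DRS28")) {
  stopifnot(inherits(processed, "processed_spectra"),
            length(combination) >= 1,
            all(combination %in% CHANNEL_IDS),
            !anyDuplicated(combination))
  meta <- processed$meta
  rows <- list(); metas <- list(); dropped <- 0L
  idx_by_set <- split(seq_len(nrow(meta)),
                      factor(meta$set_id, levels = unique(meta$set_id)))
  for (sid in names(idx_by_set)) {
    in_set <- idx_by_set[[sid]]
    feats <- numeric(0)
    ok <- TRUE
    for (ch in combination) {
      i <- in_set[meta$channel_id[in_set] == ch & meta$passed_qc[in_set]]
      if (length(i) != 1) { ok <- FALSE; break }
      f <- extract_fixed_window_features(processed$intensities[i, ],
                                         processed$valid[i, ])
      names(f) <- paste0(ch, "_", names(f))
      feats <- c(feats, f)
    }
    if (!ok) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- feats
    m <- meta[in_set[1], c("set_id", "patient_id", "sample_id", "side",
                           "position", "tissue_class", "quality_grade")]
    metas[[length(metas) + 1L]] <- m
  }
  if (length(rows) == 0) stop("no acquisition set has all channels of the combination")
  out <- cbind(do.call(rbind, metas),
               as.data.frame(do.call(rbind, rows)))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  attr(out, "combination") <- combination
  out
}

#' Names of the feature columns of a feature table
#'
#' @param feature_table A data.frame produced by [featurize()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(feature_table) {
  grep("^(DRS|IFS)[0-9]+_W[0-9]{2}_", names(feature_table), value = TRUE)
}

#' Boruta all-relevant feature selection
#'
#' Shadow-feature importance race: at each iteration every not-yet-
#' rejected feature is duplicated as a permuted "shadow", a random forest
#' is fitted on real + shadow features, and a feature scores a hit when
#' its importance exceeds the maximum shadow importance. Features are
#' confirmed (rejected) when a two-sided binomial test of their hit count
#' against rate 0.5, Bonferroni-corrected over the still-tentative
#' features, falls below `alpha` on the high (low) side. Stops when
#' nothing is tentative or at `max_iter`. Uses the current RNG state.
#'
#' @param x Numeric matrix or data.frame of features (no missing values).
#' @param y Class labels (>= 2 classes).
#' @param alpha Significance level of the binomial tests.
#' @param max_iter Maximum number of importance iterations.
#' @param num_trees Trees per random forest.
#' @return Object of class `boruta_result`: factor `decision`
#'   (`confirmed`/`rejected`/`tentative`) per feature, hit counts,
#'   iteration count, and the per-iteration importance history.
#' @export
boruta_select <- function(x, y, alpha = 0.01, max_iter = 100,
                          num_trees = 80) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("boruta_select requires complete features; impute first")
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  p <- ncol(x)
  feat_names <- colnames(x)
  if (is.null(feat_names)) feat_names <- paste0("V", seq_len(p))
  decision <- rep("tentative", p)
  hits <- integer(p)
  tested <- integer(p)   # iterations each feature took part in
  history <- list()
  n <- nrow(x)
  it <- 0L
  while (any(decision == "tentative") && it < max_iter) {
    it <- it + 1L
    live <- which(decision != "rejected")
    shadows <- apply(x[, live, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0("shadow_", seq_along(live))
    dat <- data.frame(x[, live, drop = FALSE], shadows, check.names = FALSE)
    dat$.y <- y
    fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                          num.trees = num_trees, importance = "impurity",
                          num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance
    shadow_max <- max(imp[grepl("^shadow_", names(imp))])
    real_imp <- imp[seq_along(live)]
    hit <- real_imp > shadow_max
    tent <- decision[live] == "tentative"
    hits[live[tent]] <- hits[live[tent]] + hit[tent]
    tested[live[tent]] <- tested[live[tent]] + 1L
    history[[it]] <- stats::setNames(real_imp, feat_names[live])
    tent_all <- which(decision == "tentative")
    n_tests <- length(tent_all)
    for (j in tent_all) {
      p_hi <- stats::pbinom(hits[j] - 1L, tested[j], 0.5,
                            lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[j], tested[j], 0.5)
      if (min(p_hi * n_tests, 1) < alpha) decision[j] <- "confirmed"
      else if (min(p_lo * n_tests, 1) < alpha) decision[j] <- "rejected"
    }
  }
  structure(list(
    decision = factor(decision, c("confirmed", "rejected", "tentative")),
    feature_names = feat_names, hits = hits, tested = tested,
    n_iterations = it, alpha = alpha, importance_history = history
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat(sprintf(
    "<boruta_result: %d iterations, alpha=%g; confirmed %d, rejected %d, tentative %d of %d>\n",
    x$n_iterations, x$alpha, tab["confirmed"], tab["rejected"],
    tab["tentative"], length(x$decision)))
  invisible(x)
}

#' Reduce a feature matrix to the Boruta-selected columns
#'
#' @param x Feature matrix/data.frame whose columns match the Boruta run.
#' @param result A `boruta_result`.
#' @param keep `"confirmed"` or `"confirmed_tentative"`.
#' @param fallback If nothing survives, `"all"` keeps the full matrix
#'   (with a warning); `"error"` fails.
#' @return The reduced matrix, column names and order preserved.
#' @export
select_features <- function(x, result, keep = c("confirmed",
                                                "confirmed_tentative"),
                            fallback = c("all", "error")) {
  keep <- match.arg(keep); fallback <- match.arg(fallback)
  stopifnot(inherits(result, "boruta_result"))
  if (ncol(x) != length(result$decision) ||
      !identical(colnames(x), result$feature_names))
    stop("feature matrix does not match the boruta_result")
  levels_keep <- if (keep == "confirmed") "confirmed"
                 else c("confirmed", "tentative")
  sel <- result$decision %in% levels_keep
  if (!any(sel)) {
    if (fallback == "error") stop("no features selected")
    warning("Boruta selected no features; falling back to the full matrix")
    return(x)
  }
  x[, sel, drop = FALSE]
}
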