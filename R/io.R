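#' Write a spectrum to a delimited text file
#'
#' Two-column CSV (`wavelength_nm,counts`) preceded by `#`-prefixed
#' header lines carrying `channel_id`, `integration_time_s` and any
#' metadata fields.
#'
#' @param spectrum A `raw_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_file <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  hdr <- c(sprintf("# channel_id: %s", spectrum$channel_id),
           sprintf("# integration_time_s: %.12g",
                   spectrum$integration_time_s))
  for (k in names(spectrum$metadata))
    hdr <- c(hdr, sprintf("# %s: %s", k, spectrum$metadata[[k]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "wavelength_nm,counts"), con)
  writeLines(sprintf("%.12g,%.12g", spectrum$wavelength, spectrum$counts),
             con)
  invisible(path)
}

#' Read a spectrum file
#'
#' Parses the `#`-header two-column format written by
#' [write_spectrum_file()], with distinct diagnostics for a malformed
#' header, missing integration time, non-monotone wavelengths and row
#' length problems.
#'
#' @param path File path.
#' @return A `raw_spectrum`.
#' @export
read_spectrum_file <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad))
    stop("malformed header line: ", hdr[bad][1])
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  meta <- as.list(stats::setNames(vals, keys))
  if (is.null(meta$channel_id)) stop("missing metadata: channel_id")
  if (is.null(meta$integration_time_s))
    stop("missing metadata: integration_time_s")
  body <- lines[!is_hdr]
  if (length(body) < 2 || body[1] != "wavelength_nm,counts")
    stop("malformed header: expected 'wavelength_nm,counts' column line")
  dat <- utils::read.csv(text = body)
  if (ncol(dat) != 2) stop("expected exactly two data columns")
  pos <- as.numeric(meta$position)
  raw_spectrum(dat$wavelength_nm, dat$counts, meta$channel_id,
               as.numeric(meta$integration_time_s),
               metadata = c(meta[setdiff(names(meta),
                                         c("channel_id",
                                           "integration_time_s",
                                           "position"))],
                            if (!is.null(meta$position))
                              list(position = pos)))
}

#' Write a simulated dataset to disk
#'
#' Emits one spectrum file per raw spectrum under `dir/spectra/`, the
#' calibration set under `dir/calibration/`, a per-spectrum
#' `manifest.csv` and a per-sample `samples.csv`.
#'
#' @param dataset A `drsifs_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "calibration"), showWarnings = FALSE)
  rows <- list()
  smp <- dataset$samples
  for (st in dataset$sets) {
    s <- smp[smp$sample_id == st$sample_id, ]
    for (sp in st$spectra) {
      rel <- file.path("spectra", sprintf("%s_%s.csv", st$set_id,
                                          sp$channel_id))
      write_spectrum_file(sp, file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_path = rel, patient_id = st$patient_id,
        sample_id = st$sample_id, side = st$side, position = st$position,
        channel_id = sp$channel_id,
        integration_time_s = sp$integration_time_s,
        tissue_class = s$tissue_class, quality_grade = s$quality_grade,
        max_dimension_mm = s$max_dimension_mm,
        dye = s$dye_contamination, stringsAsFactors = FALSE)
    }
  }
  cal <- dataset$calibration
  for (group in c("white", "reference", "dark"))
    for (sp in cal[[group]])
      write_spectrum_file(sp, file.path(dir, "calibration",
                                        sprintf("%s_%s.csv", group,
                                                sp$channel_id)))
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(smp, file.path(dir, "samples.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a calibration directory
#'
#' @param dir Directory holding `white_*/reference_*/dark_*` spectrum
#'   files as written by [write_dataset()].
#' @return A `calibration_set`.
#' @export
read_calibration_dir <- function(dir) {
  out <- list(white = list(), reference = list(), dark = list())
  for (f in list.files(dir, pattern = "\\.csv$", full.names = TRUE)) {
    group <- sub("_.*", "", basename(f))
    sp <- read_spectrum_file(f)
    out[[group]][[sp$channel_id]] <- sp
  }
  structure(out, class = "calibration_set")
}

#' Validate a manifest against the files on disk
#'
#' Checks path existence/uniqueness, channel/grade/class domains and
#' that every acquisition set carries all six channels.
#'
#' @param manifest Manifest data.frame (as written by [write_dataset()]).
#' @param root Directory the `spectrum_path` entries are relative to.
#' @return Character vector of violations (empty when valid).
#' @export
validate_manifest <- function(manifest, root = ".") {
  v <- character(0)
  dup <- duplicated(manifest$spectrum_path)
  if (any(dup))
    v <- c(v, sprintf("duplicate spectrum_path: %s",
                      manifest$spectrum_path[dup]))
  missing <- !file.exists(file.path(root, manifest$spectrum_path))
  if (any(missing))
    v <- c(v, sprintf("missing file: %s", manifest$spectrum_path[missing]))
  bad_ch <- !manifest$channel_id %in% CHANNEL_IDS
  if (any(bad_ch))
    v <- c(v, sprintf("unknown channel_id: %s",
                      unique(manifest$channel_id[bad_ch])))
  bad_gr <- !manifest$quality_grade %in% 1:3
  if (any(bad_gr))
    v <- c(v, sprintf("quality_grade out of 1..3 for sample %s",
                      unique(manifest$sample_id[bad_gr])))
  bad_cl <- !manifest$tissue_class %in% TISSUE_CLASSES
  if (any(bad_cl))
    v <- c(v, sprintf("unknown tissue_class: %s",
                      unique(manifest$tissue_class[bad_cl])))
  key <- paste(manifest$sample_id, manifest$side, manifest$position)
  for (k in unique(key)) {
    ch <- manifest$channel_id[key == k & !missing]
    lack <- setdiff(CHANNEL_IDS, ch)
    if (length(lack))
      v <- c(v, sprintf("acquisition set %s missing channel %s", k, lack))
  }
  v
}

#' Run the whole pipeline on a simulated dataset
#'
#' simulate -> preprocess -> featurize -> evaluate -> report, with
#' per-stage gate counts logged and every written artefact stamped into
#' an MD5 hash index (`hashes.csv`) so downstream tampering is
#' detectable with [verify_artefacts()].
#'
#' @param config A `sim_config` describing the dataset to simulate.
#' @param out_dir Output directory for artefacts.
#' @param combinations,comparisons,quality_policies Passed to
#'   [run_comparison_suite()].
#' @param cv_seed Seed for the cross-validation stage.
#' @param ... Further arguments to [run_cv()] via the suite.
#' @return Named list of `drsifs_report` objects, invisibly; artefacts
#'   (report JSON, confusion CSVs, hash index) under `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("drsifs_"),
                         combinations = list(c("IFS405", "DRS08", "DRS28")),
                         comparisons = canonical_comparisons(),
                         quality_policies = "all_grades",
                         cv_seed = config$rng_seed, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("simulate: generating dataset (seed ", config$rng_seed, ")")
  dataset <- generate_dataset(config)
  message(sprintf("simulate: %d samples, %d acquisition sets, %d spectra",
                  nrow(dataset$samples), length(dataset$sets),
                  sum(dataset$samples$n_spectra)))
  processed <- preprocess_dataset(dataset)
  message(sprintf("preprocess: %d spectra in, %d passed SNR gate, %d failed",
                  nrow(processed$meta), sum(processed$meta$passed_qc),
                  sum(!processed$meta$passed_qc)))
  reports <- run_comparison_suite(processed, comparisons, combinations,
                                  quality_policies, seed = cv_seed, ...)
  ok <- vapply(reports, inherits, TRUE, "drsifs_report")
  message(sprintf("evaluate: %d of %d cells succeeded", sum(ok),
                  length(ok)))
  json <- lapply(reports[ok], report_to_list)
  jsonlite::write_json(json, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(reports)[ok]) {
    fn <- file.path(out_dir, paste0(
      "confusion_", gsub("[^A-Za-z0-9]+", "_", key), ".csv"))
    utils::write.csv(reports[[key]]$confusion, fn)
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "hashes.csv"]
  hashes <- data.frame(
    file = substring(files, nchar(out_dir) + 2L),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  utils::write.csv(hashes, file.path(out_dir, "hashes.csv"),
                   row.names = FALSE)
  invisible(reports)
}

report_to_list <- function(r) {
  list(comparison = r$comparison, channels = r$channels,
       quality_policy = r$quality_policy,
       aggregate = lapply(r$aggregate, as.list),
       confusion = as.data.frame(as.table(r$confusion)),
       n_patients = r$n_patients, n_samples = r$n_samples,
       n_observations = r$n_observations, config = r$config)
}

#' Verify the artefact hash index of a pipeline run
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Character vector of files whose MD5 no longer matches
#'   (empty when intact).
#' @export
verify_artefacts <- function(out_dir) {
  idx <- utils::read.csv(file.path(out_dir, "hashes.csv"),
                         stringsAsFactors = FALSE)
  cur <- unname(tools::md5sum(file.path(out_dir, idx$file)))
  idx$file[is.na(cur) | cur != idx$md5]
}
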