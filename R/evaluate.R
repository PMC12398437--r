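#' Define a tissue-class comparison
#'
#' @param name Short identifier.
#' @param positive Character vector of tumour-side classes (label 1;
#'   sensitivity is computed for this side).
#' @param negative Character vector of the other side's classes.
#' @return Object of class `comparison_spec`.
#' @export
comparison_spec <- function(name, positive, negative) {
  stopifnot(length(positive) >= 1, length(negative) >= 1,
            all(c(positive, negative) %in% TISSUE_CLASSES),
            length(intersect(positive, negative)) == 0)
  structure(list(name = name, positive = positive, negative = negative),
            class = "comparison_spec")
}

#' The canonical comparison list
#'
#' Healthy versus each tumour subtype, versus invasive cancer
#' (IDC + ILC), versus all cancer (IDC + ILC + DCIS), and IDC versus ILC.
#'
#' @return Named list of `comparison_spec` objects.
#' @export
canonical_comparisons <- function() {
  cmp <- list(
    comparison_spec("healthy_vs_IDC", "IDC", "healthy"),
    comparison_spec("healthy_vs_ILC", "ILC", "healthy"),
    comparison_spec("healthy_vs_DCIS", "DCIS", "healthy"),
    comparison_spec("healthy_vs_pCR", "pCR", "healthy"),
    comparison_spec("healthy_vs_invasive", c("IDC", "ILC"), "healthy"),
    comparison_spec("healthy_vs_all_cancer", c("IDC", "ILC", "DCIS"),
                    "healthy"),
    comparison_spec("IDC_vs_ILC", "IDC", "ILC")
  )
  stats::setNames(cmp, vapply(cmp, `[[`, "", "name"))
}

#' Label a feature table for a comparison
#'
#' Every observation inherits its sample's tissue class; observations
#' outside the comparison's classes are dropped; `label` is 1 for the
#' positive (tumour) side.
#'
#' @param feature_table Output of [featurize()].
#' @param comparison A `comparison_spec`.
#' @param quality_policy `"all_grades"` or `"grade1_only"`.
#' @return The filtered table with an integer `label` column.
#' @export
assign_labels <- function(feature_table, comparison,
                          quality_policy = c("all_grades", "grade1_only")) {
  quality_policy <- match.arg(quality_policy)
  stopifnot(inherits(comparison, "comparison_spec"))
  keep <- feature_table$tissue_class %in%
    c(comparison$positive, comparison$negative)
  if (quality_policy == "grade1_only")
    keep <- keep & feature_table$quality_grade == 1L
  out <- feature_table[keep, , drop = FALSE]
  out$label <- as.integer(out$tissue_class %in% comparison$positive)
  if (length(unique(out$label)) < 2)
    stop("comparison ", comparison$name,
         ": one arm is empty after filtering")
  out
}

#' Patient-grouped stratified k-fold splits
#'
#' Patients are stratified on their (majority) class label and dealt
#' round-robin into folds after a within-class shuffle, once per repeat.
#' All observations of a patient share its fold, so train and test
#' patient sets never intersect.
#'
#' @param patient_id Character vector, one entry per observation.
#' @param label Binary labels, one per observation.
#' @param n_folds,n_repeats Folds and repeats (default 5 x 5).
#' @param seed Integer seed (splits are deterministic given it).
#' @return List of `n_repeats * n_folds` splits, each a list with
#'   `repeat_`, `fold`, `train` and `test` observation indices.
#' @export
grouped_stratified_kfold <- function(patient_id, label, n_folds = 5,
                                     n_repeats = 5, seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1,
            length(patient_id) == length(label))
  patients <- unique(patient_id)
  if (length(patients) < n_folds)
    stop("fewer patients (", length(patients), ") than folds (", n_folds, ")")
  # majority label per patient (ties -> positive)
  pat_label <- vapply(patients, function(p) {
    l <- label[patient_id == p]
    as.integer(mean(l) >= 0.5)
  }, integer(1))
  set.seed(seed)
  splits <- list()
  for (r in seq_len(n_repeats)) {
    fold_of <- stats::setNames(integer(length(patients)), patients)
    for (cl in unique(pat_label)) {
      idx <- sample(which(pat_label == cl))
      fold_of[patients[idx]] <-
        (seq_along(idx) + sample.int(n_folds, 1) - 1L) %% n_folds + 1L
    }
    for (f in seq_len(n_folds)) {
      test_pat <- patients[fold_of[patients] == f]
      test <- which(patient_id %in% test_pat)
      splits[[length(splits) + 1L]] <- list(
        repeat_ = r, fold = f,
        train = setdiff(seq_along(patient_id), test), test = test)
    }
  }
  splits
}

#' Default gradient-boosted tree hyperparameters
#'
#' @param nrounds Boosting rounds.
#' @param max_depth,eta,subsample Usual XGBoost parameters.
#' @return Named list.
#' @export
classifier_params <- function(nrounds = 80, max_depth = 4, eta = 0.3,
                              subsample = 1) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta,
       subsample = subsample)
}

#' Fit the gradient-boosted tree classifier
#'
#' Thin wrapper around `xgboost` (binary logistic objective, single
#' thread, fixed seed: deterministic given data and hyperparameters).
#'
#' @param x Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param params [classifier_params()] list.
#' @param seed Integer seed passed to xgboost.
#' @return Fitted model with a `predict_prob(newx)` closure attached.
#' @export
fit_classifier <- function(x, y, params = classifier_params(), seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("single-class training data")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth, eta = params$eta,
                  subsample = params$subsample, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
  attr(fit, "predict_prob") <- function(newx)
    predict(fit, xgboost::xgb.DMatrix(as.matrix(newx), nthread = 1))
  fit
}

#' Fold-level diagnostic metrics
#'
#' Confusion counts at the decision threshold, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, AUC via the
#' tie-corrected rank (Mann-Whitney) statistic, and mAP as the average
#' precision of the positive class (step-wise precision-recall area).
#' With a one-class fold every threshold-free metric is `NA`.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary truth (1 = tumour side).
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: `accuracy, sensitivity, specificity, auc, map,
#'   tp, fp, tn, fn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  one_class <- npos == 0 || nneg == 0
  list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (npos > 0) tp / npos else NA_real_,
    specificity = if (nneg > 0) tn / nneg else NA_real_,
    auc = if (one_class) NA_real_ else auc_rank(scores, labels),
    map = if (one_class) NA_real_ else average_precision(scores, labels),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# Mann-Whitney AUC with midrank tie correction
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# average precision (AP): mean of precision@k over the positive ranks,
# scores sorted decreasing (ties kept in stable order)
average_precision <- function(scores, labels) {
  o <- order(-scores)
  l <- labels[o]
  cum_tp <- cumsum(l)
  prec <- cum_tp / seq_along(l)
  sum(prec[l == 1]) / sum(l)
}

#' Run one patient-grouped repeated-CV evaluation
#'
#' Executes the 5 x 5 (by default) patient-grouped stratified
#' cross-validation for one labelled feature table: optional Boruta
#' selection (fitted on the training folds only in `"within_fold"` mode,
#' once on everything in `"global"` mode, skipped with `"none"`), XGB
#' fitting, and fold metrics. Train/test patient disjointness is hard-
#' asserted on every split.
#'
#' @param labelled Output of [assign_labels()].
#' @param n_folds,n_repeats CV geometry.
#' @param seed Integer seed driving the splits, Boruta and the boosters.
#' @param boruta_mode `"none"`, `"within_fold"` or `"global"`.
#' @param boruta_alpha,boruta_max_iter Boruta controls.
#' @param classifier [classifier_params()] list.
#' @param threshold Decision threshold.
#' @return List: `fold_metrics` (data.frame, one row per fold x repeat),
#'   `predictions` (pooled test predictions with repeat/fold ids),
#'   `config` echo.
#' @export
run_cv <- function(labelled, n_folds = 5, n_repeats = 5, seed = 1L,
                   boruta_mode = c("none", "within_fold", "global"),
                   boruta_alpha = 0.01, boruta_max_iter = 50,
                   classifier = classifier_params(), threshold = 0.5) {
  boruta_mode <- match.arg(boruta_mode)
  fcols <- feature_columns(labelled)
  x <- as.matrix(labelled[, fcols, drop = FALSE])
  x <- impute_features(x)
  y <- labelled$label
  pid <- labelled$patient_id
  if (boruta_mode == "global") {
    set.seed(seed)
    br <- boruta_select(x, y, alpha = boruta_alpha,
                        max_iter = boruta_max_iter)
    x <- select_features(x, br)
  }
  splits <- grouped_stratified_kfold(pid, y, n_folds, n_repeats, seed)
  fm <- list(); preds <- list()
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    stopifnot(length(intersect(pid[sp$train], pid[sp$test])) == 0)
    xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    xte <- x[sp$test, , drop = FALSE]
    if (length(unique(ytr)) < 2) next
    if (boruta_mode == "within_fold") {
      set.seed(seed + 1000L * k)
      br <- boruta_select(xtr, ytr, alpha = boruta_alpha,
                          max_iter = boruta_max_iter)
      xtr <- suppressWarnings(select_features(xtr, br))
      xte <- xte[, colnames(xtr), drop = FALSE]
    }
    fit <- fit_classifier(xtr, ytr, classifier, seed = seed + k)
    score <- attr(fit, "predict_prob")(xte)
    m <- compute_metrics(score, y[sp$test], threshold)
    fm[[length(fm) + 1L]] <- data.frame(repeat_ = sp$repeat_,
                                        fold = sp$fold,
                                        as.data.frame(m))
    preds[[length(preds) + 1L]] <- data.frame(
      repeat_ = sp$repeat_, fold = sp$fold, index = sp$test,
      patient_id = pid[sp$test], score = score, label = y[sp$test])
  }
  if (length(fm) == 0) stop("no valid CV fold")
  list(fold_metrics = do.call(rbind, fm),
       predictions = do.call(rbind, preds),
       config = list(n_folds = n_folds, n_repeats = n_repeats,
                     seed = seed, boruta_mode = boruta_mode,
                     classifier = classifier, threshold = threshold))
}

# median imputation of missing feature values (columns of all-NA -> 0)
impute_features <- function(x) {
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) {
      med <- stats::median(x[!bad, j])
      x[bad, j] <- if (is.finite(med)) med else 0
    }
  }
  x
}

#' Aggregate fold metrics into a report
#'
#' Mean and SD of each metric over the fold x repeat entries (missing
#' one-class-fold entries excluded with a warning), and a pooled
#' confusion matrix: counts summed over the test folds of each repeat,
#' then averaged (rounded) across repeats.
#'
#' @param cv Output of [run_cv()].
#' @param comparison The `comparison_spec` evaluated.
#' @param channels Channel combination used.
#' @param quality_policy Quality policy used.
#' @param n_patients,n_samples Cohort sizes (for provenance).
#' @return Object of class `drsifs_report`.
#' @export
aggregate_report <- function(cv, comparison, channels,
                             quality_policy = "all_grades",
                             n_patients = NA_integer_,
                             n_samples = NA_integer_) {
  fm <- cv$fold_metrics
  if (nrow(fm) == 0) stop("empty metric list")
  metrics <- c("accuracy", "sensitivity", "specificity", "auc", "map")
  agg <- lapply(metrics, function(m) {
    v <- fm[[m]]
    if (anyNA(v))
      warning("metric ", m, " undefined on ", sum(is.na(v)),
              " one-class fold(s); excluded from the aggregate")
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  })
  names(agg) <- metrics
  per_repeat <- lapply(split(fm, fm$repeat_), function(d)
    c(tp = sum(d$tp), fp = sum(d$fp), tn = sum(d$tn), fn = sum(d$fn)))
  pooled <- round(colMeans(do.call(rbind, per_repeat)))
  confusion <- matrix(c(pooled["tp"], pooled["fn"],
                        pooled["fp"], pooled["tn"]), 2, 2,
                      dimnames = list(truth = c("tumour", "healthy"),
                                      predicted = c("tumour", "healthy")))
  structure(list(
    comparison = comparison$name,
    positive = comparison$positive, negative = comparison$negative,
    channels = channels, quality_policy = quality_policy,
    aggregate = agg, fold_metrics = fm, confusion = confusion,
    n_patients = n_patients, n_samples = n_samples,
    n_observations = sum(pooled),
    config = cv$config
  ), class = "drsifs_report")
}

#' @export
print.drsifs_report <- function(x, ...) {
  cat(sprintf("<drsifs_report: %s | channels %s | quality %s>\n",
              x$comparison, paste(x$channels, collapse = "+"),
              x$quality_policy))
  for (m in names(x$aggregate))
    cat(sprintf("  %-11s %5.1f%% (SD %.1f)\n", m,
                100 * x$aggregate[[m]]["mean"],
                100 * x$aggregate[[m]]["sd"]))
  cat("  pooled confusion matrix (per-repeat average):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
summary.drsifs_report <- function(object, ...) {
  data.frame(
    comparison = object$comparison,
    channels = paste(object$channels, collapse = "+"),
    quality = object$quality_policy,
    t(vapply(object$aggregate, function(a) a["mean"], numeric(1))),
    row.names = NULL)
}

#' Run the full comparison suite
#'
#' One report per requested comparison x channel combination x quality
#' policy. A failure in one cell (for instance an empty arm) is caught,
#' logged and marked failed without aborting the rest.
#'
#' @param feature_tables Either a single feature table (used for every
#'   combination it covers) or a `processed_spectra` object from which
#'   tables are built per combination.
#' @param comparisons List of `comparison_spec` (default canonical 7).
#' @param combinations List of channel-id vectors.
#' @param quality_policies Character vector of quality policies.
#' @param ... Passed to [run_cv()].
#' @return List of `drsifs_report` (or condition objects for failed
#'   cells), named `comparison|channels|policy`.
#' @export
run_comparison_suite <- function(feature_tables,
                                 comparisons = canonical_comparisons(),
                                 combinations =
                                   list(c("IFS405", "DRS08", "DRS28")),
                                 quality_policies = "all_grades", ...) {
  out <- list()
  for (comb in combinations) {
    tab <- if (inherits(feature_tables, "processed_spectra"))
      featurize(feature_tables, comb) else feature_tables
    for (cmp in comparisons) for (qp in quality_policies) {
      key <- paste(cmp$name, paste(comb, collapse = "+"), qp, sep = "|")
      out[[key]] <- tryCatch({
        lab <- assign_labels(tab, cmp, qp)
        cv <- run_cv(lab, ...)
        aggregate_report(cv, cmp, comb, qp,
                         n_patients = length(unique(lab$patient_id)),
                         n_samples = length(unique(lab$sample_id)))
      }, error = function(e) {
        message("comparison cell ", key, " failed: ", conditionMessage(e))
        structure(list(key = key, message = conditionMessage(e)),
                  class = "drsifs_failed_cell")
      })
    }
  }
  out
}
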