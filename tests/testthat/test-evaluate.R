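make_toy_table <- function(n_patients = 20, per_patient = 4, seed = 1,
                           classes = c("healthy", "IDC"), informative = TRUE) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    cls <- classes[(p %% length(classes)) + 1L]
    eff <- if (informative && cls != "healthy") 2 else 0
    for (k in seq_len(per_patient)) {
      f <- stats::setNames(as.list(rnorm(5) + eff), paste0("DRS08_W0", 1:5, "_mean"))
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = sprintf("P%02d_%d", p, k), patient_id = sprintf("P%02d", p),
        sample_id = sprintf("S%02d", p), side = "anterior", position = k,
        tissue_class = cls, quality_grade = sample(1:3, 1), f,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("label assignment filters classes and counts match a brute-force group-by", {
  tab <- make_toy_table(classes = c("healthy", "IDC", "pCR"))
  cmp <- canonical_comparisons()$healthy_vs_all_cancer
  lab <- assign_labels(tab, cmp)
  expect_false(any(lab$tissue_class == "pCR"))
  expect_true(all(lab$label[lab$tissue_class == "IDC"] == 1L))
  expect_true(all(lab$label[lab$tissue_class == "healthy"] == 0L))
  expect_equal(sum(lab$label == 1), sum(tab$tissue_class %in% cmp$positive))
  expect_equal(sum(lab$label == 0), sum(tab$tissue_class == "healthy"))
  lab1 <- assign_labels(tab, cmp, "grade1_only")
  expect_true(all(lab1$quality_grade == 1L))
  only_h <- tab[tab$tissue_class == "healthy", ]
  expect_error(assign_labels(only_h, cmp), "empty")
})

test_that("grouped stratified k-fold keeps patients whole and balanced", {
  tab <- make_toy_table(n_patients = 10)
  lab <- assign_labels(tab, canonical_comparisons()$healthy_vs_IDC)
  splits <- grouped_stratified_kfold(lab$patient_id, lab$label, 5, 5, seed = 2)
  expect_length(splits, 25)
  for (sp in splits) {
    expect_length(intersect(unique(lab$patient_id[sp$train]),
                            unique(lab$patient_id[sp$test])), 0)
    expect_equal(length(unique(lab$patient_id[sp$test])), 2)  # 10 patients / 5 folds
  }
  # each patient appears in exactly one test fold per repeat
  for (r in 1:5) {
    in_r <- Filter(function(s) s$repeat_ == r, splits)
    test_pat <- unlist(lapply(in_r, function(s) unique(lab$patient_id[s$test])))
    expect_equal(sort(test_pat), sort(unique(lab$patient_id)))
  }
  expect_error(grouped_stratified_kfold(c("a", "b"), c(0, 1), 5, 1), "fewer patients")
})

test_that("stratification keeps per-fold class proportions near global across seeds", {
  # 40 patients, 60% positive: every fold should hold 4-6 positive of 8
  pid <- sprintf("P%02d", 1:40)
  lab <- rep(c(1, 1, 1, 0, 0), 8)
  obs_pid <- rep(pid, each = 3)
  obs_lab <- rep(lab, each = 3)
  for (seed in 1:100) {
    splits <- grouped_stratified_kfold(obs_pid, obs_lab, 5, 1, seed = seed)
    for (sp in splits) {
      pats <- unique(obs_pid[sp$test])
      frac <- mean(lab[match(pats, pid)])
      expect_gte(frac, 0.5); expect_lte(frac, 0.7)
    }
  }
})

test_that("the boosted-tree classifier separates a separable toy set and is deterministic", {
  set.seed(8)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- cbind(inf = y * 3 + rnorm(n, 0, 0.3), junk = rnorm(n))
  fit <- fit_classifier(x, y, seed = 4)
  acc <- mean((attr(fit, "predict_prob")(x) >= 0.5) == y)
  expect_gte(acc, 0.99)
  fit2 <- fit_classifier(x, y, seed = 4)
  expect_identical(attr(fit, "predict_prob")(x),
                   attr(fit2, "predict_prob")(x))
  expect_error(fit_classifier(x, rep(1, n)), "single-class")
})

test_that("permuted labels give null cross-validated AUC", {
  tab <- make_toy_table(n_patients = 80, per_patient = 4, seed = 5)
  lab <- assign_labels(tab, canonical_comparisons()$healthy_vs_IDC)
  set.seed(99)
  # permute class at patient level to break the signal but keep grouping
  pid <- unique(lab$patient_id)
  newcls <- sample(tapply(lab$label, lab$patient_id, max)[pid])
  lab$label <- unname(newcls[match(lab$patient_id, pid)])
  cv <- run_cv(lab, seed = 31, classifier = classifier_params(nrounds = 30))
  expect_lt(abs(mean(cv$fold_metrics$auc, na.rm = TRUE) - 0.5), 0.07)
})

test_that("fold metrics follow their defining formulas and oracles", {
  # forced confusion arithmetic: TP=8 FN=2 TN=6 FP=4
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 4), rep(0.2, 6))
  m <- compute_metrics(scores, labels)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(8, 2, 4, 6))
  # perfect ranking
  mp <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(mp$auc, 1); expect_equal(mp$map, 1)
  # AUC equals the O(n^2) pairwise oracle exactly, ties included
  set.seed(12)
  for (i in 1:5) {
    s <- round(runif(200), 2)       # rounded => ties occur
    l <- rbinom(200, 1, 0.4)
    expect_equal(compute_metrics(s, l)$auc, auc_pairwise(s, l))
  }
  # one-class fold: threshold-free metrics are missing, not an error
  m1 <- compute_metrics(c(0.2, 0.8), c(1, 1))
  expect_true(is.na(m1$auc) && is.na(m1$specificity))
})

test_that("report aggregation matches brute-force recomputation and round-trips JSON", {
  tab <- make_toy_table(n_patients = 12, seed = 3)
  cmp <- canonical_comparisons()$healthy_vs_IDC
  lab <- assign_labels(tab, cmp)
  cv <- run_cv(lab, n_folds = 3, n_repeats = 2, seed = 17,
               classifier = classifier_params(nrounds = 20))
  rep_ <- aggregate_report(cv, cmp, "DRS08")
  fm <- cv$fold_metrics
  expect_equal(unname(rep_$aggregate$accuracy["mean"]), mean(fm$accuracy))
  expect_equal(unname(rep_$aggregate$accuracy["sd"]), sd(fm$accuracy))
  expect_equal(unname(rep_$aggregate$auc["mean"]), mean(fm$auc, na.rm = TRUE))
  # pooled confusion totals one repeat's test observations
  expect_equal(sum(rep_$confusion), nrow(lab))
  # serialisation round trip
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(drsifs:::report_to_list(rep_), f,
                       auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f)
  expect_equal(back$aggregate$accuracy$mean,
               unname(rep_$aggregate$accuracy["mean"]))
  expect_equal(back$comparison, rep_$comparison)
  # degenerate aggregation: identical folds -> SD 0
  cv0 <- cv; cv0$fold_metrics <- fm[rep(1, 25), ]
  cv0$fold_metrics$accuracy <- 0.8
  r0 <- aggregate_report(cv0, cmp, "DRS08")
  expect_equal(unname(r0$aggregate$accuracy["mean"]), 0.8)
  expect_equal(unname(r0$aggregate$accuracy["sd"]), 0)
})

test_that("Boruta selection runs inside or outside the CV loop on request", {
  tab <- make_toy_table(n_patients = 12, seed = 9)
  lab <- assign_labels(tab, canonical_comparisons()$healthy_vs_IDC)
  for (mode in c("within_fold", "global")) {
    cv <- suppressWarnings(run_cv(
      lab, n_folds = 2, n_repeats = 1, seed = 13, boruta_mode = mode,
      boruta_max_iter = 10, classifier = classifier_params(nrounds = 10)))
    expect_equal(nrow(cv$fold_metrics), 2)
    expect_equal(cv$config$boruta_mode, mode)
    # the toy signal sits in every feature, so CV still ranks well
    expect_gt(mean(cv$fold_metrics$auc), 0.8)
  }
})

test_that("the comparison suite produces one report per cell and isolates failures", {
  tab <- make_toy_table(n_patients = 16, seed = 6,
                        classes = c("healthy", "IDC", "ILC"))
  reports <- suppressWarnings(run_comparison_suite(
    tab, comparisons = canonical_comparisons(),
    combinations = list("DRS08"),
    quality_policies = c("all_grades", "grade1_only"),
    n_folds = 2, n_repeats = 1,
    classifier = classifier_params(nrounds = 10)))
  expect_length(reports, 7 * 1 * 2)
  ok <- vapply(reports, inherits, TRUE, "drsifs_report")
  # cells whose classes are absent from the toy data fail gracefully
  expect_true(any(ok))
  expect_true(all(vapply(reports[!ok], inherits, TRUE, "drsifs_failed_cell")))
  # grade1_only cells only ever saw grade-1 observations
  for (r in reports[ok]) {
    if (r$quality_policy == "grade1_only") {
      expect_true(all(r$fold_metrics$tp + r$fold_metrics$fn +
                        r$fold_metrics$fp + r$fold_metrics$tn <=
                        sum(tab$quality_grade == 1)))
    }
  }
})
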