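test_that("prediction records pair every case with every target", {
  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 7, seed = 1), net)
  preds <- predict(net, co)
  expect_s3_class(preds, "bn_predictions")
  expect_equal(nrow(preds), 7L * 5L)
  expect_setequal(unique(preds$target), bn_targets(net))
  expect_true(all(preds$p_true >= 0 & preds$p_true <= 1))
  expect_identical(preds$predicted,
                   ifelse(preds$p_true > 0.5, "true", "false"))

  # an anchor-constellation case carries the anchor posterior
  case <- data.frame(case_id = "anchor", T = "T2", N = "N2a", M = "M0",
                     chemo_tolerance = "tolerant", stringsAsFactors = FALSE)
  p <- predict(net, case)
  expect_equal(p$p_true[p$target == "larynx_surgery"], 0.74, tolerance = 1e-12)

  # empty cohort, empty record list
  expect_equal(nrow(predict(net, co[0, ])), 0L)
})

test_that("invalid state labels flag the case instead of dropping it", {
  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 4, seed = 2), net)
  co$T[2] <- "T17"
  preds <- predict(net, co)
  expect_equal(nrow(preds), 20L)
  flagged <- preds[preds$case_id == co$case_id[2], ]
  expect_true(all(flagged$flagged))
  expect_true(all(is.na(flagged$p_true)))
  # flagged rows leave the metric denominators
  expect_equal(accuracy(preds)$overall$total, 15L)
})

test_that("accuracy counts decompose by target", {
  preds <- make_preds(c(0.9, 0.8, 0.2, 0.7), c("true", "true", "false", "false"))
  acc <- accuracy(preds)
  expect_equal(acc$overall$accuracy, 0.75)
  expect_equal(acc$per_target$correct, 3L)

  perfect <- make_preds(c(0.9, 0.1), c("true", "false"))
  expect_equal(accuracy(perfect)$overall$accuracy, 1)

  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 30, seed = 11), net)
  acc <- accuracy(predict(net, co))
  expect_equal(sum(acc$per_target$correct), acc$overall$correct)
  expect_equal(sum(acc$per_target$total), acc$overall$total)
  expect_equal(acc$overall$total, 30L * 5L)
})

test_that("F1 matches hand confusion-matrix arithmetic", {
  perfect <- make_preds(c(0.9, 0.9, 0.1), c("true", "true", "false"))
  expect_equal(f1_scores(perfect, "trt"),
               c(f1_positive = 1, f1_negative = 1, weighted = 1))

  # TP=2 FP=1 FN=1 TN=6 -> F1_pos = 2*2/(2*2+1+1) = 2/3
  preds <- make_preds(
    p_true = c(0.9, 0.8, 0.7, 0.3, rep(0.2, 6)),
    truth = c("true", "true", "false", "true", rep("false", 6)))
  f1 <- f1_scores(preds, "trt")
  expect_equal(unname(f1["f1_positive"]), 2 / 3, tolerance = 1e-12)
  # F1_neg: TP'=6 FP'=1 FN'=1 -> 12/14
  expect_equal(unname(f1["f1_negative"]), 6 / 7, tolerance = 1e-12)
  expect_equal(unname(f1["weighted"]), 0.3 * 2 / 3 + 0.7 * 6 / 7,
               tolerance = 1e-12)

  # all-negative truth and predictions: undefined positive F1 reported as 0
  allneg <- make_preds(c(0.1, 0.2, 0.3), rep("false", 3))
  expect_equal(f1_scores(allneg, "trt"),
               c(f1_positive = 0, f1_negative = 1, weighted = 1))
})

test_that("ROC/AUC agrees with pair counting and is rank-invariant", {
  # perfectly separating scores
  sep <- make_preds(c(0.9, 0.8, 0.3, 0.2), c("true", "true", "false", "false"))
  expect_equal(roc_curve(sep, "trt")$auc, 1)

  # 4-point toy with one swap, vs the Mann-Whitney oracle
  toy <- make_preds(c(0.9, 0.6, 0.8, 0.7), c("true", "true", "false", "false"))
  expect_equal(roc_curve(toy, "trt")$auc,
               pair_count_auc(toy$p_true, toy$truth == "true"))

  # ties handled as half-concordant, cross-checked against pROC
  tied <- make_preds(c(0.9, 0.7, 0.7, 0.2, 0.7),
                     c("true", "true", "false", "false", "false"))
  expect_equal(roc_curve(tied, "trt")$auc,
               pair_count_auc(tied$p_true, tied$truth == "true"))
  expect_equal(roc_curve(tied, "trt")$auc,
               as.numeric(pROC::auc(pROC::roc(tied$truth == "true",
                                              tied$p_true, quiet = TRUE,
                                              direction = "<"))))

  # AUC is invariant under strictly monotone transforms of the posterior
  trans <- toy; trans$p_true <- toy$p_true^3
  expect_equal(roc_curve(trans, "trt")$auc, roc_curve(toy, "trt")$auc)

  # label-independent scores give AUC ~ 0.5
  set.seed(202)
  rnd <- make_preds(stats::runif(10000),
                    sample(c("true", "false"), 10000, replace = TRUE))
  expect_lt(abs(roc_curve(rnd, "trt")$auc - 0.5), 0.02)

  # single-class truth: explicit undefined marker, not a number
  oneclass <- make_preds(c(0.9, 0.8), c("true", "true"))
  expect_true(roc_curve(oneclass, "trt")$undefined)
})

test_that("precision-recall staircases and AP match hand enumeration", {
  perfect <- make_preds(c(0.9, 0.9, 0.1), c("true", "true", "false"))
  pr <- pr_curve(perfect, "trt")
  expect_equal(pr$classes$true$ap, 1)
  expect_equal(pr$classes$false$ap, 1)
  expect_equal(pr$micro_ap, 1)

  # 6-point toy: AP = 1/3 * (1 + 2/3 + 3/4) = 29/36
  toy <- make_preds(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                    c("true", "false", "true", "true", "false", "false"))
  pr <- pr_curve(toy, "trt")
  expect_equal(pr$classes$true$ap, 29 / 36, tolerance = 1e-12)

  # a class with no positive members is omitted with a marker
  allneg <- make_preds(c(0.4, 0.3), c("false", "false"))
  pr <- pr_curve(allneg, "trt")
  expect_true(pr$classes$true$omitted)
  expect_false(pr$classes$false$omitted)
  expect_false(is.na(pr$micro_ap))
})

test_that("the metrics report bundles and serializes the validation summary", {
  net <- larynx_model()
  co <- generate_cohort(cohort_config(n = 20, seed = 6), net)
  preds <- predict(net, co)
  rep <- metrics_report(preds, cv = kfold_cv(net, co, k = 5, seed = 1),
                        provenance = list(model_hash = content_hash(net),
                                          seed = 6))
  expect_named(rep$f1, bn_targets(net))
  out <- withr::local_tempfile(fileext = ".json")
  pts <- withr::local_tempdir()
  write_metrics(rep, out, points_dir = pts)
  doc <- jsonlite::read_json(out)
  expect_equal(doc$accuracy$overall$total, 100L)
  expect_identical(doc$provenance$model_hash, content_hash(net))
  expect_true(length(list.files(pts, pattern = "^roc_.*csv$")) >= 1)
  expect_output(print(rep), "Accuracy")
})
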