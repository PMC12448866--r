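test_that("sensitivity/specificity reproduce printed contingency arithmetic", {
  # schwannoma thresholded sensitivity
  expect_equal(sensitivity_specificity(116, 9, 0, 1)$sensitivity, 92.80)
  # meningioma thresholded sensitivity / specificity
  res <- sensitivity_specificity(123, 15, 7, 277)
  expect_equal(res$sensitivity, 89.13)
  expect_equal(res$specificity, 97.54)
  # degenerate classes
  expect_equal(sensitivity_specificity(0, 5, 1, 1)$sensitivity, 0)
  expect_warning(res0 <- sensitivity_specificity(0, 0, 1, 1), "denominator")
  expect_true(is.na(res0$sensitivity))
})

test_that("averaged metrics use population SD and half-away integer rounding", {
  expect_equal(average_metrics(c(89.63, 87.59, 98.20)), list(mean = 92, sd = 5))
  expect_equal(average_metrics(c(93.27, 97.35, 97.86)), list(mean = 96, sd = 2))
  expect_equal(average_metrics(90), list(mean = 90, sd = 0))
  expect_equal(round_half_away(c(2.5, -2.5, 91.5)), c(3, -3, 92))
})

test_that("confusion matrices reconcile with one-vs-rest recounts", {
  set.seed(6)
  classes <- c("a", "b", "c")
  for (rep in 1:5) {
    actual <- sample(classes, 80, replace = TRUE)
    predicted <- sample(classes, 80, replace = TRUE)
    cm <- confusion_matrix(actual, predicted, classes)
    expect_equal(sum(cm), 80)
    expect_equal(100 * sum(actual == predicted) / 80,
                 lipidlda:::cm_accuracy(cm))
    for (cl in classes) {
      tp <- sum(actual == cl & predicted == cl)
      expect_equal(cm[cl, cl], tp)
      expect_equal(sum(cm[cl, ]), sum(actual == cl))        # row sums
      expect_equal(sum(cm[, cl]), sum(predicted == cl))     # column sums
    }
  }
})

test_that("event-level CV is exact on separable data and chance on shuffled labels", {
  sep <- cached("noiseless",
                make_cohort(classes = c(a = 6, b = 6, c = 6),
                            events_per_specimen = c(4, 4), separation = 3,
                            sigma_specimen = 0.02, sigma_event = 0.02,
                            frac_bad = 0, frac_outlier = 0, seed = 17))
  res <- crossval_event(sep$mg, folds = 5, seed = 2)
  expect_equal(res$accuracy, 100)
  expect_identical(res$cm, crossval_event(sep$mg, folds = 5, seed = 2)$cm)

  # event-level label shuffle removes all signal: accuracy within the 95%
  # binomial band of 1/3
  set.seed(4)
  shuffled <- sample(sep$mg$meta$class_label)
  chance <- crossval_event(sep$mg, shuffled, folds = 5, seed = 2)
  band <- 100 * 1.96 * sqrt((1 / 3) * (2 / 3) / chance$n_classifiable)
  expect_lt(abs(chance$accuracy - 100 / 3), band)
})

test_that("full-group leave-out iterates per specimen and stays unbiased", {
  hs <- high_sep()
  res <- crossval_fullgroup(hs$mg)
  expect_equal(res$n_iterations, length(unique(hs$mg$meta$specimen_id)))
  expect_gte(res$accuracy, 95)

  # when events within a specimen are near-duplicates, event-level CV leaks
  # specimen identity and cannot score below specimen-level CV
  leak <- cached("leaky",
                 make_cohort(classes = c(a = 8, b = 8),
                             events_per_specimen = c(6, 6),
                             separation = 0.08, sigma_specimen = 0.6,
                             sigma_event = 0.01, frac_bad = 0,
                             frac_outlier = 0, seed = 23))
  ev <- crossval_event(leak$mg, folds = 5, seed = 3)$accuracy
  grp <- crossval_fullgroup(leak$mg)$accuracy
  expect_gte(ev, grp)
  expect_gt(ev - grp, 5)  # the leakage is material, not a tie
})

test_that("spatial concordance separates event-level and unanimous-specimen views", {
  mk <- function(spec, ok) data.frame(
    event_id = sprintf("e%02d", seq_along(spec)), specimen_id = spec,
    class_label = "a", status = "classified",
    predicted_class = ifelse(ok, "a", "b"), posterior = 1,
    passes_threshold = TRUE, stringsAsFactors = FALSE)
  all_ok <- mk(rep(sprintf("s%d", 1:10), each = 2), rep(TRUE, 20))
  expect_equal(spatial_concordance(all_ok),
               list(event_pct = 100, specimen_pct = 100))
  # 2 of 10 specimens fully wrong, equal event counts -> 80% / 80%
  two_bad <- mk(rep(sprintf("s%d", 1:10), each = 2),
                rep(c(FALSE, TRUE), times = c(4, 16)))
  expect_equal(spatial_concordance(two_bad),
               list(event_pct = 80, specimen_pct = 80))
  # one mixed specimen lowers the unanimous rate more than the event rate
  mixed <- mk(rep(sprintf("s%d", 1:10), each = 2),
              c(FALSE, rep(TRUE, 19)))
  conc <- spatial_concordance(mixed)
  expect_equal(conc$event_pct, 95)
  expect_equal(conc$specimen_pct, 90)
})

test_that("report blocks mirror the two-threshold table structure", {
  hs <- high_sep()
  fit <- fit_pcalda(hs$mg)
  pred <- classify_cohort(fit, hs$m)
  report <- build_report(pred, prob_threshold = 0.95)
  ct <- report$counts
  expect_equal(ct$classifiable + ct$bad + ct$outlier, ct$total)
  expect_lte(report$thresholded$n, report$unthresholded$n)
  per <- report$unthresholded$per_class
  # per-class TP+FN equals that class's classifiable events
  cls <- pred$status == "classified"
  for (i in seq_len(nrow(per)))
    expect_equal(per$TP[i] + per$FN[i],
                 sum(pred$class_label[cls] == per$class[i]))
  # one-vs-rest totals are the same for every class within a block
  expect_equal(length(unique(per$TP + per$FN + per$FP + per$TN)), 1)
  # macro average equals average_metrics of the per-class values
  expect_equal(report$unthresholded$avg_sensitivity,
               average_metrics(per$sensitivity))
})

test_that("a hand-built table reproduces the printed thresholded block", {
  # 138 events of the positive class (123 called correctly), 284 others
  # (7 called positive): sensitivity 89.13, specificity 97.54
  pred <- data.frame(
    event_id = sprintf("e%03d", 1:422),
    specimen_id = "s1",
    class_label = rep(c("meningioma", "other"), times = c(138, 284)),
    status = "classified",
    predicted_class = c(rep(c("meningioma", "other"), times = c(123, 15)),
                        rep(c("meningioma", "other"), times = c(7, 277))),
    posterior = 1, passes_threshold = TRUE, stringsAsFactors = FALSE)
  rep1 <- build_report(pred, prob_threshold = 0.95)
  men <- rep1$thresholded$per_class
  men <- men[men$class == "meningioma", ]
  expect_equal(men[, c("TP", "FN", "FP", "TN")],
               data.frame(TP = 123L, FN = 15L, FP = 7L, TN = 277L),
               ignore_attr = TRUE)
  expect_equal(men$sensitivity, 89.13)
  expect_equal(men$specificity, 97.54)
})
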