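test_that("metrics reproduce a hand-computed confusion matrix", {
  # TP = 3, FP = 1, FN = 1, TN = 5
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  r <- classification_metrics(y_true, y_pred)
  expect_equal(r$accuracy, 0.8)
  expect_equal(unname(r$precision["1"]), 0.75)
  expect_equal(unname(r$recall["1"]), 0.75)
  expect_equal(unname(r$precision["0"]), 5 / 6)
  expect_equal(unname(r$recall["0"]), 5 / 6)
  expect_equal(r$f1, (0.75 + 5 / 6) / 2)  # per-class F1s happen to equal p = r

  perfect <- classification_metrics(y_true, y_true, scores = y_true)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(as.numeric(perfect$roc_points[1, ]), c(0, 0))
  expect_equal(as.numeric(perfect$roc_points[nrow(perfect$roc_points), ]), c(1, 1))

  expect_error(classification_metrics(1:3, 1:2), "lengths differ")
  # class absent from the truth: undefined recall, reported missing
  r0 <- classification_metrics(c(1, 1, 1), c(1, 0, 1))
  expect_true(is.na(r0$recall["0"]))
})

test_that("macro-F1 agrees with an independent oracle on random predictions", {
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- 40
      yt <- rbinom(n, 1, 0.4)
      if (length(unique(yt)) < 2) next
      yp <- rbinom(n, 1, 0.5)
      got <- classification_metrics(yt, yp)$f1
      # oracle: explicit counts
      f1s <- sapply(c(0, 1), function(cl) {
        tp <- sum(yt == cl & yp == cl)
        prec <- if (sum(yp == cl) > 0) tp / sum(yp == cl) else 0
        rec <- tp / sum(yt == cl)
        if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      })
      expect_equal(got, mean(f1s))
    }
  })
})

test_that("trapezoidal AUC matches pROC and is rank-invariant", {
  withr::with_seed(15, {
    y <- rbinom(200, 1, 0.3)
    s <- runif(200) + 0.5 * y
  })
  auc1 <- classification_metrics(y, as.integer(s >= 0.5), s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(auc1, ref, tolerance = 1e-10)

  # strictly monotone transform of scores leaves the AUC unchanged
  auc2 <- classification_metrics(y, as.integer(s >= 0.5), plogis(5 * s - 2))$auc
  expect_equal(auc1, auc2)

  # uninformative scores: AUC near 1/2
  withr::with_seed(16, {
    y <- rbinom(4000, 1, 0.25)
    s <- runif(4000)
  })
  auc3 <- classification_metrics(y, as.integer(s >= 0.5), s)$auc
  expect_lt(abs(auc3 - 0.5), 0.04)
})

test_that("cross-validation folds are balanced and each case validated once", {
  y <- rep(c(0L, 1L), c(110, 30))
  folds <- make_folds(y, 10, seed = 2)
  expect_equal(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 14))        # every observation exactly once
  expect_true(all(table(folds[y == 1]) %in% 2:4))  # stratification

  # leave-one-out boundary: k = n gives n folds of size one
  y10 <- rep(c(0L, 1L), 5)
  expect_true(all(table(make_folds(y10, 10, seed = 1)) == 1))
  expect_error(make_folds(y10, 11, seed = 1), "at least")

  d <- withr::with_seed(3, {
    x <- rnorm(60)
    list(X = cbind(x = x, z = rnorm(60)), y = as.integer(x + rnorm(60, 0, 0.7) > 0))
  })
  cv1 <- kfold_cv(model_spec("logistic_regression", seed = 4), d$X, d$y, k = 5, seed = 6)
  cv2 <- kfold_cv(model_spec("logistic_regression", seed = 4), d$X, d$y, k = 5, seed = 6)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_identical(cv1$folds, cv2$folds)
})

test_that("sampling yield averages detection over repeated draws", {
  pop <- 1:140
  flagged <- pop[1:28]
  srs <- function(s) plan_srs(pop, 0.5, s)
  res <- sampling_yield(srs, flagged, reps = 1000, seed = 3)
  expect_lt(abs(res$mean_yield - 28 / 140), 0.01)

  expect_equal(sampling_yield(srs, pop, reps = 5, seed = 1)$mean_yield, 1)
  expect_equal(sampling_yield(srs, integer(0), reps = 5, seed = 1)$mean_yield, 0)

  empty <- function(s) structure(list(selected = integer(0)), class = "audit_plan")
  expect_error(sampling_yield(empty, flagged, reps = 2, seed = 1), "empty plan")
  expect_error(sampling_yield(srs, flagged, reps = 0, seed = 1), "reps")

  # Monte-Carlo error of the mean shrinks like 1/sqrt(reps)
  vr <- sapply(c(100, 400, 1600), function(reps) {
    var(sapply(1:20, function(i)
      sampling_yield(srs, flagged, reps = reps, seed = 100 + i)$mean_yield))
  })
  expect_gt(vr[1] / vr[2], 2)
  expect_gt(vr[2] / vr[3], 2)
})

test_that("train-on-Q1 protocol predicts later quarters without refitting", {
  panel <- default_panel()
  labels <- default_labels()
  spec <- model_spec("random_forest", seed = 9)
  acc <- cross_quarter_protocol(spec, panel, labels)
  expect_named(acc, paste0("Q", 1:4))
  # persistence carries signal: later-quarter prediction accuracy stays close
  # to the model's cross-validated quarter-1 accuracy
  q1 <- panel[panel$quarter == 1, ]
  cv_q1 <- kfold_cv(spec, build_features(q1, "basic"),
                    quarter_labels(panel, labels, 1), k = 10, seed = 4)$accuracy
  expect_true(all(abs(acc[2:4] - cv_q1) <= 0.12))

  # independence oracle: labels reshuffled per quarter -> accuracy near the
  # majority-class rate
  shuffled <- labels
  withr::with_seed(17, {
    for (q in 1:4) {
      idx <- which(shuffled$quarter == q)
      shuffled$over_report[idx] <- sample(shuffled$over_report[idx])
    }
  })
  acc_s <- cross_quarter_protocol(spec, panel, shuffled)
  maj <- sapply(2:4, function(q)
    max(mean(shuffled$over_report[shuffled$quarter == q]),
        1 - mean(shuffled$over_report[shuffled$quarter == q])))
  expect_true(all(abs(acc_s[2:4] - maj) < 0.12))
})

test_that("the comparison table tags metric kinds by approach", {
  panel <- default_panel()
  labels <- default_labels()
  comp <- comparison_table(panel, labels,
                           strategies = c("srs", "offenders_first"),
                           model_specs = list(rf = model_spec("random_forest", seed = 1)),
                           reps = 100, k = 5, seed = 2)
  expect_equal(nrow(comp), 3)
  expect_equal(comp$metric, c("detection_yield_pct", "detection_yield_pct",
                              "accuracy_pct"))
  expect_true(is.na(comp$Q1[comp$approach == "offenders_first"]))
  expect_true(all(comp[comp$approach == "rf", paste0("Q", 1:4)] >= 0))
})
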