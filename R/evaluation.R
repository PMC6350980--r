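#' Classification metrics for a binary over-reporting predictor
#'
#' Computes accuracy (correct / total), per-class precision and recall,
#' macro-F1 (mean over classes of the per-class harmonic mean of precision
#' and recall), and -- when scores are supplied -- the ROC curve with its
#' trapezoidal AUC and the precision-recall curve.
#'
#' @param y_true binary 0/1 truth.
#' @param y_pred binary 0/1 predictions.
#' @param scores optional numeric risk scores (higher = more likely class 1).
#' @return a list of class `metrics_report`: `accuracy`, `precision`
#'   (named per class), `recall`, `f1`, `auc`, `roc_points`
#'   (FPR/TPR, from (0,0) to (1,1)), `pr_points` (recall/precision),
#'   `confusion`. A class absent from `y_true` gets `NA` recall (undefined),
#'   not zero.
#' @examples
#' classification_metrics(c(1,1,1,1,0,0,0,0,0,0),
#'                        c(1,1,1,0,1,0,0,0,0,0))
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  if (length(y_true) != length(y_pred)) stop_("y_true and y_pred lengths differ")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  cm <- table(factor(y_true, levels = c(0, 1)), factor(y_pred, levels = c(0, 1)),
              dnn = c("truth", "pred"))
  acc <- sum(diag(cm)) / sum(cm)
  prec <- rec <- f1c <- setNames(numeric(2), c("0", "1"))
  for (cl in c("0", "1")) {
    tp <- cm[cl, cl]
    prec[cl] <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec[cl] <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    # class absent from the truth: undefined; present but with zero recall
    # or zero precision: per-class F1 is 0
    f1c[cl] <- if (is.na(rec[cl])) NA_real_
      else if (is.na(prec[cl]) || prec[cl] + rec[cl] == 0) 0
      else 2 * prec[cl] * rec[cl] / (prec[cl] + rec[cl])
  }
  f1 <- mean(f1c, na.rm = TRUE)
  roc <- pr <- NULL
  auc <- NA_real_
  if (!is.null(scores)) {
    roc <- roc_points(y_true, scores)
    auc <- trapezoid_auc(roc$fpr, roc$tpr)
    pr <- pr_points(y_true, scores)
  }
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 auc = auc, roc_points = roc, pr_points = pr, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.3f | macro-F1 %.3f | AUC %s\n",
              x$accuracy, x$f1,
              if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)))
  cat(sprintf("  class 1: precision %.3f recall %.3f\n",
              x$precision["1"], x$recall["1"]))
  invisible(x)
}

# ROC by sweeping the decision threshold over the observed scores;
# starts at (0,0), ends at (1,1)
roc_points <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  P <- sum(y == 1); N <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct score
  data.frame(fpr = c(0, fp[keep] / max(N, 1)),
             tpr = c(0, tp[keep] / max(P, 1)))
}

pr_points <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  P <- sum(y == 1)
  tp <- cumsum(y == 1)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(recall = tp[keep] / max(P, 1),
             precision = tp[keep] / which(keep))
}

trapezoid_auc <- function(x, y) {
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Stratified fold assignment
#'
#' Deals each class's observations round-robin into k folds after a seeded
#' shuffle, so every observation is validated exactly once and fold class
#' proportions are as balanced as the counts allow.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..k) per observation.
#' @export
make_folds <- function(y, k, seed = 1L) {
  n <- length(y)
  if (n < k) stop_("need at least k = ", k, " observations, got ", n)
  folds <- integer(n)
  with_seed(seed, {
    # shuffle within class, then deal the class-grouped order cyclically into
    # a shuffled fold sequence: fold sizes differ by at most one globally and
    # each class is spread as evenly as its count allows
    ord <- unlist(lapply(split(seq_len(n), y), sample), use.names = FALSE)
    folds[ord] <- rep_len(sample.int(k), n)
  })
  folds
}

#' k-fold cross-validation of a classifier
#'
#' Partitions the data into k folds (stratified), uses each fold exactly
#' once as validation, and averages the per-fold metrics (per-fold
#' averaging, not pooled predictions).
#'
#' @param spec a [model_spec()].
#' @param X,y data.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @return list with mean `accuracy`, `precision`, `recall`, `f1`, `auc`
#'   across folds, `folds` (the assignment) and `per_fold` reports.
#' @export
kfold_cv <- function(spec, X, y, k = 10, seed = 1L) {
  y <- as.integer(y)
  folds <- make_folds(y, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2)
      stop_("training data for fold ", f, " has a single class")
    m <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr])
    s <- predict_scores(m, X[!tr, , drop = FALSE])
    classification_metrics(y[!tr], as.integer(s >= 0.5), s)
  })
  mean_of <- function(get) mean(vapply(reports, get, numeric(1)), na.rm = TRUE)
  list(accuracy = mean_of(function(r) r$accuracy),
       precision = mean_of(function(r) r$precision["1"]),
       recall = mean_of(function(r) r$recall["1"]),
       f1 = mean_of(function(r) r$f1),
       auc = mean_of(function(r) r$auc),
       folds = folds, per_fold = reports)
}

#' Out-of-fold scores under k-fold cross-validation
#'
#' Convenience wrapper returning one held-out score per observation.
#'
#' @inheritParams kfold_cv
#' @return numeric vector of out-of-fold scores aligned with `y`.
#' @export
oof_scores <- function(spec, X, y, k = 10, seed = 1L) {
  y <- as.integer(y)
  folds <- make_folds(y, k, seed)
  s <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr])
    s[!tr] <- predict_scores(m, X[!tr, , drop = FALSE])
  }
  s
}

#' Mean detection yield of a sampling strategy
#'
#' Runs a strategy repeatedly (default 1,000 independent draws without
#' replacement) and averages its detection yield: the fraction of audited
#' facilities that are flagged over-reporters. Per-repetition seeds are
#' derived reproducibly from the master seed.
#'
#' @param strategy a function `function(seed)` returning an `audit_plan`.
#' @param flagged the set of flagged facility ids.
#' @param reps number of repetitions (>= 1).
#' @param seed master seed.
#' @return list with `mean_yield`, `sd_yield`, and the per-rep `yields`.
#' @export
sampling_yield <- function(strategy, flagged, reps = 1000, seed = 1L) {
  if (reps < 1) stop_("reps must be >= 1")
  yields <- vapply(seq_len(reps), function(i) {
    plan <- strategy(derive_seed(seed, i))
    if (!length(plan$selected)) stop_("strategy produced an empty plan")
    mean(plan$selected %in% flagged)
  }, numeric(1))
  list(mean_yield = mean(yields), sd_yield = stats::sd(yields), yields = yields)
}

#' Train on quarter 1, predict quarters 2-4
#'
#' Fits the model once on quarter-1 features and labels, then scores each
#' later quarter without refitting, reporting classification accuracy per
#' quarter.
#'
#' @param spec a [model_spec()].
#' @param panel a 4-quarter facility panel.
#' @param labels labels from [label_panel()].
#' @param feature_set passed to [build_features()].
#' @return named numeric vector of accuracies for Q1 (training fit,
#'   resubstitution) and Q2-Q4 (prediction).
#' @export
cross_quarter_protocol <- function(spec, panel, labels,
                                   feature_set = "basic") {
  if (!all(1:4 %in% panel$quarter)) stop_("panel must contain quarters 1-4")
  q1 <- panel[panel$quarter == 1, ]
  X1 <- build_features(q1, feature_set)
  y1 <- labels$over_report[match(paste(q1$facility_id, 1),
                                 paste(labels$facility_id, labels$quarter))]
  if (length(unique(y1)) < 2) stop_("quarter 1 has a single label class")
  model <- fit_classifier(spec, X1, y1)
  acc <- setNames(numeric(4), paste0("Q", 1:4))
  for (q in 1:4) {
    pq <- panel[panel$quarter == q, ]
    Xq <- build_features(pq, feature_set, levels = attr(X1, "schema")$levels)
    yq <- labels$over_report[match(paste(pq$facility_id, q),
                                   paste(labels$facility_id, labels$quarter))]
    acc[q] <- mean(predict_class(model, Xq) == yq)
  }
  acc
}

#' Strategy-vs-classifier comparison table
#'
#' Builds the headline comparison of audit-targeting approaches by quarter.
#' Sampling rows report mean detection yield over repeated draws; supervised
#' rows report classification accuracy (10-fold CV in Q1, then the
#' train-Q1/predict-later protocol); the two metric kinds are tagged
#' explicitly in `metric` since they are not comparable quantities.
#'
#' @param panel a facility panel.
#' @param labels labels from [label_panel()].
#' @param strategies character subset of
#'   `c("srs","stratified_srs","offender_mixed","offenders_first")`.
#' @param model_specs named list of [model_spec()] objects (possibly empty).
#' @param srs_fraction SRS audit fraction (default 0.5).
#' @param offender_fraction offender-strategy audit fraction (default 0.2).
#' @param reps sampling repetitions.
#' @param k CV folds for the Q1 column.
#' @param seed master seed.
#' @param feature_set passed to [build_features()].
#' @return data.frame: `approach`, `metric`, `Q1`..`Q4`.
#' @export
comparison_table <- function(panel, labels,
                             strategies = c("srs", "stratified_srs",
                                            "offender_mixed", "offenders_first"),
                             model_specs = list(),
                             srs_fraction = 0.5, offender_fraction = 0.2,
                             reps = 1000, k = 10, seed = 1L,
                             feature_set = "basic") {
  facs <- unique(panel$facility_id)
  dist <- panel$district_id[match(facs, panel$facility_id)]
  n_target <- round_half_up(offender_fraction * length(facs))
  flagged_by_q <- lapply(1:4, function(q)
    labels$facility_id[labels$quarter == q & labels$over_report == 1])
  rows <- list()
  for (st in strategies) {
    vals <- setNames(rep(NA_real_, 4), paste0("Q", 1:4))
    for (q in 1:4) {
      if (st %in% c("offender_mixed", "offenders_first") && q == 1) next
      strat <- switch(st,
        srs = function(s) plan_srs(facs, srs_fraction, s, q),
        stratified_srs = function(s) plan_stratified_srs(facs, dist, srs_fraction, s, q),
        offender_mixed = function(s)
          plan_offender_mixed(facs, flagged_by_q[[q - 1]], n_target, s, q),
        offenders_first = function(s)
          plan_offenders_first(facs, flagged_by_q[[q - 1]], n_target, s, q))
      vals[q] <- 100 * sampling_yield(strat, flagged_by_q[[q]], reps,
                                      derive_seed(seed, 10 * q))$mean_yield
    }
    rows[[st]] <- data.frame(approach = st, metric = "detection_yield_pct",
                             t(vals))
  }
  for (nm in names(model_specs)) {
    spec <- model_specs[[nm]]
    q1 <- panel[panel$quarter == 1, ]
    X1 <- build_features(q1, feature_set)
    y1 <- labels$over_report[match(paste(q1$facility_id, 1),
                                   paste(labels$facility_id, labels$quarter))]
    cv <- kfold_cv(spec, X1, y1, k = k, seed = derive_seed(seed, 99))
    later <- cross_quarter_protocol(spec, panel, labels, feature_set)
    vals <- c(Q1 = 100 * cv$accuracy, 100 * later[2:4])
    rows[[nm]] <- data.frame(approach = nm, metric = "accuracy_pct", t(vals))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
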