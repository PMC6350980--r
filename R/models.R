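#' Classifier specification
#'
#' Describes one classifier configuration from the benchmark's four
#' families and their hyperparameter grids:
#' naive Bayes (feature densities as a single normal, kernel estimate, or
#' supervised discretization), logistic regression (ridge penalty 0 or
#' 1e-5 to 1e-2 by factors of 10), support vector machine (linear,
#' polynomial degree 2/3, or radial kernel with width 1e-3 to 1), and
#' random forest (50/100/200/500 trees, 1-9 features per split).
#'
#' @param family one of `"naive_bayes"`, `"logistic_regression"`, `"svm"`,
#'   `"random_forest"`.
#' @param ... hyperparameters: `density` (NB), `ridge` (LR), `kernel`,
#'   `degree`, `gamma` (SVM), `ntree`, `mtry` (RF).
#' @param seed integer seed controlling all randomness in fitting.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("naive_bayes", "logistic_regression",
                                  "svm", "random_forest"),
                       ..., seed = 1L) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    naive_bayes = list(density = "normal"),
    logistic_regression = list(ridge = 0),
    svm = list(kernel = "radial", degree = NA, gamma = 0.01),
    random_forest = list(ntree = 200, mtry = 3))
  params <- utils::modifyList(defaults, params)
  validate_spec_params(family, params)
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

validate_spec_params <- function(family, p) {
  ok <- switch(family,
    naive_bayes = p$density %in% c("normal", "kernel", "discretize"),
    logistic_regression = is.numeric(p$ridge) && p$ridge >= 0 && p$ridge <= 1e-2,
    svm = p$kernel %in% c("linear", "polynomial", "radial") &&
      (p$kernel != "polynomial" || p$degree %in% 2:3) &&
      (p$kernel != "radial" || (p$gamma >= 1e-3 && p$gamma <= 1)),
    random_forest = p$ntree %in% c(50, 100, 200, 500) && p$mtry %in% 1:9)
  if (!ok) stop_("hyperparameters outside the ", family, " grid: ",
                 paste(names(p), unlist(p), sep = "=", collapse = ", "))
}

#' Hyperparameter grid of a classifier family
#'
#' Enumerates the full grid for a family, ordered from simpler (more
#' regularized, fewer trees, lower-degree kernel) to more complex models;
#' [grid_search()] breaks accuracy ties in favor of the earlier, simpler
#' entry.
#'
#' @param family classifier family name.
#' @return list of parameter lists.
#' @export
default_grid <- function(family) {
  switch(family,
    naive_bayes = lapply(c("normal", "discretize", "kernel"),
                         function(d) list(density = d)),
    logistic_regression = lapply(c(1e-2, 1e-3, 1e-4, 1e-5, 0),
                                 function(r) list(ridge = r)),
    svm = c(list(list(kernel = "linear", degree = NA, gamma = NA)),
            lapply(2:3, function(d) list(kernel = "polynomial", degree = d, gamma = NA)),
            lapply(c(1e-3, 1e-2, 1e-1, 1), function(g)
              list(kernel = "radial", degree = NA, gamma = g))),
    random_forest = {
      g <- expand.grid(ntree = c(50, 100, 200, 500), mtry = 1:9)
      g <- g[order(g$ntree, g$mtry), ]
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    stop_("unknown family: ", family))
}

#' Fit a classifier
#'
#' Fits the specified model on an encoded feature matrix and binary labels.
#' Engines: in-package naive Bayes ([model_spec()] density variants),
#' `stats::glm` / `glmnet` for (ridge) logistic regression, `e1071::svm`,
#' and `randomForest`. Fits are deterministic given `spec$seed`.
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (see [build_features()]).
#' @param y binary labels (0/1), both classes present.
#' @return an object of class `pbf_model` exposing [predict_scores()] and
#'   [predict_class()].
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop_("y must have one label per row of X")
  if (length(unique(y)) < 2)
    stop_("y has a single class; the decision boundary is undefined")
  schema <- attr(X, "schema") %||% list(columns = colnames(X))
  p <- spec$params
  fit <- with_seed(spec$seed, switch(spec$family,
    naive_bayes = fit_nb(X, y, density = p$density),
    logistic_regression = {
      if (p$ridge == 0) {
        df <- data.frame(y = y, X)
        suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      } else {
        glmnet::glmnet(X, factor(y), family = "binomial", alpha = 0,
                       lambda = p$ridge)
      }
    },
    svm = {
      args <- list(x = X, y = factor(y, levels = c(0, 1)), kernel = p$kernel,
                   cost = 1, scale = apply(X, 2, stats::sd) > 0)
      if (p$kernel == "polynomial") args$degree <- p$degree
      if (p$kernel == "radial") args$gamma <- p$gamma
      do.call(e1071::svm, args)
    },
    random_forest = randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)),
      ntree = p$ntree, mtry = min(p$mtry, ncol(X)))))
  structure(list(spec = spec, fit = fit, schema = schema),
            class = "pbf_model")
}

#' @export
print.pbf_model <- function(x, ...) {
  cat("<pbf_model> ", x$spec$family, " (",
      paste(names(x$spec$params), unlist(x$spec$params), sep = "=", collapse = ", "),
      "), ", length(x$schema$columns), " features\n", sep = "")
  invisible(x)
}

#' Predicted over-reporting risk scores
#'
#' Returns a risk score in \[0, 1\] per row; thresholding at 0.5 gives the
#' class prediction ([predict_class()]). The input columns must match the
#' training schema.
#'
#' @param model a fitted `pbf_model`.
#' @param X feature matrix with the training columns.
#' @return numeric vector of scores, named by rownames of `X`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "pbf_model"))
  X <- check_schema(model$schema, as.matrix(X))
  s <- switch(model$spec$family,
    naive_bayes = predict_nb(model$fit, X)[, "1"],
    logistic_regression = {
      if (inherits(model$fit, "glmnet"))
        as.numeric(predict(model$fit, newx = X, type = "response"))
      else
        as.numeric(predict(model$fit, newdata = data.frame(X), type = "response"))
    },
    svm = {
      pr <- predict(model$fit, X, decision.values = TRUE)
      d <- attr(pr, "decision.values")
      # decision value is positive for the class named first in the colname
      pos_first <- startsWith(colnames(d)[1], "1")
      plogis(if (pos_first) d[, 1] else -d[, 1])
    },
    random_forest = predict(model$fit, X, type = "prob")[, "1"])
  s <- as.numeric(s)
  if (any(!is.finite(s))) stop_("non-finite prediction scores")
  names(s) <- rownames(X)
  s
}

#' @rdname predict_scores
#' @export
predict_class <- function(model, X) {
  as.integer(predict_scores(model, X) >= 0.5)
}

#' Exhaustive hyperparameter search by cross-validation
#'
#' Evaluates every grid point of the family by k-fold cross-validated
#' accuracy and returns the best (ties to the simpler model, i.e. the
#' earlier grid entry). Folds are stratified by class and shared across
#' grid points.
#'
#' @param family classifier family (see [model_spec()]).
#' @param X,y training data.
#' @param k number of folds (>= 2).
#' @param seed master seed for fold assignment and fits.
#' @param grid optional list of parameter lists (default [default_grid()]).
#' @return list with `best` (a `model_spec`), `cv_accuracy`, and `results`
#'   (a data.frame of all grid points).
#' @export
grid_search <- function(family, X, y, k = 10, seed = 1L, grid = NULL) {
  if (k < 2) stop_("k must be at least 2")
  grid <- grid %||% default_grid(family)
  folds <- make_folds(as.integer(y), k, seed)
  acc <- vapply(seq_along(grid), function(i) {
    spec <- do.call(model_spec, c(list(family = family), grid[[i]],
                                  list(seed = derive_seed(seed, i))))
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr])
      mean(predict_class(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  best_i <- which.max(acc)  # first max: ties to the simpler entry
  results <- cbind(do.call(rbind, lapply(grid, function(g)
    as.data.frame(g, stringsAsFactors = FALSE))), cv_accuracy = acc)
  list(best = do.call(model_spec, c(list(family = family), grid[[best_i]],
                                    list(seed = derive_seed(seed, best_i)))),
       cv_accuracy = acc[best_i], results = results)
}

#' Save / load a fitted model
#' @param model a `pbf_model`.
#' @param path file path.
#' @return `read_model` returns the model; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
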