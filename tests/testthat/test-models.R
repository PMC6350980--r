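toy_separable <- function(n = 40) {
  withr::with_seed(8, {
    x <- c(rnorm(n / 2, -3, 0.5), rnorm(n / 2, 3, 0.5))
    X <- cbind(x = x, z = rnorm(n))
    list(X = X, y = rep(c(0L, 1L), each = n / 2))
  })
}

test_that("every family separates a linearly separable toy problem", {
  d <- toy_separable()
  for (fam in c("naive_bayes", "logistic_regression", "svm", "random_forest")) {
    m <- fit_classifier(model_spec(fam, seed = 2), d$X, d$y)
    expect_equal(mean(predict_class(m, d$X) == d$y), 1,
                 info = fam)
    s <- predict_scores(m, d$X)
    expect_true(all(s >= 0 & s <= 1), info = fam)
  }
})

test_that("Gaussian naive Bayes posteriors match a hand Bayes-rule oracle", {
  X <- cbind(a = c(1, 2, 3, 4, 6, 7, 8, 9),
             b = c(10, 11, 12, 13, 14, 16, 18, 20))
  y <- rep(c(0L, 1L), each = 4)
  m <- fit_classifier(model_spec("naive_bayes", density = "normal", seed = 1), X, y)
  Xnew <- cbind(a = c(2, 7, 5), b = c(11, 17, 14))
  got <- predict_scores(m, Xnew)

  # hand computation: prior 1/2, product of per-feature normal densities
  lik <- function(xn, Xc) dnorm(xn[1], mean(Xc[, 1]), sd(Xc[, 1])) *
    dnorm(xn[2], mean(Xc[, 2]), sd(Xc[, 2]))
  want <- apply(Xnew, 1, function(xn) {
    l0 <- lik(xn, X[y == 0, ]); l1 <- lik(xn, X[y == 1, ])
    l1 / (l0 + l1)
  })
  expect_equal(unname(got), unname(want), tolerance = 1e-9)

  # independent implementation cross-check
  e <- e1071::naiveBayes(X, factor(y))
  ref <- predict(e, Xnew, type = "raw")[, "1"]
  expect_equal(unname(got), unname(ref), tolerance = 1e-6)

  # kernel and discretized variants run and stay in [0, 1]
  for (dens in c("kernel", "discretize")) {
    mk <- fit_classifier(model_spec("naive_bayes", density = dens, seed = 1), X, y)
    sk <- predict_scores(mk, Xnew)
    expect_true(all(sk >= 0 & sk <= 1), info = dens)
  }
})

test_that("prediction respects the training schema and is deterministic", {
  d <- toy_separable()
  m <- fit_classifier(model_spec("random_forest", ntree = 100, mtry = 1, seed = 5),
                      d$X, d$y)
  expect_error(predict_scores(m, d$X[, "x", drop = FALSE]), "missing.*z")

  # constant input rows give one constant score
  const <- d$X[rep(1, 6), ]
  expect_equal(length(unique(predict_scores(m, const))), 1)

  # refit with the same seed reproduces scores exactly
  m2 <- fit_classifier(model_spec("random_forest", ntree = 100, mtry = 1, seed = 5),
                       d$X, d$y)
  expect_identical(predict_scores(m, d$X), predict_scores(m2, d$X))

  expect_error(fit_classifier(model_spec("svm", seed = 1), d$X, rep(0L, 40)),
               "single class")
  expect_error(model_spec("random_forest", ntree = 73), "grid")
  expect_error(model_spec("logistic_regression", ridge = 1), "grid")
})

test_that("grid search picks regularization and interaction capacity when planted", {
  # one-point grid returns that point
  d <- toy_separable()
  gs <- grid_search("svm", d$X, d$y, k = 4, seed = 3,
                    grid = list(list(kernel = "linear", degree = NA, gamma = NA)))
  expect_equal(gs$best$params$kernel, "linear")
  expect_equal(nrow(gs$results), 1)
  expect_error(grid_search("svm", d$X, d$y, k = 1), "at least 2")

  # heavily collinear design: ridge beats the unpenalized model in CV
  withr::with_seed(21, {
    n <- 80
    z1 <- rnorm(n); z2 <- rnorm(n)
    X <- cbind(sapply(1:15, function(i) z1 + rnorm(n, 0, 0.05)),
               sapply(1:15, function(i) z2 + rnorm(n, 0, 0.05)),
               matrix(rnorm(n * 10), n, 10))
    colnames(X) <- paste0("f", 1:40)
    y <- as.integer(runif(n) < plogis(2 * z1 - 2 * z2))
  })
  gs <- suppressWarnings(
    grid_search("logistic_regression", X, y, k = 5, seed = 9,
                grid = lapply(c(1e-2, 1e-3, 0), function(r) list(ridge = r))))
  expect_gt(gs$best$params$ridge, 0)

  # XOR signal among noise features: more features per split wins
  withr::with_seed(22, {
    n <- 300
    X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- as.integer(xor(X[, 1] > 0, X[, 2] > 0))
    y <- ifelse(runif(n) < 0.1, 1L - y, y)  # 10% label noise
  })
  gs <- grid_search("random_forest", X, y, k = 5, seed = 9,
                    grid = list(list(ntree = 100, mtry = 1), list(ntree = 100, mtry = 4)))
  expect_gt(gs$best$params$mtry, 1)
})

test_that("random forest exploits the interaction gaming mechanism; a linear model cannot", {
  aucs <- list()
  for (mech in c("interaction", "additive")) {
    pan <- generate_panel(sim_config(n_facilities = 600, gaming_mechanism = mech,
                                     seed = 11))
    lb <- label_panel(pan)
    q1 <- pan[pan$quarter == 1, ]
    Xc <- build_features(q1, "covariates")
    y <- ever_flagged(pan, lb)
    rf <- kfold_cv(model_spec("random_forest", seed = 3), Xc, y, k = 10, seed = 5)
    lr <- kfold_cv(model_spec("logistic_regression", ridge = 1e-3, seed = 3),
                   Xc, y, k = 10, seed = 5)
    aucs[[mech]] <- c(rf = rf$auc, lr = lr$auc)
  }
  # threshold/interaction mechanism: forest clearly ahead
  expect_gt(aucs$interaction["rf"], aucs$interaction["lr"] + 0.1)
  # additive mechanism: the linear model keeps up
  expect_gt(aucs$additive["lr"], aucs$additive["rf"] - 0.05)
})
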