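# Naive Bayes with the three density treatments used in the benchmark:
# a single normal per feature, kernel density estimation, and supervised
# (entropy-guided, equal-frequency) discretization. Implemented in-package
# because no installed classifier exposes the kernel/discretized variants.

fit_nb <- function(X, y, density = c("normal", "kernel", "discretize"),
                   laplace = 1) {
  density <- match.arg(density)
  y <- factor(y)
  classes <- levels(y)
  prior <- prop.table(table(y))
  feats <- colnames(X)
  per_class <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    lapply(seq_along(feats), function(j) nb_feature_model(Xc[, j], X[, j], density))
  })
  names(per_class) <- classes
  disc <- NULL
  if (density == "discretize") {
    disc <- lapply(seq_along(feats), function(j) nb_discretize(X[, j], y))
    per_class <- lapply(classes, function(cl) {
      lapply(seq_along(feats), function(j) {
        b <- nb_bin(X[y == cl, j], disc[[j]])
        tab <- tabulate(b, nbins = length(disc[[j]]) - 1) + laplace
        tab / sum(tab)
      })
    })
    names(per_class) <- classes
  }
  structure(list(density = density, classes = classes, prior = prior,
                 per_class = per_class, disc = disc, features = feats),
            class = "nb_model")
}

nb_feature_model <- function(x_class, x_all, density) {
  sd_floor <- max(stats::sd(x_all), 1e-6) * 1e-3
  if (density == "normal" || length(unique(x_class)) < 2) {
    return(list(kind = "normal", mean = mean(x_class),
                sd = max(stats::sd(x_class), sd_floor, na.rm = TRUE)))
  }
  if (density == "kernel") {
    d <- density(x_class)
    return(list(kind = "kernel", x = d$x, y = pmax(d$y, 1e-12),
                floor = 1e-12))
  }
  NULL  # discretize handled separately
}

# equal-frequency candidate binnings; pick the bin count with minimum
# class-conditional entropy H(Y | bin)
nb_discretize <- function(x, y, max_bins = 5) {
  best <- NULL
  best_h <- Inf
  for (nb in 2:max_bins) {
    qs <- unique(quantile(x, probs = seq(0, 1, length.out = nb + 1), names = FALSE))
    if (length(qs) < 3) next
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    b <- cut(x, qs, labels = FALSE, include.lowest = TRUE)
    h <- 0
    for (bb in unique(b)) {
      p <- prop.table(table(y[b == bb]))
      h <- h + mean(b == bb) * (-sum(p * log(pmax(p, 1e-12))))
    }
    if (h < best_h - 1e-12) { best_h <- h; best <- qs }
  }
  best %||% c(-Inf, median(x), Inf)
}

nb_bin <- function(x, breaks) cut(x, breaks, labels = FALSE, include.lowest = TRUE)

nb_log_density <- function(m, x) {
  if (m$kind == "normal") return(dnorm(x, m$mean, m$sd, log = TRUE))
  log(pmax(stats::approx(m$x, m$y, xout = x, yleft = m$floor,
                         yright = m$floor)$y, m$floor))
}

predict_nb <- function(object, X) {
  n <- nrow(X)
  logp <- matrix(log(as.numeric(object$prior)), n, length(object$classes),
                 byrow = TRUE, dimnames = list(NULL, object$classes))
  for (ci in seq_along(object$classes)) {
    cl <- object$classes[ci]
    for (j in seq_along(object$features)) {
      if (object$density == "discretize") {
        b <- nb_bin(X[, j], object$disc[[j]])
        logp[, ci] <- logp[, ci] + log(object$per_class[[cl]][[j]][b])
      } else {
        logp[, ci] <- logp[, ci] + nb_log_density(object$per_class[[cl]][[j]], X[, j])
      }
    }
  }
  # normalized posterior
  mx <- apply(logp, 1, max)
  p <- exp(logp - mx)
  p / rowSums(p)
}
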