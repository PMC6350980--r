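#' Generate a synthetic facility-quarter reporting panel
#'
#' Simulates 4 quarters of reported and verified service counts for a set of
#' health facilities under a performance-based financing scheme. Each
#' facility is assigned a gaming-frequency class (number of quarters in
#' which it over-reports) from `config$type_probs`; the particular quarters
#' are placed with serial persistence (see [sim_config()]). In gamed
#' quarters reported counts are the verified counts inflated by a factor
#' drawn from `config$inflation_range` (rounded up, and at least one unit
#' per indicator, so a gamed quarter always carries a positive report); in
#' honest quarters reports equal the verified counts up to a bounded
#' relative tally error applied to counts of 20 or more, which keeps honest
#' rounding strictly below the over-reporting threshold.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` with one row per facility-quarter and columns
#'   `facility_id`, `district_id`, `pbf_flag`, `audit_arm`, `quarter`,
#'   `rep_1..rep_9`, `ver_1..ver_9`, `facility_type`, `managing_authority`,
#'   `location`, `catchment_population`, `established_posts`,
#'   `filled_posts`, and the latent `gaming_flag` (kept for evaluating the
#'   labeler; never a model feature).
#' @examples
#' panel <- generate_panel(sim_config(n_facilities = 30, seed = 7))
#' table(panel$quarter)
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  n <- cfg$n_facilities
  n_pbf <- round_half_up(n * cfg$pbf_share)
  n_pbf <- max(cfg$n_pbf_districts, min(n_pbf, n - cfg$n_nonpbf_districts))
  n_non <- n - n_pbf

  # district assignment: near-equal strata within each program arm
  d_pbf <- sort(rep_len(seq_len(cfg$n_pbf_districts), n_pbf))
  d_non <- sort(rep_len(cfg$n_pbf_districts + seq_len(cfg$n_nonpbf_districts), n_non))
  district <- c(d_pbf, d_non)
  pbf <- rep(c(1L, 0L), c(n_pbf, n_non))

  arms <- c(10L, 30L, 100L)
  audit_arm <- ifelse(pbf == 1L,
                      sample(arms, n, replace = TRUE, prob = cfg$audit_arm_probs),
                      0L)

  facility_type <- sample(
    c("rural health centre", "urban health centre", "health post",
      "rural health post", "district hospital", "mission hospital",
      "private clinic", "other"),
    n, replace = TRUE,
    prob = c(0.45, 0.10, 0.15, 0.12, 0.04, 0.06, 0.04, 0.04))
  managing_authority <- sample(
    c("government", "mission/FBO", "private", "military", "other"),
    n, replace = TRUE, prob = c(0.70, 0.15, 0.08, 0.02, 0.05))
  location <- sample(c("rural", "peri-urban", "urban"),
                     n, replace = TRUE, prob = c(0.70, 0.20, 0.10))
  catchment <- as.integer(round(rlnorm(n, meanlog = log(7000), sdlog = 0.5)))
  established <- pmax(2L, rpois(n, 3 + 4 * catchment / 7000))
  filled <- rbinom(n, established, 0.72)

  # gaming-frequency classes, coupled to covariates through a propensity rank
  k_draws <- sample(0:4, n, replace = TRUE, prob = cfg$type_probs)
  staffing_gap <- 1 - filled / established
  z_catch <- log(catchment) - log(7000)
  # who games: either a linear (additive) propensity in the covariates, or a
  # threshold interaction -- gaming concentrated in large non-rural and small
  # rural facilities -- that no linear model can represent
  prop <- switch(cfg$gaming_mechanism,
    none = rep(0, n),
    additive = 1.0 * z_catch / 0.5 + 0.8 * (location == "rural") +
      0.6 * (staffing_gap - 0.28) / 0.12,
    interaction = 2 * as.numeric(xor(z_catch > 0, location == "rural")))
  rank_score <- prop + rnorm(n, 0, cfg$signal_noise)
  k <- integer(n)
  k[order(rank_score, decreasing = TRUE)] <- sort(k_draws, decreasing = TRUE)

  # which quarters each gaming facility games: Gibbs subset model
  w <- persistence_weight(cfg$persistence, cfg$type_probs)
  qs <- quarter_subsets()
  gq <- matrix(FALSE, n, 4)
  for (kk in 1:4) {
    idx <- which(k == kk)
    if (!length(idx)) next
    info <- qs[[kk + 1]]
    pr <- w^info$adj
    pick <- sample.int(length(info$sets), length(idx), replace = TRUE, prob = pr)
    for (j in seq_along(idx)) gq[idx[j], info$sets[[pick[j]]]] <- TRUE
  }

  size_factor <- catchment / 7000
  rows <- vector("list", 4)
  for (q in 1:4) {
    mu <- outer(size_factor, cfg$indicator_means)
    ver <- matrix(rnbinom(n * 9, mu = mu, size = cfg$dispersion), n, 9)
    rep_ <- ver
    honest <- !gq[, q]
    if (any(honest)) {
      eps <- matrix(runif(sum(honest) * 9, -cfg$honest_noise, cfg$honest_noise),
                    ncol = 9)
      vh <- ver[honest, , drop = FALSE]
      noisy <- round(vh * (1 + eps))
      rep_[honest, ] <- ifelse(vh >= 20, noisy, vh)
    }
    gamed <- gq[, q]
    if (any(gamed)) {
      f <- runif(sum(gamed), cfg$inflation_range[1], cfg$inflation_range[2])
      rep_[gamed, ] <- pmax(ceiling(ver[gamed, , drop = FALSE] * f), 1L)
    }
    storage.mode(ver) <- "integer"
    storage.mode(rep_) <- "integer"
    df <- data.frame(
      facility_id = seq_len(n), district_id = district, pbf_flag = pbf,
      audit_arm = audit_arm, quarter = q)
    colnames(rep_) <- paste0("rep_", 1:9)
    colnames(ver) <- paste0("ver_", 1:9)
    rows[[q]] <- cbind(df, rep_, ver,
      data.frame(facility_type = facility_type,
                 managing_authority = managing_authority,
                 location = location,
                 catchment_population = catchment,
                 established_posts = established,
                 filled_posts = filled,
                 gaming_flag = as.integer(gq[, q])))
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$facility_id, panel$quarter), ]
  rownames(panel) <- NULL
  panel
}

#' Empirical cross-quarter persistence of over-reporting
#'
#' Computes the 4x4 matrix whose (i, j) entry is the share of facilities
#' flagged as over-reporting in quarter i that are also flagged in quarter
#' j. Diagonal entries are 1 wherever quarter i has at least one flagged
#' facility; a quarter with no flagged facilities yields `NA` entries
#' (undefined conditioning), never zero.
#'
#' @param labels a data.frame with columns `facility_id`, `quarter`,
#'   `over_report` (as returned by [label_panel()]).
#' @return a 4x4 numeric matrix of conditional probabilities.
#' @export
empirical_persistence <- function(labels) {
  stopifnot(all(c("facility_id", "quarter", "over_report") %in% names(labels)))
  flag <- with(labels, tapply(over_report, list(facility_id, quarter), function(x) x[1]))
  if (ncol(flag) != 4) stop_("labels must cover exactly 4 quarters")
  flag <- flag == 1
  out <- matrix(NA_real_, 4, 4, dimnames = list(paste0("Q", 1:4), paste0("Q", 1:4)))
  for (i in 1:4) {
    base <- which(flag[, i])
    if (!length(base)) next
    for (j in 1:4) out[i, j] <- mean(flag[base, j])
  }
  out
}

#' Write / read a facility panel as CSV
#'
#' Long format, one row per facility-quarter, the column layout produced by
#' [generate_panel()].
#'
#' @param panel a panel data.frame.
#' @param path file path.
#' @return `read_panel` returns the panel data.frame; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("facility_id", "district_id", "pbf_flag", "audit_arm", "quarter",
            paste0("rep_", 1:9), paste0("ver_", 1:9))
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop_("panel file missing columns: ", paste(miss, collapse = ", "))
  panel
}
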