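#' Price schedule for the incentivized indicators
#'
#' A PBF quantity bonus is the sum over indicators of the verified (or
#' reported) service count times the indicator's unit price. The pilot
#' rewarded nine maternal and child health indicators; unit prices are
#' program-specific, so the schedule is fully configurable. The defaults
#' are plausible magnitudes chosen so that a typical facility's quarterly
#' bonus is on the order of $1,500-$2,000.
#'
#' @param prices named numeric vector of 9 positive unit prices
#'   (currency per service).
#' @return an object of class `price_schedule`.
#' @export
price_schedule <- function(prices = c(
                             deliveries = 5.0, anc1 = 1.5, anc4 = 2.0,
                             pnc = 1.5, immunization = 2.0,
                             growth_monitoring = 0.5, family_planning = 2.5,
                             skilled_attendance = 4.0, malaria_ipt = 1.0)) {
  if (length(prices) != 9)
    stop_("a price schedule must have exactly 9 indicators, got ", length(prices))
  if (any(prices <= 0)) stop_("all unit prices must be positive")
  if (is.null(names(prices)) || any(!nzchar(names(prices))))
    names(prices) <- paste0("indicator_", 1:9)
  structure(prices, class = c("price_schedule", "numeric"))
}

#' Labeling configuration
#'
#' @param threshold relative bonus excess at or above which a quarter is
#'   labeled over-reported (default 0.10; the boundary is inclusive: a
#'   report exceeding the verified bonus by exactly 10% is flagged).
#' @param zero_verified_rule flag a quarter whose verified bonus is 0 but
#'   whose reported bonus is positive (default `TRUE`): any positive claim
#'   against zero verified services is an infinite relative excess.
#' @return an object of class `label_config`.
#' @export
label_config <- function(threshold = 0.10, zero_verified_rule = TRUE) {
  if (threshold <= 0) stop_("threshold must be positive")
  structure(list(threshold = threshold,
                 zero_verified_rule = isTRUE(zero_verified_rule)),
            class = "label_config")
}

#' Quarterly bonus from counts and prices
#'
#' The bonus is the sum over the 9 indicators of count times unit price.
#'
#' @param counts numeric 9-vector of service counts (or a matrix with 9
#'   columns, one row per facility-quarter).
#' @param schedule a [price_schedule()].
#' @return the bonus (scalar, or vector for matrix input).
#' @examples
#' compute_bonus(c(10, 5, rep(0, 7)), price_schedule(c(a=2,b=4,c=1,d=1,e=1,f=1,g=1,h=1,i=1)))
#' @export
compute_bonus <- function(counts, schedule) {
  stopifnot(inherits(schedule, "price_schedule"))
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    if (ncol(counts) != 9)
      stop_("counts has ", ncol(counts), " columns; the schedule prices 9 indicators (",
            paste(names(schedule), collapse = ", "), ")")
    if (any(counts < 0)) stop_("counts must be non-negative")
    return(drop(counts %*% as.numeric(schedule)))
  }
  if (length(counts) != 9)
    stop_("counts has length ", length(counts), "; the schedule prices 9 indicators (",
          paste(names(schedule), collapse = ", "), ")")
  if (any(counts < 0)) stop_("counts must be non-negative")
  sum(counts * as.numeric(schedule))
}

#' Binary over-reporting label for one facility-quarter
#'
#' A quarter is over-reported when the bonus computed from the reported
#' counts exceeds the bonus computed from the verified counts by the
#' threshold fraction or more (inclusive). With a zero verified bonus, a
#' positive reported bonus is flagged when `zero_verified_rule` is on.
#'
#' @param reported_bonus,verified_bonus non-negative bonus amounts.
#' @param config a [label_config()].
#' @return integer 0/1 (vectorized over its bonus arguments).
#' @examples
#' label_quarter(110, 100)   # exactly +10%: flagged
#' label_quarter(109.99, 100)
#' @export
label_quarter <- function(reported_bonus, verified_bonus, config = label_config()) {
  stopifnot(inherits(config, "label_config"))
  if (any(reported_bonus < 0) || any(verified_bonus < 0))
    stop_("bonuses must be non-negative")
  # inclusive boundary, robust to floating-point representation of the
  # threshold product (e.g. 1.1 * 100 > 110 in double arithmetic)
  tol <- 1e-9 * pmax(verified_bonus, 1)
  flag <- reported_bonus - (1 + config$threshold) * verified_bonus >= -tol &
    reported_bonus > verified_bonus
  if (config$zero_verified_rule)
    flag <- flag | (verified_bonus == 0 & reported_bonus > 0)
  else
    flag <- flag & verified_bonus > 0
  as.integer(flag)
}

#' Label every facility-quarter of a panel
#'
#' Computes reported and verified bonuses for each facility-quarter and the
#' binary over-reporting flag.
#'
#' @param panel a facility panel (see [generate_panel()]).
#' @param schedule a [price_schedule()].
#' @param config a [label_config()].
#' @return data.frame with columns `facility_id`, `quarter`,
#'   `reported_bonus`, `verified_bonus`, `over_report`.
#' @export
label_panel <- function(panel, schedule = price_schedule(), config = label_config()) {
  qt <- table(panel$facility_id)
  bad <- names(qt)[qt != 4]
  if (length(bad))
    stop_("facilities without exactly 4 quarters: ",
          paste(head(bad, 10), collapse = ", "))
  rep_m <- as.matrix(panel[, paste0("rep_", 1:9)])
  ver_m <- as.matrix(panel[, paste0("ver_", 1:9)])
  rb <- compute_bonus(rep_m, schedule)
  vb <- compute_bonus(ver_m, schedule)
  data.frame(
    facility_id = panel$facility_id,
    quarter = panel$quarter,
    reported_bonus = rb,
    verified_bonus = vb,
    over_report = label_quarter(rb, vb, config))
}

#' Distribution of facilities by number of flagged quarters
#'
#' Tabulates how many facilities were flagged as over-reporting in 0, 1, 2,
#' 3 or 4 quarters, with percentages.
#'
#' @param labels a label data.frame ([label_panel()]), or a numeric
#'   5-vector of pre-tabulated counts for 0..4 quarters.
#' @return data.frame with columns `quarters_flagged` (0..4), `n`,
#'   `percent` (to 1 decimal; sums to 100 within rounding).
#' @examples
#' offender_distribution(c(81, 32, 12, 9, 6))
#' @export
offender_distribution <- function(labels) {
  if (is.numeric(labels) && length(labels) == 5) {
    counts <- as.numeric(labels)
  } else {
    stopifnot(all(c("facility_id", "over_report") %in% names(labels)))
    per_fac <- tapply(labels$over_report, labels$facility_id, sum)
    counts <- as.numeric(table(factor(per_fac, levels = 0:4)))
  }
  n <- sum(counts)
  data.frame(quarters_flagged = 0:4,
             n = counts,
             percent = round(100 * counts / n, 1))
}
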