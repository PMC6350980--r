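#' Verification cost model
#'
#' Counter-verification of n facilities costs a marginal amount mc per
#' facility visited; each detected over-reporter (a fraction p of the
#' sample) pays back a sanction s; fixed costs fc accrue per period. Total
#' cost is the linear function
#' \deqn{tc = n[p(mc - s) + (1 - p) mc] + fc = n(mc - p s) + fc,}
#' so better targeting (higher p at fixed n) lowers cost with slope -n s.
#'
#' @param n facilities sampled.
#' @param p proportion of sampled facilities found misreporting, in \[0,1\].
#' @param mc marginal verification cost per facility (currency).
#' @param s sanction recovered per detected misreporter (currency); in the
#'   reference scenario the full quarterly bonus.
#' @param fc fixed cost per period (currency).
#' @param afc average fixed cost per facility (currency), used by the
#'   per-facility form [per_facility_cost()]; with `afc = fc / n` the two
#'   forms agree exactly.
#' @return `cost_params`: a validated parameter list.
#' @export
cost_params <- function(n, p, mc, s, fc = 0, afc = 0) {
  if (n < 0) stop_("n must be non-negative")
  if (p < 0 || p > 1) stop_("p must be a proportion in [0, 1], got ", p)
  if (mc < 0 || s < 0 || fc < 0 || afc < 0)
    stop_("mc, s, fc, afc must be non-negative")
  structure(list(n = n, p = p, mc = mc, s = s, fc = fc, afc = afc),
            class = "cost_params")
}

#' Total verification cost
#'
#' @param params a [cost_params()] object.
#' @return list of class `cost_result`: `tc` (bracketed form), and
#'   `per_facility` (tc / n when n > 0).
#' @examples
#' total_cost(cost_params(n = 10, p = 0.3, mc = 800, s = 1900, fc = 5000))
#' @export
total_cost <- function(params) {
  stopifnot(inherits(params, "cost_params"))
  with(params, {
    tc <- n * (p * (mc - s) + (1 - p) * mc) + fc
    structure(list(tc = tc,
                   per_facility = if (n > 0) tc / n else NA_real_,
                   params = params),
              class = "cost_result")
  })
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("<cost_result> tc = %.2f (per facility %.2f) at p = %.2f\n",
              x$tc, x$per_facility, x$params$p))
  invisible(x)
}

#' Average verification cost per facility
#'
#' The per-facility form of the cost model: marginal cost, less the
#' expected sanction recovery, plus the average fixed cost:
#' \deqn{mc - p s + afc.}
#' With the reference parameters (mc = 800, s = 1900, afc = 1600) this is
#' $2,039 at a detection probability of 0.19 and $728 at 0.88.
#'
#' @param p detection probability in \[0, 1\].
#' @param mc marginal cost per facility.
#' @param s sanction per detected misreporter.
#' @param afc average fixed cost per facility.
#' @return per-facility cost (currency); vectorized over `p`.
#' @examples
#' per_facility_cost(p = c(0.19, 0.88), mc = 800, s = 1900, afc = 1600)
#' @export
per_facility_cost <- function(p, mc, s, afc) {
  if (any(p < 0 | p > 1)) stop_("p must be in [0, 1]")
  if (any(c(mc, s, afc) < 0)) stop_("mc, s, afc must be non-negative")
  mc - p * s + afc
}

#' Relative cost savings from improved targeting
#'
#' Fractional reduction in per-facility verification cost when moving from
#' a baseline detection probability to an alternative:
#' (cost(p_base) - cost(p_alt)) / cost(p_base). Negative when the
#' alternative detects less.
#'
#' @param p_base,p_alt baseline and alternative detection probabilities.
#' @inheritParams per_facility_cost
#' @return proportion saved.
#' @examples
#' relative_savings(0.19, 0.88, mc = 800, s = 1900, afc = 1600)  # ~ 2/3
#' @export
relative_savings <- function(p_base, p_alt, mc, s, afc) {
  base <- per_facility_cost(p_base, mc, s, afc)
  if (any(base <= 0)) stop_("baseline per-facility cost must be positive")
  (base - per_facility_cost(p_alt, mc, s, afc)) / base
}

#' Cost scenarios over a grid of detection probabilities
#'
#' @param p vector of detection probabilities.
#' @param mc,s,afc cost parameters.
#' @param p_base baseline for the savings column (default `p[1]`).
#' @return data.frame with columns `p`, `per_facility`,
#'   `savings_vs_baseline`.
#' @export
cost_scenarios <- function(p, mc, s, afc, p_base = p[1]) {
  data.frame(p = p,
             per_facility = per_facility_cost(p, mc, s, afc),
             savings_vs_baseline = relative_savings(p_base, p, mc, s, afc))
}
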