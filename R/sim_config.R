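#' Simulation configuration for facility reporting panels
#'
#' Builds and validates the configuration object consumed by
#' [generate_panel()]. Defaults emulate a PBF pilot of 140 rural health
#' facilities observed over 4 quarters: 18 districts (10 in the PBF program,
#' 8 comparison), a facility-level over-reporting frequency distribution of
#' 81/32/12/9/6 facilities gaming in 0/1/2/3/4 quarters, and serial
#' persistence of gaming calibrated so that about 58% of facilities flagged
#' in one quarter are flagged again in the next.
#'
#' @param n_facilities number of facilities (default 140).
#' @param n_pbf_districts,n_nonpbf_districts number of program and
#'   non-program districts (defaults 10 and 8). Non-program facilities are
#'   never subject to audit (audit arm 0).
#' @param pbf_share share of facilities located in program districts
#'   (default 105/140).
#' @param type_probs probability vector over the number of quarters (0-4) in
#'   which a facility over-reports. Default `c(81, 32, 12, 9, 6)/140`.
#' @param persistence target conditional probability that a facility gaming
#'   in quarter t games again in t+1 (default 0.577). Must lie in the range
#'   attainable given `type_probs`; see Details.
#' @param indicator_means expected quarterly verified service counts for the
#'   9 incentivized indicators, for a facility of average catchment size.
#' @param dispersion negative-binomial size parameter for verified counts
#'   (smaller = more overdispersed).
#' @param inflation_range interval of the multiplicative inflation factor
#'   applied to reports in gamed quarters. The lower bound must exceed
#'   1 + `label_threshold` so gamed quarters are flaggable by construction.
#' @param honest_noise maximum symmetric relative reporting error in
#'   non-gamed quarters; must be below `label_threshold`.
#' @param audit_arm_probs allocation probabilities over the 10/30/100 percent
#'   audit-probability arms for program facilities.
#' @param gaming_mechanism how facility covariates drive who games:
#'   `"interaction"` (default; a threshold/XOR rule in catchment size and
#'   staffing shortfall), `"additive"` (linear score in the covariates), or
#'   `"none"` (gaming assigned independently of covariates).
#' @param signal_noise standard deviation of the noise added to the
#'   covariate propensity score before gaming classes are assigned by rank;
#'   larger values weaken the covariate signal.
#' @param label_threshold the downstream over-reporting label threshold the
#'   generator must respect (default 0.10); used only for validation.
#' @param seed integer random seed; the panel is a deterministic function of
#'   the full configuration.
#'
#' @details
#' Gaming quarters for a facility with k gaming quarters are drawn as a
#' size-k subset S of the 4 quarters with probability proportional to
#' w^a(S), where a(S) counts adjacent quarter pairs in S and the weight w is
#' solved numerically so the model-implied conditional
#' P(game in t+1 | game in t) equals `persistence`. With w = 1 subsets are
#' uniform, which makes quarters exchangeable; combined with binomial
#' `type_probs` that is the independence limit.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_panel()]
#' @export
sim_config <- function(n_facilities = 140,
                       n_pbf_districts = 10,
                       n_nonpbf_districts = 8,
                       pbf_share = 105 / 140,
                       type_probs = c(81, 32, 12, 9, 6) / 140,
                       persistence = 0.577,
                       indicator_means = c(
                         deliveries = 55, anc1 = 95, anc4 = 65, pnc = 75,
                         immunization = 85, growth_monitoring = 310,
                         family_planning = 130, skilled_attendance = 50,
                         malaria_ipt = 90
                       ),
                       dispersion = 8,
                       inflation_range = c(1.15, 1.60),
                       honest_noise = 0.05,
                       audit_arm_probs = c(`10` = 1, `30` = 1, `100` = 1) / 3,
                       gaming_mechanism = c("interaction", "additive", "none"),
                       signal_noise = 0.5,
                       label_threshold = 0.10,
                       seed = 1L) {
  gaming_mechanism <- match.arg(gaming_mechanism)
  if (length(type_probs) != 5 || any(type_probs < 0))
    stop_("type_probs must be 5 non-negative probabilities (0-4 gaming quarters)")
  if (abs(sum(type_probs) - 1) > 1e-12)
    stop_("type_probs must sum to 1 (off by ", format(sum(type_probs) - 1), ")")
  if (length(indicator_means) != 9 || any(indicator_means <= 0))
    stop_("indicator_means must be 9 positive values")
  if (length(inflation_range) != 2 || inflation_range[1] > inflation_range[2])
    stop_("inflation_range must be an increasing interval")
  if (inflation_range[1] <= 1 + label_threshold)
    stop_("inflation_range lower bound must exceed 1 + label_threshold (",
          1 + label_threshold, ") so gamed quarters are flaggable")
  if (honest_noise < 0 || honest_noise >= label_threshold)
    stop_("honest_noise must be in [0, label_threshold)")
  if (n_facilities < n_pbf_districts + n_nonpbf_districts)
    stop_("n_facilities (", n_facilities, ") is smaller than the number of districts (",
          n_pbf_districts + n_nonpbf_districts, "): cannot populate strata")
  if (persistence <= 0 || persistence >= 1)
    stop_("persistence must be in (0, 1)")
  if (length(audit_arm_probs) != 3 || any(audit_arm_probs < 0))
    stop_("audit_arm_probs must be 3 non-negative weights over arms 10/30/100")
  if (is.null(seed) || !is.finite(seed))
    stop_("seed is mandatory")

  cfg <- list(
    n_facilities = as.integer(n_facilities),
    n_pbf_districts = as.integer(n_pbf_districts),
    n_nonpbf_districts = as.integer(n_nonpbf_districts),
    pbf_share = pbf_share,
    type_probs = type_probs,
    persistence = persistence,
    indicator_means = indicator_means,
    dispersion = dispersion,
    inflation_range = inflation_range,
    honest_noise = honest_noise,
    audit_arm_probs = audit_arm_probs / sum(audit_arm_probs),
    gaming_mechanism = gaming_mechanism,
    signal_noise = signal_noise,
    label_threshold = label_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_facilities, " facilities, ",
      x$n_pbf_districts + x$n_nonpbf_districts, " districts, 4 quarters\n",
      "  gaming-class probs: ", paste(round(x$type_probs, 3), collapse = "/"),
      "; persistence ", x$persistence,
      "; mechanism ", x$gaming_mechanism, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# --- quarter-subset placement model -----------------------------------------

# all size-k subsets of the 4 quarters with their adjacent-pair counts
quarter_subsets <- function() {
  out <- list()
  for (k in 0:4) {
    if (k == 0) {
      out[[k + 1]] <- list(sets = list(integer(0)), adj = 0L)
      next
    }
    cmb <- utils::combn(4, k, simplify = FALSE)
    adj <- vapply(cmb, function(s) sum(diff(sort(s)) == 1L), integer(1))
    out[[k + 1]] <- list(sets = cmb, adj = adj)
  }
  out
}

# model-implied conditional P(game in Q2 | game in Q1) -- the first-row
# persistence entry -- for adjacency weight w and gaming-class distribution
implied_persistence <- function(w, type_probs) {
  qs <- quarter_subsets()
  num <- 0
  den <- 0
  for (k in 1:4) {
    info <- qs[[k + 1]]
    pr <- w^info$adj
    pr <- pr / sum(pr)
    in1 <- vapply(info$sets, function(s) 1 %in% s, logical(1))
    in12 <- vapply(info$sets, function(s) all(c(1, 2) %in% s), logical(1))
    num <- num + type_probs[k + 1] * sum(pr[in12])
    den <- den + type_probs[k + 1] * sum(pr[in1])
  }
  num / den
}

# solve for the adjacency weight achieving a target persistence; clamps to
# the attainable range with a warning
persistence_weight <- function(persistence, type_probs) {
  lo <- implied_persistence(1e-8, type_probs)
  hi <- implied_persistence(1e8, type_probs)
  # degenerate class mixes (no gaming, or a conditional pinned by the class
  # counts alone) leave nothing to calibrate: placement is w-free
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-9) return(1)
  if (persistence <= lo || persistence >= hi) {
    warning("persistence ", persistence, " outside attainable range (",
            round(lo, 3), ", ", round(hi, 3),
            ") for this type_probs; clamping", call. = FALSE)
    return(if (persistence <= lo) 1e-8 else 1e8)
  }
  f <- function(lw) implied_persistence(exp(lw), type_probs) - persistence
  exp(uniroot(f, c(log(1e-8), log(1e8)), tol = 1e-10)$root)
}
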