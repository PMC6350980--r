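#' Audit plans
#'
#' An audit plan is the set of facilities one strategy selects for
#' counter-verification in one quarter, with provenance (strategy name,
#' seed, target size). All strategies draw without replacement and consume
#' an explicit seed; there is no hidden global random state.
#'
#' @name audit_plan
NULL

new_audit_plan <- function(strategy, selected, target_size, seed, quarter = NA_integer_) {
  if (anyDuplicated(selected)) stop_("audit plan contains duplicate facilities")
  structure(list(quarter = quarter, strategy = strategy,
                 selected = selected, target_size = as.integer(target_size),
                 seed = seed),
            class = "audit_plan")
}

#' @export
print.audit_plan <- function(x, ...) {
  cat("<audit_plan> ", x$strategy, ": ", length(x$selected),
      " facilities (target ", x$target_size, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simple random sampling of facilities
#'
#' Draws a fraction of the facility population uniformly at random without
#' replacement, the default counter-verification scheme in most PBF
#' programs (typically 50% of facilities).
#'
#' @param population vector of facility ids.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @param quarter optional quarter tag for provenance.
#' @return an `audit_plan`.
#' @export
plan_srs <- function(population, fraction = 0.5, seed, quarter = NA_integer_) {
  if (!length(population)) stop_("population is empty")
  if (fraction <= 0 || fraction > 1) stop_("fraction must be in (0, 1]")
  n_sel <- round_half_up(fraction * length(population))
  sel <- with_seed(seed, sample(population, n_sel))
  new_audit_plan("srs", sel, n_sel, seed, quarter)
}

#' District-stratified random sampling
#'
#' Within each district, a fraction of facilities is drawn uniformly
#' (round-half-up per stratum), guaranteeing that counter-verification
#' visits every district with at least one eligible draw.
#'
#' @param population facility ids.
#' @param district district id per facility (same length as `population`).
#' @inheritParams plan_srs
#' @return an `audit_plan`.
#' @export
plan_stratified_srs <- function(population, district, fraction = 0.5, seed,
                                quarter = NA_integer_) {
  if (!length(population)) stop_("population is empty")
  if (length(district) != length(population))
    stop_("district must align with population")
  if (fraction <= 0 || fraction > 1) stop_("fraction must be in (0, 1]")
  sel <- with_seed(seed, {
    unlist(lapply(split(population, district), function(ids) {
      n_d <- round_half_up(fraction * length(ids))
      if (n_d == 0) return(ids[0])
      sample(ids, n_d)
    }), use.names = FALSE)
  })
  new_audit_plan("stratified_srs", sel, length(sel), seed, quarter)
}

#' Mixed prior-offender sampling
#'
#' Half of the audit sample is drawn at random from facilities that
#' over-reported in the immediately preceding quarter, the other half from
#' the remaining facilities. If there are fewer prior offenders than half
#' the target, all offenders are taken and the shortfall is reallocated to
#' the non-offender draw so the plan keeps its fixed size.
#'
#' @param population facility ids.
#' @param prior_offenders facility ids flagged in the prior quarter (subset
#'   of `population`).
#' @param target_size total audit sample size (the reference design audits
#'   20% of facilities, e.g. 28 of 140).
#' @inheritParams plan_srs
#' @return an `audit_plan`.
#' @export
plan_offender_mixed <- function(population, prior_offenders, target_size, seed,
                                quarter = NA_integer_) {
  check_offender_args(population, prior_offenders, target_size)
  others <- setdiff(population, prior_offenders)
  n_off <- min(ceiling(target_size / 2), length(prior_offenders))
  n_oth <- min(target_size - n_off, length(others))
  sel <- with_seed(seed, {
    c(if (n_off > 0) sample(prior_offenders, n_off) else prior_offenders[0],
      if (n_oth > 0) sample(others, n_oth) else others[0])
  })
  new_audit_plan("offender_mixed", sel, target_size, seed, quarter)
}

#' Offenders-first sampling
#'
#' Selects up to `target_size` facilities among prior offenders: if there
#' are more offenders than the target, a simple random subsample of
#' offenders; if fewer, all offenders plus a random fill from the remaining
#' facilities.
#'
#' @inheritParams plan_offender_mixed
#' @return an `audit_plan`.
#' @export
plan_offenders_first <- function(population, prior_offenders, target_size, seed,
                                 quarter = NA_integer_) {
  check_offender_args(population, prior_offenders, target_size)
  others <- setdiff(population, prior_offenders)
  sel <- with_seed(seed, {
    if (length(prior_offenders) >= target_size) {
      sample(prior_offenders, target_size)
    } else {
      n_fill <- min(target_size - length(prior_offenders), length(others))
      c(prior_offenders, if (n_fill > 0) sample(others, n_fill) else others[0])
    }
  })
  new_audit_plan("offenders_first", sel, target_size, seed, quarter)
}

check_offender_args <- function(population, prior_offenders, target_size) {
  if (!length(population)) stop_("population is empty")
  if (target_size > length(population))
    stop_("target_size exceeds the population size")
  extra <- setdiff(prior_offenders, population)
  if (length(extra))
    stop_("prior_offenders not in population: ", paste(head(extra, 5), collapse = ", "))
}

#' Classifier-ranked audit targeting
#'
#' Selects the `target_size` facilities with the highest predicted
#' over-reporting risk. Ties are broken deterministically: scores are
#' ordered after a seeded shuffle of the population, so equal-scored
#' facilities are picked reproducibly given the seed but without a fixed
#' bias toward low facility ids.
#'
#' @param population facility ids.
#' @param risk_scores numeric risk score per facility (same order as
#'   `population`, or a named vector keyed by facility id).
#' @inheritParams plan_srs
#' @param target_size number of facilities to audit.
#' @return an `audit_plan`.
#' @export
plan_model_ranked <- function(population, risk_scores, target_size, seed = 1L,
                              quarter = NA_integer_) {
  if (!length(population)) stop_("population is empty")
  if (!is.null(names(risk_scores))) risk_scores <- risk_scores[as.character(population)]
  if (length(risk_scores) != length(population))
    stop_("risk_scores must align with population")
  bad <- population[!is.finite(risk_scores)]
  if (length(bad))
    stop_("non-finite risk score for facilities: ", paste(head(bad, 5), collapse = ", "))
  if (target_size > length(population))
    stop_("target_size exceeds the population size")
  perm <- with_seed(seed, sample.int(length(population)))
  ord <- perm[order(risk_scores[perm], decreasing = TRUE)]
  sel <- population[ord[seq_len(target_size)]]
  new_audit_plan("model_ranked", sel, target_size, seed, quarter)
}

#' Write audit plans to CSV
#'
#' @param plans a single `audit_plan` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plans <- function(plans, path) {
  if (inherits(plans, "audit_plan")) plans <- list(plans)
  df <- do.call(rbind, lapply(plans, function(p) {
    data.frame(quarter = p$quarter, strategy_name = p$strategy,
               facility_id = p$selected, seed = p$seed)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
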