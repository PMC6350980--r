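# Shared fixtures, built in code.

default_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_panel(sim_config(seed = 42))
    cache
  }
})

default_labels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- label_panel(default_panel())
    cache
  }
})

# labels aligned to one quarter's panel rows
quarter_labels <- function(panel, labels, q) {
  pq <- panel[panel$quarter == q, ]
  labels$over_report[match(paste(pq$facility_id, q),
                           paste(labels$facility_id, labels$quarter))]
}

# facility-level label: flagged in at least one quarter, aligned to the
# facility order of one quarter's rows
ever_flagged <- function(panel, labels, q = 1) {
  pq <- panel[panel$quarter == q, ]
  per_fac <- tapply(labels$over_report, labels$facility_id, max)
  as.integer(per_fac[as.character(pq$facility_id)])
}

# a uniform toy schedule for arithmetic-oriented tests
unit_schedule <- function() price_schedule(setNames(rep(1, 9), paste0("ind", 1:9)))
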