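#' @importFrom stats rnbinom rlnorm rbinom rpois runif rnorm predict
#'   uniroot aggregate density dnorm glm binomial coef plogis quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

# Deterministic substream derivation: keeps all child seeds in 32-bit range.
derive_seed <- function(master, i) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(i)) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# round() uses banker's rounding; sample-size arithmetic wants half-up.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

# md5 of a serialized R object, via base R only
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
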