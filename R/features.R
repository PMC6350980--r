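#' Build a model feature matrix from a panel
#'
#' Encodes one quarter's facility observations as a numeric matrix with
#' one-hot encoded categoricals. The `basic` set is the reference
#' configuration: the 9 reported and 9 verified counts plus district and
#' audit-arm indicators. The `expanded` set adds 6 facility covariates
#' (facility type, managing authority, location, catchment population,
#' established and filled posts). `covariates` uses only facility
#' covariates (no counts), and `reported_only` drops the verified counts,
#' which are only observed for audited facilities in deployment.
#'
#' The latent `gaming_flag` is never included.
#'
#' @param panel panel rows (typically one quarter).
#' @param feature_set one of `"basic"`, `"expanded"`, `"covariates"`,
#'   `"reported_only"`.
#' @param levels optional list of factor level sets (as produced on a
#'   training panel); supply it when encoding new data so the columns match
#'   the training schema.
#' @return numeric matrix with a `schema` attribute (feature set + column
#'   names + level sets).
#' @export
build_features <- function(panel,
                           feature_set = c("basic", "expanded", "covariates",
                                           "reported_only"),
                           levels = NULL) {
  feature_set <- match.arg(feature_set)
  lv <- levels %||% list(
    district = sort(unique(panel$district_id)),
    audit_arm = sort(unique(panel$audit_arm)),
    facility_type = sort(unique(panel$facility_type)),
    managing_authority = sort(unique(panel$managing_authority)),
    location = sort(unique(panel$location)))

  blocks <- list()
  if (feature_set %in% c("basic", "expanded", "reported_only"))
    blocks$rep <- as.matrix(panel[, paste0("rep_", 1:9)])
  if (feature_set %in% c("basic", "expanded"))
    blocks$ver <- as.matrix(panel[, paste0("ver_", 1:9)])
  blocks$district <- one_hot(panel$district_id, lv$district, "district")
  blocks$arm <- one_hot(panel$audit_arm, lv$audit_arm, "arm")
  if (feature_set %in% c("expanded", "covariates")) {
    blocks$ftype <- one_hot(panel$facility_type, lv$facility_type, "ftype")
    blocks$auth <- one_hot(panel$managing_authority, lv$managing_authority, "auth")
    blocks$loc <- one_hot(panel$location, lv$location, "loc")
    blocks$size <- cbind(catchment_population = panel$catchment_population,
                         established_posts = panel$established_posts,
                         filled_posts = panel$filled_posts)
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- panel$facility_id
  if (anyNA(X)) stop_("feature matrix contains missing values after encoding")
  attr(X, "schema") <- list(feature_set = feature_set,
                            columns = colnames(X), levels = lv)
  X
}

one_hot <- function(x, levels, prefix) {
  f <- factor(x, levels = levels)
  if (anyNA(f))
    stop_("values outside the training levels for ", prefix, ": ",
          paste(unique(x[is.na(f)]), collapse = ", "))
  m <- matrix(0, length(x), length(levels),
              dimnames = list(NULL, paste0(prefix, "_", levels)))
  m[cbind(seq_along(x), as.integer(f))] <- 1
  m
}

check_schema <- function(model_schema, X) {
  new_schema <- attr(X, "schema")
  cols <- if (!is.null(new_schema)) new_schema$columns else colnames(X)
  miss <- setdiff(model_schema$columns, cols)
  extra <- setdiff(cols, model_schema$columns)
  if (length(miss) || length(extra))
    stop_("feature schema mismatch; missing: [",
          paste(miss, collapse = ", "), "] unexpected: [",
          paste(extra, collapse = ", "), "]")
  X[, model_schema$columns, drop = FALSE]
}
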