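#' @importFrom stats rexp runif rbinom plogis pchisq pnorm qnorm sd glm
#'   binomial poisson glm.control as.formula setNames
#' @importFrom utils read.csv write.csv head tail
#' @importFrom grDevices adjustcolor
#' @importFrom tools md5sum
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG stream: the global .Random.seed is saved and
# restored, so callers see no RNG side effects.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Days per month used for axis labelling
#'
#' Calendar months on figure axes are converted at 365/12 days per month.
#'
#' @return A single number, 365/12.
#' @export
days_per_month <- function() 365 / 12

assert_records <- function(records, require_two_arms = FALSE) {
  if (!is.data.frame(records) || nrow(records) < 1L) {
    stop("`records` must be a data.frame with at least one row", call. = FALSE)
  }
  needed <- c("time", "event", "arm")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("`records` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$time <= 0)) stop("follow-up times must be > 0", call. = FALSE)
  if (!all(records$event %in% c(0, 1))) {
    stop("`event` must be 0 (censored) or 1 (progression)", call. = FALSE)
  }
  if (!all(records$arm %in% c(0, 1))) {
    stop("`arm` must be 0 (control) or 1 (treated)", call. = FALSE)
  }
  if (require_two_arms && length(unique(records$arm)) < 2L) {
    stop("both arms (0 and 1) must be present", call. = FALSE)
  }
  invisible(records)
}
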