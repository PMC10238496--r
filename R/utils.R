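#' @importFrom stats rnorm runif rbinom rexp rpois quantile sd t.test filter
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib sccscore, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## the package calls data.table via :: only; declare NSE awareness
.datatable.aware <- TRUE

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' that seeded internals never clobber the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## derive a distinct child seed from a base seed; kept below 2^31 - 1
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7907 * k) %% 2147483629)
}

hour_floor <- function(t) (t %/% 3600) * 3600
day_floor  <- function(t) (t %/% 86400) * 86400

fmt_ts <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

parse_ts <- function(s) {
  if (is.numeric(s)) return(as.double(s))
  as.double(as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

## round-half-down to an integer (0.5 goes down); used for split sizing
round_half_down <- function(x) ceiling(x - 0.5)
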