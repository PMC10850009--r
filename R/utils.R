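# shared helpers: error classes, time axis, numeric guards

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "certifyr_format_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "certifyr_validation_error")
}

stop_integrity <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "certifyr_integrity_error")
}

#' Elapsed months on the calendar axis
#'
#' All regressions in the stability and monitoring modules operate on elapsed
#' months computed as `(date - origin) / 365.25 * 12`, so that a measurement
#' taken 14 days after the origin sits at approximately 0.46 months and a
#' measurement one calendar year later at 12.0 months.
#'
#' @param date a `Date` vector.
#' @param origin single `Date`; defaults to `min(date)`.
#' @return numeric vector of elapsed months.
#' @export
#' @examples
#' months_elapsed(as.Date(c("2022-01-01", "2022-01-15", "2022-02-01")))
months_elapsed <- function(date, origin = min(date)) {
  stopifnot(inherits(date, "Date"), inherits(origin, "Date"))
  as.numeric(date - origin) / 365.25 * 12
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_validation("%s contains non-finite values", what)
  }
  invisible(x)
}

# parse ISO dates strictly, with row-indexed error
parse_iso_date <- function(x, context = "date") {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) > 0) {
    stop_format("unparseable %s value '%s' in row %d (expected YYYY-MM-DD)",
                context, as.character(x)[bad[1]], bad[1])
  }
  if (anyNA(d)) stop_format("missing %s value in row %d", context, which(is.na(d))[1])
  d
}
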