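#' Censored laboratory measurement
#'
#' Clinical laboratory panels routinely report values against assay detection
#' limits, e.g. a plasma renin activity of "<0.1" ng/ml/hr or an
#' aldosterone:renin ratio of ">200".  A `censored_measure` carries the
#' reported bound together with the side of the censoring so that downstream
#' arithmetic (notably the aldosterone:renin ratio) can propagate the
#' uncertainty as an interval instead of silently treating the bound as an
#' exact value.
#'
#' @param value Non-negative numeric bound (or exact value) in `units`.
#' @param relation One of `"equal"`, `"below"` (true value in `[0, value)`)
#'   or `"above"` (true value in `(value, Inf)`).
#' @param units Unit string, kept for printing only.
#'
#' @return An object of class `censored_measure` with fields `value`,
#'   `relation` and `units`.
#' @examples
#' censored_measure(66, units = "ng/dl")
#' censored_measure(0.1, "below", "ng/ml/hr")
#' parse_censored("<0.1")
#' @export
censored_measure <- function(value, relation = c("equal", "below", "above"),
                             units = "") {
  relation <- match.arg(relation)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value < 0)
    stop("concentrations must be non-negative")
  structure(list(value = as.numeric(value), relation = relation,
                 units = as.character(units)),
            class = "censored_measure")
}

#' Parse a possibly censored laboratory value
#'
#' Accepts plain numbers and strings optionally prefixed with `<` or `>`
#' (the notation used in clinical tables), returning a [censored_measure()].
#' `NA`, the empty string and `"NA"` return `NULL` (measurement absent).
#'
#' @param x A number or a string such as `"37"`, `"<0.1"` or `">200"`.
#' @param units Unit string attached to the result.
#' @return A `censored_measure`, or `NULL` when `x` is missing.
#' @export
parse_censored <- function(x, units = "") {
  if (is.null(x) || length(x) == 0L) return(NULL)
  if (is.numeric(x)) {
    if (is.na(x)) return(NULL)
    return(censored_measure(x, "equal", units))
  }
  x <- trimws(as.character(x))
  if (is.na(x) || x == "" || toupper(x) == "NA") return(NULL)
  rel <- "equal"
  if (startsWith(x, "<")) {
    rel <- "below"; x <- substring(x, 2L)
  } else if (startsWith(x, ">")) {
    rel <- "above"; x <- substring(x, 2L)
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("cannot parse laboratory value: ", x)
  censored_measure(v, rel, units)
}

#' @export
format.censored_measure <- function(x, ...) {
  prefix <- switch(x$relation, equal = "", below = "<", above = ">")
  out <- paste0(prefix, format(x$value, ...))
  if (nzchar(x$units)) out <- paste(out, x$units)
  out
}

#' @export
print.censored_measure <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Interval spanned by a censored measurement
#'
#' @param x A `censored_measure`.
#' @return Numeric `c(lower, upper)`; `below` maps to `[0, value)`, `above`
#'   to `(value, Inf)`, `equal` to the degenerate point interval.
#' @keywords internal
censored_interval <- function(x) {
  switch(x$relation,
         equal = c(x$value, x$value),
         below = c(0, x$value),
         above = c(x$value, Inf))
}

is_censored <- function(x) inherits(x, "censored_measure")

#' Compare a censored measurement against a strict threshold
#'
#' Conservative semantics used by the screening rules: the comparison is
#' `TRUE` only when every value consistent with the censoring satisfies it.
#' A ">bound" measurement exceeds a strict threshold only when the bound
#' itself is at or above the threshold; a "<bound" measurement is below a
#' threshold only when the bound is at or below it.
#'
#' @param x A `censored_measure` (or `NULL`, which yields `NA`).
#' @param threshold Numeric threshold.
#' @return Logical, possibly `NA` when the censoring leaves the comparison
#'   undecided.
#' @export
censored_gt <- function(x, threshold) {
  if (is.null(x)) return(NA)
  stopifnot(is_censored(x))
  switch(x$relation,
         equal = x$value > threshold,
         above = if (x$value >= threshold) TRUE else NA,
         below = if (x$value <= threshold) FALSE else NA)
}

#' @rdname censored_gt
#' @export
censored_lt <- function(x, threshold) {
  if (is.null(x)) return(NA)
  stopifnot(is_censored(x))
  switch(x$relation,
         equal = x$value < threshold,
         below = if (x$value <= threshold) TRUE else NA,
         above = if (x$value >= threshold) FALSE else NA)
}
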