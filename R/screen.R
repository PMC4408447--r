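#' Aldosterone:renin ratio with censored-value propagation
#'
#' Computes the screening ratio for primary aldosteronism from a serum
#' aldosterone and a renin measurement, propagating assay censoring by
#' interval arithmetic:
#' an exact aldosterone divided by a below-detection renin (`<b`) yields a
#' lower bound on the ratio (`> aldo/b`); a below-detection aldosterone over
#' exact renin yields an upper bound; exact over exact is exact.  When both
#' operands are censored the resulting interval can still be one-sided (e.g.
#' `<a` over `>r` is `< a/r`), but opposite censoring that leaves both ends
#' free returns the uninformative interval flagged indeterminate.
#'
#' Reported ratios are conventionally rounded to one decimal; rounding is
#' applied to the returned value only, never before threshold comparisons
#' made by [classify_pa()].
#'
#' @param aldosterone A [censored_measure()] (or value parseable by
#'   [parse_censored()]) in ng/dl.
#' @param renin Renin measurement: plasma renin activity in ng/ml/hr or
#'   direct renin concentration in uIU/ml.
#' @param renin_kind `"pra"` or `"direct"`; recorded in the units of the
#'   result.
#' @param digits Decimal places used for the reported value (default 1).
#' @return A `censored_measure` holding the (possibly bounded) ratio, with
#'   attributes `interval` (the unrounded interval) and `indeterminate`.
#' @examples
#' compute_arr(66, 0.2)              # 330
#' compute_arr(37, 0.42)             # 88.1
#' compute_arr(20, "<0.1")           # >200
#' @export
compute_arr <- function(aldosterone, renin, renin_kind = c("pra", "direct"),
                        digits = 1) {
  renin_kind <- match.arg(renin_kind)
  a <- if (is_censored(aldosterone)) aldosterone else
    parse_censored(aldosterone, "ng/dl")
  r <- if (is_censored(renin)) renin else
    parse_censored(renin, if (renin_kind == "pra") "ng/ml/hr" else "uIU/ml")
  if (is.null(a) || is.null(r)) stop("both operands are required")
  if (r$relation == "equal" && r$value == 0)
    stop("undefined ratio: renin is exactly zero")
  ai <- censored_interval(a)
  ri <- censored_interval(r)
  # ratio interval: numerator and denominator are non-negative
  lo <- if (is.infinite(ri[2])) 0 else ai[1] / ri[2]
  hi <- if (ri[1] == 0) Inf else ai[2] / ri[1]
  units <- paste0("ng/dl per ", r$units)
  indet <- lo == 0 && is.infinite(hi)
  out <- if (lo == hi) {
    censored_measure(round(lo, digits), "equal", units)
  } else if (is.infinite(hi)) {
    censored_measure(round(lo, digits), "above", units)
  } else if (lo == 0) {
    censored_measure(round(hi, digits), "below", units)
  } else {
    # doubly censored but bounded on both sides: report the midpoint bound
    # conservatively as indeterminate
    indet <- TRUE
    censored_measure(round(hi, digits), "below", units)
  }
  attr(out, "interval") <- c(lo, hi)
  attr(out, "indeterminate") <- indet
  out
}

#' Laboratory panel for primary aldosteronism screening
#'
#' @param aldosterone Serum aldosterone (ng/dl); required.
#' @param pra Plasma renin activity (ng/ml/hr); optional.
#' @param direct_renin Direct renin concentration (uIU/ml); optional.
#' @param potassium Serum potassium (mmol/l); optional.
#' @param subject Optional subject identifier.
#'
#' Each measurement may be numeric or a censored string such as `"<0.1"`.
#' At least one of `pra` / `direct_renin` must be present for
#' classification.
#' @return A list of class `lab_panel`.
#' @export
lab_panel <- function(aldosterone, pra = NULL, direct_renin = NULL,
                      potassium = NULL, subject = NA_character_) {
  p <- structure(list(
    subject = subject,
    aldosterone = parse_censored(aldosterone, "ng/dl"),
    pra = parse_censored(pra, "ng/ml/hr"),
    direct_renin = parse_censored(direct_renin, "uIU/ml"),
    potassium = parse_censored(potassium, "mmol/l")),
    class = "lab_panel")
  if (is.null(p$aldosterone)) stop("aldosterone measurement is required")
  p
}

#' Classify a laboratory panel for primary aldosteronism
#'
#' Applies the screening rules: indicative of PA when the
#' aldosterone:PRA ratio exceeds 20 (ng/dl per ng/ml/hr) with aldosterone
#' above 15 ng/dl, or the aldosterone:direct-renin ratio exceeds 2.4 with
#' aldosterone above 15 ng/dl, or the ratio is only marginally elevated
#' (above 20 with aldosterone at or below 15) in the presence of unexplained
#' hypokalemia (K+ below 3.5 mmol/l).  Censored values are evaluated
#' conservatively: a censored comparison counts as satisfied only when every
#' value consistent with the censoring satisfies it (see [censored_gt()]).
#'
#' @param panel A [lab_panel()].
#' @return A list of class `pa_classification` with the computed ratio
#'   (`arr`), the renin measure used, `indicative` (logical) and
#'   `rule_fired` (text; `"none"` when not indicative).
#' @examples
#' classify_pa(lab_panel(37, pra = 0.42, potassium = 3.7))   # indicative
#' classify_pa(lab_panel(3, pra = 1.67))                     # not indicative
#' classify_pa(lab_panel(22, direct_renin = 22 / 37.3))      # indicative
#' @export
classify_pa <- function(panel) {
  stopifnot(inherits(panel, "lab_panel"))
  if (is.null(panel$pra) && is.null(panel$direct_renin))
    stop("classification requires PRA or direct renin")
  aldo <- panel$aldosterone
  aldo_high <- isTRUE(censored_gt(aldo, 15))
  hypokalemia <- isTRUE(censored_lt(panel$potassium, 3.5))

  arr <- NULL
  rule <- "none"
  indicative <- FALSE
  if (!is.null(panel$pra)) {
    arr <- compute_arr(aldo, panel$pra, "pra")
    arr_high <- isTRUE(censored_gt(arr, 20))
    if (arr_high && aldo_high) {
      indicative <- TRUE
      rule <- "ARR > 20 with aldosterone > 15 ng/dl"
    } else if (arr_high && !aldo_high && hypokalemia) {
      indicative <- TRUE
      rule <- "marginal ARR elevation with unexplained hypokalemia"
    }
  }
  if (!indicative && !is.null(panel$direct_renin)) {
    adr <- compute_arr(aldo, panel$direct_renin, "direct")
    if (is.null(arr)) arr <- adr
    if (isTRUE(censored_gt(adr, 2.4)) && aldo_high) {
      indicative <- TRUE
      rule <- "aldosterone/direct renin > 2.4 with aldosterone > 15 ng/dl"
      arr <- adr
    }
  }
  structure(list(subject = panel$subject, arr = arr,
                 indicative = indicative, rule_fired = rule),
            class = "pa_classification")
}

#' @export
print.pa_classification <- function(x, ...) {
  cat(if (is.na(x$subject)) "Panel" else x$subject, ": ",
      if (x$indicative) "indicative of PA" else "not indicative",
      if (x$rule_fired != "none") paste0(" (", x$rule_fired, ")") else "",
      "; ratio ", format(x$arr), "\n", sep = "")
  invisible(x)
}

#' Read laboratory panels from CSV
#'
#' Expects columns `aldo`, and any of `pra`, `direct_renin`, `k`, plus an
#' optional `subject` column; cells may be prefixed `<` or `>` for censored
#' values.
#'
#' @param path CSV file path.
#' @return A list of [lab_panel()] objects, one per row.
#' @export
read_lab_panels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  if (!"aldo" %in% names(df)) stop("CSV must contain an 'aldo' column")
  get <- function(row, col) if (col %in% names(df)) df[[col]][row] else NULL
  lapply(seq_len(nrow(df)), function(i) {
    lab_panel(df$aldo[i],
              pra = get(i, "pra"),
              direct_renin = get(i, "direct_renin"),
              potassium = get(i, "k"),
              subject = if ("subject" %in% names(df))
                df$subject[i] else NA_character_)
  })
}
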