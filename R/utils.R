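#' @keywords internal
"_PACKAGE"

# Continuous-script code-point ranges. Thai block plus the Unicode
# private-use area used by the synthetic language. Each row: c(lo, hi).
.continuous_ranges <- function() {
  list(thai = c(0x0E01L, 0x0E5BL), pua = c(0xE000L, 0xF8FFL))
}

.is_continuous_cp <- function(cp) {
  out <- rep(FALSE, length(cp))
  for (r in .continuous_ranges()) out <- out | (cp >= r[1] & cp <= r[2])
  out
}

#' Round half away from zero
#'
#' Printed clinical tables round 0.005 up, unlike [round()]'s round-half-even
#' rule. Used for every reported percentage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# percentage of part over whole, half-up rounded
.pct <- function(part, whole, digits = 2) {
  if (whole == 0) return(NA_real_)
  round_half_up(100 * part / whole, digits)
}

# median and IQR (type-7 linear-interpolation quantiles) as a named vector
.med_iqr <- function(x) {
  if (length(x) == 0) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

# Escape / unescape tabs and newlines so free text survives a one-record-per-
# line tab-separated file.
.escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

.unescape_field <- function(x) {
  # split on the escaped backslash first so \t/\n/\r escapes are unambiguous
  vapply(x, function(s) {
    parts <- strsplit(paste0(s, "\x01"), "\\\\", fixed = TRUE)[[1]]
    parts <- gsub("\\t", "\t", parts, fixed = TRUE)
    parts <- gsub("\\r", "\r", parts, fixed = TRUE)
    parts <- gsub("\\n", "\n", parts, fixed = TRUE)
    sub("\x01$", "", paste0(parts, collapse = "\\"))
  }, character(1), USE.NAMES = FALSE)
}

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
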