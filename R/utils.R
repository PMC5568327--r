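#' Percentage of a count, one decimal
#'
#' Shared formatting rule for all reported shares (group abstinence rates,
#' the share of nodes inside the largest strongly connected component, ...):
#' `100 * num / den` rounded to one decimal place.
#'
#' @param num numerator count.
#' @param den denominator count; `den == 0` yields `NA_real_`.
#' @return numeric vector of percentages rounded to one decimal.
#' @examples
#' pct(105, 1362) # 7.7
#' @export
pct <- function(num, den) {
  out <- ifelse(den == 0, NA_real_, 100 * num / den)
  round(out, 1)
}

# stop() with a consistent error class so pipeline stages can report causes
cn_stop <- function(..., class = "cessnet_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

# Internal: site reference time zone. All timestamps are UTC.
CN_TZ <- "UTC"
CN_ORIGIN <- as.POSIXct("2012-03-01 00:00:00", tz = "UTC")

# days (numeric, possibly fractional) -> POSIXct at second resolution
days_to_time <- function(d) {
  CN_ORIGIN + round(d * 86400)
}

as_time <- function(x) as.POSIXct(x, tz = CN_TZ)
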