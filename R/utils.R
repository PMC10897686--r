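#' @keywords internal
"_PACKAGE"

# Internal date helpers. All interval arithmetic is in integer days and
# intervals are half-open [start, end): a 30-day script issued on day d
# covers days d .. d+29.

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date_strict <- function(x) {
  # Parse ISO dates; anything unparseable becomes NA (no partial matching).
  out <- as.Date(rep(NA_character_, length(x)))
  chr <- as.character(x)
  ok <- !is.na(chr) & grepl("^\\d{4}-\\d{2}-\\d{2}$", chr)
  if (any(ok)) {
    parsed <- as.Date(chr[ok], format = "%Y-%m-%d", optional = TRUE)
    # as.Date accepts impossible dates like 2020-13-40 as NA already with
    # optional = TRUE; re-format to reject things like 2020-02-30.
    rt <- format(parsed, "%Y-%m-%d")
    parsed[is.na(rt) | rt != chr[ok]] <- NA
    out[ok] <- parsed
  }
  out
}

days_between <- function(from, to) as.integer(to - from)

#' Add whole years to a date
#'
#' Used for age computation; Feb 29 anniversaries roll forward to Mar 1 in
#' non-leap years, so a person born on Feb 29 turns 18 on Mar 1.
#' @noRd
add_years <- function(date, n) {
  y <- as.integer(format(date, "%Y")) + n
  md <- format(date, "-%m-%d")
  out <- as.Date(paste0(y, md), optional = TRUE)
  bad <- is.na(out) & !is.na(date)
  if (any(bad)) out[bad] <- as.Date(paste0(y[bad], "-03-01"))
  out
}

age_at <- function(dob, date) {
  # completed years at `date`
  approx <- as.integer(format(date, "%Y")) - as.integer(format(dob, "%Y"))
  had_birthday <- add_years(dob, approx) <= date
  approx - ifelse(had_birthday, 0L, 1L)
}

regimen_key <- function(ingredients) {
  paste(sort(unique(ingredients)), collapse = "+")
}

split_regimen <- function(key) strsplit(key, "+", fixed = TRUE)[[1]]

n_distinct_doses <- function(x) {
  # missing dose is its own level: NA == NA, NA != any number
  length(unique(x))
}

empty_df <- function(proto) proto[0L, , drop = FALSE]
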