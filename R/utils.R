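#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils head
NULL

# Calendar-anniversary lookback: the window [as_of - k years, as_of], both
# ends inclusive. Rolls back to the last day of the month when the
# anniversary does not exist (Feb 29).
window_start <- function(as_of_date, years) {
  lubridate::add_with_rollback(as_of_date, -lubridate::years(years))
}

in_window <- function(dates, as_of_date, years) {
  dates >= window_start(as_of_date, years) & dates <= as_of_date
}

as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & as.character(x) != "")
  if (length(bad) > 0) {
    abort(sprintf("unparseable %s at row(s) %s: %s", what,
                  paste(head(bad, 5), collapse = ", "),
                  paste(head(as.character(x)[bad], 5), collapse = ", ")))
  }
  out
}

`%notin%` <- function(x, table) !(x %in% table)
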