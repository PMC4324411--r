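#' Dosing regimen
#'
#' An ordered sequence of instantaneous oral dose events. Doses are treated
#' as bolus additions to the drug-amount compartment (the PK model has no
#' explicit absorption phase).
#'
#' @param times Event times in hours since the first dose (>= 0, strictly
#'   increasing after sorting).
#' @param amounts Dose amounts in mg (>= 0), one per event.
#' @param interval Nominal dosing interval in hours (default 24).
#' @return An object of class `regimen`: a list with `events` (data.frame
#'   `time`, `amount`) and `dosing_interval`.
#' @export
regimen <- function(times, amounts, interval = 24) {
  if (length(times) != length(amounts))
    stop_arg("`times` and `amounts` must have equal length")
  if (length(times) == 0) stop_arg("a regimen needs at least one dose event")
  if (any(amounts < 0)) stop_arg("dose amounts must be non-negative")
  if (any(times < 0)) stop_arg("dose times must be non-negative")
  o <- order(times)
  times <- times[o]; amounts <- amounts[o]
  if (any(diff(times) <= 0)) stop_arg("dose event times must be distinct")
  if (!is_scalar_num(interval) || interval <= 0)
    stop_arg("`interval` must be positive hours")
  structure(list(events = data.frame(time = times, amount = amounts),
                 dosing_interval = interval),
            class = "regimen")
}

#' Build a regimen from a maintenance dose and optional loading doses
#'
#' The first `length(loading_doses)` events take the loading amounts in
#' order; the remaining events all take the maintenance dose (e.g. loading
#' doses 7.5/5/5 mg with 15 total doses gives 12 maintenance doses). Events
#' are placed at 0, `interval`, 2*`interval`, ...
#'
#' @param maintenance_dose Maintenance dose in mg (>= 0).
#' @param n_doses Total number of doses (>= number of loading doses).
#' @param loading_doses Optional ordered vector of initial doses in mg.
#' @param interval Dosing interval in hours (default 24).
#' @return A [regimen()].
#' @export
#' @examples
#' build_regimen(1.5, n_doses = 15, loading_doses = c(7.5, 5, 5))
build_regimen <- function(maintenance_dose, n_doses, loading_doses = NULL,
                          interval = 24) {
  if (!is_scalar_num(maintenance_dose) || maintenance_dose < 0)
    stop_arg("`maintenance_dose` must be non-negative mg")
  n_doses <- as.integer(n_doses)
  k <- length(loading_doses)
  if (n_doses < k)
    stop_arg("`n_doses` (", n_doses, ") is smaller than the number of loading doses (", k, ")")
  if (n_doses < 1L) stop_arg("`n_doses` must be at least 1")
  amounts <- c(loading_doses, rep(maintenance_dose, n_doses - k))
  regimen(times = (seq_len(n_doses) - 1) * interval, amounts = amounts,
          interval = interval)
}

#' @export
print.regimen <- function(x, ...) {
  ev <- x$events
  cat(sprintf("Regimen: %d doses over %g h (interval %g h), total %g mg\n",
              nrow(ev), max(ev$time), x$dosing_interval, sum(ev$amount)))
  invisible(x)
}
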