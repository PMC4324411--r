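#' Patient treatment history
#'
#' Couples patient covariates with an observed dosing history and INR
#' observations, the input to a posteriori (Bayesian) parameter estimation.
#' INR observations recorded before the first dose are not used for fitting;
#' they are kept separately and inform the baseline INR when it is missing.
#'
#' @param covariates A [patient_covariates()] object.
#' @param doses data.frame with columns `time` (h) and `amount` (mg).
#' @param observations data.frame with columns `time` (h) and `value` (INR).
#' @return An object of class `patient_history`.
#' @export
patient_history <- function(covariates, doses, observations = NULL) {
  stopifnot(inherits(covariates, "patient_covariates"))
  doses <- as.data.frame(doses)
  if (!all(c("time", "amount") %in% names(doses)))
    stop_arg("`doses` needs columns time and amount")
  if (nrow(doses) == 0) stop_arg("history needs at least one dose")
  if (is.unsorted(doses$time)) stop_arg("dose times must be non-decreasing")
  if (any(doses$amount < 0)) stop_arg("dose amounts must be non-negative")
  if (is.null(observations))
    observations <- data.frame(time = numeric(0), value = numeric(0))
  observations <- as.data.frame(observations)
  if (nrow(observations) > 0) {
    if (!all(c("time", "value") %in% names(observations)))
      stop_arg("`observations` needs columns time and value")
    if (is.unsorted(observations$time))
      stop_arg("observation times must be non-decreasing")
    if (any(observations$value <= 0))
      stop_arg("INR observations must be positive")
  }
  first_dose <- min(doses$time)
  pre <- observations$time < first_dose
  baseline_obs <- observations[pre, , drop = FALSE]
  observations <- observations[!pre, , drop = FALSE]
  if (nrow(baseline_obs) > 0) {
    warning("INR observation(s) before the first dose retained for baseline only",
            call. = FALSE)
    if (is.na(covariates$baseline_inr))
      covariates$baseline_inr <- mean(baseline_obs$value)
  }
  structure(list(covariates = covariates, doses = doses,
                 observations = observations, baseline_obs = baseline_obs),
            class = "patient_history")
}

#' @export
print.patient_history <- function(x, ...) {
  cat(sprintf("Patient history: %d doses over %g h, %d INR observation(s)\n",
              nrow(x$doses), diff(range(x$doses$time)), nrow(x$observations)))
  invisible(x)
}

# end of the recorded history (h since first dose)
history_end <- function(history) {
  max(c(history$doses$time, history$observations$time))
}

parse_history_time <- function(x, line_no) {
  num <- suppressWarnings(as.numeric(x))
  if (!any(is.na(num))) return(list(hours = num, absolute = FALSE))
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"),
                   optional = TRUE)
  bad <- is.na(ts)
  if (any(bad))
    stop_arg("unparseable time on line ", paste(line_no[bad], collapse = ", "),
             ": ", paste(unique(x[bad]), collapse = ", "))
  list(hours = as.numeric(difftime(ts, min(ts), units = "hours")),
       absolute = TRUE)
}

#' Read a patient history file
#'
#' Reads the long-format CSV history schema: an optional covariate header
#' block of `# key: value` lines (keys `age`, `weight`, `cyp2c9`, `vkorc1`,
#' `ethnicity`, `baseline_inr`, `target` as `low:high`, `dosing_interval`),
#' followed by columns `type` (`dose` or `inr`), `time` and `value` (mg for
#' dose rows, INR for inr rows). Times are either hours since the first
#' record or ISO timestamps; timestamps are converted to hours internally.
#'
#' @param path CSV file path.
#' @param quiet Suppress the record-count log message.
#' @return A [patient_history()].
#' @export
read_history <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_arg("history file not found: ", path)
  lines <- readLines(path)
  hdr <- grepl("^\\s*#", lines)
  # covariate header block
  cov_args <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) cov_args[[m[2]]] <- m[3]
  }
  body <- lines[!hdr]
  if (length(body) < 2) stop_arg("history file has no data rows: ", path)
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("type", "time", "value")) {
    if (!col %in% names(df))
      stop_arg("history file is missing required column `", col, "`")
  }
  line_no <- which(!hdr)[-1]   # file line numbers of the data rows
  df$type <- tolower(trimws(df$type))
  bad_type <- !df$type %in% c("dose", "inr")
  if (any(bad_type))
    stop_arg("unknown record type on line ",
             paste(line_no[bad_type], collapse = ", "))
  tm <- parse_history_time(trimws(df$time), line_no)
  df$hours <- tm$hours
  df$value_num <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(df$value_num)))
    stop_arg("non-numeric value on line ",
             paste(line_no[is.na(df$value_num)], collapse = ", "))
  for (tp in c("dose", "inr")) {
    sel <- df$type == tp
    if (any(sel) && is.unsorted(df$hours[sel]))
      stop_arg(tp, " rows out of time order; see line(s) ",
               paste(line_no[sel][which(diff(df$hours[sel]) < 0) + 1L],
                     collapse = ", "))
  }
  doses <- df[df$type == "dose", ]
  obs <- df[df$type == "inr", ]
  if (nrow(doses) == 0) stop_arg("history contains no dose rows")
  # re-anchor times to the first dose
  t0 <- min(doses$hours)
  cov <- do.call(covariates_from_strings, cov_args)
  hist <- patient_history(
    covariates = cov,
    doses = data.frame(time = doses$hours - t0, amount = doses$value_num),
    observations = data.frame(time = obs$hours - t0, value = obs$value_num))
  if (!quiet)
    message(sprintf("read_history: %d dose and %d INR record(s) spanning %g h",
                    nrow(hist$doses), nrow(hist$observations),
                    history_end(hist)))
  hist
}

# build patient_covariates from the string key/value header block
covariates_from_strings <- function(age = NA, weight = NA, cyp2c9 = NA,
                                    vkorc1 = NA, ethnicity = "unspecified",
                                    baseline_inr = NA, target = "2:3",
                                    dosing_interval = "24", ...) {
  extra <- names(list(...))
  if (length(extra) > 0)
    warning("ignoring unknown covariate key(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  if (is.na(age) || is.na(weight))
    stop_arg("history header must provide `age` and `weight`")
  tg <- as.numeric(strsplit(target, "[:\\-]")[[1]])
  if (length(tg) != 2 || any(is.na(tg)))
    stop_arg("`target` must look like 2:3")
  patient_covariates(age = as.numeric(age), weight = as.numeric(weight),
                     cyp2c9 = if (is.na(cyp2c9)) NA_character_ else cyp2c9,
                     vkorc1 = if (is.na(vkorc1)) NA_character_ else vkorc1,
                     ethnicity = ethnicity,
                     baseline_inr = as.numeric(baseline_inr),
                     target_low = tg[1], target_high = tg[2],
                     dosing_interval = as.numeric(dosing_interval))
}

#' Write a patient history file
#'
#' Inverse of [read_history()]: writes the covariate header block and the
#' long-format records with times normalized to hours since the first dose.
#'
#' @param history A [patient_history()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  cov <- history$covariates
  hdr <- c(
    sprintf("# age: %g", cov$age),
    sprintf("# weight: %g", cov$weight),
    if (!is.na(cov$cyp2c9)) sprintf("# cyp2c9: %s", cov$cyp2c9),
    if (!is.na(cov$vkorc1)) sprintf("# vkorc1: %s", cov$vkorc1),
    sprintf("# ethnicity: %s", cov$ethnicity),
    if (!is.na(cov$baseline_inr)) sprintf("# baseline_inr: %g", cov$baseline_inr),
    sprintf("# target: %g:%g", cov$target_low, cov$target_high),
    sprintf("# dosing_interval: %g", cov$dosing_interval))
  rows <- rbind(
    data.frame(type = "dose", time = history$doses$time,
               value = history$doses$amount),
    if (nrow(history$baseline_obs) > 0)
      data.frame(type = "inr", time = history$baseline_obs$time,
                 value = history$baseline_obs$value),
    data.frame(type = "inr", time = history$observations$time,
               value = history$observations$value))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
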