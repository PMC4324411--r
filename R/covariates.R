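CYP2C9_LEVELS <- c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3")
VKORC1_LEVELS <- c("G/G", "A/G", "A/A")
ETHNICITY_LEVELS <- c("Caucasian", "Asian", "African", "unspecified")

#' Patient covariates
#'
#' Bundles the demographics, genotypes and INR targets that drive the
#' typical-parameter computation: age, bodyweight, CYP2C9 genotype (affects
#' warfarin clearance), VKORC1 genotype (affects sensitivity, i.e. EDK50),
#' ethnicity (used only to impute a missing VKORC1 genotype), baseline INR
#' and the target INR range.
#'
#' Genotypes and baseline INR may be `NA`; [resolve_missing_covariates()]
#' fills them with the documented defaults.
#'
#' @param age Age in years (> 0).
#' @param weight Bodyweight in kg (> 0).
#' @param cyp2c9 CYP2C9 genotype, one of `"*1/*1"`, `"*1/*2"`, `"*1/*3"`,
#'   `"*2/*2"`, `"*2/*3"`, `"*3/*3"`, or `NA` if unknown.
#' @param vkorc1 VKORC1 genotype, one of `"G/G"`, `"A/G"`, `"A/A"`, or `NA`.
#' @param ethnicity One of `"Caucasian"`, `"Asian"`, `"African"`,
#'   `"unspecified"`.
#' @param baseline_inr Pre-treatment INR (>= 0.8), or `NA` if unknown.
#' @param target_low,target_high Target INR range bounds (low < high).
#' @param dosing_interval Dosing interval in hours; default 24 (once daily).
#' @return An object of class `patient_covariates`.
#' @export
#' @examples
#' patient_covariates(age = 60, weight = 70, cyp2c9 = "*1/*1",
#'                    vkorc1 = "A/G", baseline_inr = 1)
patient_covariates <- function(age, weight,
                               cyp2c9 = NA_character_,
                               vkorc1 = NA_character_,
                               ethnicity = "unspecified",
                               baseline_inr = NA_real_,
                               target_low = 2, target_high = 3,
                               dosing_interval = 24) {
  if (!is_scalar_num(age) || age <= 0) stop_arg("`age` must be a positive number of years")
  if (!is_scalar_num(weight) || weight <= 0) stop_arg("`weight` must be a positive number of kg")
  if (!is.na(cyp2c9) && !cyp2c9 %in% CYP2C9_LEVELS)
    stop_arg("unknown CYP2C9 genotype '", cyp2c9, "'")
  if (!is.na(vkorc1) && !vkorc1 %in% VKORC1_LEVELS)
    stop_arg("unknown VKORC1 genotype '", vkorc1, "'")
  ethnicity <- match.arg(ethnicity, ETHNICITY_LEVELS)
  if (!is.na(baseline_inr) && baseline_inr < 0.8)
    stop_arg("`baseline_inr` must be >= 0.8 when present")
  if (!is_scalar_num(target_low) || !is_scalar_num(target_high) ||
      target_low >= target_high)
    stop_arg("target range requires target_low < target_high")
  if (!is_scalar_num(dosing_interval) || dosing_interval <= 0)
    stop_arg("`dosing_interval` must be positive hours")
  structure(
    list(age = age, weight = weight,
         cyp2c9 = as.character(cyp2c9), vkorc1 = as.character(vkorc1),
         ethnicity = ethnicity, baseline_inr = as.numeric(baseline_inr),
         target_low = target_low, target_high = target_high,
         dosing_interval = dosing_interval),
    class = "patient_covariates")
}

#' Fill in missing covariates with their documented defaults
#'
#' Missing genotypes are replaced by the most common genotype conditioned on
#' ethnicity: CYP2C9 `*1/*1` (the genotype with the highest dose requirement)
#' regardless of ethnicity; VKORC1 `A/G` for Caucasians and unspecified
#' ethnicity (intermediate dose requirement), `A/A` for Asians (low dose
#' requirement) and `G/G` for Africans (high dose requirement). A missing
#' baseline INR defaults to 1. Values already present are never changed.
#'
#' @param cov A [patient_covariates()] object.
#' @return A `patient_covariates` object with no missing fields.
#' @export
resolve_missing_covariates <- function(cov) {
  stopifnot(inherits(cov, "patient_covariates"))
  if (is.na(cov$cyp2c9)) cov$cyp2c9 <- "*1/*1"
  if (is.na(cov$vkorc1)) {
    cov$vkorc1 <- switch(cov$ethnicity,
                         Caucasian = "A/G", unspecified = "A/G",
                         Asian = "A/A", African = "G/G")
  }
  if (is.na(cov$baseline_inr)) cov$baseline_inr <- 1
  cov
}

covariates_resolved <- function(cov) {
  !is.na(cov$cyp2c9) && !is.na(cov$vkorc1) && !is.na(cov$baseline_inr)
}

#' @export
print.patient_covariates <- function(x, ...) {
  cat("Patient covariates\n")
  cat(sprintf("  age: %g y   weight: %g kg   ethnicity: %s\n",
              x$age, x$weight, x$ethnicity))
  cat(sprintf("  CYP2C9: %s   VKORC1: %s\n",
              ifelse(is.na(x$cyp2c9), "(missing)", x$cyp2c9),
              ifelse(is.na(x$vkorc1), "(missing)", x$vkorc1)))
  cat(sprintf("  baseline INR: %s   target INR: %g-%g   interval: %g h\n",
              ifelse(is.na(x$baseline_inr), "(missing)",
                     format(x$baseline_inr)),
              x$target_low, x$target_high, x$dosing_interval))
  invisible(x)
}
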