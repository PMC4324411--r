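#' Population model parameters
#'
#' Holds the typical (population-mean) parameter values, covariate relations,
#' between-subject variances and residual variance of the warfarin KPD model.
#' Normally built by [read_config()] from a YAML configuration file rather
#' than called directly.
#'
#' The structural parameters are: typical clearance `tv_cl` (L/h) and volume
#' `tv_v` (L) at the reference covariates (giving k10 = CL/V); `edk50_by_vkorc1`,
#' the dose rate (mg/h) of half-maximal inhibition per VKORC1 genotype;
#' the sigmoidicity `gamma`; `emax` (fixed to 1); mean transit times `mtt1`
#' and `mtt2` (h) of the two parallel 3-compartment chains; and `inr_max`,
#' the theoretical maximal INR rise above baseline (fixed to 20).
#'
#' @param tv_cl,tv_v Typical clearance (L/h) and volume (L).
#' @param edk50_by_vkorc1 Named numeric vector/list mapping VKORC1 genotype
#'   (`"G/G"`, `"A/G"`, `"A/A"`) to EDK50 in mg/h.
#' @param gamma Hill coefficient of the inhibition curve (> 0).
#' @param emax Maximum degree of inhibition; 1 unless explicitly overridden.
#' @param mtt1,mtt2 Mean transit times (h) of chains 1 and 2.
#' @param n_transit Compartments per chain; 3 unless explicitly overridden.
#' @param inr_max Maximal INR increase from baseline; 20 unless overridden.
#' @param covariate_relations List with `reference_weight`,
#'   `cl_weight_exponent`, `v_weight_exponent`, `reference_age`,
#'   `cl_age_slope` (exponential age effect on CL per year) and `cl_cyp2c9`
#'   (named multipliers per genotype).
#' @param omega_k10,omega_edk50 Variances of the log-scale between-subject
#'   random effects on k10 and EDK50.
#' @param sigma_add Additive residual SD on the INR scale.
#' @param residual_model `"additive"` (default) or `"proportional"`.
#' @param provenance Free-text string identifying the parameter source.
#' @return An object of class `population_model`.
#' @export
population_model <- function(tv_cl, tv_v, edk50_by_vkorc1, gamma,
                             mtt1, mtt2,
                             omega_k10, omega_edk50, sigma_add,
                             emax = 1, n_transit = 3L, inr_max = 20,
                             covariate_relations = list(),
                             residual_model = c("additive", "proportional"),
                             provenance = "unspecified") {
  residual_model <- match.arg(residual_model)
  pos <- list(tv_cl = tv_cl, tv_v = tv_v, gamma = gamma, emax = emax,
              mtt1 = mtt1, mtt2 = mtt2, inr_max = inr_max,
              omega_k10 = omega_k10, omega_edk50 = omega_edk50,
              sigma_add = sigma_add)
  for (nm in names(pos)) {
    if (!is_scalar_num(pos[[nm]]) || pos[[nm]] <= 0)
      stop_arg("population parameter `", nm, "` must be a positive number")
  }
  edk50_by_vkorc1 <- unlist(edk50_by_vkorc1)
  if (!all(VKORC1_LEVELS %in% names(edk50_by_vkorc1)))
    stop_arg("`edk50_by_vkorc1` must name all of: ",
             paste(VKORC1_LEVELS, collapse = ", "))
  if (any(edk50_by_vkorc1 <= 0)) stop_arg("EDK50 values must be positive")
  n_transit <- as.integer(n_transit)
  if (n_transit < 1L) stop_arg("`n_transit` must be a positive integer")
  cr_defaults <- list(reference_weight = 70, cl_weight_exponent = 0,
                      v_weight_exponent = 0, reference_age = 40,
                      cl_age_slope = 0,
                      cl_cyp2c9 = setNames(rep(1, length(CYP2C9_LEVELS)),
                                           CYP2C9_LEVELS))
  cr <- modifyList(cr_defaults, covariate_relations)
  cr$cl_cyp2c9 <- unlist(cr$cl_cyp2c9)
  structure(
    list(tv_cl = tv_cl, tv_v = tv_v,
         edk50_by_vkorc1 = edk50_by_vkorc1[VKORC1_LEVELS],
         gamma = gamma, emax = emax, mtt1 = mtt1, mtt2 = mtt2,
         n_transit = n_transit, inr_max = inr_max,
         covariate_relations = cr,
         omega_k10 = omega_k10, omega_edk50 = omega_edk50,
         sigma_add = sigma_add, residual_model = residual_model,
         provenance = provenance),
    class = "population_model")
}

#' Read a population-parameter configuration file
#'
#' Loads a YAML configuration into a [population_model()]. The loader
#' validates completeness and positivity of every rate, volume and variance,
#' converts EDK50 entries declared in mg/day to the internal mg/h (logged),
#' and logs the config's provenance string.
#'
#' @param path Path to the YAML config.
#' @param quiet Suppress the provenance/conversion messages.
#' @return A `population_model`.
#' @seealso [demo_config()] for the bundled demonstration parameter set.
#' @export
read_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- function(block, key, where = path) {
    if (is.null(block[[key]]))
      stop_arg("config is missing required key `", key, "` (", where, ")")
    block[[key]]
  }
  popb <- need(cfg, "population")
  reb <- need(cfg, "random_effects")
  resb <- need(cfg, "residual")
  edk50 <- unlist(need(popb, "edk50_by_vkorc1"))
  unit <- tolower((cfg$units$edk50) %||% "mg/h")
  if (unit %in% c("mg/day", "mg/d", "mg/24h")) {
    edk50 <- edk50 / 24
    if (!quiet) message("read_config: EDK50 declared in ", unit,
                        "; converted to mg/h (factor 1/24)")
  } else if (!unit %in% c("mg/h", "mg/hour")) {
    stop_arg("unrecognized edk50 unit `", unit, "` (use mg/h or mg/day)")
  }
  prov <- cfg$provenance %||% "unspecified"
  if (!quiet) message("read_config: loaded population parameters [", prov, "]")
  pop <- population_model(
    tv_cl = need(popb, "tv_cl"), tv_v = need(popb, "tv_v"),
    edk50_by_vkorc1 = edk50,
    gamma = need(popb, "gamma"),
    emax = popb$emax %||% 1,
    mtt1 = need(popb, "mtt1"), mtt2 = need(popb, "mtt2"),
    n_transit = popb$n_transit %||% 3L,
    inr_max = popb$inr_max %||% 20,
    covariate_relations = cfg$covariate_relations %||% list(),
    omega_k10 = need(reb, "omega_k10"),
    omega_edk50 = need(reb, "omega_edk50"),
    sigma_add = need(resb, "sigma"),
    residual_model = resb$model %||% "additive",
    provenance = prov)
  pop
}

#' Path to, or loaded copy of, the bundled demo parameter set
#'
#' The demo configuration is physiologically plausible but **not clinically
#' valid**; it exists so that every function in the package can be exercised
#' without transcribing published population parameters.
#'
#' @param load If `TRUE` (default) return the loaded `population_model`,
#'   otherwise the file path.
#' @return A `population_model` or a file path.
#' @export
demo_config <- function(load = TRUE) {
  path <- system.file("extdata", "demo_population.yaml", package = "warfinr",
                      mustWork = TRUE)
  if (load) read_config(path, quiet = TRUE) else path
}

#' @export
print.population_model <- function(x, ...) {
  cat("Warfarin KPD population model [", x$provenance, "]\n", sep = "")
  cat(sprintf("  CL %g L/h, V %g L (typical k10 = %.4g /h)\n",
              x$tv_cl, x$tv_v, x$tv_cl / x$tv_v))
  cat(sprintf("  EDK50 (mg/h): G/G %g, A/G %g, A/A %g;  gamma %g, Emax %g\n",
              x$edk50_by_vkorc1[["G/G"]], x$edk50_by_vkorc1[["A/G"]],
              x$edk50_by_vkorc1[["A/A"]], x$gamma, x$emax))
  cat(sprintf("  transit chains: %d compartments, MTT %g / %g h;  INRmax %g\n",
              x$n_transit, x$mtt1, x$mtt2, x$inr_max))
  cat(sprintf("  omega^2(k10) %g, omega^2(EDK50) %g, residual %s SD %g\n",
              x$omega_k10, x$omega_edk50, x$residual_model, x$sigma_add))
  invisible(x)
}
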