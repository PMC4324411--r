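# shared fixtures: the demo population model and a reference adult patient

demo_pop <- demo_config()

adult_cov <- function(...) {
  args <- modifyList(
    list(age = 60, weight = 70, cyp2c9 = "*1/*1", vkorc1 = "A/G",
         ethnicity = "Caucasian", baseline_inr = 1,
         target_low = 2, target_high = 3),
    list(...))
  do.call(patient_covariates, args)
}

adult_indiv <- function(pop = demo_pop, cov = adult_cov()) {
  typical_parameters(resolve_missing_covariates(cov), pop)
}

# write a small history fixture file and return its path
write_history_fixture <- function(path = tempfile(fileext = ".csv"),
                                  n_doses = 7, dose = 5,
                                  inr = data.frame(time = c(64, 112, 160),
                                                   value = c(1.6, 2.1, 2.4))) {
  lines <- c("# age: 60", "# weight: 70", "# cyp2c9: *1/*1",
             "# vkorc1: A/G", "# ethnicity: Caucasian",
             "# baseline_inr: 1", "# target: 2:3",
             "type,time,value",
             sprintf("dose,%g,%g", (seq_len(n_doses) - 1) * 24, dose),
             sprintf("inr,%g,%g", inr$time, inr$value))
  writeLines(lines, path)
  path
}
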