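# Shared fixtures: all built in code at test time.

# A clinical table of healthy subjects; override any column per subject.
make_clinical <- function(n = 1, ...) {
  out <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    age = rep(60, n), gender = rep("female", n),
    sbp = rep(120, n), dbp = rep(75, n),
    glycemia = rep(0.9, n), cholesterol = rep(2.0, n), bmi = rep(23, n),
    gds = rep(2, n), high_education = rep(TRUE, n),
    active_smoker = rep(FALSE, n),
    self_reported_diabetes = rep(FALSE, n),
    antidiabetic_drug = rep(FALSE, n),
    self_reported_hypertension = rep(FALSE, n),
    antihypertensive_drug = rep(FALSE, n),
    self_reported_hypercholesterolemia = rep(FALSE, n),
    lipid_lowering_drug = rep(FALSE, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

battery_columns <- c(
  "mmse", "mattis", "corsi_direct", "corsi_inverse", "digit_direct",
  "digit_inverse", "grober_buschke_total_recall", "dms_immediate",
  "rey_immediate", "rey_3min", "stroop_interference_time", "tmt_a_time",
  "tmt_b_time", "bref", "phonematic_fluency", "semantic_fluency", "do80")

# Random raw battery table (times kept positive).
make_battery <- function(n, seed = 1) {
  set.seed(seed)
  out <- data.frame(subject_id = sprintf("T%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (cc in battery_columns) out[[cc]] <- rnorm(n, 20, 5)
  out$tmt_a_time <- runif(n, 20, 45)
  out$tmt_b_time <- out$tmt_a_time + runif(n, 10, 60)
  out$stroop_interference_time <- runif(n, 30, 80)
  out
}
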