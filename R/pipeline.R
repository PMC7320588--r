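#' Merge the analysis tables into one subject-level table
#'
#' Runs risk scoring, across-test variability and derived volumetrics, and
#' joins them by subject id. The PET table may cover a subset of subjects;
#' its column is NA elsewhere.
#'
#' @param clinical,battery,volumes,lesions,pet the five input tables (see
#'   \code{\link{score_risk}}, \code{\link{cohort_variability}},
#'   \code{\link{derive_volumetrics}}); \code{pet} (columns
#'   \code{subject_id}, \code{gci}) may be NULL.
#' @param spec battery definition, defaulting to
#'   \code{\link{default_battery}}.
#' @return data.frame with one row per subject: demographics, risk flags
#'   and scores, \code{a_i}/\code{v_i}, volume fractions, WML summary,
#'   \code{gci}, and \code{gender_male} (0/1) for regression use.
#' @export
merge_cohort <- function(clinical, battery, volumes, lesions, pet = NULL,
                         spec = default_battery()) {
  risk <- score_risk(clinical)
  vi <- cohort_variability(battery, spec)
  vol <- derive_volumetrics(volumes, lesions)
  base <- data.frame(subject_id = as.character(clinical$subject_id),
                     age = clinical$age, gender = clinical$gender,
                     gender_male = as.integer(clinical$gender == "male"),
                     bmi = clinical$bmi,
                     stringsAsFactors = FALSE)
  m <- merge(base, risk, by = "subject_id", sort = FALSE)
  m <- merge(m, vi, by = "subject_id", sort = FALSE)
  m <- merge(m, vol, by = "subject_id", sort = FALSE)
  if (!is.null(pet) && nrow(pet))
    m <- merge(m, pet[, c("subject_id", "gci")], by = "subject_id",
               all.x = TRUE, sort = FALSE)
  else m$gci <- NA_real_
  if (nrow(m) != nrow(clinical))
    stop("tables do not share a consistent subject_id set", call. = FALSE)
  m <- m[match(as.character(clinical$subject_id), m$subject_id), ]
  rownames(m) <- NULL
  m
}

#' Run the full baseline analysis
#'
#' Executes the four analysis blocks on a merged cohort table (or the raw
#' tables of a \code{\link{simulate_cohort}} result):
#' \enumerate{
#'   \item exhaustive-subset LOOCV regression of the total white-matter
#'     lesion fraction on cardiovascular risk, cognitive risk, age and
#'     gender;
#'   \item the same selection for white-matter, gray-matter and left/right
#'     hippocampal volume fractions over \{V, age, gender, combined risk\};
#'   \item a median split of the combined risk score; after residualising
#'     age out of each outcome, pooled t-tests compare low vs high risk on
#'     V, on the six temporal cortical-thickness measures (one Holm
#'     family), and on PET GCI over the PET subset;
#'   \item Spearman correlations of cardiovascular risk with the three
#'     lesion-class fractions and lesion count, the partial correlation of
#'     combined risk with V given age and gender, and Spearman checks of
#'     GCI against V and age.
#' }
#'
#' @param cohort a \code{"synthetic_cohort"} (or any list with elements
#'   \code{clinical}, \code{battery}, \code{volumetrics}, \code{lesions},
#'   \code{pet}), or an already-merged data.frame from
#'   \code{\link{merge_cohort}}.
#' @param alpha family-wise error level for the Holm-corrected family.
#' @param spec battery definition (ignored when \code{cohort} is already
#'   merged).
#' @return object of class \code{"baseline_report"}: list with
#'   \code{merged}, \code{wml_model}, \code{volume_models} (named list of
#'   \code{\link{loocv_select}} fits), \code{split} (cut and group sizes),
#'   \code{group_comparisons} (data.frame with t, df, raw and Holm p per
#'   family), \code{correlations} (data.frame), \code{alpha}.
#' @export
run_baseline <- function(cohort, alpha = 0.05, spec = default_battery()) {
  merged <- if (is.data.frame(cohort)) cohort
  else merge_cohort(cohort$clinical, cohort$battery, cohort$volumetrics,
                    cohort$lesions, cohort$pet, spec = spec)

  # block 1: WML prediction
  wml_model <- loocv_select(
    total_lesion_volume_frac ~ cardiovascular + cognitive + age +
      gender_male, merged)

  # block 2: brain-volume prediction
  vol_outcomes <- c(white_matter = "wm_frac", gray_matter = "gm_frac",
                    hippocampus_left = "hippocampus_left_frac",
                    hippocampus_right = "hippocampus_right_frac")
  volume_models <- lapply(vol_outcomes, function(o)
    loocv_select(stats::as.formula(
      paste(o, "~ v_i + age + gender_male + combined")), merged))

  # block 3: median-split group comparisons, age residualised
  split <- median_split(merged$combined)
  grp <- split$group
  temporal <- c("medial_temporal_L", "medial_temporal_R",
                "parahippocampal_L", "parahippocampal_R",
                "entorhinal_L", "entorhinal_R")
  compare <- function(var, rows = TRUE) {
    y <- residualize(merged[[var]][rows], merged$age[rows])
    g <- grp[rows]
    tt <- two_sample_t(y[g == "low"], y[g == "high"])
    data.frame(outcome = var, t = tt$t, df = tt$df, p_raw = tt$p,
               mean_low = tt$mean_a, mean_high = tt$mean_b,
               stringsAsFactors = FALSE)
  }
  cmp_vi <- compare("v_i")
  cmp_vi$family <- "variability"
  cmp_vi$p_holm <- cmp_vi$p_raw
  cmp_vi$reject <- cmp_vi$p_raw <= alpha

  cmp_th <- do.call(rbind, lapply(temporal, compare))
  adj <- holm_adjust(cmp_th$p_raw, alpha, family = "temporal_thickness")
  cmp_th$family <- adj$family
  cmp_th$p_holm <- adj$p_holm
  cmp_th$reject <- adj$reject

  pet_rows <- !is.na(merged$gci)
  cmp_pet <- NULL
  if (sum(pet_rows) >= 4 && length(unique(grp[pet_rows])) == 2) {
    cmp_pet <- compare("gci", pet_rows)
    cmp_pet$family <- "pet"
    cmp_pet$p_holm <- cmp_pet$p_raw
    cmp_pet$reject <- cmp_pet$p_raw <= alpha
  } else warning("PET subset too small; GCI comparison skipped")
  group_comparisons <- rbind(cmp_vi, cmp_th, cmp_pet)

  # block 4: correlations
  cors <- list(
    cv_periventricular = spearman_cor(merged$cardiovascular,
                                      merged$periventricular_frac),
    cv_juxtacortical = spearman_cor(merged$cardiovascular,
                                    merged$juxtacortical_frac),
    cv_deep_white = spearman_cor(merged$cardiovascular,
                                 merged$deep_white_frac),
    cv_lesion_count = spearman_cor(merged$cardiovascular,
                                   merged$total_lesion_count),
    risk_vi_partial = partial_cor(merged$combined, merged$v_i,
                                  cbind(age = merged$age,
                                        gender = merged$gender_male)))
  if (sum(pet_rows) >= 4) {
    cors$vi_gci <- spearman_cor(merged$v_i[pet_rows],
                                merged$gci[pet_rows])
    cors$gci_age <- spearman_cor(merged$gci[pet_rows],
                                 merged$age[pet_rows])
  }
  correlations <- do.call(rbind, lapply(names(cors), function(nm) {
    cc <- cors[[nm]]
    data.frame(analysis = nm, method = cc$method, estimate = cc$estimate,
               p = cc$p, n = cc$n, stringsAsFactors = FALSE)
  }))

  structure(list(merged = merged, wml_model = wml_model,
                 volume_models = volume_models, split = split,
                 group_comparisons = group_comparisons,
                 correlations = correlations, alpha = alpha),
            class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, digits = 3, ...) {
  cat("Baseline cohort analysis (n =", nrow(x$merged), ")\n\n")
  cat("[1] WML-fraction model selection:\n    selected:",
      paste(x$wml_model$selected, collapse = " + "),
      sprintf("(bias-corrected LOOCV RMSE = %.3g)\n", x$wml_model$criterion))
  cat("\n[2] Volume model selection:\n")
  for (nm in names(x$volume_models))
    cat(sprintf("    %-18s -> %s (RMSE = %.3g)\n", nm,
                paste(x$volume_models[[nm]]$selected, collapse = " + "),
                x$volume_models[[nm]]$criterion))
  cat(sprintf("\n[3] Median split at combined risk <= %g (n_low = %d, n_high = %d), age residualised:\n",
              x$split$cut, x$split$n_low, x$split$n_high))
  print(format(x$group_comparisons[, c("outcome", "t", "p_raw", "p_holm",
                                       "family", "reject")],
               digits = digits), row.names = FALSE)
  cat("\n[4] Correlations:\n")
  print(format(x$correlations, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Cohort descriptive summary
#'
#' Means, SDs and percentages of the main baseline characteristics, with
#' TIV-corrected volumes reported in percent. With a single subject the SD
#' columns are NA.
#'
#' @param merged merged subject-level table from \code{\link{merge_cohort}}.
#' @return data.frame with columns \code{characteristic}, \code{value},
#'   \code{sd} (NA for percentages and counts).
#' @export
descriptives <- function(merged) {
  if (!nrow(merged)) stop("empty table", call. = FALSE)
  row <- function(name, value, sd = NA_real_)
    data.frame(characteristic = name, value = value, sd = sd,
               stringsAsFactors = FALSE)
  pct <- function(x) 100 * mean(x)
  sd_ <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  pet <- merged$gci[!is.na(merged$gci)]
  out <- rbind(
    row("n_subjects", nrow(merged)),
    row("female_pct", pct(merged$gender == "female")),
    row("age_years", mean(merged$age), sd_(merged$age)),
    row("high_education_pct", pct(!merged$low_education)),
    row("diabetes_pct", pct(merged$diabetes)),
    row("hypertension_pct", pct(merged$hypertension)),
    row("dyslipidemia_pct", pct(merged$dyslipidemia)),
    row("bmi", mean(merged$bmi), sd_(merged$bmi)),
    row("depression_pct", pct(merged$depression_risk)),
    row("across_test_variability", mean(merged$v_i), sd_(merged$v_i)),
    row("gray_matter_pct_tiv", 100 * mean(merged$gm_frac),
        100 * sd_(merged$gm_frac)),
    row("white_matter_pct_tiv", 100 * mean(merged$wm_frac),
        100 * sd_(merged$wm_frac)),
    row("csf_pct_tiv", 100 * mean(merged$csf_frac),
        100 * sd_(merged$csf_frac)),
    row("hippocampus_pct_tiv",
        100 * mean(merged$hippocampus_left_frac +
                     merged$hippocampus_right_frac),
        100 * sd_(merged$hippocampus_left_frac +
                    merged$hippocampus_right_frac)),
    row("total_lesion_count", mean(merged$total_lesion_count),
        sd_(merged$total_lesion_count)),
    row("total_lesion_volume_pct_tiv",
        100 * mean(merged$total_lesion_volume_frac),
        100 * sd_(merged$total_lesion_volume_frac)),
    row("pet_n", length(pet)),
    row("gci", if (length(pet)) mean(pet) else NA_real_, sd_(pet)),
    row("amyloid_positive_pct",
        if (length(pet)) pct(classify_amyloid(pet)) else NA_real_))
  out
}
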