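#' Composite cardiovascular and cognitive risk scoring
#'
#' Converts raw clinical fields into binary risk flags and composite scores.
#' Five cardiovascular flags (diabetes, hypertension, dyslipidemia, active
#' smoking, obesity) and two cognitive flags (depression risk, low education)
#' are each worth one point; the combined score is their sum (0--7).
#'
#' Flag definitions:
#' \itemize{
#'   \item diabetes: glycemia > 1.26 g/L, self-reported diabetes, or
#'     antidiabetic drug intake;
#'   \item hypertension: antihypertensive drug intake, self-reported
#'     hypertension, or an elevated blood-pressure measurement
#'     (systolic >= 140 mmHg and/or diastolic >= 90 mmHg, see
#'     \code{hypertension_rule});
#'   \item dyslipidemia: cholesterol > 2.5 mmol/L, self-report, or
#'     lipid-lowering drug;
#'   \item smoking: active smoker at inclusion;
#'   \item obesity: body mass index > 30 kg/m2;
#'   \item depression_risk: Geriatric Depression Scale score > 9;
#'   \item low_education: below baccalaureate-level education.
#' }
#' All numeric thresholds are applied exactly as stated (strict or inclusive
#' as written above). APOE epsilon-4 carrier status, a non-modifiable risk
#' factor, is deliberately not part of any score.
#'
#' @param clinical data.frame with one row per subject. Required columns:
#'   \code{subject_id}, \code{sbp}, \code{dbp} (mmHg), \code{glycemia} (g/L),
#'   \code{cholesterol} (mmol/L), \code{bmi} (kg/m2), \code{gds},
#'   \code{high_education}, and the logical columns \code{active_smoker},
#'   \code{self_reported_diabetes}, \code{antidiabetic_drug},
#'   \code{self_reported_hypertension}, \code{antihypertensive_drug},
#'   \code{self_reported_hypercholesterolemia}, \code{lipid_lowering_drug}.
#' @param hypertension_rule \code{"or"} (default) flags blood pressure when
#'   sbp >= 140 OR dbp >= 90; \code{"and"} requires both.
#' @param assume_absent_when_missing if TRUE, missing self-report/drug
#'   booleans are treated as FALSE. Default FALSE: missing fields are an
#'   error, because silently imputing risk flags biases scores.
#' @return data.frame: \code{subject_id}, seven logical flag columns,
#'   \code{cardiovascular} (0--5), \code{cognitive} (0--2),
#'   \code{combined} (0--7).
#' @examples
#' clin <- data.frame(
#'   subject_id = "s1", sbp = 142, dbp = 85, glycemia = 0.9,
#'   cholesterol = 2.1, bmi = 24, gds = 2, high_education = TRUE,
#'   active_smoker = FALSE, self_reported_diabetes = FALSE,
#'   antidiabetic_drug = FALSE, self_reported_hypertension = FALSE,
#'   antihypertensive_drug = FALSE,
#'   self_reported_hypercholesterolemia = FALSE,
#'   lipid_lowering_drug = FALSE)
#' score_risk(clin)  # hypertension flag only: cardiovascular = 1
#' @export
score_risk <- function(clinical, hypertension_rule = c("or", "and"),
                       assume_absent_when_missing = FALSE) {
  cv <- score_cardiovascular(clinical, hypertension_rule,
                             assume_absent_when_missing)
  cog <- score_cognitive(clinical)
  out <- cbind(cv, cog[, c("depression_risk", "low_education", "cognitive")])
  out$combined <- combine_risk(out$cardiovascular, out$cognitive)
  out
}

#' Cardiovascular risk flags and score
#'
#' @inheritParams score_risk
#' @return data.frame with \code{subject_id}, the five cardiovascular flags
#'   and the \code{cardiovascular} count (0--5).
#' @export
score_cardiovascular <- function(clinical,
                                 hypertension_rule = c("or", "and"),
                                 assume_absent_when_missing = FALSE) {
  hypertension_rule <- match.arg(hypertension_rule)
  num_fields <- c("sbp", "dbp", "glycemia", "cholesterol", "bmi")
  bool_fields <- c("active_smoker", "self_reported_diabetes",
                   "antidiabetic_drug", "self_reported_hypertension",
                   "antihypertensive_drug",
                   "self_reported_hypercholesterolemia",
                   "lipid_lowering_drug")
  clinical <- check_fields(clinical, num_fields, bool_fields,
                           assume_absent_when_missing)

  bp_high <- if (hypertension_rule == "or") {
    clinical$sbp >= 140 | clinical$dbp >= 90
  } else {
    clinical$sbp >= 140 & clinical$dbp >= 90
  }

  flags <- data.frame(
    subject_id = as.character(clinical$subject_id),
    diabetes = clinical$glycemia > 1.26 |
      clinical$self_reported_diabetes | clinical$antidiabetic_drug,
    hypertension = clinical$antihypertensive_drug |
      clinical$self_reported_hypertension | bp_high,
    dyslipidemia = clinical$cholesterol > 2.5 |
      clinical$self_reported_hypercholesterolemia |
      clinical$lipid_lowering_drug,
    smoking = clinical$active_smoker,
    obesity = clinical$bmi > 30,
    stringsAsFactors = FALSE)
  flags$cardiovascular <- as.integer(
    flags$diabetes + flags$hypertension + flags$dyslipidemia +
      flags$smoking + flags$obesity)
  flags
}

#' Cognitive risk flags and score
#'
#' Depression risk is GDS > 9; low education is the complement of holding at
#' least a baccalaureate-level degree.
#'
#' @inheritParams score_risk
#' @return data.frame with \code{subject_id}, \code{depression_risk},
#'   \code{low_education} and the \code{cognitive} count (0--2).
#' @export
score_cognitive <- function(clinical) {
  for (f in c("gds", "high_education")) {
    if (is.null(clinical[[f]]))
      stop("missing required field: ", f, call. = FALSE)
    if (anyNA(clinical[[f]]))
      stop("missing values in field: ", f, call. = FALSE)
  }
  if (any(clinical$gds < 0)) stop("gds must be non-negative", call. = FALSE)
  out <- data.frame(
    subject_id = as.character(clinical$subject_id),
    depression_risk = clinical$gds > 9,
    low_education = !clinical$high_education,
    stringsAsFactors = FALSE)
  out$cognitive <- as.integer(out$depression_risk + out$low_education)
  out
}

#' Combine cardiovascular and cognitive scores
#'
#' @param cardiovascular integer vector in 0--5.
#' @param cognitive integer vector in 0--2.
#' @return integer vector of combined modifiable-risk scores in 0--7.
#' @export
combine_risk <- function(cardiovascular, cognitive) {
  if (any(cardiovascular < 0 | cardiovascular > 5))
    stop("cardiovascular score out of range [0, 5]", call. = FALSE)
  if (any(cognitive < 0 | cognitive > 2))
    stop("cognitive score out of range [0, 2]", call. = FALSE)
  as.integer(cardiovascular + cognitive)
}

#' Amyloid positivity from the global cortical index
#'
#' A subject is amyloid-positive when the global cortical index (GCI, the
#' mean amyloid-PET SUVr over associative cortex referenced to cerebellar
#' gray matter) exceeds 1.45 strictly.
#'
#' @param gci positive numeric vector of global cortical index values.
#' @return logical vector, TRUE where gci > 1.45.
#' @examples
#' classify_amyloid(c(1.28, 1.45, 1.46))  # FALSE FALSE TRUE
#' @export
classify_amyloid <- function(gci) {
  ok <- !is.na(gci)
  if (any(gci[ok] <= 0)) stop("gci must be positive", call. = FALSE)
  gci > 1.45
}

# Validate presence/finiteness of clinical fields; optionally default
# missing booleans to FALSE.
check_fields <- function(clinical, num_fields, bool_fields, assume_absent) {
  for (f in num_fields) {
    if (is.null(clinical[[f]]))
      stop("missing required field: ", f, call. = FALSE)
    if (anyNA(clinical[[f]]) || any(!is.finite(clinical[[f]])))
      stop("missing or non-finite values in field: ", f, call. = FALSE)
  }
  for (f in bool_fields) {
    if (is.null(clinical[[f]])) {
      if (assume_absent) clinical[[f]] <- rep(FALSE, nrow(clinical))
      else stop("missing required field: ", f, call. = FALSE)
    }
    if (anyNA(clinical[[f]])) {
      if (assume_absent) clinical[[f]][is.na(clinical[[f]])] <- FALSE
      else stop("missing values in field: ", f, call. = FALSE)
    }
  }
  if (any(clinical$sbp <= clinical$dbp) || any(clinical$dbp <= 0))
    stop("blood pressure must satisfy sbp > dbp > 0", call. = FALSE)
  if (any(clinical$bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  clinical
}
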