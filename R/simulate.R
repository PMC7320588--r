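#' Configuration for the synthetic baseline cohort generator
#'
#' Bundles every marginal target and latent-model parameter of the
#' generator. Defaults emulate a healthy-aging cohort of 142 volunteers
#' aged 50--70: marginal distributions of the clinical, neuropsychological,
#' volumetric and lesion tables match the cohort's baseline summary table,
#' and the cross-domain associations are calibrated to the reported values
#' (age vs white-matter fraction r = -0.41, age vs lesion fraction
#' r = 0.39, combined risk vs across-test variability partial r = 0.21
#' given age and gender, a 1.08-SD male-female gap in TIV).
#'
#' The neuropsychological model is a single general-cognition factor g per
#' subject plus subject-specific noise whose scale s_i (the latent
#' inconsistency) is log-normal; the combined risk score shifts log s_i
#' upward, which induces the risk--variability association. The latent
#' inconsistency is the recoverable ground truth for the variability
#' statistic V.
#'
#' @param n number of subjects (>= 10).
#' @param seed integer seed; one global seed is expanded into fixed
#'   per-table substreams so adding a table never perturbs the others.
#' @param effects named list overriding any effect-size parameter (see
#'   Details); \code{\link{null_config}} zeroes them all.
#' @details Effect parameters (all zeroed in a null cohort):
#'   \code{r_age_wm} (-0.41), \code{r_age_gm} (-0.22),
#'   \code{r_incons_wm} (-0.30), \code{r_age_wml} (0.39),
#'   \code{r_cv_wml} (0.23), \code{r_cog_wml} (0.16),
#'   \code{r_age_thick} (-0.22), \code{tiv_gender_gap_sd} (1.08),
#'   \code{v_beta_risk} (shift of log-inconsistency per combined risk
#'   point), \code{thick_highrisk_d} (per-region Cohen's d of the
#'   high-risk thickness reduction), hippocampal age/gender effects
#'   (\code{r_age_hip_l/r}, \code{hip_gender_d_l/r}) and lesion-count
#'   slopes (\code{count_age_slope}, \code{count_cv_slope}).
#' @return list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n = 142, seed = 1, effects = list()) {
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    # demographics
    p_female = 0.5,
    age_mean = 60, age_parent_sd = 7.9, age_range = c(50, 70),
    # risk-flag prevalences (counts out of 142 in the target cohort)
    p_diabetes = 7 / 142, p_hypertension = 43 / 142,
    p_dyslipidemia = 39 / 142, p_smoking = 8 / 142, p_obesity = 16 / 142,
    p_depression = 9 / 142, p_high_education = 118 / 142,
    p_apoe_carrier = 0.229,
    # latent cognition / inconsistency model (calibrated; see vignette)
    v_loading = 0.30, v_mu = 0.183, v_sigma = 0.407,
    # volumetric marginals
    tiv_male_mean = 1500000, tiv_sd = 110000,
    gm_frac_mean = 0.4781, gm_frac_sd = 0.0204,
    wm_frac_mean = 0.3559, wm_frac_sd = 0.0276,
    hip_frac_mean = 0.0028, hip_frac_sd = 0.00025,
    mean_thick_mean = 2.45, mean_thick_sd = 0.08,
    temporal_regions = c(medial_temporal_L = 2.90, medial_temporal_R = 2.90,
                         parahippocampal_L = 2.70, parahippocampal_R = 2.70,
                         entorhinal_L = 3.20, entorhinal_R = 3.20),
    temporal_sd = c(0.15, 0.15, 0.18, 0.18, 0.25, 0.25),
    # white-matter lesions
    wml_frac_mean = 8.72e-4, wml_frac_sd = 1.2e-4,
    count_mean = 10.6, count_size = 3.1,
    class_weights = c(periventricular = 0.837, juxtacortical = 0.103,
                      deep_white = 0.060),
    class_alpha = 5,
    # PET
    pet_fraction = 81 / 142, p_amyloid_positive = 0.086,
    gci_neg = c(mean = 1.26, sd = 0.105),
    gci_pos = c(mean = 1.55, sd = 0.10),
    # effect sizes (cross-domain associations)
    r_age_wm = -0.41, r_age_gm = -0.22, r_incons_wm = -0.30,
    r_age_wml = 0.39, r_cv_wml = 0.23, r_cog_wml = 0.16,
    r_age_thick = -0.22, tiv_gender_gap_sd = 1.08,
    v_beta_risk = 0.1175,
    thick_highrisk_d = c(0.73, 0.30, 0.57, 0.51, 0.30, 0.25),
    r_age_hip_l = -0.18, r_age_hip_r = -0.13,
    hip_gender_d_l = 0.65, hip_gender_d_r = 0.28,
    count_age_slope = 0.25, count_cv_slope = 1.5)
  for (nm in names(effects)) {
    if (!nm %in% names(cfg))
      stop("unknown config entry: ", nm, call. = FALSE)
    cfg[[nm]] <- effects[[nm]]
  }
  structure(cfg, class = "cohort_config")
}

#' Null-cohort configuration
#'
#' Same marginals as \code{\link{cohort_config}} but with every
#' cross-domain effect set to zero, for type-I-error testing of the
#' pipeline.
#'
#' @inheritParams cohort_config
#' @return list of class \code{"cohort_config"}.
#' @export
null_config <- function(n = 142, seed = 1, effects = list()) {
  zero <- list(r_age_wm = 0, r_age_gm = 0, r_incons_wm = 0,
               r_age_wml = 0, r_cv_wml = 0, r_cog_wml = 0,
               r_age_thick = 0, tiv_gender_gap_sd = 0, v_beta_risk = 0,
               thick_highrisk_d = rep(0, 6),
               r_age_hip_l = 0, r_age_hip_r = 0,
               hip_gender_d_l = 0, hip_gender_d_r = 0,
               count_age_slope = 0, count_cv_slope = 0)
  zero[names(effects)] <- effects
  cohort_config(n = n, seed = seed, effects = zero)
}

# Inverse-CDF truncated-normal sampler (fixed number of RNG draws).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Analytic moments of a truncated normal.
tnorm_moments <- function(mean, sd, lower, upper) {
  al <- (lower - mean) / sd; be <- (upper - mean) / sd
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Analytic mean/var of the combined risk score under independent flags.
risk_moments <- function(cfg) {
  p <- c(cfg$p_diabetes, cfg$p_hypertension, cfg$p_dyslipidemia,
         cfg$p_smoking, cfg$p_obesity, cfg$p_depression,
         1 - cfg$p_high_education)
  list(mean = sum(p), var = sum(p * (1 - p)),
       cv_mean = sum(p[1:5]), cv_var = sum(p[1:5] * (1 - p[1:5])),
       cog_mean = sum(p[6:7]), cog_var = sum(p[6:7] * (1 - p[6:7])))
}

#' Generate a synthetic baseline cohort
#'
#' Draws the five analysis tables (clinical, neuropsychological battery,
#' volumetrics, per-lesion records, PET) plus a ground-truth table of the
#' latent variables, reproducibly from the configuration seed.
#'
#' @param config a \code{\link{cohort_config}} (or \code{\link{null_config}}).
#' @return list of class \code{"synthetic_cohort"} with data.frames
#'   \code{clinical}, \code{battery}, \code{volumetrics}, \code{lesions},
#'   \code{pet}, \code{ground_truth}, and the \code{config}. All tables
#'   share one subject_id set (PET covers a subset, as in a cohort where
#'   not everyone has been scanned).
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 50, seed = 7))
#' names(coh)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  n <- cfg$n
  ids <- sprintf("S%04d", seq_len(n))
  rm <- risk_moments(cfg)

  clinical <- local({
    set.seed(cfg$seed + 1L)
    age <- rtnorm(n, cfg$age_mean, cfg$age_parent_sd,
                  cfg$age_range[1], cfg$age_range[2])
    gender <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
    f_dia <- stats::runif(n) < cfg$p_diabetes
    f_hyp <- stats::runif(n) < cfg$p_hypertension
    f_dys <- stats::runif(n) < cfg$p_dyslipidemia
    f_smo <- stats::runif(n) < cfg$p_smoking
    f_obe <- stats::runif(n) < cfg$p_obesity
    f_dep <- stats::runif(n) < cfg$p_depression
    high_ed <- stats::runif(n) < cfg$p_high_education

    # hypertension: mix of treated/self-reported (controlled BP) and
    # untreated elevated BP
    treated <- f_hyp & stats::runif(n) < 0.6
    elevated <- f_hyp & !treated
    sbp <- rtnorm(n, 122, 9, 95, 139.9)
    sbp[treated] <- rtnorm(sum(treated), 132, 8, 100, 139.9)
    sbp[elevated] <- rtnorm(sum(elevated), 150, 9, 140, 185)
    dbp <- pmin(rtnorm(n, 76, 7, 55, 89.9), sbp - 12)
    dbp[elevated] <- pmin(rtnorm(sum(elevated), 90, 7, 62, 115),
                          sbp[elevated] - 12)
    antihyp <- treated & stats::runif(n) < 0.8
    self_hyp <- treated & !antihyp

    gly_treated <- f_dia & stats::runif(n) < 0.5
    glycemia <- rtnorm(n, 0.95, 0.10, 0.6, 1.26)
    glycemia[f_dia & !gly_treated] <-
      rtnorm(sum(f_dia & !gly_treated), 1.45, 0.15, 1.261, 2.2)
    glycemia[gly_treated] <- rtnorm(sum(gly_treated), 1.10, 0.10, 0.7, 1.26)
    antidia <- gly_treated
    self_dia <- f_dia & (antidia | stats::runif(n) < 0.5)

    lip_treated <- f_dys & stats::runif(n) < 0.45
    cholesterol <- rtnorm(n, 2.15, 0.18, 1.4, 2.5)
    cholesterol[f_dys & !lip_treated] <-
      rtnorm(sum(f_dys & !lip_treated), 2.75, 0.20, 2.501, 3.6)
    cholesterol[lip_treated] <- rtnorm(sum(lip_treated), 2.2, 0.2, 1.5, 2.5)
    lipdrug <- lip_treated
    self_dys <- f_dys & (lipdrug | stats::runif(n) < 0.5)

    bmi <- rtnorm(n, 24, 2.6, 16.5, 30)
    bmi[f_obe] <- rtnorm(sum(f_obe), 33, 2.5, 30.01, 45)

    gds <- pmin(9, round(abs(stats::rnorm(n, 0, 4.2))))
    gds[f_dep] <- 10 + stats::rpois(sum(f_dep), 2)

    carrier <- stats::runif(n) < cfg$p_apoe_carrier
    apoe <- ifelse(carrier, ifelse(stats::runif(n) < 0.04, 2L, 1L), 0L)

    data.frame(subject_id = ids, age = age, gender = gender,
               sbp = sbp, dbp = dbp, glycemia = glycemia,
               cholesterol = cholesterol, bmi = bmi,
               active_smoker = f_smo,
               self_reported_diabetes = self_dia,
               antidiabetic_drug = antidia,
               self_reported_hypertension = self_hyp,
               antihypertensive_drug = antihyp,
               self_reported_hypercholesterolemia = self_dys,
               lipid_lowering_drug = lipdrug,
               gds = gds, high_education = high_ed,
               apoe_e4_copies = apoe, stringsAsFactors = FALSE)
  })

  risk <- score_risk(clinical)
  combined_c <- risk$combined - rm$mean
  cv_c <- risk$cardiovascular - rm$cv_mean
  cog_c <- risk$cognitive - rm$cog_mean
  age_c <- clinical$age - tnorm_moments(cfg$age_mean, cfg$age_parent_sd,
                                        cfg$age_range[1],
                                        cfg$age_range[2])["mean"]
  sd_age <- tnorm_moments(cfg$age_mean, cfg$age_parent_sd,
                          cfg$age_range[1], cfg$age_range[2])["sd"]
  male <- clinical$gender == "male"

  # latent cognition factor and log-normal inconsistency scale
  latent <- local({
    set.seed(cfg$seed + 2L)
    g <- stats::rnorm(n)
    u <- stats::rnorm(n)
    log_s <- cfg$v_mu + cfg$v_beta_risk * combined_c + cfg$v_sigma * u
    sd_log_s <- sqrt(cfg$v_sigma^2 + cfg$v_beta_risk^2 * rm$var)
    z_s <- if (sd_log_s > 0) (log_s - cfg$v_mu) / sd_log_s else 0 * log_s
    list(g = g, s = exp(log_s), log_s = log_s, z_s = z_s)
  })

  battery <- local({
    set.seed(cfg$seed + 3L)
    lam <- cfg$v_loading
    draw <- function(mean, sd, sign = 1, lower = -Inf, upper = Inf) {
      y <- lam * latent$g + latent$s * stats::rnorm(n)
      x <- mean + sd * sign * y
      pmin(pmax(x, lower), upper)
    }
    tmt_a <- rtnorm(n, 31.9, 9.8, 8, 90)
    tmt_diff <- pmax(40.4 + 20 * -(lam * latent$g +
                                     latent$s * stats::rnorm(n)), 1)
    data.frame(
      subject_id = ids,
      mmse = draw(29.2, 1.0),
      mattis = draw(142.3, 2.8),
      corsi_direct = draw(5.3, 0.9),
      corsi_inverse = draw(4.7, 0.9),
      digit_direct = draw(6.0, 1.1),
      digit_inverse = draw(4.7, 1.1),
      grober_buschke_total_recall = draw(46.6, 1.4),
      dms_immediate = draw(96.9, 3.7, upper = 100),
      rey_immediate = draw(35.0, 1.4, upper = 36),
      rey_3min = draw(20.5, 7.4, lower = 0, upper = 36),
      stroop_interference_time = draw(53.8, 11.8, sign = -1, lower = 5),
      tmt_a_time = tmt_a,
      tmt_b_time = tmt_a + tmt_diff,
      bref = draw(17.1, 1.3, upper = 18),
      phonematic_fluency = draw(23.9, 6.7, lower = 0),
      semantic_fluency = draw(39.0, 9.1, lower = 0),
      do80 = draw(79.8, 0.7, upper = 80),
      stringsAsFactors = FALSE)
  })

  volumetrics <- local({
    set.seed(cfg$seed + 4L)
    tiv <- stats::rnorm(n, cfg$tiv_male_mean, cfg$tiv_sd) -
      (!male) * cfg$tiv_gender_gap_sd * cfg$tiv_sd

    lin <- function(mean, sd, r_age = 0, r_extra = 0, extra = 0,
                    d_gender = 0) {
      # variance decomposition: age slope + one extra standardized driver
      # + gender shift + residual noise, holding the marginal SD at `sd`
      p_gender <- mean(male) * (1 - mean(male))
      res <- 1 - r_age^2 - r_extra^2 - d_gender^2 * p_gender
      if (res < 0.05)
        stop("infeasible correlation targets (residual variance < 0)",
             call. = FALSE)
      mean + sd * (r_age / sd_age * age_c + r_extra * extra +
                     d_gender * (!male - mean(!male)) +
                     sqrt(res) * stats::rnorm(n))
    }
    wm_frac <- lin(cfg$wm_frac_mean, cfg$wm_frac_sd, cfg$r_age_wm,
                   cfg$r_incons_wm, latent$z_s)
    gm_frac <- lin(cfg$gm_frac_mean, cfg$gm_frac_sd, cfg$r_age_gm)
    hip_l <- lin(cfg$hip_frac_mean, cfg$hip_frac_sd, cfg$r_age_hip_l,
                 d_gender = cfg$hip_gender_d_l)
    hip_r <- lin(cfg$hip_frac_mean, cfg$hip_frac_sd, cfg$r_age_hip_r,
                 d_gender = cfg$hip_gender_d_r)
    th_mean_l <- lin(cfg$mean_thick_mean, cfg$mean_thick_sd, cfg$r_age_thick)
    th_mean_r <- lin(cfg$mean_thick_mean, cfg$mean_thick_sd, cfg$r_age_thick)

    high <- risk$combined > 1
    p_high <- mean(high) * (1 - mean(high))
    th <- lapply(seq_along(cfg$temporal_regions), function(j) {
      d <- cfg$thick_highrisk_d[j]
      res <- 1 - cfg$r_age_thick^2 - d^2 * p_high
      cfg$temporal_regions[j] + cfg$temporal_sd[j] *
        (cfg$r_age_thick / sd_age * age_c - d * (high - mean(high)) +
           sqrt(res) * stats::rnorm(n))
    })
    names(th) <- names(cfg$temporal_regions)

    out <- data.frame(
      subject_id = ids, tiv = tiv,
      gm_volume = gm_frac * tiv, wm_volume = wm_frac * tiv,
      csf_volume = pmax(1 - gm_frac - wm_frac, 0.02) * tiv,
      hippocampus_left = pmax(hip_l, 5e-4) * tiv,
      hippocampus_right = pmax(hip_r, 5e-4) * tiv,
      mean_thickness_L = th_mean_l, mean_thickness_R = th_mean_r,
      stringsAsFactors = FALSE)
    for (nm in names(th)) out[[nm]] <- th[[nm]]
    out$fazekas <- pmin(3L, pmax(0L, as.integer(round(
      1.2 + 0.35 * (cfg$r_age_wml / sd_age * age_c * 6.3 / 1.2) +
        stats::rnorm(n, 0, 0.9)))))
    out
  })

  lesions <- local({
    set.seed(cfg$seed + 5L)
    res <- 1 - cfg$r_age_wml^2 - cfg$r_cv_wml^2 - cfg$r_cog_wml^2
    total_frac <- pmax(
      cfg$wml_frac_mean + cfg$wml_frac_sd *
        (cfg$r_age_wml / sd_age * age_c +
           cfg$r_cv_wml / sqrt(rm$cv_var) * cv_c +
           cfg$r_cog_wml / sqrt(rm$cog_var) * cog_c +
           sqrt(res) * stats::rnorm(n)),
      1e-5)
    mu_count <- pmax(cfg$count_mean + cfg$count_age_slope * age_c +
                       cfg$count_cv_slope * cv_c, 1)
    count <- pmax(1L, stats::rnbinom(n, mu = mu_count,
                                     size = cfg$count_size))
    w <- cfg$class_weights / sum(cfg$class_weights)
    alpha <- cfg$class_alpha * w
    # per-subject class volume shares: normalized gamma draws (Dirichlet)
    shares <- matrix(stats::rgamma(n * 3, shape = rep(alpha, each = n)),
                     nrow = n)
    shares <- shares / rowSums(shares)
    rows <- vector("list", n)
    total_vol <- total_frac * volumetrics$tiv
    for (i in seq_len(n)) {
      cls_count <- drop(stats::rmultinom(1, count[i], shares[i, ]))
      present <- cls_count > 0
      sh <- shares[i, ] * present
      sh <- sh / sum(sh)
      les_class <- rep(wml_classes, cls_count)
      vol <- numeric(count[i])
      pos <- 0
      for (k in which(present)) {
        wts <- stats::runif(cls_count[k], 0.2, 1)
        vol[pos + seq_len(cls_count[k])] <-
          total_vol[i] * sh[k] * wts / sum(wts)
        pos <- pos + cls_count[k]
      }
      rows[[i]] <- data.frame(
        subject_id = ids[i],
        lesion_id = sprintf("%s_L%03d", ids[i], seq_len(count[i])),
        lesion_class = les_class, volume = vol,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  pet <- local({
    set.seed(cfg$seed + 6L)
    n_pet <- round(cfg$pet_fraction * n)
    sel <- sort(sample.int(n, n_pet))
    pos <- stats::runif(n_pet) < cfg$p_amyloid_positive
    gci <- rtnorm(n_pet, cfg$gci_neg["mean"], cfg$gci_neg["sd"],
                  0.8, 1.45)
    gci[pos] <- rtnorm(sum(pos), cfg$gci_pos["mean"], cfg$gci_pos["sd"],
                       1.4501, 2.5)
    data.frame(subject_id = ids[sel], gci = gci,
               stringsAsFactors = FALSE)
  })

  ground_truth <- data.frame(
    subject_id = ids, g = latent$g, log_inconsistency = latent$log_s,
    inconsistency_z = latent$z_s, combined_risk = risk$combined,
    high_risk = risk$combined > 1, stringsAsFactors = FALSE)

  structure(list(clinical = clinical, battery = battery,
                 volumetrics = volumetrics, lesions = lesions, pet = pet,
                 ground_truth = ground_truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic baseline cohort: n = %d (seed %d)\n",
              x$config$n, x$config$seed))
  cat(sprintf("  tables: clinical (%d x %d), battery (%d x %d), volumetrics (%d x %d),\n",
              nrow(x$clinical), ncol(x$clinical), nrow(x$battery),
              ncol(x$battery), nrow(x$volumetrics), ncol(x$volumetrics)))
  cat(sprintf("          lesions (%d records), PET (n = %d)\n",
              nrow(x$lesions), nrow(x$pet)))
  invisible(x)
}
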