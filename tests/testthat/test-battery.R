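test_that("battery reduction orients and combines components as specified", {
  bat <- make_battery(3, seed = 2)
  bat$tmt_a_time <- c(31.9, 40, 25)
  bat$tmt_b_time <- c(72.3, 90, 60)
  m <- reduce_battery(bat)
  # TMT is the negated B - A time difference
  expect_equal(m[1, "tmt_b_minus_a"], -40.4)
  # single higher-is-better subtests pass the raw column through
  expect_equal(unname(m[, "mmse"]), bat$mmse)
  # lower-is-better single subtests are negated
  expect_equal(unname(m[, "stroop"]), -bat$stroop_interference_time)
})

test_that("mean_of_z reduction averages component z-scores (hand oracle)", {
  bat <- make_battery(3, seed = 3)
  bat$corsi_direct <- c(4, 5, 6)
  bat$corsi_inverse <- c(5, 3, 4)
  m <- reduce_battery(bat)
  z1 <- (bat$corsi_direct - 5) / sd(bat$corsi_direct)
  z2 <- (bat$corsi_inverse - 4) / sd(bat$corsi_inverse)
  expect_equal(unname(m[, "corsi"]), (z1 + z2) / 2, tolerance = 1e-12)
})

test_that("unknown columns in a spec are a schema error", {
  bat <- make_battery(3)
  spec <- list(list(name = "oops", components = "not_a_column",
                    orientation = "higher_is_better", reduction = "single"))
  expect_error(reduce_battery(bat, spec), "not_a_column")
})

test_that("cohort z-transformation standardises every column", {
  expect_equal(unname(zscore_cohort(cbind(a = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  set.seed(4)
  x <- matrix(rnorm(15, 10, 4), 5, 3)
  z <- zscore_cohort(x)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
  # brute-force per-column oracle
  oracle <- apply(x, 2, function(cc) (cc - mean(cc)) / sd(cc))
  expect_equal(unname(z), unname(oracle), tolerance = 1e-12)
  expect_error(zscore_cohort(cbind(a = rnorm(5), b = rep(2, 5))), "b")
})

test_that("subject mean and across-test variability match their formulas", {
  expect_equal(subject_mean(c(1, -1)), 0)
  expect_equal(subject_mean(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(across_test_variability(c(1, -1)), sqrt(2))
  expect_equal(across_test_variability(c(1, 0, -1)), 1)
  expect_equal(across_test_variability(rep(0.3, 14)), 0)
  set.seed(5)
  row <- rnorm(14)
  expect_equal(subject_mean(row), sum(row) / 14)
  a <- mean(row)
  expect_equal(across_test_variability(row),
               sqrt(sum((row - a)^2) / 13), tolerance = 1e-12)
  expect_error(across_test_variability(1), "K >= 2")
  expect_error(subject_mean(numeric(0)), "empty")
})

test_that("cohort variability equals a from-scratch oracle on 10 subjects", {
  bat <- make_battery(10, seed = 6)
  res <- cohort_variability(bat)
  # independent recomputation: orient, z-score via scale(), per-row sd
  std <- function(x) (x - mean(x)) / sd(x)
  cols <- cbind(
    bat$mmse, bat$mattis,
    (std(bat$corsi_direct) + std(bat$corsi_inverse)) / 2,
    (std(bat$digit_direct) + std(bat$digit_inverse)) / 2,
    bat$grober_buschke_total_recall, bat$dms_immediate,
    bat$rey_immediate, bat$rey_3min,
    -bat$stroop_interference_time,
    -(bat$tmt_b_time - bat$tmt_a_time),
    bat$bref, bat$phonematic_fluency, bat$semantic_fluency, bat$do80)
  z <- scale(cols)
  expect_equal(res$v_i, unname(apply(z, 1, sd)), tolerance = 1e-10)
  expect_equal(res$a_i, unname(rowMeans(z)), tolerance = 1e-10)
  expect_true(all(res$k_used == 14L))
  expect_true(abs(mean(res$a_i)) < 1e-10)
  expect_true(all(res$v_i >= 0))
})

test_that("a cohort of identical profiles is a degenerate-column error", {
  bat <- make_battery(4, seed = 7)
  for (cc in battery_columns) bat[[cc]] <- rep(bat[[cc]][1], 4)
  expect_error(cohort_variability(bat), "zero-variance")
})

test_that("clone groups get identical variability", {
  b2 <- make_battery(2, seed = 8)
  bat <- rbind(b2, b2, b2)
  bat$subject_id <- sprintf("T%03d", 1:6)
  res <- cohort_variability(bat)
  expect_equal(res$v_i[1:2], res$v_i[3:4], tolerance = 1e-12)
  expect_equal(res$v_i[1:2], res$v_i[5:6], tolerance = 1e-12)
})

test_that("variability is invariant to affine rescaling of raw columns", {
  bat <- make_battery(12, seed = 9)
  res <- cohort_variability(bat)
  shifted <- bat
  shifted$mattis <- bat$mattis * 3.7 + 11
  shifted$stroop_interference_time <- bat$stroop_interference_time * 2.2
  expect_equal(cohort_variability(shifted)$v_i, res$v_i, tolerance = 1e-10)
})

test_that("permutations act as expected on subjects and subtests", {
  bat <- make_battery(9, seed = 10)
  res <- cohort_variability(bat)
  perm <- sample(9)
  resp <- cohort_variability(bat[perm, ])
  expect_equal(resp$v_i, res$v_i[perm], tolerance = 1e-12)
  spec <- default_battery()
  resq <- cohort_variability(bat, spec[c(5:14, 1:4)])
  expect_equal(resq$v_i, res$v_i, tolerance = 1e-12)
})

test_that("missing scores error by default and are droppable per policy", {
  bat <- make_battery(12, seed = 11)
  bat$mmse[3] <- NA
  expect_error(cohort_variability(bat), "T003")
  res <- cohort_variability(bat, missing = "available")
  expect_equal(res$k_used[3], 13L)
  expect_equal(res$k_used[-3], rep(14L, 11))
  expect_error(cohort_variability(bat, missing = "available", min_k = 14),
               "min_k")
})
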