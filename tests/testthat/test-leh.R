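obs_row <- function(cej, height, wear, id = "A", idx = 1L) {
  data.frame(specimen_id = id, defect_index = idx, cej_distance_mm = cej,
             crown_height_mm = height, wear_grade = wear,
             stringsAsFactors = FALSE)
}

test_that("wear grades map to the stated crown-height fractions", {
  expect_equal(wearFraction(0:2), c(0, 0.05, 0.10))
  expect_true(is.na(wearFraction(3)))
  expect_true(is.na(wearFraction(8)))
  expect_error(wearFraction(-1), ">= 0")
})

test_that("onset estimation hits the calibration boundaries and worked case", {
  cal <- crownCalibration()
  # defect at the CEJ: onset at the end of crown formation
  expect_equal(estimateOnsetAge(obs_row(0, 10, 0), cal)$onset_age_years, 6.5)
  # defect at the reconstructed cusp tip: onset at the start
  expect_equal(estimateOnsetAge(obs_row(9.5 / 0.95, 9.5, 1), cal)$onset_age_years,
               1.5, tolerance = 1e-9)
  # worked example: height 9.0 mm, grade 1, defect 4.0 mm above the CEJ
  est <- estimateOnsetAge(obs_row(4.0, 9.0, 1), cal)
  expect_equal(est$onset_age_years, 4.3889, tolerance = 1e-4)
  # wear above grade 2 is excluded, not estimated
  worn <- estimateOnsetAge(obs_row(4.0, 9.0, 5), cal)
  expect_true(is.na(worn$onset_age_years))
  expect_identical(worn$excluded_reason, "wear > grade 2")
  # a defect beyond the reconstructed crown is an error
  expect_error(estimateOnsetAge(obs_row(11, 10, 0), cal), "exceeds")
})

test_that("defects closer to the CEJ never yield younger onsets", {
  cal <- crownCalibration()
  d <- seq(0, 9, by = 0.5)
  ages <- estimateOnsetAge(
    do.call(rbind, lapply(seq_along(d), function(i)
      obs_row(d[i], 9.5, 1, idx = i))), cal)$onset_age_years
  expect_true(all(diff(ages) < 0))  # larger distance from CEJ -> younger
  expect_true(all(ages >= 1.5 & ages <= 6.5))
})

test_that("generated CEJ distances invert back to the true onsets", {
  cal <- crownCalibration()
  sim <- simulateLEH(rep(c("male", "female"), 10), seed = 8, p_affected = 1)
  est <- estimateOnsetAge(sim$observations, cal)
  keep <- !is.na(est$onset_age_years)
  expect_gt(sum(keep), 0)
  expect_equal(est$onset_age_years[keep], sim$truth$true_onset_years[keep],
               tolerance = 1e-9)
  expect_true(all(est$onset_age_years[keep] >= 1.5 &
                  est$onset_age_years[keep] <= 6.5))
})

test_that("a plug-in non-linear calibration round-trips through its inverse", {
  cal <- crownCalibration(mapping = function(f) 1.5 + 5 * f^1.3)
  ages <- c(1.5, 2.9, 4.4, 6.5)
  expect_equal(cal$to_age(cal$to_fraction(ages)), ages, tolerance = 1e-8)
})

test_that("prevalence bookkeeping matches the published cohort counts", {
  # 23 females (15 affected), 12 males (9 affected), 1 probable female
  # without defects; overall prevalence is computed over all 36
  ids <- sprintf("I%02d", 1:36)
  sexes <- rep(c("female", "male", "probable_female"), c(23, 12, 1))
  sc <- calls_df(ids, sexes)
  affected <- c(ids[1:15], ids[24:32])
  obs <- data.frame(specimen_id = affected, defect_index = 1L,
                    cej_distance_mm = 4, crown_height_mm = 9, wear_grade = 0,
                    stringsAsFactors = FALSE)
  expect_message(prev <- lehPrevalence(obs, sc), "excluded")
  expect_equal(round(100 * prev$overall$proportion), 67)
  expect_equal(round(100 * prev$female$proportion), 65)
  expect_equal(round(100 * prev$male$proportion), 75)
  expect_identical(prev$overall$n_affected, 24L)
  expect_identical(prev$excluded_n, 1L)

  # defect-count distribution
  obs3 <- data.frame(specimen_id = rep(ids[1], 3), defect_index = 1:3,
                     cej_distance_mm = 4, crown_height_mm = 9,
                     wear_grade = 0, stringsAsFactors = FALSE)
  prev3 <- suppressMessages(lehPrevalence(obs3, sc))
  expect_identical(unname(prev3$female$defect_counts), c(0L, 0L, 1L))

  # no observations at all
  prev0 <- suppressMessages(lehPrevalence(obs3[0, ], sc))
  expect_identical(prev0$overall$n_affected, 0L)
  expect_equal(prev0$overall$proportion, 0)
})

test_that("onset summaries compare the sexes with the expected t behaviour", {
  ids <- sprintf("I%02d", 1:8)
  sc <- calls_df(ids, rep(c("female", "male"), each = 4))
  est <- data.frame(specimen_id = ids, defect_index = 1L,
                    onset_age_years = rep(c(3.0, 3.5, 4.0, 4.5), 2),
                    stringsAsFactors = FALSE)
  res <- onsetSummary(est, sc)
  expect_equal(res$female$mean, res$male$mean)
  expect_equal(res$test$t, 0)
  expect_equal(res$test$p_value, 1)

  # earliest defect represents a multi-defect individual
  est2 <- rbind(est, data.frame(specimen_id = ids[1], defect_index = 2L,
                                onset_age_years = 2.0))
  res2 <- onsetSummary(est2, sc)
  expect_equal(res2$female$min, 2.0)

  # too few estimable individuals: summary without test
  res3 <- onsetSummary(est[c(1, 5), ], sc)
  expect_null(res3$test)
})

test_that("sex-specific onset means are recovered from synthetic cohorts", {
  cal <- crownCalibration()
  set.seed(17)
  mk <- function(n, mu, prefix) {
    onset <- qnorm(runif(n, pnorm(2.6, mu, 0.5), pnorm(4.6, mu, 0.5)), mu, 0.5)
    h0 <- rnorm(n, 11, 0.8)
    data.frame(specimen_id = sprintf("%s%02d", prefix, 1:n),
               defect_index = 1L,
               cej_distance_mm = h0 * (1 - cal$to_fraction(onset)),
               crown_height_mm = h0, wear_grade = 0,
               stringsAsFactors = FALSE)
  }
  obs <- rbind(mk(12, 3.5, "F"), mk(7, 3.9, "M"))
  sc <- calls_df(obs$specimen_id,
                 rep(c("female", "male"), c(12, 7)))
  res <- onsetSummary(estimateOnsetAge(obs, cal), sc)
  expect_equal(res$female$n, 12L)
  expect_equal(res$male$n, 7L)
  expect_lt(abs(res$female$mean - 3.5), 2 * 0.5 / sqrt(12))
  expect_lt(abs(res$male$mean - 3.9), 2 * 0.5 / sqrt(7))
  expect_true(res$test$p_value > 0 && res$test$p_value <= 1)
})
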