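#' Fraction of crown height lost to occlusal wear
#'
#' Wear is scored on the ordinal occlusal-attrition scale and converted to
#' a crown-height fraction: grade 0 means no loss, grade 1 a 5% loss,
#' grade 2 a 10% loss. Grades above 2 preclude defect-age estimation and
#' return `NA`.
#'
#' @param wear_grade integer vector of wear grades (>= 0).
#' @return numeric vector of fractions (0, 0.05, 0.10) or `NA` for grades
#'   above 2.
#' @export
wearFraction <- function(wear_grade) {
  if (any(wear_grade < 0)) stop("wear grade must be >= 0", call. = FALSE)
  out <- rep(NA_real_, length(wear_grade))
  out[wear_grade == 0] <- 0
  out[wear_grade == 1] <- 0.05
  out[wear_grade == 2] <- 0.10
  out
}

#' Crown formation-age calibration
#'
#' Maps a defect's position on the crown (fraction of reconstructed crown
#' height from the cusp tip, 0 = cusp, 1 = cementum-enamel junction) to an
#' age of onset. Canine crown enamel mineralizes between about 1.5 years
#' (cusp) and 6.5 years (CEJ); the default mapping interpolates linearly
#' between those ages. Literature regression calibrations can be plugged in
#' as any monotone-increasing fraction-to-age function; the inverse (used
#' by the synthetic generator) is solved numerically for non-linear
#' mappings.
#'
#' @param age_at_cusp age (years) at which crown formation starts.
#' @param age_at_cej age (years) at which enamel reaches the CEJ; must
#'   exceed `age_at_cusp`.
#' @param mapping optional monotone-increasing function from position
#'   fraction in \[0, 1\] to age in years; default is linear interpolation.
#' @return list with `age_at_cusp`, `age_at_cej`, `to_age(fraction)` and
#'   `to_fraction(age)` (class `"crownCalibration"`).
#' @export
crownCalibration <- function(age_at_cusp = 1.5, age_at_cej = 6.5,
                             mapping = NULL) {
  if (age_at_cej <= age_at_cusp)
    stop("age_at_cej must exceed age_at_cusp", call. = FALSE)
  if (is.null(mapping)) {
    to_age <- function(f) age_at_cusp + f * (age_at_cej - age_at_cusp)
    to_fraction <- function(a) (a - age_at_cusp) / (age_at_cej - age_at_cusp)
  } else {
    to_age <- mapping
    to_fraction <- function(a) vapply(a, function(ai)
      stats::uniroot(function(f) mapping(f) - ai, c(0, 1),
                     tol = 1e-12)$root, numeric(1))
  }
  structure(list(age_at_cusp = age_at_cusp, age_at_cej = age_at_cej,
                 to_age = to_age, to_fraction = to_fraction),
            class = "crownCalibration")
}

#' Estimate age of onset for enamel defects
#'
#' For each observation with wear grade at most 2, the unworn crown height
#' is reconstructed as `H0 = measured_height / (1 - wear_fraction)` (wear
#' removes height from the cusp end only), the defect's position fraction
#' from the cusp is `f = (H0 - cej_distance) / H0`, and the onset age is
#' `calibration$to_age(f)`. Observations with wear above grade 2 are
#' excluded with a reason rather than estimated.
#'
#' @param observations data.frame with columns `specimen_id`,
#'   `defect_index`, `cej_distance_mm`, `crown_height_mm`, `wear_grade`.
#' @param calibration a [crownCalibration()].
#' @return the observations with added `onset_age_years` (NA when
#'   excluded) and `excluded_reason` ("" when estimated).
#' @export
estimateOnsetAge <- function(observations, calibration = crownCalibration()) {
  d <- observations
  if (any(d$cej_distance_mm < 0) || any(d$crown_height_mm <= 0))
    stop("distances must be >= 0 and crown heights > 0", call. = FALSE)
  w <- wearFraction(d$wear_grade)
  h0 <- d$crown_height_mm / (1 - w)
  est <- !is.na(w)
  if (any(est & d$cej_distance_mm > h0 + 1e-9))
    stop("CEJ distance exceeds reconstructed crown height", call. = FALSE)
  f <- (h0 - d$cej_distance_mm) / h0
  d$onset_age_years <- ifelse(est, calibration$to_age(f), NA_real_)
  d$excluded_reason <- ifelse(est, "", "wear > grade 2")
  d
}

#' Per-sex prevalence of enamel defects
#'
#' Counts, per individual, the presence of at least one defect and the
#' distribution of defect counts (1, 2, 3 or more). The overall summary
#' covers every individual in `sex_calls`; the per-sex split covers only
#' confidently sexed individuals, with probable-female and undetermined
#' specimens excluded from it with a logged count.
#'
#' @param observations data.frame of defect observations (one row per
#'   defect) with `specimen_id`; individuals absent from it are counted as
#'   unaffected.
#' @param sex_calls data.frame with `specimen_id` and `call`.
#' @return list with one element per sex (`female`, `male`) and `overall`,
#'   each a list of `n`, `n_affected`, `proportion`, `defect_counts`
#'   (named counts for "1", "2", "3+"); plus `excluded_n` (individuals
#'   absent from the per-sex split).
#' @export
lehPrevalence <- function(observations, sex_calls) {
  conf <- sex_calls$call %in% c("male", "female")
  excluded <- sum(!conf)
  if (excluded > 0)
    message(excluded, " specimen(s) without confident sex call excluded ",
            "from the per-sex split")
  per_ind <- table(factor(observations$specimen_id,
                          levels = sex_calls$specimen_id))
  summarise <- function(ids) {
    cnt <- per_ind[ids]
    affected <- cnt > 0
    list(n = length(ids), n_affected = sum(affected),
         proportion = if (length(ids)) sum(affected) / length(ids) else 0,
         defect_counts = c(`1` = sum(cnt == 1), `2` = sum(cnt == 2),
                           `3+` = sum(cnt >= 3)))
  }
  list(female = summarise(sex_calls$specimen_id[conf & sex_calls$call == "female"]),
       male = summarise(sex_calls$specimen_id[conf & sex_calls$call == "male"]),
       overall = summarise(sex_calls$specimen_id),
       excluded_n = excluded)
}

#' Per-sex summary and comparison of onset ages
#'
#' Each individual contributes one onset age (by default the earliest of
#' its estimable defects). Reports mean, min, max and n per sex, and an
#' unpaired equal-variance Student's t-test between the sexes when both
#' have at least two individuals.
#'
#' @param estimates output of [estimateOnsetAge()].
#' @param sex_calls data.frame with `specimen_id` and `call`.
#' @param individual_summary how an individual with several estimable
#'   defects is represented: `"earliest"` (default), `"mean"` or
#'   `"latest"`.
#' @return list with `female` and `male` summaries (`mean`, `min`, `max`,
#'   `n`), and `test` (`t`, `p_value`) or `NULL` when either sex has fewer
#'   than two estimable individuals.
#' @export
onsetSummary <- function(estimates, sex_calls,
                         individual_summary = c("earliest", "mean", "latest")) {
  individual_summary <- match.arg(individual_summary)
  fun <- switch(individual_summary, earliest = min, mean = mean, latest = max)
  est <- estimates[!is.na(estimates$onset_age_years), , drop = FALSE]
  per_ind <- tapply(est$onset_age_years, est$specimen_id, fun)
  call_of <- sex_calls$call[match(names(per_ind), sex_calls$specimen_id)]
  summarise <- function(v) if (length(v))
    list(mean = mean(v), min = min(v), max = max(v), n = length(v))
  else list(mean = NA_real_, min = NA_real_, max = NA_real_, n = 0L)
  fem <- as.numeric(per_ind[call_of == "female" & !is.na(call_of)])
  mal <- as.numeric(per_ind[call_of == "male" & !is.na(call_of)])
  test <- if (length(fem) >= 2L && length(mal) >= 2L)
    studentsT(fem, mal) else NULL
  list(female = summarise(fem), male = summarise(mal), test = test)
}
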