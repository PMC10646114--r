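#' Configuration for the chromatogram generator
#'
#' Defaults describe a 65-minute gradient sampled at a 3-second MS1 cadence
#' with Gaussian elution peaks of sigma 0.15 min, 1 ppm mass error on
#' marker centroids, 25 uniform noise centroids per scan, and a faint
#' in-window chemical baseline centroid per marker per scan (present in all
#' profiles, including blanks) so that extracted traces carry a realistic
#' non-zero baseline for noise estimation.
#'
#' @param seed integer seed; mandatory, every draw in the generator is
#'   derived from it.
#' @param run_length_min gradient length in minutes.
#' @param scan_interval_s MS1 scan interval in seconds.
#' @param peak_sigma_min Gaussian elution peak sigma in minutes.
#' @param rt_jitter_min per-run s.d. of the elution-time shift around each
#'   marker's nominal time (minutes).
#' @param ppm_error_sd s.d. of the mass error applied to marker centroids
#'   (ppm).
#' @param noise_points_per_scan number of random noise centroids per scan.
#' @param noise_intensity,noise_mz_range uniform ranges for noise centroid
#'   intensity (counts) and m/z.
#' @param baseline_intensity uniform intensity range of the per-marker
#'   chemical baseline centroid (counts).
#' @param baseline_ppm_sd s.d. of the baseline centroid's mass offset from
#'   the marker m/z (ppm).
#' @return validated list of class `"generatorConfig"`.
#' @export
generatorConfig <- function(seed, run_length_min = 65, scan_interval_s = 3,
                            peak_sigma_min = 0.15, rt_jitter_min = 0.2,
                            ppm_error_sd = 1, noise_points_per_scan = 25,
                            noise_intensity = c(50, 500),
                            noise_mz_range = c(300, 1000),
                            baseline_intensity = c(50, 200),
                            baseline_ppm_sd = 1.5) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  for (nm in c("run_length_min", "scan_interval_s", "peak_sigma_min",
               "rt_jitter_min", "ppm_error_sd"))
    .stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  structure(list(seed = as.integer(seed), run_length_min = run_length_min,
                 scan_interval_s = scan_interval_s,
                 peak_sigma_min = peak_sigma_min,
                 rt_jitter_min = rt_jitter_min, ppm_error_sd = ppm_error_sd,
                 noise_points_per_scan = as.integer(noise_points_per_scan),
                 noise_intensity = noise_intensity,
                 noise_mz_range = noise_mz_range,
                 baseline_intensity = baseline_intensity,
                 baseline_ppm_sd = baseline_ppm_sd),
            class = "generatorConfig")
}

# per-profile apex intensity bands (counts, log-uniform draws);
# female/degraded/blank emit no AMELY signal by construction
.profileBands <- function(profile) {
  switch(profile,
    male = list(AMELY = c(1e5, 1e6), AMELX = c(1e6, 1e7),
                AMELXY_shared = c(3e5, 3e6), ENAM = c(3e5, 3e6)),
    female = list(AMELX = c(1e6, 1e7),
                  AMELXY_shared = c(3e5, 3e6), ENAM = c(3e5, 3e6)),
    degraded = list(AMELX = c(5e4, 5e5),
                    AMELXY_shared = c(1e4, 1e5), ENAM = c(1e4, 1e5)),
    blank = list(),
    stop("unknown profile: ", profile, call. = FALSE))
}

.runif_log <- function(n, range) 10^stats::runif(n, log10(range[1]), log10(range[2]))

#' Simulate one LC-MS run
#'
#' Generates a run of centroided MS1 scans at a fixed scan interval. Each
#' marker emitted under the sample profile contributes a Gaussian elution
#' peak: its apex intensity is drawn log-uniformly from the profile's band
#' (male: AMELY plus AMELX; female: AMELX only at 1e6-1e7 counts; degraded:
#' attenuated AMELX at 5e4-5e5 counts; blank: background only), its elution
#' time is the marker's nominal time plus a per-run jitter, and its
#' centroids carry Gaussian ppm mass error. Uniform noise centroids and a
#' faint per-marker baseline centroid are added to every scan. The drawn
#' ground truth (profile, per-marker apex and elution time) is stored in
#' the run's `metadata`.
#'
#' @param profile one of `"male"`, `"female"`, `"degraded"`, `"blank"`.
#' @param panel a [MarkerPanel-class]; its `rt_min` column supplies nominal
#'   elution times (markers without one get a deterministic spread across
#'   the mid-gradient).
#' @param config a [generatorConfig()]; all randomness derives from its
#'   seed.
#' @param sample_id sample identifier for the run.
#' @return an [MSRun-class] with ground truth in `metadata`.
#' @export
simulateRun <- function(profile, panel = defaultPanel(), config,
                        sample_id = profile) {
  stopifnot(inherits(config, "generatorConfig"))
  profile <- match.arg(profile, c("male", "female", "degraded", "blank"))
  m <- markerTable(panel)
  nominal_rt <- m$rt_min
  nominal_rt[is.na(nominal_rt)] <-
    seq(0.25, 0.75, length.out = sum(is.na(nominal_rt))) * config$run_length_min
  .withSeed(config$seed, {
    dt <- config$scan_interval_s / 60
    rt <- seq(dt, config$run_length_min, by = dt)
    ns <- length(rt)
    bands <- .profileBands(profile)
    emitted <- m$specificity %in% names(bands)
    apex <- rep(NA_real_, nrow(m))
    peak_rt <- rep(NA_real_, nrow(m))
    mz_all <- int_all <- numeric(0)
    scan_all <- integer(0)
    for (i in which(emitted)) {
      apex[i] <- .runif_log(1, bands[[m$specificity[i]]])
      peak_rt[i] <- nominal_rt[i] + stats::rnorm(1, 0, config$rt_jitter_min)
      shape <- apex[i] *
        exp(-(rt - peak_rt[i])^2 / (2 * config$peak_sigma_min^2))
      on <- which(shape >= 1)
      if (!length(on)) next
      mz_all <- c(mz_all, m$mz[i] *
                    (1 + stats::rnorm(length(on), 0, config$ppm_error_sd) * 1e-6))
      int_all <- c(int_all, shape[on])
      scan_all <- c(scan_all, on)
    }
    # per-marker chemical baseline, every scan, all profiles
    for (i in seq_len(nrow(m))) {
      mz_all <- c(mz_all, m$mz[i] *
                    (1 + stats::rnorm(ns, 0, config$baseline_ppm_sd) * 1e-6))
      int_all <- c(int_all, stats::runif(ns, config$baseline_intensity[1],
                                         config$baseline_intensity[2]))
      scan_all <- c(scan_all, seq_len(ns))
    }
    # unstructured noise centroids
    nn <- config$noise_points_per_scan
    if (nn > 0) {
      mz_all <- c(mz_all, stats::runif(ns * nn, config$noise_mz_range[1],
                                       config$noise_mz_range[2]))
      int_all <- c(int_all, stats::runif(ns * nn, config$noise_intensity[1],
                                         config$noise_intensity[2]))
      scan_all <- c(scan_all, rep(seq_len(ns), each = nn))
    }
    ord <- order(scan_all, mz_all)
    mz_all <- mz_all[ord]; int_all <- int_all[ord]; scan_all <- scan_all[ord]
    idx <- split(seq_along(scan_all), factor(scan_all, levels = seq_len(ns)))
    pk <- lapply(idx, function(j)
      cbind(mz = mz_all[j], intensity = int_all[j]))
    names(pk) <- NULL
    truth <- data.frame(marker_label = m$label, emitted = emitted,
                        true_apex = apex, true_rt = peak_rt,
                        stringsAsFactors = FALSE)
    MSRun(sampleId = sample_id, rtime = rt, peaks = pk,
          gradientLength = config$run_length_min,
          metadata = list(profile = profile, truth = truth,
                          seed = config$seed))
  })
}

#' Simulate a cohort of runs plus an extraction blank
#'
#' One run per profile label plus one blank, each from its own sub-seed
#' derived deterministically from `config$seed`, with a ground-truth table.
#'
#' @param labels character vector of profiles (`"male"`, `"female"`,
#'   `"degraded"`).
#' @param panel a [MarkerPanel-class].
#' @param config a [generatorConfig()].
#' @param sample_ids optional ids (default `"S001"`, ...).
#' @return list with `runs` (named list of [MSRun-class]), `blank`
#'   (an [MSRun-class]) and `truth` (data.frame `sample_id`, `profile`).
#' @export
simulateCohort <- function(labels, panel = defaultPanel(), config,
                           sample_ids = NULL) {
  if (!length(labels)) stop("labels must be non-empty", call. = FALSE)
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_along(labels))
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique", call. = FALSE)
  subseeds <- .withSeed(config$seed,
                        sample.int(.Machine$integer.max - 1L,
                                   length(labels) + 1L))
  runs <- lapply(seq_along(labels), function(i) {
    cfg <- config; cfg$seed <- subseeds[i]
    simulateRun(labels[i], panel, cfg, sample_id = sample_ids[i])
  })
  names(runs) <- sample_ids
  cfg_blank <- config; cfg_blank$seed <- subseeds[length(subseeds)]
  blank <- simulateRun("blank", panel, cfg_blank, sample_id = "blank")
  list(runs = runs, blank = blank,
       truth = data.frame(sample_id = sample_ids, profile = labels,
                          stringsAsFactors = FALSE))
}

#' Simulate a repeated odontometric measurement table
#'
#' Per-specimen true buccolingual diameters are drawn from sex-specific
#' normal distributions; each observer x session yields three repeats with
#' independent zero-mean measurement error. True diameters and sexes are
#' returned as ground truth.
#'
#' @param sex_labels character vector of true sexes (`"male"`/`"female"`).
#' @param specimen_ids optional ids (default `"T001"`, ...).
#' @param seed integer seed.
#' @param female_mean_mm,male_mean_mm sex-specific mean diameters (mm).
#' @param between_sd_mm between-specimen s.d. (mm).
#' @param repeat_sd_mm repeat measurement error s.d. (mm).
#' @param observers,sessions observer ids and session numbers.
#' @return list with `measurements` (data.frame `specimen_id`,
#'   `observer_id`, `session`, `rep1_mm`..`rep3_mm`) and `truth`
#'   (data.frame `specimen_id`, `sex`, `true_diameter_mm`).
#' @export
simulateOdontometry <- function(sex_labels, specimen_ids = NULL, seed,
                                female_mean_mm = 7.30, male_mean_mm = 7.95,
                                between_sd_mm = 0.35, repeat_sd_mm = 0.05,
                                observers = c("RG", "DG"), sessions = 1:2) {
  if (is.null(specimen_ids))
    specimen_ids <- sprintf("T%03d", seq_along(sex_labels))
  .withSeed(seed, {
    mu <- ifelse(sex_labels == "male", male_mean_mm, female_mean_mm)
    true_d <- stats::rnorm(length(mu), mu, between_sd_mm)
    grid <- expand.grid(specimen = seq_along(specimen_ids),
                        observer_id = observers, session = sessions,
                        stringsAsFactors = FALSE)
    reps <- matrix(stats::rnorm(3L * nrow(grid), true_d[grid$specimen],
                                repeat_sd_mm),
                   ncol = 3L)
    measurements <- data.frame(
      specimen_id = specimen_ids[grid$specimen],
      observer_id = grid$observer_id, session = grid$session,
      rep1_mm = reps[, 1], rep2_mm = reps[, 2], rep3_mm = reps[, 3],
      stringsAsFactors = FALSE)
    list(measurements = measurements,
         truth = data.frame(specimen_id = specimen_ids, sex = sex_labels,
                            true_diameter_mm = true_d,
                            stringsAsFactors = FALSE))
  })
}

# truncated-normal draws via inverse CDF
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a linear enamel hypoplasia observation table
#'
#' Individuals are affected with probability `p_affected`; affected
#' individuals carry 1-3 defects. Each defect's true onset age is drawn
#' from a truncated normal, inverted through the crown calibration to a
#' CEJ distance on an unworn crown of specimen-specific height, and the
#' recorded crown height is reduced by the sampled wear grade's height
#' fraction (grades above 2 make the defect non-estimable downstream, as
#' in real material).
#'
#' @param sex_labels character vector of true sexes.
#' @param specimen_ids optional ids.
#' @param seed integer seed.
#' @param calibration a [crownCalibration()].
#' @param p_affected probability an individual has at least one defect.
#' @param defect_probs probabilities of 1, 2, 3 defects given affected.
#' @param onset_mean,onset_sd,onset_range truncated-normal parameters for
#'   the true onset age (years).
#' @param wear_probs sampling probabilities of wear grades 0, 1, 2, 3.
#' @param crown_height_mean,crown_height_sd unworn crown height (mm).
#' @return list with `observations` (data.frame `specimen_id`,
#'   `defect_index`, `cej_distance_mm`, `crown_height_mm`, `wear_grade`)
#'   and `truth` (adds `true_onset_years`, `sex`).
#' @export
simulateLEH <- function(sex_labels, specimen_ids = NULL, seed,
                        calibration = crownCalibration(),
                        p_affected = 0.67,
                        defect_probs = c(0.58, 0.25, 0.17),
                        onset_mean = 3.6, onset_sd = 0.5,
                        onset_range = c(2.6, 4.6),
                        wear_probs = c(0.30, 0.25, 0.20, 0.25),
                        crown_height_mean = 11, crown_height_sd = 0.8) {
  if (is.null(specimen_ids))
    specimen_ids <- sprintf("T%03d", seq_along(sex_labels))
  .withSeed(seed, {
    affected <- stats::runif(length(specimen_ids)) < p_affected
    n_def <- integer(length(specimen_ids))
    n_def[affected] <- sample(1:3, sum(affected), replace = TRUE,
                              prob = defect_probs)
    wear <- sample(0:3, length(specimen_ids), replace = TRUE,
                   prob = wear_probs)
    h0 <- stats::rnorm(length(specimen_ids), crown_height_mean,
                       crown_height_sd)
    rows <- lapply(which(n_def > 0), function(i) {
      onset <- .rtruncnorm(n_def[i], onset_mean, onset_sd,
                           onset_range[1], onset_range[2])
      f <- calibration$to_fraction(onset)
      w <- wear[i]
      wf <- if (w <= 2) wearFraction(w) else 0.15
      data.frame(specimen_id = specimen_ids[i],
                 defect_index = seq_len(n_def[i]),
                 cej_distance_mm = h0[i] * (1 - f),
                 crown_height_mm = h0[i] * (1 - wf),
                 wear_grade = w, true_onset_years = onset,
                 sex = sex_labels[i], stringsAsFactors = FALSE)
    })
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(specimen_id = character(), defect_index = integer(),
                 cej_distance_mm = numeric(), crown_height_mm = numeric(),
                 wear_grade = integer(), true_onset_years = numeric(),
                 sex = character(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    obs_cols <- c("specimen_id", "defect_index", "cej_distance_mm",
                  "crown_height_mm", "wear_grade")
    list(observations = truth[, obs_cols], truth = truth)
  })
}

#' Complete synthetic cohort mirroring the Escoural Cave assemblage
#'
#' A 36-individual cohort with the published count structure — inside the
#' cave 8 male-profile, 21 female-profile and 1 degraded-profile runs;
#' outside the cave 4 male- and 2 female-profile runs — plus an extraction
#' blank, an odontometric measurement table and an LEH observation table
#' for the same individuals, all with ground truth. The structure (counts,
#' contexts) is fixed; the raw signals vary with the seed. The degraded
#' individual's true sex is female.
#'
#' @param seed integer seed.
#' @param panel a [MarkerPanel-class].
#' @param config optional [generatorConfig()] (its seed is overridden by
#'   `seed`).
#' @return list: `specimens` (data.frame `specimen_id`, `context`,
#'   `profile`, `true_sex`), `runs`, `blank`, `truth` (chromatogram ground
#'   truth), `odontometry` and `leh` (each with `measurements`/
#'   `observations` and `truth`), `panel`, `config`.
#' @export
escouralFixture <- function(seed, panel = defaultPanel(), config = NULL) {
  if (is.null(config)) config <- generatorConfig(seed = seed)
  config$seed <- as.integer(seed)
  specimens <- data.frame(
    specimen_id = sprintf("ESC%03d", 1:36),
    context = c(rep("inside", 30), rep("outside", 6)),
    profile = c(rep("male", 8), rep("female", 21), "degraded",
                rep("male", 4), rep("female", 2)),
    stringsAsFactors = FALSE)
  specimens$true_sex <- ifelse(specimens$profile == "male", "male", "female")
  cohort <- simulateCohort(specimens$profile, panel, config,
                           sample_ids = specimens$specimen_id)
  odo <- simulateOdontometry(specimens$true_sex, specimens$specimen_id,
                             seed = config$seed + 1L)
  leh <- simulateLEH(specimens$true_sex, specimens$specimen_id,
                     seed = config$seed + 2L)
  list(specimens = specimens, runs = cohort$runs, blank = cohort$blank,
       truth = cohort$truth, odontometry = odo, leh = leh,
       panel = panel, config = config)
}
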