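#' Median of a triplicate diameter measurement
#'
#' Buccolingual diameters are measured three times and only the median is
#' carried into analysis, damping single-reading slips.
#'
#' @param repeats numeric vector of exactly three measurements (mm).
#' @return the middle order statistic (mm).
#' @export
medianDiameter <- function(repeats) {
  if (length(repeats) != 3L || anyNA(repeats))
    stop("exactly three repeat measurements are required", call. = FALSE)
  stats::median(repeats)
}

#' Per-specimen median diameters from a measurement table
#'
#' @param measurements data.frame with columns `specimen_id`, `observer_id`,
#'   `session`, `rep1_mm`, `rep2_mm`, `rep3_mm`.
#' @param observer,session optional filters selecting one observer and/or
#'   session before taking medians.
#' @return data.frame with columns `specimen_id`, `diameter_mm`.
#' @export
medianDiameters <- function(measurements, observer = NULL, session = NULL) {
  d <- measurements
  if (!is.null(observer)) d <- d[d$observer_id == observer, , drop = FALSE]
  if (!is.null(session)) d <- d[d$session == session, , drop = FALSE]
  if (!nrow(d)) stop("no measurements left after filtering", call. = FALSE)
  med <- apply(d[, c("rep1_mm", "rep2_mm", "rep3_mm")], 1, stats::median)
  agg <- tapply(med, d$specimen_id, stats::median)
  data.frame(specimen_id = names(agg), diameter_mm = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Odontometric sex classification by diameter cut-off
#'
#' Diameters strictly above the cut-off classify as male, at or below as
#' female. The reference cut-off of 7.73 mm for the lower permanent canine
#' buccolingual diameter comes from a recent Portuguese reference
#' population. A diameter exactly at the cut-off classifies female: the
#' reference rule is "larger than the cut-off is male", which also matches
#' the observed error direction when the reference population is larger
#' toothed than the study population (males leak into the female class).
#'
#' @param diameter_mm numeric vector of diameters (mm, > 0).
#' @param cutoff_mm discriminating cut-off in mm (default 7.73).
#' @return character vector of `"male"` / `"female"`.
#' @export
classifyByCutoff <- function(diameter_mm, cutoff_mm = 7.73) {
  if (cutoff_mm <= 0) stop("cutoff must be positive", call. = FALSE)
  if (any(diameter_mm <= 0)) stop("diameters must be positive", call. = FALSE)
  ifelse(diameter_mm > cutoff_mm, "male", "female")
}

#' Sample-specific cut-off candidates
#'
#' Two means usable as sample-specific discriminating cut-offs: the grand
#' mean of the median diameters (sex pooled mean) and the unweighted
#' average of the two sex-specific means (which removes the influence of an
#' unbalanced sex ratio). Samples below 40 specimens are flagged: below
#' that size a sample-specific cut-off is not recommended.
#'
#' @param diameters numeric vector of per-specimen median diameters (mm).
#' @param sex_labels character vector (`"male"`/`"female"`) aligned to
#'   `diameters`; required for the sex-weighted variant.
#' @return list with `pooled_mean`, `sex_weighted_mean`, `n`,
#'   `small_sample_warning` (TRUE when n < 40).
#' @export
sampleSpecificCutoffs <- function(diameters, sex_labels = NULL) {
  if (!length(diameters)) stop("diameters must be non-empty", call. = FALSE)
  pooled <- mean(diameters)
  weighted <- NA_real_
  if (!is.null(sex_labels)) {
    if (length(sex_labels) != length(diameters))
      stop("sex_labels must be aligned to diameters", call. = FALSE)
    if (!all(c("male", "female") %in% sex_labels))
      stop("sex-weighted mean needs both male and female specimens",
           call. = FALSE)
    weighted <- (mean(diameters[sex_labels == "male"]) +
                 mean(diameters[sex_labels == "female"])) / 2
  }
  list(pooled_mean = pooled, sex_weighted_mean = weighted,
       n = length(diameters), small_sample_warning = length(diameters) < 40)
}

#' Technical error of measurement between two measurement series
#'
#' Classical two-series TEM for intra-observer (session 1 vs session 2) or
#' inter-observer comparisons:
#' `TEM = sqrt(sum((a_i - b_i)^2) / (2n))`;
#' `%TEM = 100 * TEM / mean(c(a, b))`; the coefficient of reliability is
#' `R = 1 - TEM^2 / s^2` with `s^2` the variance of all `2n` values. A
#' %TEM below 2% and R of at least 0.93 are conventional benchmarks for
#' replicable odontometric measurement.
#'
#' @param series_a,series_b paired numeric vectors of equal length
#'   (n >= 2), same specimens in the same order.
#' @return list: `tem_mm`, `percent_tem`, `reliability_R`, `n_pairs`.
#' @export
temStats <- function(series_a, series_b) {
  n <- length(series_a)
  if (length(series_b) != n) stop("series must have equal length", call. = FALSE)
  if (n < 2L) stop("at least two pairs are required", call. = FALSE)
  tem <- sqrt(sum((series_a - series_b)^2) / (2 * n))
  all_vals <- c(series_a, series_b)
  list(tem_mm = tem,
       percent_tem = 100 * tem / mean(all_vals),
       reliability_R = 1 - tem^2 / stats::var(all_vals),
       n_pairs = n)
}

# kappa from a 2x2 (or kxk) contingency table of matched calls
.kappaFromTable <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Agreement between peptide and odontometric sex estimates
#'
#' Cross-tabulates the two call sets over shared specimens (confident
#' peptide calls only: probable-female and undetermined specimens are
#' excluded with a logged count), and reports the confusion matrix (rows =
#' peptide sex F/M, columns = odontometric sex F/M), overall and per-class
#' accuracy, and Cohen's kappa. The kappa significance p-value is obtained
#' by a permutation test (label shuffles of the odontometric calls; one
#' sided, large kappa), since the reference analyses do not state an
#' asymptotic method.
#'
#' @param peptide_calls data.frame with `specimen_id` and `call`
#'   (`"male"`/`"female"`/`"probable_female"`/`"undetermined"`), e.g. the
#'   `calls` element of [callBatch()].
#' @param odontometric_calls data.frame with `specimen_id` and `call`
#'   (`"male"`/`"female"`), e.g. from [classifyByCutoff()].
#' @param n_perm number of label permutations for the kappa p-value
#'   (default 10000); uses the current RNG stream, so set a seed for
#'   reproducibility.
#' @return list: `matrix` (2x2 confusion counts), `accuracy`, `per_class`
#'   (named accuracy within peptide-female and peptide-male), `kappa`,
#'   `kappa_p`, `excluded_n`, `n`.
#' @export
sexAgreement <- function(peptide_calls, odontometric_calls, n_perm = 10000) {
  common <- intersect(peptide_calls$specimen_id,
                      odontometric_calls$specimen_id)
  if (!length(common)) stop("no shared specimens", call. = FALSE)
  pep <- peptide_calls$call[match(common, peptide_calls$specimen_id)]
  odo <- odontometric_calls$call[match(common, odontometric_calls$specimen_id)]
  keep <- pep %in% c("male", "female")
  excluded <- sum(!keep)
  if (excluded > 0)
    message(excluded, " specimen(s) without confident peptide call excluded")
  pep <- factor(pep[keep], levels = c("female", "male"))
  odo <- factor(odo[keep], levels = c("female", "male"))
  if (!length(pep)) stop("no confidently called shared specimens", call. = FALSE)
  tab <- table(peptide = pep, odontometric = odo)
  acc <- sum(diag(tab)) / sum(tab)
  per_class <- c(female = unname(tab["female", "female"] / sum(tab["female", ])),
                 male = unname(tab["male", "male"] / sum(tab["male", ])))
  kap <- .kappaFromTable(tab)
  perm <- vapply(seq_len(n_perm), function(i)
    .kappaFromTable(table(pep, sample(odo))), numeric(1))
  kappa_p <- (1 + sum(perm >= kap)) / (n_perm + 1)
  list(matrix = unclass(tab), accuracy = acc, per_class = per_class,
       kappa = kap, kappa_p = kappa_p, excluded_n = excluded,
       n = sum(tab))
}
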