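#' Sex ratio (males per female)
#'
#' @param n_male,n_female non-negative counts of confidently called males
#'   and females.
#' @return list with `value` (`n_male / n_female`, `NA` when undefined),
#'   `label` (`"x.xx:1"`, or `"undefined"`), `defined` (logical).
#'   A cohort with males but no females has no finite males-per-female
#'   ratio; it is reported as a distinct undefined state, not infinity.
#' @examples
#' sexRatio(12, 23)$label  # "0.52:1"
#' @export
sexRatio <- function(n_male, n_female) {
  if (n_male < 0 || n_female < 0) stop("counts must be >= 0", call. = FALSE)
  if (n_female == 0) {
    if (n_male == 0)
      return(list(value = NA_real_, label = "undefined", defined = FALSE))
    return(list(value = NA_real_, label = "undefined", defined = FALSE))
  }
  v <- n_male / n_female
  list(value = v, label = sprintf("%.2f:1", v), defined = TRUE)
}

#' Demographic sex-ratio bands
#'
#' Natural human cohort sex ratios fall between about 0.95 and 1.02 males
#' per female; ratios at or below 0.90 or at or above 1.05 are considered
#' extreme, the gaps in between intermediate.
#'
#' @return list with `natural` (`c(0.95, 1.02)`), `extreme_low` (0.90) and
#'   `extreme_high` (1.05).
#' @export
ratioBands <- function() {
  list(natural = c(0.95, 1.02), extreme_low = 0.90, extreme_high = 1.05)
}

#' Classify a sex ratio into a demographic band
#'
#' @param ratio males-per-female ratio (>= 0).
#' @param bands band definition from [ratioBands()].
#' @return one of `"extreme_low"`, `"intermediate_low"`, `"natural"`,
#'   `"intermediate_high"`, `"extreme_high"`.
#' @export
classifyRatio <- function(ratio, bands = ratioBands()) {
  .stopifnot_scalar_number(ratio, "ratio")
  if (ratio < 0) stop("ratio must be >= 0", call. = FALSE)
  if (ratio <= bands$extreme_low) "extreme_low"
  else if (ratio < bands$natural[1]) "intermediate_low"
  else if (ratio <= bands$natural[2]) "natural"
  else if (ratio < bands$extreme_high) "intermediate_high"
  else "extreme_high"
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (no continuity correction) with 1 degree
#' of freedom.
#'
#' @param tab 2x2 matrix of non-negative counts; no marginal may be zero.
#' @return list with `statistic`, `p_value`, `expected`.
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required", call. = FALSE)
  if (any(tab < 0) || sum(tab) == 0)
    stop("counts must be non-negative with positive total", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       expected = ct$expected)
}

#' Unpaired equal-variance Student's t-test
#'
#' Two-sided, pooled-variance two-sample t-test. When the pooled variance
#' is exactly zero the test statistic is undefined: identical means report
#' `t = 0, p = 1`, and complete separation is reported as an
#' exact-separation signal (`t = +/-Inf`, `p = 0`) rather than an error.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t`, `p_value`, `df`, and `note` (non-empty for the
#'   degenerate zero-variance case).
#' @export
studentsT <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs at least two values", call. = FALSE)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    d <- mean(sample_a) - mean(sample_b)
    if (d == 0)
      return(list(t = 0, p_value = 1,
                  df = length(sample_a) + length(sample_b) - 2L,
                  note = "zero pooled variance, equal means"))
    return(list(t = sign(d) * Inf, p_value = 0,
                df = length(sample_a) + length(sample_b) - 2L,
                note = "exact separation (zero pooled variance)"))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), note = "")
}

#' Assemble a cohort sex profile
#'
#' Per-context and total counts of male, female and probable-female calls,
#' with the males-per-female ratio (confident calls only; probable females
#' are reported as their own column, never in the ratio) and its
#' demographic band. Externally sexed individuals (e.g. by hip-bone
#' morphology) can be appended to produce an overall row.
#'
#' @param specimens data.frame with `specimen_id`, `context` (e.g.
#'   `"inside"` / `"outside"`) and `call`.
#' @param external optional data.frame with `specimen_id` and `sex`
#'   (`"male"`/`"female"`) of individuals sexed by other means.
#' @param bands band definition from [ratioBands()].
#' @return data.frame with one row per context plus `"total"` (and
#'   `"overall"` when `external` is given): columns `context`, `n_male`,
#'   `n_female`, `n_probable_female`, `ratio`, `ratio_label`, `band`.
#' @export
assembleProfile <- function(specimens, external = NULL, bands = ratioBands()) {
  if (anyDuplicated(specimens$specimen_id))
    stop("specimen ids must be unique", call. = FALSE)
  mk_row <- function(ctx, m, f, pf) {
    r <- sexRatio(m, f)
    data.frame(context = ctx, n_male = m, n_female = f,
               n_probable_female = pf,
               ratio = if (r$defined) r$value else NA_real_,
               ratio_label = r$label,
               band = if (r$defined) classifyRatio(r$value, bands)
                      else NA_character_,
               stringsAsFactors = FALSE)
  }
  ctxs <- unique(specimens$context)
  rows <- lapply(ctxs, function(ctx) {
    s <- specimens[specimens$context == ctx, ]
    mk_row(ctx, sum(s$call == "male"), sum(s$call == "female"),
           sum(s$call == "probable_female"))
  })
  tot_m <- sum(specimens$call == "male")
  tot_f <- sum(specimens$call == "female")
  tot_pf <- sum(specimens$call == "probable_female")
  rows <- c(rows, list(mk_row("total", tot_m, tot_f, tot_pf)))
  if (!is.null(external) && nrow(external)) {
    rows <- c(rows, list(mk_row("overall",
                                tot_m + sum(external$sex == "male"),
                                tot_f + sum(external$sex == "female"),
                                tot_pf)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
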