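#' @import methods
NULL

#' MarkerPanel: a panel of sex-informative enamel peptides
#'
#' Ordered collection of marker peptides (amelogenin X/Y isoforms and
#' enamelin) with their modifications, charge states, protein specificity,
#' panel role and theoretical m/z. Construct with [MarkerPanel()] or use the
#' built-in [defaultPanel()].
#'
#' @slot markers data.frame with one row per marker: `label`, `sequence`,
#'   `mod_pos` (integer, `NA` if unmodified), `mod_name` (character, `NA` if
#'   unmodified), `charge` (integer), `specificity` (one of `"AMELX"`,
#'   `"AMELY"`, `"AMELXY_shared"`, `"ENAM"`), `role` (one of
#'   `"sex_diagnostic"`, `"shared_corroboration"`, `"preservation_qc"`),
#'   `rt_min` (expected elution time in minutes, `NA` if unknown) and `mz`
#'   (theoretical m/z).
#'
#' @aliases MarkerPanel-class
#' @exportClass MarkerPanel
setClass("MarkerPanel", representation(markers = "data.frame"))

.validMarkerPanel <- function(object) {
  m <- object@markers
  need <- c("label", "sequence", "mod_pos", "mod_name", "charge",
            "specificity", "role", "rt_min", "mz")
  msg <- character()
  if (!all(need %in% names(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$label))
    msg <- c(msg, "marker labels must be unique")
  if (any(m$charge < 1L))
    msg <- c(msg, "charge must be >= 1")
  ok_spec <- c("AMELX", "AMELY", "AMELXY_shared", "ENAM")
  if (!all(m$specificity %in% ok_spec))
    msg <- c(msg, paste("specificity must be one of:", paste(ok_spec, collapse = ", ")))
  ok_role <- c("sex_diagnostic", "shared_corroboration", "preservation_qc")
  if (!all(m$role %in% ok_role))
    msg <- c(msg, paste("role must be one of:", paste(ok_role, collapse = ", ")))
  if (!any(m$specificity == "AMELY" & m$role == "sex_diagnostic"))
    msg <- c(msg, "panel needs at least one AMELY-specific sex-diagnostic marker")
  if (!any(m$specificity == "AMELX" & m$role == "sex_diagnostic"))
    msg <- c(msg, "panel needs at least one AMELX-specific sex-diagnostic marker")
  if (length(msg)) msg else TRUE
}
setValidity("MarkerPanel", .validMarkerPanel)

#' MSRun: an LC-MS run of centroided MS1 scans
#'
#' In-memory model of a chromatographic run: an ordered series of centroided
#' MS1 scans, each a two-column `mz`/`intensity` matrix, with retention times
#' in minutes. Structural integrity (aligned lengths, matrix shape) is
#' enforced by the class; data-quality issues (unsorted m/z, negative
#' intensities, non-monotone retention times) are reported as findings by
#' [validateRun()] rather than as errors, so that problematic files can
#' still be inspected.
#'
#' @slot sampleId single character sample identifier.
#' @slot rtime numeric vector of retention times in minutes, one per scan.
#' @slot peaks list of numeric matrices (columns `mz`, `intensity`), one per
#'   scan; a scan may be empty (0 rows).
#' @slot gradientLength length of the chromatographic gradient in minutes.
#' @slot metadata free-form list (the synthetic generator stores its ground
#'   truth here).
#'
#' @aliases MSRun-class
#' @exportClass MSRun
setClass("MSRun", representation(
  sampleId = "character",
  rtime = "numeric",
  peaks = "list",
  gradientLength = "numeric",
  metadata = "list"
))

.validMSRun <- function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@rtime) != length(object@peaks))
    msg <- c(msg, "rtime and peaks must have the same length")
  if (any(object@rtime < 0))
    msg <- c(msg, "retention times must be >= 0")
  if (length(object@gradientLength) != 1L ||
      (!is.na(object@gradientLength) && object@gradientLength <= 0))
    msg <- c(msg, "gradientLength must be a single positive number (or NA)")
  bad <- !vapply(object@peaks, function(p)
    is.matrix(p) && is.numeric(p) && ncol(p) == 2L, logical(1))
  if (any(bad))
    msg <- c(msg, "every scan must be a numeric matrix with columns mz, intensity")
  if (length(msg)) msg else TRUE
}
setValidity("MSRun", .validMSRun)

#' XICTrace: an extracted ion chromatogram
#'
#' Per-scan summed intensity of all centroids falling inside a ppm mass
#' window around a target m/z, against retention time.
#'
#' @slot markerLabel label of the marker the trace was extracted for.
#' @slot targetMz target m/z at the centre of the extraction window.
#' @slot tolPpm half-width of the extraction window in parts per million.
#' @slot rtime retention times in minutes (ascending).
#' @slot intensity summed in-window intensity per scan (same length as
#'   `rtime`; scans with no in-window centroid contribute 0).
#'
#' @aliases XICTrace-class
#' @exportClass XICTrace
setClass("XICTrace", representation(
  markerLabel = "character",
  targetMz = "numeric",
  tolPpm = "numeric",
  rtime = "numeric",
  intensity = "numeric"
))

.validXICTrace <- function(object) {
  msg <- character()
  if (length(object@rtime) != length(object@intensity))
    msg <- c(msg, "rtime and intensity must be aligned")
  if (is.unsorted(object@rtime))
    msg <- c(msg, "rtime must be ascending")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@tolPpm) != 1L || object@tolPpm <= 0)
    msg <- c(msg, "tolPpm must be a single positive number")
  if (length(msg)) msg else TRUE
}
setValidity("XICTrace", .validXICTrace)
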