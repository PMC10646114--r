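#' Construct an MSRun
#'
#' @param sampleId sample identifier.
#' @param rtime retention times in minutes, one per scan.
#' @param peaks list of two-column numeric matrices (`mz`, `intensity`).
#' @param gradientLength gradient length in minutes.
#' @param metadata free-form list.
#' @return an [MSRun-class].
#' @rdname MSRun
#' @export
MSRun <- function(sampleId, rtime = numeric(0), peaks = list(),
                  gradientLength = 65, metadata = list()) {
  peaks <- lapply(peaks, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("each scan needs columns mz, intensity", call. = FALSE)
    colnames(p) <- c("mz", "intensity")
    p
  })
  new("MSRun", sampleId = as.character(sampleId), rtime = as.numeric(rtime),
      peaks = peaks, gradientLength = as.numeric(gradientLength),
      metadata = metadata)
}

#' @rdname MSRun
#' @export
setMethod("sampleId", "MSRun", function(object) object@sampleId)

#' @rdname MSRun
#' @export
setMethod("rtime", "MSRun", function(object) object@rtime)

#' @rdname MSRun
#' @export
setMethod("peaksData", "MSRun", function(object) object@peaks)

#' @rdname MSRun
#' @export
setMethod("gradientLength", "MSRun", function(object) object@gradientLength)

#' @rdname MSRun
#' @export
setMethod("nScans", "MSRun", function(object) length(object@rtime))

setMethod("show", "MSRun", function(object) {
  cat("MSRun", sQuote(object@sampleId), "with", nScans(object),
      "MS1 scans\n")
  if (nScans(object) > 0)
    cat(sprintf("  retention time %.2f - %.2f min; %d centroids total\n",
                min(object@rtime), max(object@rtime),
                sum(vapply(object@peaks, nrow, integer(1)))))
  if (!is.null(object@metadata$profile))
    cat("  simulated profile:", object@metadata$profile, "\n")
})

#' Quality-control findings for an MSRun
#'
#' Reports structural data-quality problems without raising errors:
#' retention times out of order, m/z arrays not sorted ascending, and
#' negative intensities, each naming the offending scan index.
#'
#' @param run an [MSRun-class].
#' @return character vector of findings; empty means clean.
#' @export
validateRun <- function(run) {
  stopifnot(is(run, "MSRun"))
  findings <- character()
  rt <- rtime(run)
  if (length(rt) > 1L && any(diff(rt) <= 0))
    findings <- c(findings, paste0(
      "retention times not strictly increasing at scan(s) ",
      paste(which(diff(rt) <= 0) + 1L, collapse = ", ")))
  for (i in seq_along(run@peaks)) {
    p <- run@peaks[[i]]
    if (nrow(p) > 1L && is.unsorted(p[, "mz"]))
      findings <- c(findings, sprintf("scan %d: m/z array not sorted ascending", i))
    if (any(p[, "intensity"] < 0))
      findings <- c(findings, sprintf("scan %d: negative intensity", i))
  }
  findings
}
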