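#' Read a centroided MS1 run from mzML
#'
#' Reads an mzML file (plain or gzip-compressed) and returns its MS1 scans
#' in retention-time order as an [MSRun-class]. MS2 (and higher) scans are
#' skipped with a message giving their count. Profile-mode MS1 spectra are
#' rejected: the downstream decision logic operates on centroid peak
#' intensities, and silent centroiding would change sex calls.
#'
#' Retention times are converted from the mzML seconds to minutes.
#'
#' @param path path to an mzML file.
#' @return an [MSRun-class].
#' @seealso [writeMzML()]
#' @export
readMzML <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  is_ms1 <- hdr$msLevel == 1L
  n_skipped <- sum(!is_ms1)
  if (n_skipped > 0)
    message("skipping ", n_skipped, " non-MS1 scan(s)")
  prof <- which(is_ms1 & !is.na(hdr$centroided) & !hdr$centroided)
  if (length(prof))
    stop("profile-mode MS1 spectra are not supported (scan ",
         paste(hdr$seqNum[prof], collapse = ", "), ")", call. = FALSE)
  idx <- which(is_ms1)
  rt_min <- hdr$retentionTime[idx] / 60
  ord <- order(rt_min)
  idx <- idx[ord]
  rt_min <- rt_min[ord]
  pk <- lapply(idx, function(i) {
    p <- mzR::peaks(fh, i)
    p <- matrix(as.numeric(p), ncol = 2L,
                dimnames = list(NULL, c("mz", "intensity")))
    p
  })
  sample_id <- sub("\\.mzML(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  grad <- if (length(rt_min)) max(rt_min) else NA_real_
  MSRun(sampleId = sample_id, rtime = rt_min, peaks = pk,
        gradientLength = grad)
}

#' Write an MSRun to mzML
#'
#' Writes the run's centroided MS1 scans to a schema-valid mzML file
#' (via the proteowizard bindings in `mzR`). Retention times are written in
#' seconds per the mzML convention; the round trip through [readMzML()] is
#' lossless for retention time, m/z and intensity within floating-point
#' precision.
#'
#' @param run an [MSRun-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMzML <- function(run, path) {
  stopifnot(is(run, "MSRun"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  n <- nScans(run)
  pk <- peaksData(run)
  npts <- vapply(pk, nrow, integer(1))
  bp_mz <- vapply(pk, function(p)
    if (nrow(p)) p[which.max(p[, "intensity"]), "mz"] else 0, numeric(1))
  bp_int <- vapply(pk, function(p)
    if (nrow(p)) max(p[, "intensity"]) else 0, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npts,
    totIonCurrent = vapply(pk, function(p) sum(p[, "intensity"]), numeric(1)),
    retentionTime = rtime(run) * 60,
    basePeakMZ = bp_mz, basePeakIntensity = bp_int,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, "mz"]) else 0, numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, "mz"]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  if (file.exists(path)) unlink(path)
  suppressMessages(mzR::writeMSData(unname(pk), file = path, header = hdr,
                                    outformat = "mzml"))
  invisible(path)
}
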