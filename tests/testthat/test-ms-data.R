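test_that("an MSRun round-trips through mzML losslessly", {
  run <- make_run(c(1, 2, 3),
                  list(c(400, 540.2796, 1e3, 1e6),
                       c(440.2233, 2e5),
                       c(500.5, 77)),
                  id = "rt3")
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(run, path)
  back <- readMzML(path)
  expect_identical(nScans(back), 3L)
  expect_equal(rtime(back), rtime(run), tolerance = 1e-9)
  for (i in 1:3)
    expect_equal(peaksData(back)[[i]], peaksData(run)[[i]],
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("larger runs preserve scan counts and intensities through mzML", {
  cfg <- generatorConfig(seed = 11, run_length_min = 5)
  run <- simulateRun("female", config = cfg)
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(run, path)
  back <- readMzML(path)
  expect_identical(nScans(back), nScans(run))
  expect_equal(vapply(peaksData(back), nrow, integer(1)),
               vapply(peaksData(run), nrow, integer(1)))
  expect_equal(max(unlist(lapply(peaksData(back), function(p) p[, "intensity"]))),
               max(unlist(lapply(peaksData(run), function(p) p[, "intensity"]))),
               tolerance = 1e-6)
})

test_that("a run containing an empty scan writes and reads back", {
  run <- make_run(c(1, 2), list(c(500, 10), numeric(0)))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(run, path)
  back <- readMzML(path)
  expect_identical(nScans(back), 2L)
  expect_identical(nrow(peaksData(back)[[2]]), 0L)
})

test_that("MS2 scans are skipped on read with a message", {
  # craft a mixed MS1/MS2 file directly through mzR
  n <- 4L
  hdr <- data.frame(
    seqNum = 1:n, acquisitionNum = 1:n, msLevel = c(1L, 2L, 1L, 2L),
    polarity = 1L, peaksCount = 1L, totIonCurrent = 10,
    retentionTime = c(60, 61, 120, 121), basePeakMZ = 500,
    basePeakIntensity = 10, collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = 500, highMZ = 500, precursorScanNum = c(0L, 1L, 0L, 3L),
    precursorMZ = c(0, 500, 0, 500), precursorCharge = c(0L, 2L, 0L, 2L),
    precursorIntensity = c(0, 10, 0, 10), mergedScan = 0L,
    mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = paste0("scan=", 1:n),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
  pks <- rep(list(cbind(mz = 500, intensity = 10)), n)
  path <- withr::local_tempfile(fileext = ".mzML")
  suppressMessages(mzR::writeMSData(pks, file = path, header = hdr))
  expect_message(run <- readMzML(path), "2 non-MS1")
  expect_identical(nScans(run), 2L)
  expect_equal(rtime(run), c(1, 2), tolerance = 1e-9)
})

test_that("a zero-scan run is a valid object", {
  run <- MSRun("empty")
  expect_identical(nScans(run), 0L)
  expect_identical(validateRun(run), character(0))
})

test_that("validateRun reports findings instead of raising", {
  clean <- make_run(c(1, 2), list(c(500, 10), c(501, 11)))
  expect_identical(validateRun(clean), character(0))

  neg <- make_run(c(1, 2), list(c(500, 10), c(501, -1)))
  expect_match(validateRun(neg), "scan 2: negative intensity", all = FALSE)

  shuffled <- make_run(c(1, 2), list(c(500, 10), c(501, 11)))
  shuffled@rtime <- c(2, 1)
  expect_match(validateRun(shuffled), "not strictly increasing", all = FALSE)

  unsorted <- make_run(1, list(matrix(c(501, 500, 1, 2), ncol = 2)))
  expect_match(validateRun(unsorted), "not sorted ascending", all = FALSE)
})

test_that("two writes of the same run have identical binary payloads", {
  skip_if_not_installed("xml2")
  run <- make_run(c(1, 2), list(c(500.1, 123.4), c(600.2, 567.8)))
  p1 <- withr::local_tempfile(fileext = ".mzML")
  p2 <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(run, p1)
  writeMzML(run, p2)
  payload <- function(p) xml2::xml_text(
    xml2::xml_find_all(xml2::read_xml(p), "//d1:binary",
                       xml2::xml_ns(xml2::read_xml(p))))
  expect_identical(payload(p1), payload(p2))
  expect_gt(length(payload(p1)), 0L)
})

test_that("profile-mode MS1 spectra are rejected", {
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = 1L, totIonCurrent = 10, retentionTime = 60,
    basePeakMZ = 500, basePeakIntensity = 10, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 500, highMZ = 500,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".mzML")
  suppressMessages(mzR::writeMSData(list(cbind(mz = 500, intensity = 10)),
                                    file = path, header = hdr))
  expect_error(readMzML(path), "profile-mode")
  expect_error(readMzML(file.path(tempdir(), "missing.mzML")), "not found")
})
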