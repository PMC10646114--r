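#' Monoisotopic residue masses and mass constants
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues, the mass
#' of water added on peptide-bond hydrolysis, the proton mass used for
#' charging, and the supported modification deltas. The proton mass (not the
#' hydrogen atom mass) is used so that computed m/z agree with instrument
#' inclusion-list values to four decimals.
#'
#' @return `residueMasses()` returns a named numeric vector of residue
#'   masses; `modificationDeltas()` a named numeric vector of modification
#'   mass shifts (currently methionine oxidation, `"ox"`).
#' @examples
#' residueMasses()[["G"]]
#' modificationDeltas()[["ox"]]
#' @export
residueMasses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
}

#' @rdname residueMasses
#' @export
modificationDeltas <- function() c(ox = 15.994915)

.WATER_MONO <- 18.010565
.PROTON_MASS <- 1.007276

#' Monoisotopic mass of a peptide
#'
#' Sums residue masses over the sequence, adds the mass of water, and adds
#' the mass shift of each declared modification.
#'
#' @param sequence peptide as a one-letter amino-acid string.
#' @param mod_positions integer vector of modified residue positions
#'   (1-based); empty for an unmodified peptide.
#' @param mod_names character vector of modification names aligned to
#'   `mod_positions`; currently only `"ox"` (Met oxidation, +15.994915 Da).
#' @return monoisotopic mass in Da.
#' @examples
#' monoisotopicMass("G")                      # 75.03203
#' monoisotopicMass("SMIRPPY", 2L, "ox")      # oxidised AMELY peptide
#' @export
monoisotopicMass <- function(sequence, mod_positions = integer(0),
                             mod_names = character(0)) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string", call. = FALSE)
  tab <- residueMasses()
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(aa, names(tab))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  mod_positions <- as.integer(mod_positions)
  if (length(mod_positions) != length(mod_names))
    stop("mod_positions and mod_names must be aligned", call. = FALSE)
  if (length(mod_positions)) {
    if (any(mod_positions < 1L | mod_positions > length(aa)))
      stop("modification position out of sequence range", call. = FALSE)
    deltas <- modificationDeltas()
    bad <- setdiff(mod_names, names(deltas))
    if (length(bad))
      stop("unknown modification(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    modmass <- sum(deltas[mod_names])
  } else modmass <- 0
  sum(tab[aa]) + .WATER_MONO + modmass
}

#' Theoretical m/z of a (modified) peptide ion
#'
#' `(M + z * m_proton) / z` for the monoisotopic mass M.
#'
#' @inheritParams monoisotopicMass
#' @param charge positive integer charge state.
#' @return theoretical m/z.
#' @examples
#' theoreticalMz("SIRPPYPSY", 2L)         # 540.2796, the AMELX marker
#' theoreticalMz("SMIRPPY", 2L, 2L, "ox") # 440.2233, the AMELY marker
#' @export
theoreticalMz <- function(sequence, charge = 2L, mod_positions = integer(0),
                          mod_names = character(0)) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop("charge must be a positive integer", call. = FALSE)
  m <- monoisotopicMass(sequence, mod_positions, mod_names)
  (m + charge * .PROTON_MASS) / charge
}

#' Symmetric ppm mass window
#'
#' @param mz centre m/z (> 0).
#' @param tol_ppm half-width of the window in parts per million (>= 0).
#' @return numeric vector `c(low, high)` = `mz * (1 -/+ tol_ppm * 1e-6)`.
#' @examples
#' ppmInterval(540.2796, 5)
#' @export
ppmInterval <- function(mz, tol_ppm) {
  .stopifnot_scalar_number(mz, "mz", positive = TRUE)
  .stopifnot_scalar_number(tol_ppm, "tol_ppm")
  if (tol_ppm < 0) stop("tol_ppm must be >= 0", call. = FALSE)
  mz * c(1 - tol_ppm * 1e-6, 1 + tol_ppm * 1e-6)
}

#' Construct a marker panel
#'
#' Builds a [MarkerPanel-class] from a marker table, computing each marker's
#' theoretical m/z from its sequence, modifications and charge. If the table
#' carries an `mz` column of reference values (e.g. instrument inclusion-list
#' values), the computed m/z are checked against it and a discrepancy larger
#' than 0.0005 is an error — this guards the mass table against typos.
#'
#' @param markers data.frame with columns `label`, `sequence`, `mod_pos`,
#'   `mod_name`, `charge`, `specificity`, `role`, and optionally `rt_min`
#'   and `mz` (reference values).
#' @return a `MarkerPanel`.
#' @seealso [defaultPanel()] for the built-in six-marker panel.
#' @export
MarkerPanel <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (is.null(markers$rt_min)) markers$rt_min <- NA_real_
  if (is.null(markers$mod_pos)) markers$mod_pos <- NA_integer_
  if (is.null(markers$mod_name)) markers$mod_name <- NA_character_
  markers$charge <- as.integer(markers$charge)
  markers$mod_pos <- as.integer(markers$mod_pos)
  computed <- vapply(seq_len(nrow(markers)), function(i) {
    r <- markers[i, ]
    if (is.na(r$mod_pos))
      theoreticalMz(r$sequence, r$charge)
    else
      theoreticalMz(r$sequence, r$charge, r$mod_pos, r$mod_name)
  }, numeric(1))
  if (!is.null(markers$mz) && any(!is.na(markers$mz))) {
    ref <- markers$mz
    off <- which(!is.na(ref) & abs(computed - ref) > 5e-4)
    if (length(off))
      stop("computed m/z disagrees with reference value for: ",
           paste(markers$label[off], collapse = ", "), call. = FALSE)
  }
  markers$mz <- computed
  rownames(markers) <- NULL
  new("MarkerPanel", markers = markers)
}

#' Default enamel marker panel
#'
#' The six-marker panel used for enamel-peptide sex estimation: two
#' AMELY-specific sex-diagnostic peptides (SM(ox)IRPPY, M(ox)IRPPY), one
#' AMELX-specific sex-diagnostic peptide (SIRPPYPSY), two peptides shared
#' between the X and Y isoforms used as corroboration (SYEVLTPLK,
#' YEVLTPLKWY), and one enamelin peptide used as a preservation/QC marker
#' (PYFGYFGYH). All are doubly protonated. The `rt_min` column holds
#' nominal elution times for the synthetic generator; the detector does not
#' constrain retention time by default because expected times are
#' gradient-specific.
#'
#' @return a [MarkerPanel-class] of six markers.
#' @examples
#' defaultPanel()
#' @export
defaultPanel <- function() {
  MarkerPanel(data.frame(
    label = c("SM(ox)IRPPY", "M(ox)IRPPY", "SIRPPYPSY",
              "SYEVLTPLK", "YEVLTPLKWY", "PYFGYFGYH"),
    sequence = c("SMIRPPY", "MIRPPY", "SIRPPYPSY",
                 "SYEVLTPLK", "YEVLTPLKWY", "PYFGYFGYH"),
    mod_pos = c(2L, 1L, NA, NA, NA, NA),
    mod_name = c("ox", "ox", NA, NA, NA, NA),
    charge = 2L,
    specificity = c("AMELY", "AMELY", "AMELX",
                    "AMELXY_shared", "AMELXY_shared", "ENAM"),
    role = c("sex_diagnostic", "sex_diagnostic", "sex_diagnostic",
             "shared_corroboration", "shared_corroboration",
             "preservation_qc"),
    rt_min = c(20.0, 18.5, 24.0, 26.0, 33.0, 30.0),
    mz = c(440.2233, 396.7073, 540.2796, 525.2975, 656.3528, 575.7533),
    stringsAsFactors = FALSE
  ))
}

#' @rdname MarkerPanel
#' @param object a `MarkerPanel`.
#' @export
setMethod("markerTable", "MarkerPanel", function(object) object@markers)

#' @export
setMethod("length", "MarkerPanel", function(x) nrow(x@markers))

setMethod("show", "MarkerPanel", function(object) {
  m <- object@markers
  cat("MarkerPanel with", nrow(m), "markers\n")
  print(m[, c("label", "specificity", "role", "charge", "mz")],
        row.names = FALSE, digits = 8)
})

#' Read / write a marker panel as YAML
#'
#' Serializes the panel as a YAML list (label, sequence, modification,
#' charge, specificity, role, optional retention-time window in minutes);
#' reading recomputes and re-validates each m/z.
#'
#' @param path file path.
#' @param panel a [MarkerPanel-class].
#' @return `readPanel()` returns a `MarkerPanel`; `writePanel()` the path,
#'   invisibly.
#' @export
writePanel <- function(panel, path) {
  m <- markerTable(panel)
  lst <- lapply(seq_len(nrow(m)), function(i) {
    r <- as.list(m[i, ])
    r[!vapply(r, function(x) is.na(x) || is.null(x), logical(1))]
  })
  yaml::write_yaml(list(markers = lst), path)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lst <- yaml::read_yaml(path)$markers
  if (is.null(lst)) stop("no 'markers' block in panel file", call. = FALSE)
  rows <- lapply(lst, function(r) data.frame(
    label = r$label, sequence = r$sequence,
    mod_pos = if (is.null(r$mod_pos)) NA_integer_ else as.integer(r$mod_pos),
    mod_name = if (is.null(r$mod_name)) NA_character_ else r$mod_name,
    charge = as.integer(r$charge), specificity = r$specificity,
    role = r$role,
    rt_min = if (is.null(r$rt_min)) NA_real_ else as.numeric(r$rt_min),
    mz = if (is.null(r$mz)) NA_real_ else as.numeric(r$mz),
    stringsAsFactors = FALSE))
  MarkerPanel(do.call(rbind, rows))
}
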