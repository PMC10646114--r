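# Independent element-composition mass oracle: sums monoisotopic element
# masses over each residue's CHNOS formula. Shares nothing with the
# package's residue-mass table.
.elements <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

oracle_mass <- function(sequence, n_oxidations = 0) {
  aa <- strsplit(sequence, "")[[1]]
  res <- sum(vapply(aa, function(a) {
    f <- .residue_formula[[a]]
    sum(.elements[names(f)] * f)
  }, numeric(1)))
  water <- 2 * .elements[["H"]] + .elements[["O"]]
  res + water + n_oxidations * .elements[["O"]]
}

# tiny hand-built run: one scan per row of rt, centroids supplied as a list
make_run <- function(rt, centroids, id = "test") {
  MSRun(sampleId = id, rtime = rt,
        peaks = lapply(centroids, function(p)
          matrix(p, ncol = 2, dimnames = list(NULL, c("mz", "intensity")))),
        gradientLength = max(rt, 1))
}

# sex-call data.frames for agreement tests
calls_df <- function(ids, calls) {
  data.frame(specimen_id = ids, call = calls, stringsAsFactors = FALSE)
}
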