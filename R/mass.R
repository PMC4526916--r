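# Peptide mass arithmetic: residue tables, precursor m/z, b/y fragment
# ladders, internal-standard design, transition selection and spectrum
# annotation for ion-trap style targeted assays.

# Monoisotopic residue masses (Da), 20 canonical amino acids.
AA_MONO <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# Average residue masses (Da).
AA_AVG <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MONO <- 18.010565
WATER_AVG  <- 18.01528
PROTON     <- 1.007276

AA_CANONICAL <- names(AA_MONO)

# Split a peptide string into residues, rejecting anything outside the 20
# canonical residues with the offending position.
split_residues <- function(peptide, arg = "peptide") {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide))
    stop(sprintf("'%s' must be a single character string", arg), call. = FALSE)
  if (!nzchar(peptide))
    stop(sprintf("'%s' must be non-empty", arg), call. = FALSE)
  res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  bad <- which(!(res %in% AA_CANONICAL))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 res[bad[1L]], bad[1L], arg), call. = FALSE)
  res
}

#' Monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (the free peptide).
#' Masses are additive: `mass(AB) == mass(A) + mass(B) - water`.
#'
#' @param peptide Amino-acid string (uppercase, 20 canonical residues).
#' @return Neutral monoisotopic mass in Dalton.
#' @examples
#' monoisotopic_mass("PAGNYIGARPY")  # ~1177.588
#' @export
monoisotopic_mass <- function(peptide) {
  res <- split_residues(peptide)
  sum(AA_MONO[res]) + WATER_MONO
}

#' Average (chemical) mass of a peptide
#'
#' As [monoisotopic_mass()] but using average residue masses; always
#' greater than or equal to the monoisotopic mass.
#'
#' @inheritParams monoisotopic_mass
#' @return Neutral average mass in Dalton.
#' @export
average_mass <- function(peptide) {
  res <- split_residues(peptide)
  sum(AA_AVG[res]) + WATER_AVG
}

#' Precursor m/z of a protonated peptide
#'
#' `(M + z * proton) / z` where M is the neutral mass. The proton mass used
#' is 1.007276 Da.
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge state (default 2, the usual
#'   ion-trap precursor charge for an 11-mer).
#' @param type `"monoisotopic"` (default) or `"average"` neutral mass.
#' @return m/z in Thomson.
#' @examples
#' precursor_mz("PAGNYIGARPY", 2)  # 589.80
#' @export
precursor_mz <- function(peptide, charge = 2L,
                         type = c("monoisotopic", "average")) {
  type <- match.arg(type)
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
      charge < 1 || charge != as.integer(charge))
    stop("'charge' must be a positive integer", call. = FALSE)
  m <- if (type == "monoisotopic") monoisotopic_mass(peptide)
       else average_mass(peptide)
  (m + charge * PROTON) / charge
}

#' b/y fragment-ion ladder of a peptide
#'
#' Singly (or higher) charged b and y ions for indices 1..(n-1):
#' `b_i = sum(residues[1:i]) + z*proton` and
#' `y_i = sum(residues[(n-i+1):n]) + water + z*proton`, each divided by z.
#' Complementarity `b_i + y_(n-i) = M + 2*proton` holds at z = 1.
#'
#' @inheritParams monoisotopic_mass
#' @param charge Fragment charge (default 1, CID ion-trap convention).
#' @return data.frame with columns `ion`, `series`, `index`, `charge`, `mz`.
#' @examples
#' fragment_ladder("PAGNYIGARPY")  # b9 ~900.47, y6 ~676.38
#' @export
fragment_ladder <- function(peptide, charge = 1L) {
  res <- split_residues(peptide)
  n <- length(res)
  if (n < 2L)
    stop("peptide must have at least 2 residues to fragment", call. = FALSE)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != as.integer(charge))
    stop("'charge' must be a positive integer", call. = FALSE)
  idx <- seq_len(n - 1L)
  b_neutral <- cumsum(AA_MONO[res])[idx]
  y_neutral <- cumsum(AA_MONO[rev(res)])[idx] + WATER_MONO
  out <- data.frame(
    ion    = c(paste0("b", idx), paste0("y", idx)),
    series = rep(c("b", "y"), each = n - 1L),
    index  = c(idx, idx),
    charge = as.integer(charge),
    mz     = c((b_neutral + charge * PROTON) / charge,
               (y_neutral + charge * PROTON) / charge),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Parse substitutions given as "G3A"/"3A" strings or a 2-column
# data.frame(position, residue) into a canonical data.frame.
parse_substitutions <- function(substitutions) {
  if (is.data.frame(substitutions)) {
    stopifnot(ncol(substitutions) >= 2L)
    out <- data.frame(position = as.integer(substitutions[[1L]]),
                      new = toupper(as.character(substitutions[[2L]])),
                      old = NA_character_, stringsAsFactors = FALSE)
    return(out)
  }
  if (!is.character(substitutions) || !length(substitutions))
    stop("'substitutions' must be strings like \"G3A\" or a data.frame",
         call. = FALSE)
  m <- regmatches(substitutions,
                  regexec("^([A-Za-z]?)([0-9]+)([A-Za-z])$", substitutions))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop(sprintf("cannot parse substitution '%s'", substitutions[bad][1L]),
         call. = FALSE)
  data.frame(
    position = vapply(m, function(x) as.integer(x[3L]), 1L),
    new = toupper(vapply(m, function(x) x[4L], "")),
    old = toupper(vapply(m, function(x) if (nzchar(x[2L])) x[2L]
                         else NA_character_, "")),
    stringsAsFactors = FALSE)
}

#' Design a sequence-substituted internal standard
#'
#' Applies point substitutions to the analyte peptide and reports the
#' precursor m/z shift at the assay charge, flagging a collision when the
#' shift does not exceed the XIC extraction tolerance. Both monoisotopic
#' and average precursor m/z are reported, as printed assay values may
#' follow either convention.
#'
#' @param analyte Analyte peptide sequence.
#' @param substitutions Character vector like `c("G3A", "N4A", "P10A")`
#'   (the original residue letter is optional but checked when given), or a
#'   data.frame of (position, new residue). No-op substitutions are
#'   rejected.
#' @param charge Assay precursor charge (default 2).
#' @param xic_tolerance XIC extraction half-window in Thomson (default 0.5);
#'   |delta m/z| <= tolerance raises the collision flag.
#' @return Object of class `cape_is_design`: list with `peptide`,
#'   `analyte`, `substitutions`, `analyte_mz`, `is_mz` (each with
#'   monoisotopic and average entries), `delta_mz` (monoisotopic), and
#'   `collision`.
#' @examples
#' design_internal_standard("PAGNYIGARPY", c("G3A", "N4A", "P10A"))
#' @export
design_internal_standard <- function(analyte, substitutions, charge = 2L,
                                     xic_tolerance = 0.5) {
  res <- split_residues(analyte, "analyte")
  subs <- parse_substitutions(substitutions)
  n <- length(res)
  for (k in seq_len(nrow(subs))) {
    p <- subs$position[k]
    if (is.na(p) || p < 1L || p > n)
      stop(sprintf("substitution position %s outside peptide (length %d)",
                   p, n), call. = FALSE)
    if (!(subs$new[k] %in% AA_CANONICAL))
      stop(sprintf("substitution to unknown residue '%s'", subs$new[k]),
           call. = FALSE)
    if (!is.na(subs$old[k]) && subs$old[k] != res[p])
      stop(sprintf("substitution '%s%d%s': position %d is '%s'",
                   subs$old[k], p, subs$new[k], p, res[p]), call. = FALSE)
    if (res[p] == subs$new[k])
      stop(sprintf("no-op substitution at position %d ('%s' -> '%s')",
                   p, res[p], subs$new[k]), call. = FALSE)
    res[p] <- subs$new[k]
  }
  is_pep <- paste(res, collapse = "")
  a_mono <- precursor_mz(analyte, charge)
  i_mono <- precursor_mz(is_pep, charge)
  delta <- i_mono - a_mono
  out <- list(
    peptide = is_pep,
    analyte = analyte,
    substitutions = subs,
    charge = as.integer(charge),
    analyte_mz = c(monoisotopic = a_mono,
                   average = precursor_mz(analyte, charge, "average")),
    is_mz = c(monoisotopic = i_mono,
              average = precursor_mz(is_pep, charge, "average")),
    delta_mz = delta,
    xic_tolerance = xic_tolerance,
    collision = abs(delta) <= xic_tolerance)
  class(out) <- "cape_is_design"
  out
}

#' @export
print.cape_is_design <- function(x, ...) {
  cat(sprintf("Internal standard design: %s -> %s (z=%d)\n",
              x$analyte, x$peptide, x$charge))
  cat(sprintf("  analyte m/z %.4f (mono) / %.4f (avg)\n",
              x$analyte_mz[["monoisotopic"]], x$analyte_mz[["average"]]))
  cat(sprintf("  IS      m/z %.4f (mono) / %.4f (avg)\n",
              x$is_mz[["monoisotopic"]], x$is_mz[["average"]]))
  cat(sprintf("  delta m/z %+.4f Th; collision (|delta| <= %.2f): %s\n",
              x$delta_mz, x$xic_tolerance,
              if (x$collision) "YES" else "no"))
  invisible(x)
}

#' Select targeted transitions from a fragment ladder
#'
#' Deterministic stand-in for "most intense fragments": keeps ions inside
#' `[min_mz, max_mz]` and takes the `k` of highest m/z (ties broken by
#' series then index). The result is invariant to the input row order; an
#' explicitly curated transition list can be passed downstream instead.
#'
#' @param ladder data.frame from [fragment_ladder()].
#' @param k Number of transitions (default 3).
#' @param min_mz,max_mz Optional m/z window.
#' @return Subset of `ladder`, ordered by descending m/z. When fewer than
#'   `k` ions are in range, all of them are returned with a warning.
#' @export
select_transitions <- function(ladder, k = 3L, min_mz = NULL, max_mz = NULL) {
  stopifnot(is.data.frame(ladder), all(c("series", "index", "mz") %in%
                                       names(ladder)))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("'k' must be a positive integer", call. = FALSE)
  keep <- rep(TRUE, nrow(ladder))
  if (!is.null(min_mz)) keep <- keep & ladder$mz >= min_mz
  if (!is.null(max_mz)) keep <- keep & ladder$mz <= max_mz
  sel <- ladder[keep, , drop = FALSE]
  sel <- sel[order(-sel$mz, sel$series, sel$index), , drop = FALSE]
  if (nrow(sel) < k) {
    warning(sprintf("only %d ions in range; returning all", nrow(sel)))
    return(sel)
  }
  sel[seq_len(k), , drop = FALSE]
}

#' Annotate an observed spectrum with the theoretical b/y ladder
#'
#' Matches each theoretical singly charged b/y ion to the nearest observed
#' peak within `tolerance`; peak/ion pairs are assigned greedily by
#' ascending m/z error so that one peak satisfies at most one ion and the
#' closest pair wins. Coverage is matched ions over the n-1 possible ions
#' per series.
#'
#' @param observed_peaks data.frame (or 2-column matrix) with columns `mz`
#'   and `intensity`. May be empty (zero coverage).
#' @param peptide Peptide sequence the spectrum is annotated against.
#' @param tolerance Matching half-window in Thomson (default 0.5).
#' @return Object of class `spectrum_annotation`: list with `matched`
#'   (data.frame ion/series/index/mz_theoretical/mz_observed/error),
#'   `y_coverage`, `b_coverage`.
#' @export
annotate_spectrum <- function(observed_peaks, peptide, tolerance = 0.5) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("'tolerance' must be > 0", call. = FALSE)
  if (is.matrix(observed_peaks))
    observed_peaks <- data.frame(mz = observed_peaks[, 1L],
                                 intensity = observed_peaks[, 2L])
  if (is.null(observed_peaks) || !nrow(observed_peaks)) {
    observed_peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  }
  stopifnot(all(c("mz", "intensity") %in% names(observed_peaks)))
  ladder <- fragment_ladder(peptide, charge = 1L)
  n1 <- nchar(peptide) - 1L

  pairs <- expand.grid(ion = seq_len(nrow(ladder)),
                       peak = seq_len(nrow(observed_peaks)))
  if (nrow(pairs)) {
    pairs$error <- abs(ladder$mz[pairs$ion] - observed_peaks$mz[pairs$peak])
    pairs <- pairs[pairs$error <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$error, pairs$ion, pairs$peak), , drop = FALSE]
  }
  used_ion <- logical(nrow(ladder))
  used_peak <- logical(nrow(observed_peaks))
  keep <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$ion[r]; p <- pairs$peak[r]
    if (!used_ion[i] && !used_peak[p]) {
      used_ion[i] <- TRUE
      used_peak[p] <- TRUE
      keep <- c(keep, r)
    }
  }
  hits <- pairs[keep, , drop = FALSE]
  matched <- data.frame(
    ion = ladder$ion[hits$ion],
    series = ladder$series[hits$ion],
    index = ladder$index[hits$ion],
    mz_theoretical = ladder$mz[hits$ion],
    mz_observed = observed_peaks$mz[hits$peak],
    error = ladder$mz[hits$ion] - observed_peaks$mz[hits$peak],
    stringsAsFactors = FALSE)
  matched <- matched[order(matched$series, matched$index), , drop = FALSE]
  rownames(matched) <- NULL
  out <- list(matched = matched,
              y_coverage = sum(matched$series == "y") / n1,
              b_coverage = sum(matched$series == "b") / n1)
  class(out) <- "spectrum_annotation"
  out
}

#' @export
print.spectrum_annotation <- function(x, ...) {
  cat(sprintf("Spectrum annotation: %d matched ions; y coverage %.0f%%, b coverage %.0f%%\n",
              nrow(x$matched), 100 * x$y_coverage, 100 * x$b_coverage))
  if (nrow(x$matched)) print(x$matched, ...)
  invisible(x)
}
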