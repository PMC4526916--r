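# Worked-example inputs: the nine Arabidopsis CAPE peptides, a synthetic
# stand-in for the AtCAPE1 precursor, and the published AtCAPE1 targeted
# assay configuration.

#' The nine putative Arabidopsis CAPE peptides
#'
#' The published catalogue of putative Arabidopsis CAPEs: the 11-residue
#' C-terminal peptide matching `PxGNxxxxxPY` for each of the nine
#' CAP-superfamily precursors, named in descending order of percent
#' identity to tomato CAPE1. AtCAPE1 (from AT4G33730) is the salt-regulated
#' peptide the targeted assay quantifies.
#'
#' @return data.frame with columns `name`, `peptide`, `gene`.
#' @export
atcape_catalog <- function() {
  data.frame(
    name = paste0("AtCAPE", 1:9),
    peptide = c("PAGNYIGARPY", "PPGNWVGEWPY", "PPGNWVGEWPY", "PPGNYVGEKPY",
                "PPGNYVGEKPY", "PPGNFLGRKPY", "PPGNYANQKPY", "PPGNYRGRWPY",
                "PRGNYVNEKPY"),
    gene = c("AT4G33730", "AT4G25780", "AT4G33720", "AT4G25790", "AT5G57625",
             "AT4G30320", "PRB1", "AT5G26130", "PR1"),
    stringsAsFactors = FALSE)
}

#' Synthetic stand-in for the AtCAPE1 precursor (PROAtCAPE1)
#'
#' Builds a deterministic SYNTHETIC 172-residue precursor reproducing the
#' documented architecture of PROAtCAPE1 rather than its exact sequence
#' (which is not bundled with the package): an N-terminal signal peptide
#' ending at residue 27, a CAP-domain-like core, the CNYD cleavage signal
#' at residues 158-161 (so the critical tyrosine sits at position 160), and
#' the mature AtCAPE1 peptide PAGNYIGARPY at residues 162-172. The filler
#' residues are pseudo-random but fixed, so the object is identical across
#' calls.
#'
#' @return A [precursor_protein()] with id `"PROAtCAPE1_synthetic"` and
#'   `signal_peptide_end = 27`.
#' @export
synthetic_proatcape1 <- function() {
  filler <- with_seed(420073L, function()
    sample(AA_CANONICAL, 157L, replace = TRUE))
  seq <- paste0(paste(filler, collapse = ""), "CNYD", "PAGNYIGARPY")
  stopifnot(nchar(seq) == 172L)
  precursor_protein("PROAtCAPE1_synthetic", seq, signal_peptide_end = 27L)
}

#' The published AtCAPE1 targeted LC-MS/MS assay
#'
#' The assay as run in the source study: analyte PAGNYIGARPY at precursor
#' charge 2 (m/z 589.8) with singly charged transitions y5, y6 and b9
#' (563.3, 676.4, 900.5 Th theoretical), and the triply substituted
#' internal standard PAAAYIGARAY (G3A, N4A, P10A; precursor m/z 562.3
#' monoisotopic) with transitions y5, y6 and y7 (537.3, 650.4, 813.4 Th).
#'
#' @return A `cape_assay` object (see [build_assay()]).
#' @export
atcape1_assay <- function() {
  build_assay(
    analyte = "PAGNYIGARPY",
    is_substitutions = c("G3A", "N4A", "P10A"),
    precursor_charge = 2L,
    analyte_transitions = data.frame(series = c("y", "y", "b"),
                                     index = c(5L, 6L, 9L)),
    is_transitions = data.frame(series = c("y", "y", "y"),
                                index = c(5L, 6L, 7L)))
}

#' Build a targeted assay definition
#'
#' Pairs an analyte peptide with a substituted internal standard and a set
#' of singly charged b/y transitions for each. Transitions may be given
#' explicitly as a data.frame of (series, index) or left `NULL` to be
#' picked by [select_transitions()] from the fragment ladder.
#'
#' @param analyte Analyte peptide sequence.
#' @param is_substitutions Substitutions defining the internal standard
#'   (see [design_internal_standard()]); alternatively pass the internal
#'   standard sequence via `internal_standard`.
#' @param internal_standard Optional explicit IS peptide sequence
#'   (overrides `is_substitutions`).
#' @param precursor_charge Precursor charge state (default 2).
#' @param analyte_transitions,is_transitions Optional data.frames with
#'   columns `series` ("b"/"y") and `index`; `NULL` = automatic selection.
#' @param k,min_mz,max_mz Passed to [select_transitions()] when automatic.
#' @param xic_tolerance XIC half-window (Th) used for the precursor
#'   collision check (default 0.5).
#' @return Object of class `cape_assay`: list with `analyte`,
#'   `internal_standard`, `precursor_charge`, `analyte_mz`, `is_mz`, and
#'   per-peptide transition tables carrying `transition_id` columns
#'   (`analyte_<ion>` / `is_<ion>`).
#' @export
build_assay <- function(analyte, is_substitutions = NULL,
                        internal_standard = NULL, precursor_charge = 2L,
                        analyte_transitions = NULL, is_transitions = NULL,
                        k = 3L, min_mz = NULL, max_mz = NULL,
                        xic_tolerance = 0.5) {
  split_residues(analyte, "analyte")
  if (is.null(internal_standard)) {
    if (is.null(is_substitutions))
      stop("give either 'is_substitutions' or 'internal_standard'",
           call. = FALSE)
    internal_standard <- design_internal_standard(
      analyte, is_substitutions, charge = precursor_charge,
      xic_tolerance = xic_tolerance)$peptide
  } else {
    split_residues(internal_standard, "internal_standard")
  }
  a_mz <- precursor_mz(analyte, precursor_charge)
  i_mz <- precursor_mz(internal_standard, precursor_charge)
  if (abs(a_mz - i_mz) <= xic_tolerance)
    stop(sprintf(
      "analyte and internal standard precursor m/z differ by %.3f Th, within the %.2f Th XIC tolerance",
      abs(a_mz - i_mz), xic_tolerance), call. = FALSE)
  pick <- function(peptide, spec, prefix) {
    ladder <- fragment_ladder(peptide, charge = 1L)
    if (is.null(spec)) {
      tr <- select_transitions(ladder, k = k, min_mz = min_mz,
                               max_mz = max_mz)
    } else {
      stopifnot(is.data.frame(spec), all(c("series", "index") %in%
                                         names(spec)))
      key <- paste0(spec$series, spec$index)
      tr <- ladder[match(key, ladder$ion), , drop = FALSE]
      if (anyNA(tr$mz))
        stop(sprintf("transition %s not in the %s ladder",
                     key[which(is.na(tr$mz))[1L]], prefix), call. = FALSE)
    }
    tr$transition_id <- paste0(prefix, "_", tr$ion)
    rownames(tr) <- NULL
    tr
  }
  out <- list(
    analyte = analyte,
    internal_standard = internal_standard,
    precursor_charge = as.integer(precursor_charge),
    analyte_mz = a_mz,
    is_mz = i_mz,
    analyte_transitions = pick(analyte, analyte_transitions, "analyte"),
    is_transitions = pick(internal_standard, is_transitions, "is"),
    xic_tolerance = xic_tolerance)
  class(out) <- "cape_assay"
  out
}

#' @export
print.cape_assay <- function(x, ...) {
  cat(sprintf("Targeted assay: %s (m/z %.2f, z=%d) with IS %s (m/z %.2f)\n",
              x$analyte, x$analyte_mz, x$precursor_charge,
              x$internal_standard, x$is_mz))
  cat("  analyte transitions:",
      paste(sprintf("%s %.2f", x$analyte_transitions$ion,
                    x$analyte_transitions$mz), collapse = ", "), "\n")
  cat("  IS transitions:     ",
      paste(sprintf("%s %.2f", x$is_transitions$ion,
                    x$is_transitions$mz), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an assay definition as TSV
#'
#' One row per transition: `role` (analyte/is), `peptide`, `precursor_charge`,
#' `precursor_mz`, `series`, `index`, `fragment_mz`, `transition_id`.
#'
#' @param assay A `cape_assay`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(assay, path) {
  stopifnot(inherits(assay, "cape_assay"))
  row <- function(tr, role, pep, pmz)
    data.frame(role = role, peptide = pep,
               precursor_charge = assay$precursor_charge, precursor_mz = pmz,
               series = tr$series, index = tr$index, fragment_mz = tr$mz,
               transition_id = tr$transition_id, stringsAsFactors = FALSE)
  tab <- rbind(row(assay$analyte_transitions, "analyte", assay$analyte,
                   assay$analyte_mz),
               row(assay$is_transitions, "is", assay$internal_standard,
                   assay$is_mz))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
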