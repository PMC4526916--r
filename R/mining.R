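# Proteome mining for CAPE precursors: homology prefilter (local alignment
# score), C-terminal motif matching with a cleavage-competence flag, percent
# identity, and identity-based candidate ranking.

#' Motif specification for CAPE mining
#'
#' The mature CAPE is an 11-residue C-terminal peptide matching a positional
#' pattern (default `PxGNxxxxxPY`, `x` = any residue), immediately preceded
#' by a 4-residue cleavage signal (default `CNYx`). The residue at
#' `critical_position` of the cleavage signal (default 3, the tyrosine)
#' must be Y for the precursor to be cleavage competent; a mismatch there
#' still yields a motif hit, flagged incompetent. `terminal_slack` is the
#' maximum number of residues allowed after the motif's final position
#' (default 0: the peptide ends the precursor).
#'
#' @param peptide_pattern 11-position pattern, `x` (or `.`) = wildcard.
#' @param cleavage_signal 4-position pattern preceding the peptide.
#' @param critical_position Index within `cleavage_signal` whose residue
#'   must be tyrosine for cleavage competence.
#' @param terminal_slack Max residues allowed after the motif end.
#' @return Object of class `cape_motif`.
#' @export
motif_spec <- function(peptide_pattern = "PxGNxxxxxPY",
                       cleavage_signal = "CNYx",
                       critical_position = 3L,
                       terminal_slack = 0L) {
  if (nchar(peptide_pattern) != 11L)
    stop("'peptide_pattern' must have 11 positions", call. = FALSE)
  if (nchar(cleavage_signal) != 4L)
    stop("'cleavage_signal' must have 4 positions", call. = FALSE)
  if (critical_position < 1L || critical_position > 4L)
    stop("'critical_position' must be in 1..4", call. = FALSE)
  if (terminal_slack < 0L)
    stop("'terminal_slack' must be >= 0", call. = FALSE)
  out <- list(peptide_pattern = peptide_pattern,
              cleavage_signal = cleavage_signal,
              critical_position = as.integer(critical_position),
              terminal_slack = as.integer(terminal_slack),
              peptide_regex = pattern_to_regex(peptide_pattern))
  class(out) <- "cape_motif"
  out
}

# Positional pattern -> anchored regular expression ("x"/"." wildcards).
pattern_to_regex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  ch[ch %in% c("X", ".")] <- "."
  bad <- which(!(ch %in% c(".", AA_CANONICAL)))
  if (length(bad))
    stop(sprintf("pattern position %d ('%s') is not a residue or wildcard",
                 bad[1L], ch[bad[1L]]), call. = FALSE)
  paste0("^", paste(ch, collapse = ""), "$")
}

#' Precursor protein record
#'
#' A proteome entry: identifier, validated sequence (uppercase, 20 canonical
#' residues, 1-based numbering) and an optional signal-peptide end position
#' (an annotation that is accepted, never computed).
#'
#' @param id Identifier string.
#' @param sequence Amino-acid sequence.
#' @param signal_peptide_end Optional last residue index of the signal
#'   peptide (must be < sequence length).
#' @return Object of class `precursor_protein`.
#' @export
precursor_protein <- function(id, sequence, signal_peptide_end = NULL) {
  res <- split_residues(sequence, sprintf("sequence of '%s'", id))
  if (!is.null(signal_peptide_end)) {
    signal_peptide_end <- as.integer(signal_peptide_end)
    if (signal_peptide_end < 1L || signal_peptide_end >= length(res))
      stop("'signal_peptide_end' must lie inside the sequence", call. = FALSE)
  }
  structure(list(id = as.character(id), sequence = sequence,
                 signal_peptide_end = signal_peptide_end),
            class = "precursor_protein")
}

#' Find the C-terminal CAPE motif in a precursor
#'
#' Scans the last `terminal_slack + 1` possible windows of length 15
#' (4-residue cleavage signal + 11-residue peptide) and returns the
#' C-terminal-most window whose peptide positions match the peptide
#' pattern. Cleavage competence is set from the critical position of the
#' cleavage signal (Y required); the cleavage site is the bond between
#' signal position 4 and peptide position 1. Proteins shorter than 15
#' residues (or with no matching window) give `NULL`.
#'
#' @param protein A [precursor_protein()], or a single sequence string
#'   (id then defaults to `"protein"`).
#' @param motif A [motif_spec()].
#' @return One-row data.frame (class `cape_candidate` rows): columns
#'   `precursor_id`, `peptide`, `start`, `end`, `cleavage_signal`,
#'   `cleavage_site`, `cleavage_competent`; or `NULL` when no window
#'   matches.
#' @examples
#' find_cterm_motif("MSSTNLACNYDPAGNYIGARPY")
#' @export
find_cterm_motif <- function(protein, motif = motif_spec()) {
  if (is.character(protein)) protein <- precursor_protein("protein", protein)
  stopifnot(inherits(protein, "precursor_protein"),
            inherits(motif, "cape_motif"))
  seq <- protein$sequence
  n <- nchar(seq)
  if (n < 15L) return(NULL)
  # candidate end positions, C-terminal-most first
  ends <- seq.int(n, by = -1L, length.out = min(motif$terminal_slack + 1L, n))
  ends <- ends[ends >= 15L]
  for (e in ends) {
    pep <- substr(seq, e - 10L, e)
    if (grepl(motif$peptide_regex, pep)) {
      sig <- substr(seq, e - 14L, e - 11L)
      crit <- substr(sig, motif$critical_position, motif$critical_position)
      out <- data.frame(
        precursor_id = protein$id,
        peptide = pep,
        start = e - 10L,
        end = e,
        cleavage_signal = sig,
        cleavage_site = e - 11L,   # bond between this residue and start
        cleavage_competent = identical(crit, "Y"),
        stringsAsFactors = FALSE)
      return(out)
    }
  }
  NULL
}

# Load the BLOSUM62 substitution matrix shipped with Biostrings.
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local-alignment (Smith-Waterman) score
#'
#' Affine-gap local alignment score, where a gap of length L costs
#' `gap_open + L * gap_extend`. Symmetric in its sequence arguments for a
#' symmetric substitution matrix. Used as the homology prefilter standing
#' in for a database E-value cut-off: on a desk-scale fixture the raw score
#' is the meaningful quantity.
#'
#' @param seq_a,seq_b Amino-acid sequences (20 canonical residues).
#' @param substitution_matrix Square numeric matrix with residue dimnames;
#'   default BLOSUM62 (from Biostrings).
#' @param gap_open,gap_extend Affine gap parameters (defaults 10 and 1).
#' @return The optimal local alignment score (0 when no positive-scoring
#'   alignment exists).
#' @export
local_align_score <- function(seq_a, seq_b, substitution_matrix = NULL,
                              gap_open = 10, gap_extend = 1) {
  split_residues(seq_a, "seq_a")
  split_residues(seq_b, "seq_b")
  if (is.null(substitution_matrix)) substitution_matrix <- get_blosum62()
  stopifnot(is.matrix(substitution_matrix),
            !is.null(rownames(substitution_matrix)),
            identical(rownames(substitution_matrix),
                      colnames(substitution_matrix)))
  sw_score_cpp(seq_a, seq_b, substitution_matrix,
               paste(rownames(substitution_matrix), collapse = ""),
               gap_open, gap_extend)
}

#' Percent identity between two equal-length peptides
#'
#' `100 * matches / length`, position by position. CAPEs are all 11-mers,
#' so unequal lengths are rejected rather than aligned.
#'
#' @param peptide_a,peptide_b Peptide sequences of equal length.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("PAGNYIGARPY", "PAAAYIGARAY")  # 72.7
#' @export
percent_identity <- function(peptide_a, peptide_b) {
  a <- split_residues(peptide_a, "peptide_a")
  b <- split_residues(peptide_b, "peptide_b")
  if (length(a) != length(b))
    stop("peptides must have equal length", call. = FALSE)
  100 * sum(a == b) / length(a)
}

#' Rank CAPE candidates by identity to a reference peptide
#'
#' Orders candidates by descending percent identity to the reference
#' peptide (the nomenclature rule), breaking ties by ascending precursor
#' id.
#'
#' @param candidates data.frame of candidates (needs `precursor_id` and
#'   `peptide` columns), e.g. from [mine_proteome()].
#' @param reference_peptide Reference peptide, same length as the
#'   candidates' peptides.
#' @return `candidates` with an `identity_to_reference` column, reordered.
#' @export
rank_candidates <- function(candidates, reference_peptide) {
  stopifnot(is.data.frame(candidates),
            all(c("precursor_id", "peptide") %in% names(candidates)))
  if (!nrow(candidates)) {
    candidates$identity_to_reference <- numeric(0)
    return(candidates)
  }
  candidates$identity_to_reference <- vapply(
    candidates$peptide, percent_identity, numeric(1),
    peptide_b = reference_peptide, USE.NAMES = FALSE)
  ord <- order(-candidates$identity_to_reference, candidates$precursor_id)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Coerce FASTA path / AAStringSet / named character vector to a named
# character vector of sequences.
as_sequences <- function(fasta) {
  if (inherits(fasta, "AAStringSet"))
    return(stats::setNames(as.character(fasta), names(fasta)))
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    set <- Biostrings::readAAStringSet(fasta)
    return(stats::setNames(as.character(set), names(set)))
  }
  if (is.character(fasta)) {
    if (is.null(names(fasta)))
      names(fasta) <- sprintf("seq%03d", seq_along(fasta))
    return(fasta)
  }
  stop("'fasta' must be a file path, AAStringSet or named character vector",
       call. = FALSE)
}

#' Mine a proteome for CAPE precursor candidates
#'
#' Optionally prefilters proteins by local-alignment score against a query
#' precursor (`score_threshold = 0` disables the prefilter), then applies
#' the C-terminal motif rule to each remaining protein. When a reference
#' peptide is supplied the candidates are ranked by percent identity to it
#' ([rank_candidates()]); otherwise they are returned in ascending
#' precursor-id order.
#'
#' @param fasta FASTA file path, `AAStringSet`, or named character vector
#'   of protein sequences.
#' @param motif A [motif_spec()].
#' @param query Optional query precursor sequence for the homology
#'   prefilter.
#' @param score_threshold Minimum local-alignment score against `query`
#'   (>= 0); 0 disables prefiltering.
#' @param reference_peptide Optional reference peptide for identity
#'   ranking.
#' @param gap_open,gap_extend Affine gap parameters for the prefilter.
#' @return data.frame of candidates: `precursor_id`, `peptide`, `start`,
#'   `end`, `cleavage_signal`, `cleavage_site`, `cleavage_competent`,
#'   `homology_score` (NA when the prefilter is disabled) and, when
#'   ranked, `identity_to_reference`.
#' @export
mine_proteome <- function(fasta, motif = motif_spec(), query = NULL,
                          score_threshold = 0, reference_peptide = NULL,
                          gap_open = 10, gap_extend = 1) {
  if (score_threshold < 0)
    stop("'score_threshold' must be >= 0", call. = FALSE)
  seqs <- as_sequences(fasta)
  empty <- data.frame(
    precursor_id = character(0), peptide = character(0),
    start = integer(0), end = integer(0), cleavage_signal = character(0),
    cleavage_site = integer(0), cleavage_competent = logical(0),
    homology_score = numeric(0), stringsAsFactors = FALSE)
  if (!length(seqs)) {
    warning("empty proteome: no candidates")
    return(empty)
  }
  scores <- rep(NA_real_, length(seqs))
  keep <- rep(TRUE, length(seqs))
  if (score_threshold > 0) {
    if (is.null(query))
      stop("'query' is required when 'score_threshold' > 0", call. = FALSE)
    scores <- vapply(seqs, local_align_score, numeric(1), seq_b = query,
                     gap_open = gap_open, gap_extend = gap_extend,
                     USE.NAMES = FALSE)
    keep <- scores >= score_threshold
  }
  rows <- list()
  for (i in which(keep)) {
    cand <- find_cterm_motif(precursor_protein(names(seqs)[i], seqs[[i]]),
                             motif)
    if (!is.null(cand)) {
      cand$homology_score <- scores[i]
      rows[[length(rows) + 1L]] <- cand
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (!is.null(reference_peptide)) {
    out <- rank_candidates(out, reference_peptide)
  } else {
    out <- out[order(out$precursor_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
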