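# Seeded synthetic-data generators: planted-motif proteomes with decoys,
# Gaussian transition chromatograms with analytically known areas, and
# expression matrices with planted stress responses. Every generator takes
# a spec carrying its own seed and is byte-reproducible for a fixed spec.

DECOY_MODES <- c("no_motif", "internal_motif", "mutated_cleavage_Y",
                 "broken_motif")

random_residues <- function(n) sample(AA_CANONICAL, n, replace = TRUE)

# Random instance of the 11-position peptide pattern (fixed P.GN.....PY
# scaffold, wildcards drawn uniformly from the 20 residues).
random_cape_peptide <- function() {
  p <- random_residues(11L)
  p[1L] <- "P"; p[3L] <- "G"; p[4L] <- "N"; p[10L] <- "P"; p[11L] <- "Y"
  paste(p, collapse = "")
}

#' Specification for a synthetic planted-motif proteome
#'
#' True precursors carry, at the extreme C terminus, a CNYx cleavage signal
#' followed by an 11-residue `PxGNxxxxxPY` peptide, behind a random body
#' with a nominal 25-residue signal peptide. Decoys probe the mining rules
#' one at a time: `no_motif` (random sequence), `internal_motif` (motif
#' planted away from the C terminus, excluded by the terminal-slack rule),
#' `mutated_cleavage_Y` (terminal motif but the critical tyrosine mutated:
#' a hit flagged cleavage-incompetent), `broken_motif` (one fixed peptide
#' position destroyed: no hit).
#'
#' @param n_true_precursors,n_decoys Record counts (>= 0).
#' @param decoy_modes Subset of
#'   `c("no_motif", "internal_motif", "mutated_cleavage_Y", "broken_motif")`;
#'   decoys are distributed round-robin across the chosen modes.
#' @param min_len,max_len Sequence length range in residues (min >= 40 so
#'   the signal peptide and motif always fit).
#' @param seed Integer seed; generation is bit-identical for a fixed spec.
#' @return Object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_true_precursors, n_decoys = 0L,
                          decoy_modes = "no_motif",
                          min_len = 120L, max_len = 250L, seed) {
  stopifnot(n_true_precursors >= 0L, n_decoys >= 0L)
  if (min_len > max_len)
    stop("'min_len' must be <= 'max_len'", call. = FALSE)
  if (min_len < 40L)
    stop("'min_len' must be >= 40 residues", call. = FALSE)
  decoy_modes <- match.arg(decoy_modes, DECOY_MODES, several.ok = TRUE)
  structure(list(n_true_precursors = as.integer(n_true_precursors),
                 n_decoys = as.integer(n_decoys),
                 decoy_modes = decoy_modes,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 seed = check_seed(seed)),
            class = "proteome_spec")
}

#' Generate a synthetic proteome with ground truth
#'
#' @param spec A [proteome_spec()].
#' @param out_dir Optional directory; when given, writes `proteome.fasta`
#'   (wrapped at 60 columns) and `proteome_truth.tsv`.
#' @return List of class `cape_proteome_sim`: `sequences` (named character
#'   vector), `truth` (data.frame: `id`, `role`, `is_true`, `expected_hit`,
#'   `expected_competent`, `peptide`), and file paths when written.
#' @export
generate_proteome <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "proteome_spec"))
  motif <- motif_spec()
  terminal_match <- function(seq) {
    n <- nchar(seq)
    n >= 11L && grepl(motif$peptide_regex, substr(seq, n - 10L, n))
  }
  build <- with_seed(spec$seed, function() {
    seqs <- character(0); truth <- list()
    add <- function(id, seq, role, is_true, hit, competent, pep) {
      seqs[[id]] <<- seq
      truth[[length(truth) + 1L]] <<- data.frame(
        id = id, role = role, is_true = is_true, expected_hit = hit,
        expected_competent = competent, peptide = pep,
        stringsAsFactors = FALSE)
    }
    rand_len <- function() sample(spec$min_len:spec$max_len, 1L)
    # body of given total length with no terminal peptide-pattern match
    clean_random <- function(len) {
      repeat {
        s <- paste(random_residues(len), collapse = "")
        if (!terminal_match(s)) return(s)
      }
    }
    for (i in seq_len(spec$n_true_precursors)) {
      len <- rand_len()
      pep <- random_cape_peptide()
      sig <- paste0("CNY", sample(AA_CANONICAL, 1L))
      body <- clean_random(len - 15L)
      add(sprintf("TRUE_%03d", i), paste0(body, sig, pep),
          "true_precursor", TRUE, TRUE, TRUE, pep)
    }
    if (spec$n_decoys > 0L) {
      modes <- rep_len(spec$decoy_modes, spec$n_decoys)
      for (i in seq_len(spec$n_decoys)) {
        len <- rand_len()
        id <- sprintf("DECOY_%s_%03d", modes[i], i)
        switch(modes[i],
          no_motif = add(id, clean_random(len), modes[i],
                         FALSE, FALSE, FALSE, NA_character_),
          internal_motif = {
            pep <- random_cape_peptide()
            sig <- paste0("CNY", sample(AA_CANONICAL, 1L))
            tail_len <- sample(12:30, 1L)
            prefix <- clean_random(max(len - 15L - tail_len, 20L))
            repeat {
              seq <- paste0(prefix, sig, pep, clean_random(tail_len))
              if (!terminal_match(seq)) break
            }
            add(id, seq, modes[i], FALSE, FALSE, FALSE, pep)
          },
          mutated_cleavage_Y = {
            pep <- random_cape_peptide()
            not_y <- sample(setdiff(AA_CANONICAL, "Y"), 1L)
            sig <- paste0("CN", not_y, sample(AA_CANONICAL, 1L))
            add(id, paste0(clean_random(len - 15L), sig, pep), modes[i],
                FALSE, TRUE, FALSE, pep)
          },
          broken_motif = {
            p <- strsplit(random_cape_peptide(), "")[[1L]]
            # destroy one fixed pattern position
            pos <- sample(c(1L, 3L, 4L, 10L, 11L), 1L)
            p[pos] <- sample(setdiff(AA_CANONICAL, p[pos]), 1L)
            pep <- paste(p, collapse = "")
            sig <- paste0("CNY", sample(AA_CANONICAL, 1L))
            seq <- paste0(clean_random(len - 15L), sig, pep)
            # the break must not leave an accidental match
            stopifnot(!terminal_match(seq))
            add(id, seq, modes[i], FALSE, FALSE, FALSE, NA_character_)
          })
      }
    }
    list(seqs = unlist(seqs), truth = do.call(rbind, truth))
  })
  if (is.null(build$truth))
    build$truth <- data.frame(id = character(0), role = character(0),
                              is_true = logical(0), expected_hit = logical(0),
                              expected_competent = logical(0),
                              peptide = character(0), stringsAsFactors = FALSE)
  out <- list(sequences = build$seqs, truth = build$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$fasta_path <- file.path(out_dir, "proteome.fasta")
    out$truth_path <- file.path(out_dir, "proteome_truth.tsv")
    set <- Biostrings::AAStringSet(out$sequences)
    Biostrings::writeXStringSet(set, out$fasta_path, width = 60L)
    utils::write.table(out$truth, out$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  class(out) <- "cape_proteome_sim"
  out
}

#' Specification for a synthetic targeted-MS run
#'
#' Each sample gets one Gaussian elution peak per transition on a shared
#' retention-time grid. The analyte transition amplitude is
#' `1000 * response_factor * designed_abundance * global_scale`; the
#' internal-standard amplitude uses `is_abundance` in place of the designed
#' abundance (the IS is spiked equally into every sample before scaling,
#' so normalization cancels `global_scale`). The true area of each peak is
#' the closed form `amplitude * rt_sigma * sqrt(2*pi)`. Noise is additive
#' zero-mean Gaussian on intensity, truncated at 0.
#'
#' @param sample_labels Character vector of sample ids.
#' @param designed_abundance Positive relative abundances, one per sample
#'   (recycled named or unnamed).
#' @param is_abundance Internal-standard spike level (default 1).
#' @param rt_center Peak apex retention time in seconds (default 300).
#' @param rt_sigma Peak width (Gaussian sigma) in seconds (default 8).
#' @param noise_sd Additive intensity noise sd (default 20, i.e. 2% of the
#'   base amplitude).
#' @param rt_jitter_sd Per-sample apex jitter sd in seconds (default 2).
#' @param global_scale Per-sample global intensity multiplier (default 1),
#'   emulating injection/instrument variation.
#' @param sampling_interval Grid spacing in seconds (default `rt_sigma/8`).
#' @param seed Integer seed.
#' @return Object of class `run_spec`.
#' @export
run_spec <- function(sample_labels, designed_abundance, is_abundance = 1,
                     rt_center = 300, rt_sigma = 8, noise_sd = 20,
                     rt_jitter_sd = 2, global_scale = 1,
                     sampling_interval = NULL, seed) {
  stopifnot(length(sample_labels) >= 1L, !anyDuplicated(sample_labels))
  designed_abundance <- rep_len(designed_abundance, length(sample_labels))
  global_scale <- rep_len(global_scale, length(sample_labels))
  if (any(designed_abundance <= 0) || is_abundance <= 0)
    stop("abundances must be > 0", call. = FALSE)
  if (rt_sigma <= 0) stop("'rt_sigma' must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (is.null(sampling_interval)) sampling_interval <- rt_sigma / 8
  structure(list(sample_labels = as.character(sample_labels),
                 designed_abundance = stats::setNames(designed_abundance,
                                                      sample_labels),
                 is_abundance = is_abundance, rt_center = rt_center,
                 rt_sigma = rt_sigma, noise_sd = noise_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 global_scale = stats::setNames(global_scale, sample_labels),
                 sampling_interval = sampling_interval,
                 seed = check_seed(seed)),
            class = "run_spec")
}

#' Generate synthetic transition chromatograms for an assay
#'
#' @param spec A [run_spec()].
#' @param assay A `cape_assay` (see [build_assay()]).
#' @param out_dir Optional directory; writes `traces.tsv` (columns
#'   `sample_id`, `transition_id`, `rt_sec`, `intensity`) and
#'   `run_truth.tsv`.
#' @return List of class `cape_run_sim`: `traces` (long data.frame),
#'   `truth$areas` (true per-transition areas), `truth$samples` (per-sample
#'   true summed areas, normalized ratio and relative ratio against the
#'   first sample), plus file paths when written.
#' @export
generate_run <- function(spec, assay, out_dir = NULL) {
  stopifnot(inherits(spec, "run_spec"), inherits(assay, "cape_assay"))
  if (!nrow(assay$analyte_transitions) || !nrow(assay$is_transitions))
    stop("assay needs at least one analyte and one IS transition",
         call. = FALSE)
  # fixed relative response factors per transition (deterministic)
  rf <- function(n) rep_len(c(1, 0.8, 0.6, 0.5, 0.4), n)
  trans <- rbind(
    data.frame(transition_id = assay$analyte_transitions$transition_id,
               role = "analyte",
               factor = rf(nrow(assay$analyte_transitions)),
               stringsAsFactors = FALSE),
    data.frame(transition_id = assay$is_transitions$transition_id,
               role = "is", factor = rf(nrow(assay$is_transitions)),
               stringsAsFactors = FALSE))
  half <- 6 * spec$rt_sigma + 4 * abs(spec$rt_jitter_sd)
  grid <- seq(spec$rt_center - half, spec$rt_center + half,
              by = spec$sampling_interval)
  base_amp <- 1000
  sim <- with_seed(spec$seed, function() {
    traces <- list(); areas <- list()
    for (s in spec$sample_labels) {
      apex <- spec$rt_center + stats::rnorm(1L, 0, spec$rt_jitter_sd)
      for (t in seq_len(nrow(trans))) {
        level <- if (trans$role[t] == "analyte")
          spec$designed_abundance[[s]] else spec$is_abundance
        amp <- base_amp * trans$factor[t] * level * spec$global_scale[[s]]
        signal <- amp * exp(-(grid - apex)^2 / (2 * spec$rt_sigma^2))
        if (spec$noise_sd > 0)
          signal <- pmax(signal + stats::rnorm(length(grid), 0,
                                               spec$noise_sd), 0)
        traces[[length(traces) + 1L]] <- data.frame(
          sample_id = s, transition_id = trans$transition_id[t],
          rt_sec = grid, intensity = signal, stringsAsFactors = FALSE)
        areas[[length(areas) + 1L]] <- data.frame(
          sample_id = s, transition_id = trans$transition_id[t],
          role = trans$role[t],
          true_area = amp * spec$rt_sigma * sqrt(2 * pi),
          stringsAsFactors = FALSE)
      }
    }
    list(traces = do.call(rbind, traces), areas = do.call(rbind, areas))
  })
  areas <- sim$areas
  per_sample <- do.call(rbind, lapply(spec$sample_labels, function(s) {
    a <- sum(areas$true_area[areas$sample_id == s & areas$role == "analyte"])
    i <- sum(areas$true_area[areas$sample_id == s & areas$role == "is"])
    data.frame(sample_id = s, true_analyte_area = a, true_is_area = i,
               true_normalized = a / i, stringsAsFactors = FALSE)
  }))
  per_sample$true_relative_ratio <-
    per_sample$true_normalized / per_sample$true_normalized[1L]
  out <- list(traces = sim$traces,
              truth = list(areas = areas, samples = per_sample))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$traces_path <- file.path(out_dir, "traces.tsv")
    out$truth_path <- file.path(out_dir, "run_truth.tsv")
    utils::write.table(out$traces, out$traces_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(per_sample, out$truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  class(out) <- "cape_run_sim"
  out
}

#' Specification for a synthetic expression matrix
#'
#' Log-normal intensities: per-gene baseline log2 level drawn from
#' `N(baseline_log_mean, baseline_log_sd)`, replicate noise
#' `N(0, noise_sd)` on the log2 scale, planted responses added as log2
#' fold changes in the named non-control conditions. Optional planted QC
#' failures: `qc_low_genes` genes sit entirely below the raw-intensity
#' floor; `qc_highcv_genes` genes get a fixed high-dispersion replicate
#' pattern (CV ~ 112% at every time point) instead of noise.
#'
#' @param n_genes Number of genes.
#' @param conditions Character vector of stress labels; must include
#'   `"control"`. Default panel: control, salt, osmotic, drought, cold,
#'   oxidative (root tissue, 12 h).
#' @param n_replicates Replicates per condition (>= 2; default 3).
#' @param planted_responses data.frame with columns `gene` (id or index),
#'   `condition` (stress label), `log2fc`; or `NULL`.
#' @param baseline_log_mean,baseline_log_sd Baseline log2 intensity
#'   distribution (defaults 10 and 1.5, i.e. raw intensities around 1000).
#'   Baseline draws are truncated below at log2(180) so that every
#'   non-QC-failure gene sits unambiguously above the raw-intensity floor
#'   and the QC ground truth is exact by construction.
#' @param noise_sd Replicate noise sd on log2 scale (default 0.25, about
#'   18% CV on the raw scale).
#' @param qc_low_genes,qc_highcv_genes Planted QC-failure counts
#'   (default 0); these genes are drawn from the last gene indices and are
#'   never planted responders.
#' @param tissue,time_h Metadata constants (defaults "root", 12).
#' @param seed Integer seed.
#' @return Object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 200L,
                            conditions = c("control", "salt", "osmotic",
                                           "drought", "cold", "oxidative"),
                            n_replicates = 3L, planted_responses = NULL,
                            baseline_log_mean = 10, baseline_log_sd = 1.5,
                            noise_sd = 0.25, qc_low_genes = 0L,
                            qc_highcv_genes = 0L, tissue = "root",
                            time_h = 12, seed) {
  if (n_replicates < 2L)
    stop("'n_replicates' must be >= 2 (CV and t-test undefined otherwise)",
         call. = FALSE)
  if (!("control" %in% conditions))
    stop("'conditions' must include \"control\"", call. = FALSE)
  gene_ids <- sprintf("GENE_%04d", seq_len(n_genes))
  if (!is.null(planted_responses)) {
    stopifnot(is.data.frame(planted_responses),
              all(c("gene", "condition", "log2fc") %in%
                  names(planted_responses)))
    if (is.numeric(planted_responses$gene))
      planted_responses$gene <- gene_ids[planted_responses$gene]
    if (!all(planted_responses$gene %in% gene_ids))
      stop("planted gene not in the generated gene set", call. = FALSE)
    if (!all(planted_responses$condition %in% setdiff(conditions, "control")))
      stop("planted condition must be a non-control condition", call. = FALSE)
  }
  n_fail <- qc_low_genes + qc_highcv_genes
  if (n_fail > n_genes)
    stop("more planted QC failures than genes", call. = FALSE)
  if (!is.null(planted_responses) && n_fail > 0L) {
    fail_ids <- gene_ids[seq.int(n_genes - n_fail + 1L, n_genes)]
    if (any(planted_responses$gene %in% fail_ids))
      stop("planted responders overlap planted QC failures", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 planted_responses = planted_responses,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, noise_sd = noise_sd,
                 qc_low_genes = as.integer(qc_low_genes),
                 qc_highcv_genes = as.integer(qc_highcv_genes),
                 tissue = tissue, time_h = time_h, seed = check_seed(seed)),
            class = "expression_spec")
}

#' Generate a synthetic expression matrix with ground truth
#'
#' @param spec An [expression_spec()].
#' @param out_dir Optional directory; writes `expression.tsv` (gene rows,
#'   sample columns) and `samples.tsv` (sample_id, stress, tissue, time_h,
#'   replicate).
#' @return List of class `cape_expression_sim`: `matrix` (genes x samples),
#'   `metadata`, `truth` (per gene: `gene`, `role`, `expected_qc_pass`,
#'   and per planted response its condition and log2fc), plus paths when
#'   written.
#' @export
generate_expression <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "expression_spec"))
  meta <- expand.grid(replicate = seq_len(spec$n_replicates),
                      stress = spec$conditions, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%dh_r%d", meta$stress, spec$time_h,
                        meta$replicate),
    stress = meta$stress, tissue = spec$tissue, time_h = spec$time_h,
    replicate = meta$replicate, stringsAsFactors = FALSE)
  n_fail_low <- spec$qc_low_genes
  n_fail_cv <- spec$qc_highcv_genes
  n <- spec$n_genes
  role <- rep("baseline", n)
  if (n_fail_cv > 0L)
    role[seq.int(n - n_fail_cv + 1L, n)] <- "qc_highcv"
  if (n_fail_low > 0L)
    role[seq.int(n - n_fail_cv - n_fail_low + 1L, n - n_fail_cv)] <- "qc_low"
  planted <- spec$planted_responses
  if (!is.null(planted) && nrow(planted))
    role[match(unique(planted$gene), spec$gene_ids)] <- "planted"

  mat <- with_seed(spec$seed, function() {
    base <- pmax(stats::rnorm(n, spec$baseline_log_mean,
                              spec$baseline_log_sd), log2(180))
    base[role == "qc_low"] <- stats::rnorm(sum(role == "qc_low"), 4, 0.3)
    m <- matrix(0, nrow = n, ncol = nrow(meta),
                dimnames = list(spec$gene_ids, meta$sample_id))
    # fixed replicate pattern giving CV ~112% regardless of noise
    cv_pattern <- rep_len(c(0.05, 1, 3), spec$n_replicates)
    for (j in seq_len(nrow(meta))) {
      lfc <- rep(0, n)
      if (!is.null(planted) && nrow(planted)) {
        hit <- planted$condition == meta$stress[j]
        if (any(hit))
          lfc[match(planted$gene[hit], spec$gene_ids)] <- planted$log2fc[hit]
      }
      m[, j] <- 2^(base + lfc + stats::rnorm(n, 0, spec$noise_sd))
      cvg <- role == "qc_highcv"
      if (any(cvg))
        m[cvg, j] <- 2^(base[cvg]) * cv_pattern[meta$replicate[j]]
    }
    m
  })
  truth <- data.frame(gene = spec$gene_ids, role = role,
                      expected_qc_pass = role %in% c("baseline", "planted"),
                      stringsAsFactors = FALSE)
  out <- list(matrix = mat, metadata = meta, truth = truth,
              planted_responses = planted)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$matrix_path <- file.path(out_dir, "expression.tsv")
    out$metadata_path <- file.path(out_dir, "samples.tsv")
    tab <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, out$matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(meta, out$metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  class(out) <- "cape_expression_sim"
  out
}
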