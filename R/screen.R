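# Expression screening: microarray-style QC (raw intensity floor + CV
# ceiling at any time point), median normalization, Welch-t differential
# expression with a linear fold-change threshold, multi-stress specificity
# classification, and the qPCR relative-transcript transform.

#' Screen configuration
#'
#' Thresholds of the expression screen: genes are kept by QC when at some
#' time point the mean raw intensity exceeds `min_intensity` AND the
#' replicate CV (sd/mean) is below `max_cv` percent; a contrast is called
#' differentially expressed at `fold_change >= fc_threshold` (or <= its
#' reciprocal) with `p <= p_threshold`; a gene is salt specific when it is
#' DE under salt and DE in at most `specificity_stress_limit` non-salt
#' stress categories.
#'
#' @param min_intensity Raw-intensity floor (default 100).
#' @param max_cv CV ceiling in percent (default 50).
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @param specificity_stress_limit Non-salt stress categories a
#'   salt-specific gene may also respond to (default 1).
#' @param adjust_p Apply Benjamini-Hochberg FDR before thresholding
#'   (default FALSE, reproducing a raw-p screen).
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(min_intensity = 100, max_cv = 50,
                          fc_threshold = 1.5, p_threshold = 0.05,
                          specificity_stress_limit = 1L,
                          adjust_p = FALSE) {
  stopifnot(min_intensity > 0, max_cv > 0, fc_threshold > 0,
            p_threshold > 0, specificity_stress_limit >= 0)
  structure(list(min_intensity = min_intensity, max_cv = max_cv,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 specificity_stress_limit = as.integer(
                   specificity_stress_limit),
                 adjust_p = isTRUE(adjust_p)),
            class = "screen_config")
}

# condition key used to group replicates ("time point")
condition_key <- function(meta) paste(meta$stress, meta$time_h, sep = "@")

# columns of `matrix` belonging to a condition label, which may be a
# stress name or a full "stress@time" key
samples_for <- function(meta, label) {
  hit <- meta$stress == label | condition_key(meta) == label
  meta$sample_id[hit]
}

check_matrix <- function(matrix, meta) {
  if (is.data.frame(matrix)) {
    if ("gene" %in% names(matrix)) {
      rn <- matrix$gene
      matrix <- as.matrix(matrix[setdiff(names(matrix), "gene")])
      rownames(matrix) <- rn
    } else matrix <- as.matrix(matrix)
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  if (!all(meta$sample_id %in% colnames(matrix)))
    stop("metadata sample_id values missing from the matrix columns",
         call. = FALSE)
  matrix[, meta$sample_id, drop = FALSE]
}

#' Quality-control filter on raw intensities
#'
#' A gene passes when there EXISTS a time point (a stress/time condition)
#' at which the mean raw intensity across replicates exceeds
#' `min_intensity` and the coefficient of variation (sd/mean, percent) is
#' below `max_cv`. Conditions with a single replicate cannot qualify (CV
#' undefined) and raise a warning.
#'
#' @param matrix Genes x samples numeric matrix of raw intensities (or a
#'   data.frame with a `gene` column).
#' @param meta Sample metadata data.frame: `sample_id`, `stress`,
#'   `time_h`, `replicate`.
#' @param config A [screen_config()].
#' @return Character vector of gene ids passing QC.
#' @export
qc_filter <- function(matrix, meta, config = screen_config()) {
  m <- check_matrix(matrix, meta)
  keys <- condition_key(meta)
  pass <- rep(FALSE, nrow(m))
  for (key in unique(keys)) {
    cols <- which(keys == key)
    if (length(cols) < 2L) {
      warning(sprintf(
        "condition '%s' has a single replicate; CV undefined, skipped", key))
      next
    }
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    cv <- 100 * apply(sub, 1L, stats::sd) / mu
    pass <- pass | (mu > config$min_intensity & cv < config$max_cv)
  }
  rownames(m)[pass]
}

#' Median-scale normalization to a control condition
#'
#' Scales each sample so that its median matches the median of the
#' control-condition sample medians (the published screen normalized to
#' the untreated control without naming an algorithm; per-sample median
#' scaling is the declared substitute).
#'
#' @inheritParams qc_filter
#' @param control Condition label (stress or `"stress@time"`) used as the
#'   normalization reference.
#' @return Normalized matrix, same dimensions.
#' @export
normalize_expression <- function(matrix, meta, control = "control") {
  m <- check_matrix(matrix, meta)
  ctrl <- samples_for(meta, control)
  if (!length(ctrl))
    stop(sprintf("control condition '%s' not found", control), call. = FALSE)
  med <- apply(m, 2L, stats::median)
  ref <- stats::median(med[ctrl])
  sweep(m, 2L, ref / med, `*`)
}

#' Call differential expression for one contrast
#'
#' Fold change is the ratio of condition means on the (optionally
#' median-normalized) linear scale; the p-value comes from a Welch
#' (unequal-variance) two-sample t-test on log2 intensities. The DE flag
#' requires `fold_change >= fc_threshold` or `<= 1/fc_threshold` together
#' with `p <= p_threshold`. Two identical zero-variance groups get p = 1
#' by convention (zero-variance groups with different means get p = 0).
#'
#' @inheritParams qc_filter
#' @param contrast Length-2 character: condition labels (a, b); fold
#'   change is mean(a)/mean(b).
#' @param genes Optional gene subset (e.g. the [qc_filter()] result).
#' @param normalize Normalize to `contrast[2]` first (default TRUE).
#' @return data.frame: `gene`, `mean_a`, `mean_b`, `fold_change`,
#'   `direction` ("up"/"down"), `p_value`, `de_flag`.
#' @export
call_de <- function(matrix, meta, contrast, config = screen_config(),
                    genes = NULL, normalize = TRUE) {
  stopifnot(length(contrast) == 2L)
  m <- if (normalize) normalize_expression(matrix, meta, contrast[2L])
       else check_matrix(matrix, meta)
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  ca <- samples_for(meta, contrast[1L])
  cb <- samples_for(meta, contrast[2L])
  if (length(ca) < 2L || length(cb) < 2L)
    stop("both contrast conditions need >= 2 replicates", call. = FALSE)
  a <- m[, ca, drop = FALSE]
  b <- m[, cb, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  la <- log2(a)
  lb <- log2(b)
  p <- vapply(seq_len(nrow(m)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
      return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
    stats::t.test(xa, xb, var.equal = FALSE)$p.value
  }, numeric(1))
  if (config$adjust_p) p <- stats::p.adjust(p, method = "BH")
  fc <- mean_a / mean_b
  out <- data.frame(
    gene = rownames(m), mean_a = mean_a, mean_b = mean_b, fold_change = fc,
    direction = ifelse(fc >= 1, "up", "down"), p_value = p,
    de_flag = (fc >= config$fc_threshold | fc <= 1 / config$fc_threshold) &
      p <= config$p_threshold,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify stress specificity across a condition panel
#'
#' Takes DE calls for one stress panel (long format: one row per gene and
#' stress) and classifies each gene: `salt_specific` when DE under salt
#' and DE in at most `specificity_stress_limit` non-salt stress
#' categories; `multi_stress` when DE in more non-salt categories than the
#' limit; `non_responsive` otherwise. The panel must contain the salt
#' condition and at least two non-salt categories; the classification does
#' not depend on the row order.
#'
#' @param de_results data.frame with columns `gene`, `stress`, `de_flag`
#'   (e.g. stacked [call_de()] outputs with a `stress` column added).
#' @param config A [screen_config()].
#' @param salt_label Name of the salt condition (default "salt").
#' @return data.frame: `gene`, `de_salt`, `n_other_stress`,
#'   `specificity_class`.
#' @export
classify_specificity <- function(de_results, config = screen_config(),
                                 salt_label = "salt") {
  stopifnot(is.data.frame(de_results),
            all(c("gene", "stress", "de_flag") %in% names(de_results)))
  stresses <- unique(de_results$stress)
  if (!(salt_label %in% stresses))
    stop(sprintf("panel lacks the salt condition ('%s')", salt_label),
         call. = FALSE)
  if (length(setdiff(stresses, salt_label)) < 2L)
    stop("panel needs at least 2 non-salt stress categories", call. = FALSE)
  genes <- sort(unique(de_results$gene))
  out <- do.call(rbind, lapply(genes, function(g) {
    d <- de_results[de_results$gene == g, , drop = FALSE]
    de_salt <- any(d$de_flag[d$stress == salt_label])
    n_other <- length(unique(d$stress[d$de_flag & d$stress != salt_label]))
    cls <- if (n_other > config$specificity_stress_limit) "multi_stress"
           else if (de_salt) "salt_specific"
           else "non_responsive"
    data.frame(gene = g, de_salt = de_salt, n_other_stress = n_other,
               specificity_class = cls, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' qPCR relative transcript level
#'
#' `scale * 2^-(Ct_target - Ct_reference)`: the scaled 2^-dCt transform
#' against a reference gene (vectorized).
#'
#' @param ct_target,ct_reference Finite Ct values.
#' @param scale Reporting scale (default 1000).
#' @return Relative transcript level(s).
#' @examples
#' relative_transcript(21, 21)  # 1000
#' relative_transcript(22, 21)  # 500
#' @export
relative_transcript <- function(ct_target, ct_reference, scale = 1000) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  scale * 2^(-(ct_target - ct_reference))
}
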