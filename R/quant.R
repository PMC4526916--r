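# Label-free targeted quantification: XIC extraction, baseline-subtracted
# trapezoidal peak integration, transition summing, internal-standard
# normalization and relative ratios against a control sample.

#' Read transition chromatograms from the canonical TSV
#'
#' Expected columns: `sample_id`, `transition_id`, `rt_sec`, `intensity`.
#'
#' @param path TSV path.
#' @return Long data.frame of traces.
#' @export
read_traces <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "transition_id", "rt_sec", "intensity")
  if (!all(need %in% names(tr)))
    stop(sprintf("trace file must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  tr
}

#' Extract an ion chromatogram
#'
#' Two input routes. Raw-spectrum route: a long data.frame of profile data
#' with columns `rt_sec`, `mz`, `intensity` is reduced to one point per
#' scan by summing intensity within `target_mz +/- tolerance`. Canonical
#' trace route: a trace data.frame (see [read_traces()]) is subset by
#' `transition_id` (and `sample_id` when given). An empty result is an
#' empty trace, not an error.
#'
#' @param x Spectra or trace data.frame.
#' @param target_mz Centre of the extraction window (spectra route).
#' @param tolerance Half-window in Thomson (default 0.5).
#' @param transition_id,sample_id Selection for the trace route.
#' @return data.frame with columns `rt_sec`, `intensity` (plus the
#'   identifying columns on the trace route), ordered by retention time.
#' @export
extract_xic <- function(x, target_mz = NULL, tolerance = 0.5,
                        transition_id = NULL, sample_id = NULL) {
  if (tolerance <= 0) stop("'tolerance' must be > 0", call. = FALSE)
  stopifnot(is.data.frame(x))
  if ("mz" %in% names(x)) {
    if (is.null(target_mz))
      stop("'target_mz' is required for spectrum input", call. = FALSE)
    sel <- x[abs(x$mz - target_mz) <= tolerance, , drop = FALSE]
    if (!nrow(sel))
      return(data.frame(rt_sec = numeric(0), intensity = numeric(0)))
    agg <- stats::aggregate(intensity ~ rt_sec, data = sel, FUN = sum)
    return(agg[order(agg$rt_sec), c("rt_sec", "intensity")])
  }
  stopifnot(all(c("transition_id", "rt_sec", "intensity") %in% names(x)))
  sel <- x
  if (!is.null(transition_id))
    sel <- sel[sel$transition_id %in% transition_id, , drop = FALSE]
  if (!is.null(sample_id))
    sel <- sel[sel$sample_id %in% sample_id, , drop = FALSE]
  sel[order(sel$rt_sec), , drop = FALSE]
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integration of intensity over retention time within
#' `rt_window`, after baseline subtraction. `baseline = "edge_median"`
#' (default) subtracts the median of the first and last three points of
#' the window (so a constant trace integrates to zero); `"none"` skips
#' subtraction. The area is clamped at 0.
#'
#' @param trace data.frame with `rt_sec`, `intensity`.
#' @param rt_window Optional `c(start, end)` in seconds; default is the
#'   whole trace.
#' @param baseline `"edge_median"` or `"none"`.
#' @return Peak area (intensity x seconds), >= 0. Fewer than 3 points in
#'   the window gives 0 with a warning.
#' @export
integrate_peak <- function(trace, rt_window = NULL,
                           baseline = c("edge_median", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(trace),
            all(c("rt_sec", "intensity") %in% names(trace)))
  tr <- trace[order(trace$rt_sec), , drop = FALSE]
  if (!is.null(rt_window)) {
    stopifnot(length(rt_window) == 2L, rt_window[1L] <= rt_window[2L])
    tr <- tr[tr$rt_sec >= rt_window[1L] & tr$rt_sec <= rt_window[2L], ,
             drop = FALSE]
  }
  if (nrow(tr) < 3L) {
    warning("fewer than 3 points in the integration window; area = 0")
    return(0)
  }
  y <- tr$intensity
  if (baseline == "edge_median") {
    k <- min(3L, nrow(tr))
    y <- y - stats::median(c(utils::head(tr$intensity, k),
                             utils::tail(tr$intensity, k)))
  }
  max(trapz(tr$rt_sec, y), 0)
}

# Locate the apex of a trace (optionally restricted near an expected RT)
# and return the integration window around it.
apex_window <- function(tr, rt_expected = NULL, rt_tol = Inf,
                        window_halfwidth = 30) {
  sel <- tr
  if (!is.null(rt_expected) && is.finite(rt_tol))
    sel <- tr[abs(tr$rt_sec - rt_expected) <= rt_tol, , drop = FALSE]
  if (!nrow(sel)) sel <- tr
  apex <- sel$rt_sec[which.max(sel$intensity)]
  c(apex - window_halfwidth, apex + window_halfwidth)
}

#' Quantify one sample from its transition traces
#'
#' For each assay transition: find the apex (within `rt_expected +/-
#' rt_tol` when given), integrate `apex +/- window_halfwidth`, then sum
#' areas over the analyte transitions and over the internal-standard
#' transitions. `normalized = analyte_area / is_area`. Missing transitions
#' contribute area 0 with a warning; a zero IS area flags the sample and
#' leaves `normalized` as NA.
#'
#' @param traces Long trace data.frame for one sample (a `sample_id`
#'   column, when present, must be constant).
#' @param assay A `cape_assay`.
#' @param rt_expected,rt_tol Optional expected apex location and search
#'   half-window (seconds).
#' @param window_halfwidth Integration half-window in seconds (default 30).
#' @param baseline Passed to [integrate_peak()].
#' @return One-row data.frame: `sample_id`, `analyte_area`, `is_area`,
#'   `normalized`, `flagged`.
#' @export
quantify_sample <- function(traces, assay, rt_expected = NULL, rt_tol = Inf,
                            window_halfwidth = 30,
                            baseline = c("edge_median", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(assay, "cape_assay"), is.data.frame(traces))
  sid <- if ("sample_id" %in% names(traces)) {
    u <- unique(traces$sample_id)
    if (length(u) > 1L)
      stop("'traces' contains several samples; use quantify_samples()",
           call. = FALSE)
    if (length(u)) u else NA_character_
  } else NA_character_
  area_of <- function(tid) {
    tr <- traces[traces$transition_id == tid, , drop = FALSE]
    if (!nrow(tr)) {
      warning(sprintf("transition '%s' missing in sample '%s'; area = 0",
                      tid, sid))
      return(0)
    }
    tr <- tr[order(tr$rt_sec), , drop = FALSE]
    win <- apex_window(tr, rt_expected, rt_tol, window_halfwidth)
    integrate_peak(tr, rt_window = win, baseline = baseline)
  }
  a <- sum(vapply(assay$analyte_transitions$transition_id, area_of,
                  numeric(1)))
  i <- sum(vapply(assay$is_transitions$transition_id, area_of, numeric(1)))
  flagged <- i <= 0
  if (flagged)
    warning(sprintf("sample '%s': internal-standard area is 0; flagged", sid))
  data.frame(sample_id = sid, analyte_area = a, is_area = i,
             normalized = if (flagged) NA_real_ else a / i,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Quantify every sample in a trace table
#'
#' @inheritParams quantify_sample
#' @param traces Long trace data.frame with a `sample_id` column.
#' @return data.frame with one row per sample (order of first appearance).
#' @export
quantify_samples <- function(traces, assay, rt_expected = NULL,
                             rt_tol = Inf, window_halfwidth = 30,
                             baseline = c("edge_median", "none")) {
  baseline <- match.arg(baseline)
  stopifnot("sample_id" %in% names(traces))
  ids <- unique(traces$sample_id)
  do.call(rbind, lapply(ids, function(s)
    quantify_sample(traces[traces$sample_id == s, , drop = FALSE], assay,
                    rt_expected = rt_expected, rt_tol = rt_tol,
                    window_halfwidth = window_halfwidth,
                    baseline = baseline)))
}

#' Relative ratios against a control sample
#'
#' Divides each sample's IS-normalized area by the control sample's; the
#' control itself gets ratio exactly 1. The control must be present and
#' not flagged. Flagged samples keep an NA ratio.
#'
#' @param results data.frame from [quantify_samples()].
#' @param control_sample_id Id of the reference sample.
#' @return `results` with a `relative_ratio` column.
#' @export
relative_ratios <- function(results, control_sample_id) {
  stopifnot(is.data.frame(results),
            all(c("sample_id", "normalized", "flagged") %in% names(results)))
  k <- match(control_sample_id, results$sample_id)
  if (is.na(k))
    stop(sprintf("control sample '%s' not found", control_sample_id),
         call. = FALSE)
  if (results$flagged[k])
    stop(sprintf("control sample '%s' is flagged (zero IS area)",
                 control_sample_id), call. = FALSE)
  results$relative_ratio <- results$normalized / results$normalized[k]
  results$relative_ratio[k] <- 1
  results
}

#' End-to-end quantification of a run
#'
#' [quantify_samples()] followed by [relative_ratios()].
#'
#' @inheritParams quantify_samples
#' @param control_sample_id Control (reference) sample id.
#' @return data.frame with per-sample areas, normalized values and
#'   relative ratios.
#' @export
quantify_run <- function(traces, assay, control_sample_id,
                         rt_expected = NULL, rt_tol = Inf,
                         window_halfwidth = 30,
                         baseline = c("edge_median", "none")) {
  res <- quantify_samples(traces, assay, rt_expected = rt_expected,
                          rt_tol = rt_tol,
                          window_halfwidth = window_halfwidth,
                          baseline = baseline)
  relative_ratios(res, control_sample_id)
}
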