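# Semi-quantitative seedling phenotypes under salt stress: severity
# classes I-IV from leaf counts/colour, class distributions, and
# germination-rate summaries.

#' Severity class of a seedling observation
#'
#' Ordinal classes generalizing the published six-leaf diagram to leaf
#' fractions: class I when dead or no green leaves; IV when the green
#' fraction is at least 5/6; III at least 4/6; II when the pale-or-green
#' fraction is at least 4/6 but the green fraction is below 4/6; otherwise
#' I. Exact six-leaf cases reproduce the published assignments (vectorized
#' over observations).
#'
#' @param total_leaves Total leaf count (> 0 for living seedlings).
#' @param green_leaves,pale_leaves Green and yellow-to-pale-green leaf
#'   counts; `green + pale <= total`.
#' @param alive Logical; dead seedlings are class I.
#' @return Character vector of classes `"I"`, `"II"`, `"III"`, `"IV"`.
#' @examples
#' severity_class(6, 5)              # "IV"
#' severity_class(6, 4)              # "III"
#' severity_class(6, 0, alive = FALSE)  # "I"
#' @export
severity_class <- function(total_leaves, green_leaves, pale_leaves = 0,
                           alive = TRUE) {
  n <- max(length(total_leaves), length(green_leaves), length(pale_leaves),
           length(alive))
  total_leaves <- rep_len(total_leaves, n)
  green_leaves <- rep_len(green_leaves, n)
  pale_leaves <- rep_len(pale_leaves, n)
  alive <- rep_len(alive, n)
  if (any(green_leaves < 0 | pale_leaves < 0 | total_leaves < 0))
    stop("leaf counts must be >= 0", call. = FALSE)
  if (any(green_leaves + pale_leaves > total_leaves))
    stop("green + pale leaves exceed total leaves", call. = FALSE)
  if (any(alive & total_leaves == 0))
    stop("living seedling with zero leaves is inconsistent", call. = FALSE)
  gf <- ifelse(total_leaves > 0, green_leaves / total_leaves, 0)
  pg <- ifelse(total_leaves > 0,
               (green_leaves + pale_leaves) / total_leaves, 0)
  out <- rep("I", n)
  live <- alive & green_leaves > 0
  out[live & gf >= 5 / 6] <- "IV"
  out[live & gf >= 4 / 6 & gf < 5 / 6] <- "III"
  out[live & pg >= 4 / 6 & gf < 4 / 6] <- "II"
  out
}

#' Distribution of severity classes
#'
#' Percentage of observations in each class I-IV; percentages sum to 100.
#'
#' @param classes Character vector of classes (e.g. from
#'   [severity_class()]); must be non-empty.
#' @return Named numeric vector over `I`, `II`, `III`, `IV`, in percent.
#' @export
class_distribution <- function(classes) {
  if (!length(classes)) stop("no observations", call. = FALSE)
  if (!all(classes %in% c("I", "II", "III", "IV")))
    stop("classes must be I, II, III or IV", call. = FALSE)
  counts <- table(factor(classes, levels = c("I", "II", "III", "IV")))
  stats::setNames(100 * as.vector(counts) / length(classes), names(counts))
}

#' Germination rate per day
#'
#' `100 * n_germinated / n_total` per record. When the counts are
#' cumulative the percentages are checked to be non-decreasing over days.
#'
#' @param records data.frame with columns `day`, `n_germinated`,
#'   `n_total`.
#' @param cumulative Counts are cumulative (default TRUE); enables the
#'   monotonicity check.
#' @return data.frame `day`, `percent`, ordered by day.
#' @export
germination_rate <- function(records, cumulative = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("day", "n_germinated", "n_total") %in% names(records)))
  if (any(records$n_total <= 0))
    stop("'n_total' must be > 0", call. = FALSE)
  if (any(records$n_germinated < 0 |
          records$n_germinated > records$n_total))
    stop("'n_germinated' must lie in [0, n_total]", call. = FALSE)
  out <- data.frame(day = records$day,
                    percent = 100 * records$n_germinated / records$n_total)
  out <- out[order(out$day), , drop = FALSE]
  if (cumulative && nrow(out) > 1L && any(diff(out$percent) < -1e-9))
    stop("cumulative germination percentages must be non-decreasing",
         call. = FALSE)
  rownames(out) <- NULL
  out
}
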