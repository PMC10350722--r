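#' Place an item score on the common 0-1 scale
#'
#' Divides the raw score by the item's points-possible (its number of
#' response choices), so a score of 2 on a 1-4 item becomes 0.50. This
#' literal convention is the default used everywhere scale mean-scores,
#' facets and factor scores are built: a 1-4 item maps to 0.25-1.00 and a
#' 0-3 item to 0.00-0.75. An alternative `"minmax"` mode maps each item's
#' admissible range onto exactly [0, 1] for sensitivity analysis.
#'
#' @param score Integer score(s) on the item's native scale.
#' @param item An [item_definition()].
#' @param mode `"points_possible"` (default, literal) or `"minmax"`.
#' @return Numeric in [0, 1], same length as `score`.
#' @examples
#' it <- item_definition("X1", "example", n_options = 4, min_score = 1)
#' rescale_item(2, it)  # 0.5
#' @export
rescale_item <- function(score, item, mode = c("points_possible", "minmax")) {
  mode <- match.arg(mode)
  stopifnot(inherits(item, "item_definition"))
  ok <- is.na(score) | (score >= item$min_score & score <= item$max_score)
  if (!all(ok))
    stop("score out of range [", item$min_score, ", ", item$max_score,
         "] for item '", item$item_id, "'", call. = FALSE)
  if (mode == "points_possible") score / item$points_possible
  else (score - item$min_score) / (item$max_score - item$min_score)
}

#' Rescale every response in a cube
#'
#' @inheritParams rescale_item
#' @param cube A [response_cube()].
#' @return The cube's long response table with an added `value` column of
#'   rescaled scores.
#' @export
rescale_responses <- function(cube, mode = c("points_possible", "minmax")) {
  mode <- match.arg(mode)
  r <- cube$responses
  it <- cube$items
  idx <- match(r$item_id, it$item_id)
  r$value <- if (mode == "points_possible") r$score / it$points_possible[idx]
  else (r$score - it$min_score[idx]) / (it$max_score[idx] - it$min_score[idx])
  r
}

# internal: rescaled score matrix (patients x items) at one timepoint
rescaled_matrix <- function(cube, item_ids, timepoint, patients = NULL,
                            mode = "points_possible") {
  m <- score_matrix(cube, item_ids, timepoint, patients)
  it <- cube$items
  idx <- match(colnames(m), it$item_id)
  if (mode == "points_possible") {
    sweep(m, 2L, it$points_possible[idx], "/")
  } else {
    m <- sweep(m, 2L, it$min_score[idx], "-")
    sweep(m, 2L, it$max_score[idx] - it$min_score[idx], "/")
  }
}

#' QIDS-SR16 compound-criterion sum-score
#'
#' The conventional total: within each of the three compound criteria
#' (Sleep = QIDS1-4, Weight/appetite = QIDS6-9, Psychomotor = QIDS15-16)
#' only the highest-scored member counts, and these three maxima are summed
#' with the six singleton criterion items (QIDS5, QIDS10-QIDS14), giving an
#' integer in 0-27.
#'
#' @param cube A [response_cube()].
#' @param timepoint Single timepoint.
#' @param patients Optional subset; default all patients. Patients missing
#'   any of the 16 items raise an error naming the absent items (use
#'   `na_rm_patients = TRUE` to silently drop incomplete patients instead).
#' @param na_rm_patients Drop patients with incomplete QIDS instead of
#'   erroring.
#' @return `data.frame` with columns `patient_id`, `timepoint`, `scale_id`,
#'   `variant` (`"qids_sum"`), `value`.
#' @export
qids_sum_score <- function(cube, timepoint, patients = NULL,
                           na_rm_patients = FALSE) {
  items <- paste0("QIDS", 1:16)
  m <- score_matrix(cube, items, timepoint, patients)
  incomplete <- rowSums(is.na(m)) > 0L
  if (any(incomplete)) {
    if (!na_rm_patients) {
      p <- rownames(m)[incomplete][1L]
      absent <- colnames(m)[is.na(m[p, ])]
      stop("patient '", p, "' is missing QIDS item(s) at '", timepoint,
           "': ", paste(absent, collapse = ", "), call. = FALSE)
    }
    m <- m[!incomplete, , drop = FALSE]
  }
  crit <- cbind(
    apply(m[, paste0("QIDS", 1:4), drop = FALSE], 1L, max),
    apply(m[, paste0("QIDS", 6:9), drop = FALSE], 1L, max),
    apply(m[, paste0("QIDS", 15:16), drop = FALSE], 1L, max),
    m[, paste0("QIDS", 10:14), drop = FALSE], m[, "QIDS5"])
  data.frame(patient_id = rownames(m), timepoint = timepoint,
             scale_id = "QIDS", variant = "qids_sum",
             value = unname(rowSums(crit)), row.names = NULL)
}

# item sets for the de-compounded QIDS mean-scores: reverse-direction
# sleep/appetite/weight items are excluded rather than reverse-coded
.qids_variant_excl <- list(
  all_items_1 = c("QIDS4", "QIDS7", "QIDS9"),
  all_items_2 = c("QIDS4", "QIDS6", "QIDS8"))

#' De-compounded QIDS mean-score variants
#'
#' Averages 13 rescaled QIDS items with no max-selection anywhere.
#' Variant `all_items_1` drops Sleeping too much, Increased appetite and
#' Increased weight; `all_items_2` drops Sleeping too much, Decreased
#' appetite and Decreased weight (averaging "increased" and "decreased"
#' items together would require reverse-scoring, so each variant keeps one
#' direction).
#'
#' @inheritParams qids_sum_score
#' @param variant `"all_items_1"` or `"all_items_2"`.
#' @param mode Rescaling convention passed to the internal rescaler.
#' @return `data.frame` as in [qids_sum_score()] with variant
#'   `"qids_mean_all_items_1"` or `"_2"` and `value` in [0, 1].
#' @export
qids_mean_variant <- function(cube, timepoint,
                              variant = c("all_items_1", "all_items_2"),
                              patients = NULL, na_rm_patients = FALSE,
                              mode = "points_possible") {
  variant <- match.arg(variant)
  items <- setdiff(paste0("QIDS", 1:16), .qids_variant_excl[[variant]])
  m <- rescaled_matrix(cube, items, timepoint, patients, mode)
  incomplete <- rowSums(is.na(m)) > 0L
  if (any(incomplete) && !na_rm_patients) {
    p <- rownames(m)[incomplete][1L]
    stop("patient '", p, "' is missing QIDS item(s) at '", timepoint, "': ",
         paste(colnames(m)[is.na(m[p, ])], collapse = ", "), call. = FALSE)
  }
  m <- m[!incomplete, , drop = FALSE]
  data.frame(patient_id = rownames(m), timepoint = timepoint,
             scale_id = "QIDS",
             variant = paste0("qids_mean_", variant),
             value = unname(rowMeans(m)), row.names = NULL)
}

#' Scale mean-score on the common 0-1 scale
#'
#' Rescales each item by its points-possible and averages all items of the
#' instrument, so every scale lives on the same response metric.
#'
#' @inheritParams qids_mean_variant
#' @param scale_id One of the ids in `cube$scales`.
#' @param min_complete Minimum fraction of the scale's items a patient must
#'   have for a score (default 1 = complete cases; the mean is over the
#'   items present).
#' @return `data.frame` as in [qids_sum_score()] with variant
#'   `"mean_score"`.
#' @export
scale_mean_score <- function(cube, scale_id, timepoint, patients = NULL,
                             mode = "points_possible", min_complete = 1) {
  sc <- cube$scales[[scale_id]]
  if (is.null(sc)) stop("unknown scale id: ", scale_id, call. = FALSE)
  m <- rescaled_matrix(cube, names(sc$items), timepoint, patients, mode)
  frac <- rowMeans(!is.na(m))
  if (all(frac == 0))
    stop("no '", scale_id, "' responses at timepoint '", timepoint, "'",
         call. = FALSE)
  keep <- frac >= min_complete & frac > 0
  m <- m[keep, , drop = FALSE]
  data.frame(patient_id = rownames(m), timepoint = timepoint,
             scale_id = scale_id, variant = "mean_score",
             value = unname(rowMeans(m, na.rm = TRUE)), row.names = NULL)
}

#' Cronbach's alpha and corrected item-total correlations
#'
#' alpha = k/(k-1) * (1 - sum(item variances)/var(total)); r.drop for each
#' item is the Pearson correlation between the item and the total of the
#' remaining items. Patients with any missing item are listwise-deleted and
#' counted in the report.
#'
#' @param mat Numeric matrix, patients x items (>= 2 items; >= 3 complete
#'   patients).
#' @return Object of class `reliability_report`: list with `alpha`,
#'   `r_drop` (named per item), `n_items`, `n_patients` (complete cases),
#'   `n_dropped`.
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 items", call. = FALSE)
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 3L)
    stop("need at least 3 complete patients", call. = FALSE)
  k <- ncol(mat)
  total <- rowSums(mat)
  vt <- stats::var(total)
  if (vt == 0) stop("total score has zero variance; alpha undefined",
                    call. = FALSE)
  alpha <- k / (k - 1) * (1 - sum(apply(mat, 2L, stats::var)) / vt)
  r_drop <- vapply(seq_len(k), function(j) {
    item <- mat[, j]
    rest <- total - item
    if (stats::sd(item) == 0 || stats::sd(rest) == 0)
      stop("zero variance in item '", colnames(mat)[j],
           "' or its complement; r.drop undefined", call. = FALSE)
    stats::cor(item, rest)
  }, numeric(1))
  names(r_drop) <- colnames(mat)
  structure(list(alpha = alpha, r_drop = r_drop, n_items = k,
                 n_patients = nrow(mat), n_dropped = n_dropped),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> alpha = %.3f (%d items, %d patients",
              x$alpha, x$n_items, x$n_patients))
  if (x$n_dropped) cat(", ", x$n_dropped, " dropped", sep = "")
  cat(")\n")
  invisible(x)
}

#' Check response-option endorsement frequencies for ordinality
#'
#' In a normal population, endorsement should fall as symptom severity
#' rises, so the per-option frequency vector should be non-increasing.
#' Each adjacent pair where the higher option is endorsed strictly more
#' often than its predecessor is flagged.
#'
#' @param freqs Non-negative counts per response option, lowest option
#'   first (>= 2 options). Names, if present, label the options; otherwise
#'   options are labelled 0, 1, 2, ...
#' @return `data.frame` of violations with columns `option_from`,
#'   `option_to`, `freq_from`, `freq_to`; zero rows means the vector is
#'   consistent with ordinality (ties do not violate).
#' @examples
#' ordinality_check(c(1518, 532, 100, 393))  # one violation, options 2 -> 3
#' @export
ordinality_check <- function(freqs) {
  if (length(freqs) < 2L) stop("need at least 2 options", call. = FALSE)
  if (any(freqs < 0)) stop("counts must be non-negative", call. = FALSE)
  labs <- if (!is.null(names(freqs))) names(freqs)
  else as.character(seq_along(freqs) - 1L)
  j <- which(diff(freqs) > 0)
  data.frame(option_from = labs[j], option_to = labs[j + 1L],
             freq_from = unname(freqs[j]), freq_to = unname(freqs[j + 1L]),
             row.names = NULL)
}

#' Write tidy scale scores to CSV
#'
#' @param scores A `data.frame` as returned by the scoring functions
#'   (possibly row-bound across variants/timepoints).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
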