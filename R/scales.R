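#' Define a single rating-scale item
#'
#' An item is the unit of measurement throughout the package: an ordinal
#' response with a fixed number of response choices. The number of choices
#' (`n_options`) doubles as the "points-possible" denominator used when items
#' from different instruments are placed on a common 0-1 scale.
#'
#' @param item_id Character id, unique within its instrument (e.g. `"QIDS1"`).
#' @param label Human-readable item description.
#' @param n_options Integer number of response choices (>= 2).
#' @param min_score Lowest response choice (0 for most instruments, 1 for
#'   SHAPS as shipped here).
#' @return An object of class `item_definition`.
#' @seealso [scale_definition()], [builtin_scales()], [rescale_item()]
#' @export
item_definition <- function(item_id, label, n_options, min_score = 0L) {
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  n_options <- as.integer(n_options)
  min_score <- as.integer(min_score)
  if (is.na(n_options) || n_options < 2L)
    stop("item '", item_id, "': n_options must be an integer >= 2", call. = FALSE)
  structure(
    list(item_id = item_id, label = as.character(label),
         n_options = n_options, points_possible = n_options,
         min_score = min_score, max_score = min_score + n_options - 1L),
    class = "item_definition")
}

#' Define a rating scale (instrument)
#'
#' Bundles an ordered set of items with any compound criteria: named groups
#' of items scored by selecting the single highest-scored member (the
#' QIDS-SR16 Sleep, Weight/appetite and Psychomotor criteria).
#'
#' @param scale_id One of `"QIDS"`, `"MADRS"`, `"HRS"`, `"BDI"`, `"SHAPS"`
#'   for the built-ins; arbitrary ids are allowed for user-defined scales.
#' @param items List of [item_definition()] objects, in instrument order.
#' @param compound_criteria Named list of character vectors of member item
#'   ids; members must exist in `items` and be disjoint across criteria.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(scale_id, items, compound_criteria = list()) {
  stopifnot(is.character(scale_id), length(scale_id) == 1L)
  if (!all(vapply(items, inherits, logical(1), "item_definition")))
    stop("all elements of 'items' must be item_definition objects", call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids))
    stop("duplicate item ids in scale '", scale_id, "'", call. = FALSE)
  members <- unlist(compound_criteria, use.names = FALSE)
  if (length(members)) {
    unknown <- setdiff(members, ids)
    if (length(unknown))
      stop("compound-criterion members not in scale '", scale_id, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (anyDuplicated(members))
      stop("compound-criterion members must be disjoint within a scale",
           call. = FALSE)
  }
  names(items) <- ids
  structure(
    list(scale_id = scale_id, items = items,
         compound_criteria = compound_criteria),
    class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat("<scale_definition> ", x$scale_id, ": ", length(x$items), " items",
      sep = "")
  if (length(x$compound_criteria))
    cat(", ", length(x$compound_criteria), " compound criteria (",
        paste(names(x$compound_criteria), collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

# labels kept close to the published instruments so diagnostic tables read
# naturally; HAM-D-17 ranges follow the standard instrument (ten 0-4 items,
# seven 0-2 items) and are overridable by supplying a modified definition.
.qids_labels <- c(
  "Falling asleep", "Sleep during night", "Waking up too early",
  "Sleeping too much", "Feeling sad", "Decreased appetite",
  "Increased appetite", "Decreased weight", "Increased weight",
  "Concentration/decision making", "View of myself",
  "Thoughts of death or suicide", "General interests", "Energy level",
  "Feeling slowed down", "Feeling restless")

.madrs_labels <- c(
  "Apparent sadness", "Reported sadness", "Inner tension", "Reduced sleep",
  "Reduced appetite", "Concentration difficulties", "Lassitude",
  "Inability to feel", "Pessimistic thoughts", "Suicidal thoughts")

.hamd_labels <- c(
  "Depressed mood", "Guilt feelings and delusions", "Suicide",
  "Early insomnia", "Middle insomnia", "Late insomnia",
  "Work and interests", "Retardation", "Agitation", "Psychic anxiety",
  "Somatic anxiety", "Gastrointestinal somatic symptoms", "Somatic energy",
  "Libido", "Hypochondriasis", "Weight loss", "Insight")
.hamd_5opt <- c(1L, 2L, 3L, 7L, 8L, 9L, 10L, 11L, 15L)

.bdi_labels <- c(
  "Sadness", "Hopelessness", "Thoughts of failure",
  "Dissatisfaction with life", "Guilt", "Feelings of punishment",
  "Disappointment in self", "Self-criticism", "Suicidal thoughts",
  "Increased crying", "Irritability", "Loss of interest in people",
  "Indecisiveness", "Worthlessness", "Inability to work", "Insomnia",
  "Fatigue", "Loss of appetite", "Weight loss", "Somatic preoccupation",
  "Reduced sexual interest")

#' Built-in study instruments
#'
#' Returns the five instruments used throughout the package:
#' \describe{
#'   \item{QIDS}{QIDS-SR16, 16 items scored 0-3, with the three compound
#'     criteria Sleep = QIDS1-QIDS4, Weight/appetite = QIDS6-QIDS9 and
#'     Psychomotor = QIDS15-QIDS16. The six singleton criterion items are
#'     QIDS5, QIDS10, QIDS11, QIDS12, QIDS13, QIDS14.}
#'   \item{MADRS}{10 clinician-rated items scored 0-6.}
#'   \item{HRS}{HAM-D-17; items 1-3, 7-11 and 15 scored 0-4, the remaining
#'     eight scored 0-2 (maximum total 52).}
#'   \item{BDI}{BDI-IA, 21 self-report items scored 0-3.}
#'   \item{SHAPS}{14 anhedonia items with four response choices, scored 1-4.}
#' }
#'
#' @return Named list of [scale_definition()] objects.
#' @examples
#' sum(vapply(builtin_scales(), function(s) length(s$items), integer(1)))  # 78
#' @export
builtin_scales <- function() {
  mk <- function(prefix, labels, n_options, min_score = 0L) {
    lapply(seq_along(labels), function(i)
      item_definition(paste0(prefix, i), labels[i],
                      if (length(n_options) == 1L) n_options else n_options[i],
                      min_score))
  }
  qids <- scale_definition(
    "QIDS", mk("QIDS", .qids_labels, 4L),
    compound_criteria = list(
      Sleep = paste0("QIDS", 1:4),
      `Weight/appetite` = paste0("QIDS", 6:9),
      Psychomotor = paste0("QIDS", 15:16)))
  madrs <- scale_definition("MADRS", mk("MADRS", .madrs_labels, 7L))
  hamd_opts <- ifelse(seq_len(17L) %in% .hamd_5opt, 5L, 3L)
  hrs <- scale_definition("HRS", mk("HAMD", .hamd_labels, hamd_opts))
  bdi <- scale_definition("BDI", mk("BDI", .bdi_labels, 4L))
  shaps <- scale_definition(
    "SHAPS", mk("SHAPS", paste("Anhedonia item", 1:14), 4L, min_score = 1L))
  list(QIDS = qids, MADRS = madrs, HRS = hrs, BDI = bdi, SHAPS = shaps)
}

#' Flat item table for a set of scales
#'
#' @param scales Named list of [scale_definition()]s (default: the built-ins).
#' @return `data.frame` with one row per item: `item_id`, `scale_id`,
#'   `label`, `n_options`, `points_possible`, `min_score`, `max_score`.
#' @export
item_table <- function(scales = builtin_scales()) {
  rows <- lapply(scales, function(sc) {
    data.frame(
      item_id = vapply(sc$items, `[[`, character(1), "item_id"),
      scale_id = sc$scale_id,
      label = vapply(sc$items, `[[`, character(1), "label"),
      n_options = vapply(sc$items, `[[`, integer(1), "n_options"),
      points_possible = vapply(sc$items, `[[`, integer(1), "points_possible"),
      min_score = vapply(sc$items, `[[`, integer(1), "min_score"),
      max_score = vapply(sc$items, `[[`, integer(1), "max_score"),
      row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$item_id))
    stop("item ids must be unique across scales", call. = FALSE)
  out
}

# internal: look one item up across scales, erroring on unknown ids
find_item <- function(item_id, scales = builtin_scales()) {
  for (sc in scales)
    if (item_id %in% names(sc$items)) return(sc$items[[item_id]])
  stop("unknown item id: ", item_id, call. = FALSE)
}
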