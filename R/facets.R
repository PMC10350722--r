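#' Read an item -> facet allocation config
#'
#' The YAML layout has a `facets:` mapping (facet name -> `items:` list)
#' and an optional `unallocated:` list of items deliberately assigned to no
#' facet (logged with reason `no_relevant_factor` by [build_facets()]).
#'
#' @param path YAML file path.
#' @return `data.frame` with columns `facet`, `item_id`, `provenance`
#'   (facet `NA` for unallocated items).
#' @export
read_facet_allocation <- function(path) {
  cfg <- yaml::read_yaml(path)
  prov <- if (!is.null(cfg$provenance)) cfg$provenance else "user"
  rows <- lapply(names(cfg$facets), function(f)
    data.frame(facet = f, item_id = unlist(cfg$facets[[f]]$items),
               provenance = prov, row.names = NULL))
  out <- do.call(rbind, rows)
  if (length(cfg$unallocated))
    out <- rbind(out, data.frame(facet = NA_character_,
                                 item_id = unlist(cfg$unallocated),
                                 provenance = prov))
  if (anyDuplicated(out$item_id))
    stop("each item may appear in at most one facet", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Default item -> facet allocation
#'
#' Ships the package's rational-default allocation of the 78 built-in items
#' to the seven emitted facets (Amotivation, ReducedAppetite, ImpairedSleep,
#' SuicidalThoughts, NegativeCognition, DepressedMood, Anhedonia) plus the
#' Tension facet, which [build_facets()] always drops. Every row carries
#' provenance `"rational-default"`; supply your own table via
#' [read_facet_allocation()] to override.
#'
#' @return `data.frame` with columns `facet`, `item_id`, `provenance`.
#' @export
default_facet_allocation <- function() {
  path <- system.file("extdata", "facet_allocation.yaml",
                      package = "depfacet", mustWork = TRUE)
  read_facet_allocation(path)
}

#' Baseline endorsement filter
#'
#' An item is dropped when no more than `min_patients` patients endorse it
#' above its lowest response choice at baseline (so exactly `min_patients`
#' endorsers still drops; `min_patients + 1` keeps).
#'
#' @param cube A [response_cube()].
#' @param item_id Item to test.
#' @param timepoint Timepoint to count endorsement at (default baseline).
#' @param min_patients Endorsement threshold (default 5).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
endorsement_filter <- function(cube, item_id, timepoint = "baseline",
                               min_patients = 5L) {
  item <- find_item(item_id, cube$scales)
  s <- score_matrix(cube, item_id, timepoint)[, 1L]
  sum(s > item$min_score, na.rm = TRUE) > min_patients
}

#' Prune items by corrected item-total correlation
#'
#' Computes r.drop for every candidate item within the set and removes all
#' items with r.drop strictly below the threshold. The default is a single
#' pass (compute once, drop simultaneously - deterministic and order-free);
#' `iterative = TRUE` recomputes after each pass until stable.
#'
#' @param mat Numeric matrix, patients x candidate items (>= 3 items).
#' @param threshold r.drop cut (default 0.20; an item at exactly the
#'   threshold is retained).
#' @param iterative Recompute r.drop after dropping and repeat.
#' @return List with `retained` (character), `dropped` (character),
#'   `r_drop` (named vector from the final pass over the candidates
#'   evaluated in it), and logical `degenerate` (fewer than 2 items
#'   survive).
#' @export
r_drop_prune <- function(mat, threshold = 0.20, iterative = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L)
    stop("need at least 3 candidate items for a meaningful item-total",
         call. = FALSE)
  current <- colnames(mat)
  dropped <- character()
  repeat {
    rel <- cronbach_alpha(mat[, current, drop = FALSE])
    low <- names(rel$r_drop)[rel$r_drop < threshold]
    if (!length(low)) break
    dropped <- c(dropped, low)
    current <- setdiff(current, low)
    if (!iterative || length(current) < 3L) break
  }
  list(retained = current, dropped = dropped, r_drop = rel$r_drop,
       degenerate = length(current) < 2L)
}

#' Build narrow symptom-facet scores from the pooled item bank
#'
#' Pipeline: rescale items to the common 0-1 metric, allocate them to
#' facets, apply the baseline endorsement filter, prune by r.drop within
#' each facet, then score each facet at each timepoint as the mean of its
#' retained rescaled items. The Tension facet is never emitted; facets
#' reduced below two items are dropped as degenerate. Every exclusion is
#' logged with exactly one reason.
#'
#' @param cube A [response_cube()].
#' @param allocation Allocation table ([default_facet_allocation()] or a
#'   user table from [read_facet_allocation()]).
#' @param timepoints Timepoints to score (default baseline and week6).
#' @param endorsement_min Endorsement threshold (see [endorsement_filter()]).
#' @param r_drop_threshold r.drop cut for pruning (default 0.20).
#' @param iterative Iterative r.drop pruning (see [r_drop_prune()]).
#' @param mode Rescaling convention.
#' @return Object of class `facet_result`: list with
#'   \describe{
#'     \item{spec}{per-facet list: `candidate_items`, `retained_items`.}
#'     \item{scores}{tidy `data.frame` `patient_id`, `timepoint`, `facet`,
#'       `value` (in [0, 1]; `NA` when all retained items are missing).}
#'     \item{alpha}{per facet x timepoint Cronbach's alpha of the retained
#'       rescaled items (`flagged` = TRUE for 2-item facets).}
#'     \item{exclusions}{`data.frame` `item_id`, `facet`, `reason` in
#'       `no_relevant_factor`, `low_endorsement`, `low_r_drop`,
#'       `tension_dropped`, `degenerate_facet`.}
#'   }
#' @export
build_facets <- function(cube, allocation = default_facet_allocation(),
                         timepoints = c("baseline", "week6"),
                         endorsement_min = 5L, r_drop_threshold = 0.20,
                         iterative = FALSE, mode = "points_possible") {
  baseline <- timepoints[1L]
  excl <- list()
  log_excl <- function(item, facet, reason)
    excl[[length(excl) + 1L]] <<- data.frame(item_id = item, facet = facet,
                                             reason = reason)

  unalloc <- allocation$item_id[is.na(allocation$facet)]
  for (it in unalloc) log_excl(it, NA_character_, "no_relevant_factor")
  alloc <- allocation[!is.na(allocation$facet), ]

  # endorsement filter runs once over the pooled candidates at baseline
  keep_endorse <- vapply(alloc$item_id, function(it)
    endorsement_filter(cube, it, baseline, endorsement_min), logical(1))
  for (i in which(!keep_endorse))
    log_excl(alloc$item_id[i], alloc$facet[i], "low_endorsement")
  alloc <- alloc[keep_endorse, ]

  spec <- list(); scores <- list(); alphas <- list()
  for (f in unique(alloc$facet)) {
    cand <- alloc$item_id[alloc$facet == f]
    if (identical(f, "Tension")) {
      for (it in cand) log_excl(it, f, "tension_dropped")
      next
    }
    retained <- cand
    if (length(cand) >= 3L) {
      m <- rescaled_matrix(cube, cand, baseline, mode = mode)
      pr <- r_drop_prune(m, threshold = r_drop_threshold,
                         iterative = iterative)
      retained <- pr$retained
      for (it in pr$dropped) log_excl(it, f, "low_r_drop")
    }
    if (length(retained) < 2L) {
      for (it in retained) log_excl(it, f, "degenerate_facet")
      next
    }
    spec[[f]] <- list(facet = f, candidate_items = cand,
                      retained_items = retained)
    for (tp in timepoints) {
      m <- rescaled_matrix(cube, retained, tp, mode = mode)
      present <- rowSums(!is.na(m)) > 0L
      scores[[length(scores) + 1L]] <- data.frame(
        patient_id = rownames(m), timepoint = tp, facet = f,
        value = ifelse(present, rowMeans(m, na.rm = TRUE), NA_real_),
        row.names = NULL)
      a <- tryCatch(cronbach_alpha(m)$alpha, error = function(e) NA_real_)
      alphas[[length(alphas) + 1L]] <- data.frame(
        facet = f, timepoint = tp, alpha = a,
        n_items = length(retained), flagged = length(retained) == 2L,
        row.names = NULL)
    }
  }
  structure(
    list(spec = spec,
         scores = do.call(rbind, scores),
         alpha = do.call(rbind, alphas),
         exclusions = if (length(excl)) do.call(rbind, excl)
         else data.frame(item_id = character(), facet = character(),
                         reason = character())),
    class = "facet_result")
}

#' @export
print.facet_result <- function(x, ...) {
  cat("<facet_result> ", length(x$spec), " facets: ",
      paste(names(x$spec), collapse = ", "), "\n  ",
      nrow(x$exclusions), " item exclusions logged\n", sep = "")
  invisible(x)
}
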