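# round half away from zero: the convention that reproduces the printed
# integer percentages for switching counts (e.g. 13/59 -> 22)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Highest-scored item within a compound criterion
#'
#' @param scores Named numeric vector of member scores (names = item ids in
#'   within-scale order).
#' @param tie How to resolve tied maxima: `"first"` (default; first item in
#'   within-scale order wins), `"last"`, or `"error"`.
#' @return The winning item id (length-1 character).
#' @export
highest_item <- function(scores, tie = c("first", "last", "error")) {
  tie <- match.arg(tie)
  if (anyNA(scores))
    stop("missing member score(s): ",
         paste(names(scores)[is.na(scores)], collapse = ", "), call. = FALSE)
  winners <- which(scores == max(scores))
  if (length(winners) > 1L && tie == "error")
    stop("tied maximum among: ",
         paste(names(scores)[winners], collapse = ", "), call. = FALSE)
  names(scores)[if (tie == "last") winners[length(winners)] else winners[1L]]
}

#' Pearson correlations for a compound-criterion item pair
#'
#' Computed cohort-wide (all complete-case patients, not only switchers):
#' `r_item` correlates the two items' scores at `t0`; `r_delta` correlates
#' their change scores (`t1` minus `t0`).
#'
#' @param cube A [response_cube()].
#' @param item_a,item_b Item ids.
#' @param t0,t1 Baseline and endpoint timepoints.
#' @return List with `r_item`, `r_delta`, `n` (complete pairs) and logical
#'   `undefined` flags; zero variance in a vector yields `NA` with the flag
#'   set rather than a silent 0.
#' @export
criterion_pair_correlations <- function(cube, item_a, item_b,
                                        t0 = "baseline", t1 = "week6") {
  a0 <- score_matrix(cube, item_a, t0)[, 1L]
  b0 <- score_matrix(cube, item_b, t0)[, 1L]
  a1 <- score_matrix(cube, item_a, t1)[, 1L]
  b1 <- score_matrix(cube, item_b, t1)[, 1L]
  keep <- stats::complete.cases(cbind(a0, b0, a1, b1))
  if (sum(keep) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  a0 <- a0[keep]; b0 <- b0[keep]; a1 <- a1[keep]; b1 <- b1[keep]
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }
  r_item <- safe_cor(a0, b0)
  r_delta <- safe_cor(a1 - a0, b1 - b0)
  list(r_item = r_item, r_delta = r_delta, n = sum(keep),
       undefined = c(r_item = is.na(r_item), r_delta = is.na(r_delta)))
}

#' Highest-item switching diagnostics for compound criteria
#'
#' For each compound criterion, finds patients whose highest-scored member
#' item differs between the two timepoints, tabulates each ordered
#' (baseline-highest -> endpoint-highest) pattern, and attaches the
#' cohort-wide correlations of the pattern's two items (at baseline) and of
#' their change scores. A tie resolved to the same winner at both
#' timepoints is not inconsistency.
#'
#' @param cube A [response_cube()].
#' @param t0,t1 Baseline and endpoint timepoints.
#' @param criteria Named list of member-item vectors; defaults to every
#'   compound criterion of every scale in the cube.
#' @param tie Tie-break rule passed to [highest_item()].
#' @param n_total Denominator for the integer percentages (default: the
#'   full cohort size; pass the complete-case count to change convention).
#' @return Object of class `inconsistency_table`: `data.frame` with columns
#'   `criterion`, `pattern`, `item_from`, `item_to`, `n_patients`, `pct`
#'   (integer, half-away-from-zero), `r_delta`, `r_item`; attributes
#'   `totals` (switching patients per criterion with percentages) and
#'   `n_total`.
#' @export
inconsistency_table <- function(cube, t0 = "baseline", t1 = "week6",
                                criteria = NULL, tie = "first",
                                n_total = NULL) {
  if (is.null(criteria)) {
    criteria <- list()
    for (sc in cube$scales)
      for (nm in names(sc$compound_criteria))
        criteria[[nm]] <- sc$compound_criteria[[nm]]
  }
  if (is.null(n_total)) n_total <- length(cube$patients)
  if (n_total == 0L) stop("empty cohort", call. = FALSE)

  rows <- list(); totals <- list()
  for (nm in names(criteria)) {
    members <- criteria[[nm]]
    m0 <- score_matrix(cube, members, t0)
    m1 <- score_matrix(cube, members, t1)
    keep <- stats::complete.cases(cbind(m0, m1))
    w0 <- apply(m0[keep, , drop = FALSE], 1L, function(s)
      highest_item(stats::setNames(s, members), tie = tie))
    w1 <- apply(m1[keep, , drop = FALSE], 1L, function(s)
      highest_item(stats::setNames(s, members), tie = tie))
    switched <- w0 != w1
    totals[[nm]] <- data.frame(
      criterion = nm, n_patients = sum(switched),
      pct = as.integer(round_half_away(100 * sum(switched) / n_total)),
      n_complete = sum(keep), row.names = NULL)
    if (!any(switched)) next
    pat <- table(paste(w0[switched], w1[switched], sep = " -> "))
    for (p in names(pat)) {
      ab <- strsplit(p, " -> ", fixed = TRUE)[[1L]]
      cors <- criterion_pair_correlations(cube, ab[1L], ab[2L], t0, t1)
      rows[[length(rows) + 1L]] <- data.frame(
        criterion = nm, pattern = p, item_from = ab[1L], item_to = ab[2L],
        n_patients = as.integer(pat[[p]]),
        pct = as.integer(round_half_away(100 * pat[[p]] / n_total)),
        r_delta = cors$r_delta, r_item = cors$r_item, row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(criterion = character(), pattern = character(),
                  item_from = character(), item_to = character(),
                  n_patients = integer(), pct = integer(),
                  r_delta = numeric(), r_item = numeric())
  structure(out, totals = do.call(rbind, totals), n_total = n_total,
            class = c("inconsistency_table", "data.frame"))
}
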