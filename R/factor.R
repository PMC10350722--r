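#' Default composite structure for the single-factor model
#'
#' The variables entering the one-factor extraction are rescaled items from
#' the four depression instruments (SHAPS excluded), with within-scale
#' facet composites averaged to keep the correlation matrix well-behaved at
#' trial sample sizes. Six composites follow the published composite
#' memberships (provenance `"table-note"`); every remaining item passes
#' through as its own variable (provenance `"pass-through"`).
#'
#' @return `data.frame` with columns `composite_id`, `item_id`, `source`,
#'   `provenance`; each of the 64 depression-scale items appears exactly
#'   once.
#' @export
default_composites <- function() {
  grp <- list(
    "QIDS Depressed Mood"    = c("QIDS5", "QIDS15"),
    "QIDS Impaired Sleep"    = c("QIDS2", "QIDS3"),
    "BDI Amotivation"        = c("BDI4", "BDI11", "BDI12", "BDI13", "BDI15"),
    "BDI Negative Cognition" = c("BDI10", "BDI5", "BDI6", "BDI7"),
    "HRS Depressed Mood"     = c("HAMD1", "HAMD7", "HAMD8"),
    "MADRS Depressed Mood"   = c("MADRS1", "MADRS2", "MADRS6", "MADRS8"))
  comp <- do.call(rbind, lapply(names(grp), function(g)
    data.frame(composite_id = g, item_id = grp[[g]],
               source = "scale_facet_composite", provenance = "table-note")))
  all_items <- item_table(builtin_scales())
  dep_items <- all_items$item_id[all_items$scale_id != "SHAPS"]
  singles <- setdiff(dep_items, comp$item_id)
  out <- rbind(comp,
               data.frame(composite_id = singles, item_id = singles,
                          source = "single_item",
                          provenance = "pass-through"))
  rownames(out) <- NULL
  out
}

#' Build the composite score matrix at one timepoint
#'
#' Each composite is the unweighted mean of its members' rescaled scores;
#' single items pass through unchanged. A composite is missing for a
#' patient whenever any member is missing (logged via the returned
#' attribute `n_missing`).
#'
#' @param cube A [response_cube()].
#' @param timepoint Single timepoint.
#' @param composites Composite table (see [default_composites()]).
#' @param mode Rescaling convention.
#' @return Numeric matrix patients x composites with attribute `n_missing`
#'   (per-composite count of patients lacking a member).
#' @export
build_composites <- function(cube, timepoint,
                             composites = default_composites(),
                             mode = "points_possible") {
  ids <- unique(composites$composite_id)
  m <- rescaled_matrix(cube, unique(composites$item_id), timepoint,
                       mode = mode)
  out <- matrix(NA_real_, nrow(m), length(ids),
                dimnames = list(rownames(m), ids))
  for (cid in ids) {
    members <- composites$item_id[composites$composite_id == cid]
    sub <- m[, members, drop = FALSE]
    vals <- rowMeans(sub)          # NA as soon as any member is missing
    out[, cid] <- vals
  }
  attr(out, "n_missing") <- stats::setNames(as.integer(colSums(is.na(out))),
                                            colnames(out))
  out
}

#' Drop low-variability variables
#'
#' A variable is excluded when fewer than `min_endorsers` patients sit
#' above its floor (the minimum attainable value) at baseline; constants
#' are always dropped.
#'
#' @param mat Patients x variables matrix (baseline values).
#' @param min_endorsers Minimum number of above-floor patients to keep a
#'   variable (default 6, i.e. 5 or fewer endorsers drop).
#' @param floor Named vector of per-variable floors; defaults to each
#'   column's attainable minimum taken as `min()` of the observed scale...
#'   supply explicitly when columns may not reach their floor in-sample.
#' @return List with `kept` matrix and `dropped` character vector.
#' @export
low_variability_exclusion <- function(mat, min_endorsers = 6L,
                                      floor = NULL) {
  if (is.null(floor)) floor <- apply(mat, 2L, min, na.rm = TRUE)
  endorsers <- vapply(colnames(mat), function(j)
    sum(mat[, j] > floor[[j]] + 1e-12, na.rm = TRUE), integer(1))
  drop <- names(endorsers)[endorsers < min_endorsers]
  list(kept = mat[, setdiff(colnames(mat), drop), drop = FALSE],
       dropped = drop)
}

#' Extract a single factor by unweighted least squares (minres)
#'
#' Fits the one-factor model R ~ lambda lambda' + Psi by minimising the sum
#' of squared off-diagonal residuals of the correlation matrix (the minres
#' discrepancy), via quasi-Newton optimisation with analytic gradient from
#' a principal-component start. Loadings are sign-flipped so the factor is
#' severity-positive (mean loading >= 0); Heywood loadings are clipped to
#' |lambda| = 1 and flagged.
#'
#' @param x Patients x variables numeric matrix, or a correlation matrix
#'   (square, symmetric, unit diagonal).
#' @param use Correlation missing-data rule when `x` is raw data:
#'   `"complete.obs"` (default) or `"pairwise.complete.obs"`.
#' @return Object of class `one_factor_model`: list with `loadings`
#'   (`data.frame` `composite_id`, `lambda`, `communality`, `uniqueness`),
#'   `variance_explained` (sum(lambda^2)/p), `converged`, `heywood`
#'   (character vector of clipped variables), `n_obs`.
#' @export
extract_single_factor <- function(x, use = c("complete.obs",
                                             "pairwise.complete.obs")) {
  use <- match.arg(use)
  x <- as.matrix(x)
  is_cor <- nrow(x) == ncol(x) && all(abs(diag(x) - 1) < 1e-8) &&
    isTRUE(all.equal(x, t(x), tolerance = 1e-8))
  if (is_cor) {
    R <- x
    n_obs <- NA_integer_
  } else {
    if (ncol(x) < 5L) stop("need at least 5 variables", call. = FALSE)
    sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sds)) || any(sds == 0))
      stop("zero-variance column(s): ",
           paste(colnames(x)[!is.finite(sds) | sds == 0], collapse = ", "),
           call. = FALSE)
    R <- stats::cor(x, use = use)
    n_obs <- if (use == "complete.obs") sum(stats::complete.cases(x))
    else nrow(x)
  }
  if (anyNA(R)) stop("correlation matrix contains NA", call. = FALSE)
  p <- ncol(R)

  # objective: sum_{i<j} (r_ij - l_i l_j)^2, with analytic gradient
  off <- function(l) R - tcrossprod(l)
  fn <- function(l) { E <- off(l); diag(E) <- 0; sum(E^2) / 2 }
  gr <- function(l) { E <- off(l); diag(E) <- 0; -2 * E %*% l }

  e <- eigen(R, symmetric = TRUE)
  start <- e$vectors[, 1L] * sqrt(max(e$values[1L], 0.1))
  start <- pmin(pmax(start, -0.995), 0.995)
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = rep(-1, p), upper = rep(1, p),
                      control = list(maxit = 1000L, factr = 1e4))
  if (opt$convergence != 0)
    stop("minres optimisation failed to converge (code ", opt$convergence,
         "): ", opt$message, call. = FALSE)
  lambda <- as.numeric(opt$par)
  if (mean(lambda) < 0) lambda <- -lambda
  heywood <- colnames(R)[abs(lambda) > 1 - 1e-6]
  lambda <- pmin(pmax(lambda, -1), 1)
  loadings <- data.frame(composite_id = colnames(R), lambda = lambda,
                         communality = lambda^2,
                         uniqueness = 1 - lambda^2, row.names = NULL)
  structure(list(loadings = loadings,
                 variance_explained = sum(lambda^2) / p,
                 converged = TRUE, heywood = heywood, n_obs = n_obs),
            class = "one_factor_model")
}

#' @export
print.one_factor_model <- function(x, ...) {
  cat(sprintf(
    "<one_factor_model> %d variables, variance explained %.1f%%\n",
    nrow(x$loadings), 100 * x$variance_explained))
  if (length(x$heywood))
    cat("  Heywood-clipped:", paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

#' Loading-threshold factor scores
#'
#' The factor score is the unweighted mean of the composites whose loading
#' exceeds the threshold (strictly), computed per patient at each supplied
#' timepoint with the same retained set throughout (loadings are estimated
#' once, at baseline by default - see [depression_factor()]).
#'
#' @param model A [one_factor_model][extract_single_factor()].
#' @param matrices Named list of patients x composites matrices, one per
#'   timepoint (e.g. from [build_composites()]).
#' @param threshold Loading retention cut (default 0.40).
#' @return List with `retained` (composite ids), `scores` (tidy
#'   `data.frame` `patient_id`, `timepoint`, `value` in [0, 1]).
#' @export
factor_scores <- function(model, matrices, threshold = 0.40) {
  keep <- model$loadings$composite_id[model$loadings$lambda > threshold]
  if (!length(keep)) stop("no composite loads above ", threshold,
                          call. = FALSE)
  rows <- lapply(names(matrices), function(tp) {
    m <- matrices[[tp]][, keep, drop = FALSE]
    present <- rowSums(!is.na(m)) > 0L
    data.frame(patient_id = rownames(m), timepoint = tp,
               value = ifelse(present, rowMeans(m, na.rm = TRUE), NA_real_),
               row.names = NULL)
  })
  list(retained = keep, scores = do.call(rbind, rows))
}

#' Derive the core-depression factor score end to end
#'
#' Orchestrates the factor-model stage: build composites at both
#' timepoints, exclude low-variability variables at baseline, extract one
#' minres factor from the baseline correlation matrix, retain composites
#' loading above the threshold, and score patients at both timepoints as
#' the mean of the retained rescaled composites. Estimating the loadings on
#' baseline data only avoids treatment-effect contamination of the factor
#' structure; pass `pool_timepoints = TRUE` to estimate on stacked
#' baseline + endpoint rows instead.
#'
#' @param cube A [response_cube()].
#' @param t0,t1 Baseline and endpoint timepoints.
#' @param composites Composite table (default [default_composites()]).
#' @param threshold Loading retention cut (default 0.40).
#' @param min_endorsers Low-variability cut (default 6; see
#'   [low_variability_exclusion()]).
#' @param use Correlation missing-data rule (complete-case default).
#' @param pool_timepoints Estimate loadings on pooled t0 + t1 rows.
#' @param mode Rescaling convention.
#' @return List with `model`, `retained`, `scores`, `excluded`
#'   (low-variability drops), `alpha` (per-timepoint Cronbach's alpha of
#'   the retained set).
#' @export
depression_factor <- function(cube, t0 = "baseline", t1 = "week6",
                              composites = default_composites(),
                              threshold = 0.40, min_endorsers = 6L,
                              use = "complete.obs",
                              pool_timepoints = FALSE,
                              mode = "points_possible") {
  m0 <- build_composites(cube, t0, composites, mode)
  m1 <- build_composites(cube, t1, composites, mode)
  # attainable floor per composite = mean of member floors after rescaling
  it <- cube$items
  floors <- vapply(unique(composites$composite_id), function(cid) {
    members <- composites$item_id[composites$composite_id == cid]
    idx <- match(members, it$item_id)
    if (mode == "points_possible")
      mean(it$min_score[idx] / it$points_possible[idx])
    else 0
  }, numeric(1))
  lv <- low_variability_exclusion(m0, min_endorsers, floor = floors)
  fit_mat <- if (pool_timepoints)
    rbind(lv$kept, m1[, colnames(lv$kept), drop = FALSE])
  else lv$kept
  model <- extract_single_factor(fit_mat, use = use)
  fs <- factor_scores(model, stats::setNames(list(m0, m1), c(t0, t1)),
                      threshold)
  alpha <- do.call(rbind, lapply(c(t0, t1), function(tp) {
    m <- (if (tp == t0) m0 else m1)[, fs$retained, drop = FALSE]
    data.frame(timepoint = tp,
               alpha = tryCatch(cronbach_alpha(m)$alpha,
                                error = function(e) NA_real_),
               row.names = NULL)
  }))
  list(model = model, retained = fs$retained, scores = fs$scores,
       excluded = lv$dropped, alpha = alpha)
}
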