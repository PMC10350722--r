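#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one cohort: scale scoring (QIDS sum,
#' de-compounded variants, scale mean-scores), compound-criterion switching
#' diagnostics, variance/SE diagnostics across scale mean-scores, per-item
#' Time x Condition profiles, facet construction, the single-factor model,
#' and mixed-model inference for each facet and the factor score, with
#' expectancy-moderation refits for outcomes whose Time x Condition term is
#' significant. Outputs are plain CSV plus a JSON manifest; identical
#' (cube, thresholds) inputs produce identical artifacts.
#'
#' @param cube A [response_cube()]; if `NULL`, one is generated from
#'   `config` and `seed`.
#' @param config A [generator_config()] used when `cube` is `NULL`.
#' @param seed Seed for generation (ignored when a cube is supplied).
#' @param out_dir Output directory for CSV artifacts; `NULL` skips writing.
#' @param t0,t1 Baseline and primary endpoint timepoints.
#' @param r_drop_threshold,loading_threshold,endorsement_min,alpha_level
#'   Analysis thresholds (validated before any computation).
#' @param allocation,composites Facet allocation and composite tables.
#' @param verbose Emit stage-scoped progress messages with row counts.
#' @return List (invisibly when writing) with elements `scores`,
#'   `inconsistency`, `variance`, `item_profile`, `facets`, `factor`,
#'   `lme`, `expectancy_models`, `manifest`.
#' @export
run_pipeline <- function(cube = NULL, config = generator_config(),
                         seed = 1L, out_dir = NULL,
                         t0 = "baseline", t1 = "week6",
                         r_drop_threshold = 0.20, loading_threshold = 0.40,
                         endorsement_min = 5L, alpha_level = 0.05,
                         allocation = default_facet_allocation(),
                         composites = default_composites(),
                         verbose = FALSE) {
  if (r_drop_threshold < -1 || r_drop_threshold > 1)
    stop("r_drop_threshold must lie in [-1, 1]", call. = FALSE)
  if (loading_threshold < 0 || loading_threshold > 1)
    stop("loading_threshold must lie in [0, 1]", call. = FALSE)
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("alpha_level must lie in (0, 1)", call. = FALSE)
  if (endorsement_min < 0)
    stop("endorsement_min must be non-negative", call. = FALSE)
  say <- function(stage, ...) if (verbose)
    message("[", stage, "] ", ...)

  if (is.null(cube)) {
    say("simulate", "generating cohort, seed ", seed)
    cube <- generate_cohort(config, seed)$cube
  }
  validate_cube(cube)
  has_week5 <- "week5" %in% cube$timepoints

  say("score", "scale scores")
  score_sets <- list(
    qids_sum_score(cube, t0, na_rm_patients = TRUE),
    qids_sum_score(cube, t1, na_rm_patients = TRUE),
    qids_mean_variant(cube, t1, "all_items_1", na_rm_patients = TRUE),
    qids_mean_variant(cube, t1, "all_items_2", na_rm_patients = TRUE))
  for (sid in names(cube$scales))
    for (tp in c(t0, t1))
      score_sets[[length(score_sets) + 1L]] <-
        scale_mean_score(cube, sid, tp)
  scores <- do.call(rbind, score_sets)
  say("score", nrow(scores), " score rows")

  say("diagnose", "compound-criterion switching, ", t0, " -> ", t1)
  incons <- inconsistency_table(cube, t0, t1)

  say("diagnose", "variance diagnostics")
  vd <- if (has_week5) variance_diagnostics(cube) else NULL

  say("items", "per-item response profiles")
  prof_cmp <- list(QIDS = c(if (has_week5) "week5", t1),
                   MADRS = t1, HRS = t1, BDI = t1)
  profile <- item_response_profile(cube, comparisons = prof_cmp)

  say("facets", "building facet scores")
  facets <- build_facets(cube, allocation, timepoints = c(t0, t1),
                         endorsement_min = endorsement_min,
                         r_drop_threshold = r_drop_threshold)
  say("facets", length(facets$spec), " facets, ",
      nrow(facets$exclusions), " exclusions")

  say("factor", "single-factor extraction")
  fac <- depression_factor(cube, t0, t1, composites = composites,
                           threshold = loading_threshold)
  say("factor", length(fac$retained), " retained composites")

  say("fit", "Time x Condition models")
  outcomes <- c(
    lapply(names(facets$spec), function(f) list(
      id = paste0("Facet: ", f),
      scores = stats::setNames(
        facets$scores[facets$scores$facet == f,
                      c("patient_id", "timepoint", "value")],
        c("patient_id", "timepoint", "value")))),
    list(list(id = "Depression factor",
              scores = fac$scores[c("patient_id", "timepoint", "value")])))
  fits <- lapply(outcomes, function(o)
    tryCatch(fit_time_condition(o$scores, cube$arms, t0, t1,
                                outcome_id = o$id),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  lme_tab <- do.call(rbind, lapply(fits[ok], function(r)
    cbind(outcome_id = r$outcome_id, r$terms, row.names = NULL)))

  rexp <- relative_expectancy(cube)
  exp_models <- list()
  if (any(!is.na(rexp))) {
    for (i in which(ok)) {
      r <- fits[[i]]
      p_int <- r$terms$p[r$terms$term == "Time x Condition"]
      if (is.finite(p_int) && p_int < alpha_level) {
        say("fit", "expectancy moderation for ", r$outcome_id)
        em <- tryCatch(
          expectancy_moderation(outcomes[[i]]$scores, cube$arms, rexp,
                                t0, t1, outcome_id = r$outcome_id),
          error = function(e) NULL)
        if (!is.null(em)) exp_models[[r$outcome_id]] <- em
      }
    }
  }
  exp_tab <- if (length(exp_models))
    do.call(rbind, lapply(exp_models, function(em)
      cbind(outcome_id = em$outcome_id, em$terms, row.names = NULL)))

  manifest <- list(
    package = "depfacet",
    version = as.character(utils::packageVersion("depfacet")),
    seed = as.integer(seed),
    n_patients = length(cube$patients),
    timepoints = cube$timepoints,
    thresholds = list(r_drop = r_drop_threshold,
                      loading = loading_threshold,
                      endorsement = endorsement_min,
                      alpha_level = alpha_level),
    cube_hash = hash_object(cube),
    config_hash = hash_object(list(t0 = t0, t1 = t1,
                                   allocation = allocation,
                                   composites = composites)))

  bundle <- list(scores = scores, inconsistency = incons, variance = vd,
                 item_profile = profile, facets = facets, factor = fac,
                 lme = lme_tab, expectancy_models = exp_models,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
    wr(scores, "scale_scores.csv")
    wr(as.data.frame(incons), "inconsistency_patterns.csv")
    wr(attr(incons, "totals"), "inconsistency_totals.csv")
    if (!is.null(vd)) {
      wr(vd$table, "variance_diagnostics.csv")
      wr(vd$pct_excess, "variance_pct_excess.csv")
    }
    wr(profile, "item_profile.csv")
    wr(facets$scores, "facet_scores.csv")
    wr(facets$alpha, "facet_alpha.csv")
    wr(facets$exclusions, "facet_exclusions.csv")
    wr(fac$model$loadings, "factor_loadings.csv")
    wr(fac$scores, "factor_scores.csv")
    wr(lme_tab, "lme_results.csv")
    wr(exp_tab, "expectancy_models.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}

# stable md5 of an R object (serialization version pinned for
# reproducibility across sessions)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}
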