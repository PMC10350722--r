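# internal: assemble the long two-timepoint data frame an outcome fit needs.
# scores: data.frame patient_id, timepoint, value (one row per patient x tp)
outcome_long <- function(scores, arms, t0, t1) {
  d <- scores[scores$timepoint %in% c(t0, t1) & !is.na(scores$value), ]
  d$time <- as.integer(d$timepoint == t1)
  d$arm <- unname(arms[d$patient_id])
  d$cond <- as.integer(d$arm == "PT")   # ET is the reference arm
  d
}

# containment ("between-within") degrees of freedom: terms involving Time
# vary within patient and get N_patients - 2; purely between-patient terms
# get N_obs - N_patients - n_between.
containment_df <- function(term_names, n_pat, n_obs) {
  within <- grepl("time", term_names)
  n_between <- sum(!within)
  ifelse(within, n_pat - 2L, n_obs - n_pat - n_between)
}

#' Random-intercept Time x Condition model for one outcome
#'
#' Fits `value ~ time * cond + (1 | patient)` by REML (lme4), with Time
#' coded 0 at `t0` / 1 at `t1` and Condition 0 = ET (reference), 1 = PT.
#' The Time x Condition coefficient is the between-arm difference in change
#' - the difference-in-differences. Standardized coefficients (`b`) rescale
#' the outcome by its pooled baseline mean/SD (treatment-free), an exact
#' affine transform of the fit, so t and p are identical for `B` and `b`
#' on every slope term (the standardized intercept is additionally
#' baseline-centered, so its own t would test a shifted null; the reported
#' t/p always come from the unstandardized fit).
#' Two-tailed p-values use a containment degrees-of-freedom rule: terms
#' involving Time get `n_patients - 2`, between-patient terms
#' `n_obs - n_patients - 2`.
#'
#' @param scores `data.frame` with columns `patient_id`, `timepoint`,
#'   `value` (one outcome; rows at both timepoints).
#' @param arms Named character vector patient -> `"PT"`/`"ET"` (e.g.
#'   `cube$arms`).
#' @param t0,t1 Baseline and endpoint timepoints.
#' @param outcome_id Label carried into the result.
#' @return Object of class `lme_tc`: list with `terms` (`data.frame`
#'   `term`, `B`, `SE_B`, `b`, `SE_b`, `DF`, `t`, `p`), `outcome_id`,
#'   `n_patients`, `n_obs`, `t0`, `t1`, and the underlying `fit`.
#' @export
fit_time_condition <- function(scores, arms, t0 = "baseline",
                               t1 = "week6", outcome_id = "outcome") {
  d <- outcome_long(scores, arms, t0, t1)
  if (nrow(d) == 0L) stop("no observations for '", outcome_id, "'",
                          call. = FALSE)
  if (length(unique(d$cond)) < 2L)
    stop("both arms must be represented", call. = FALSE)
  if (stats::sd(d$value) == 0)
    stop("outcome '", outcome_id, "' has zero variance", call. = FALSE)
  base <- d$value[d$time == 0L]
  if (length(base) < 2L || stats::sd(base) == 0)
    stop("baseline values of '", outcome_id,
         "' have zero variance; cannot standardize", call. = FALSE)
  m0 <- mean(base); s0 <- stats::sd(base)

  fit <- suppressMessages(lme4::lmer(
    value ~ time * cond + (1 | patient_id), data = d, REML = TRUE))
  B <- lme4::fixef(fit)
  SE <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_pat <- length(unique(d$patient_id)); n_obs <- nrow(d)
  DF <- containment_df(names(B), n_pat, n_obs)
  tval <- B / SE
  p <- 2 * stats::pt(-abs(tval), DF)
  # exact affine standardization: slopes divide by s0, intercept also shifts
  b <- B / s0; b[1L] <- (B[[1L]] - m0) / s0
  SE_b <- SE / s0
  label <- c(`(Intercept)` = "Intercept", cond = "Condition",
             time = "Time", `time:cond` = "Time x Condition")
  terms <- data.frame(
    term = unname(label[names(B)]),
    B = unname(B), SE_B = unname(SE), b = unname(b), SE_b = unname(SE_b),
    DF = unname(DF), t = unname(tval), p = unname(p), row.names = NULL)
  terms <- terms[match(label, terms$term), ]
  rownames(terms) <- NULL
  structure(list(outcome_id = outcome_id, terms = terms,
                 n_patients = n_pat, n_obs = n_obs, t0 = t0, t1 = t1,
                 baseline_mean = m0, baseline_sd = s0, fit = fit),
            class = "lme_tc")
}

#' @export
print.lme_tc <- function(x, ...) {
  cat("<lme_tc> outcome:", x$outcome_id, "(", x$n_patients, "patients,",
      x$n_obs, "obs )\n")
  print(format(x$terms, digits = 3), row.names = FALSE)
  invisible(x)
}

# internal: interaction row of a fit, as a one-row data.frame
interaction_row <- function(res) {
  r <- res$terms[res$terms$term == "Time x Condition", ]
  cbind(data.frame(outcome_id = res$outcome_id, t1 = res$t1), r,
        row.names = NULL)
}

#' Per-item Time x Condition response profile
#'
#' Regresses every rescaled item separately on Time x Condition with a
#' random patient intercept, following the study's timing convention:
#' QIDS items are analysed baseline -> week 5 and baseline -> week 6, all
#' other instruments baseline -> week 6 only (override via `comparisons`).
#' Per-item failures are logged, not fatal.
#'
#' @param cube A [response_cube()].
#' @param items Item ids to profile (default: all items of the four
#'   depression scales, i.e. excluding SHAPS).
#' @param comparisons Named list scale_id -> character vector of endpoint
#'   timepoints.
#' @param mode Rescaling convention.
#' @return `data.frame` with one row per item x endpoint: `outcome_id`
#'   (item id), `t1`, `term`, `B`, `SE_B`, `b`, `SE_b`, `DF`, `t`, `p`;
#'   attribute `failures` records items that could not be fitted.
#' @export
item_response_profile <- function(cube, items = NULL,
                                  comparisons = list(
                                    QIDS = c("week5", "week6"),
                                    MADRS = "week6", HRS = "week6",
                                    BDI = "week6"),
                                  mode = "points_possible") {
  it <- cube$items
  if (is.null(items))
    items <- it$item_id[it$scale_id %in% names(comparisons)]
  rows <- list(); failures <- list()
  resc <- rescale_responses(cube, mode)
  for (id in items) {
    sc <- it$scale_id[match(id, it$item_id)]
    for (tp in comparisons[[sc]]) {
      s <- resc[resc$item_id == id, c("patient_id", "timepoint", "value")]
      res <- tryCatch(
        fit_time_condition(s, cube$arms, t0 = "baseline", t1 = tp,
                           outcome_id = id),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(item_id = id, t1 = tp, message = conditionMessage(res))
      } else rows[[length(rows) + 1L]] <- interaction_row(res)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
  out
}

#' Time x Condition x Relative-Expectancy moderation model
#'
#' Full-factorial fixed effects of Time, Condition and the patient's
#' relative treatment expectancy (PT minus ET rating), with a random
#' patient intercept; reports whether the Time x Condition term survives
#' expectancy adjustment. Patients without expectancy ratings are dropped.
#'
#' @inheritParams fit_time_condition
#' @param rel_expectancy Named numeric vector patient -> relative
#'   expectancy (see [relative_expectancy()]).
#' @param center Center expectancy at its mean before fitting (changes
#'   lower-order terms, never the three-way coefficient).
#' @return List with `terms` (8-row coefficient table with containment DF
#'   and p), `time_condition_p`, `survives` (logical at alpha = 0.05),
#'   `n_patients`, `fit`.
#' @export
expectancy_moderation <- function(scores, arms, rel_expectancy,
                                  t0 = "baseline", t1 = "week6",
                                  outcome_id = "outcome", center = TRUE) {
  d <- outcome_long(scores, arms, t0, t1)
  d$rexp <- unname(rel_expectancy[d$patient_id])
  d <- d[!is.na(d$rexp), ]
  if (nrow(d) == 0L) stop("no patients with expectancy data", call. = FALSE)
  if (stats::sd(d$rexp) == 0)
    stop("relative expectancy is constant; three-way terms inestimable",
         call. = FALSE)
  if (center) d$rexp <- d$rexp - mean(d$rexp[d$time == 0L])
  fit <- suppressMessages(lme4::lmer(
    value ~ time * cond * rexp + (1 | patient_id), data = d, REML = TRUE))
  B <- lme4::fixef(fit)
  SE <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_pat <- length(unique(d$patient_id)); n_obs <- nrow(d)
  DF <- containment_df(names(B), n_pat, n_obs)
  tval <- B / SE
  p <- 2 * stats::pt(-abs(tval), DF)
  terms <- data.frame(term = names(B), B = unname(B), SE_B = unname(SE),
                      DF = unname(DF), t = unname(tval), p = unname(p),
                      row.names = NULL)
  txc <- terms$p[terms$term == "time:cond"]
  list(outcome_id = outcome_id, terms = terms, time_condition_p = txc,
       survives = txc < 0.05, n_patients = n_pat, fit = fit)
}

#' Standard-error and variance diagnostics across scale mean-scores
#'
#' For each scale mean-score (plus the de-compounded QIDS variants),
#' reports the SE of the fitted Time x Condition coefficient, the SD of
#' baseline scores and the SD of change scores, with QIDS rows at both
#' week 5 and week 6. A companion table gives the percent excess of each
#' QIDS row over each other scale (positive = QIDS larger).
#'
#' @param cube A [response_cube()].
#' @param scales Scale ids to include besides the QIDS variants.
#' @param mode Rescaling convention.
#' @return List with `table` (`data.frame` `outcome`, `t1`,
#'   `se_interaction`, `sd_baseline`, `sd_change`, `n_patients`) and
#'   `pct_excess` (QIDS row vs comparison scale, percent differences).
#' @export
variance_diagnostics <- function(cube, scales = c("MADRS", "HRS", "BDI"),
                                 mode = "points_possible") {
  specs <- c(
    lapply(scales, function(s) list(outcome = paste0(s, " mean-score"),
                                    scale = s, variant = "mean", t1 = "week6")),
    list(
      list(outcome = "QIDS mean-score", scale = "QIDS", variant = "mean",
           t1 = "week5"),
      list(outcome = "QIDS mean-score", scale = "QIDS", variant = "mean",
           t1 = "week6"),
      list(outcome = "QIDS all items 1", scale = "QIDS",
           variant = "all_items_1", t1 = "week5"),
      list(outcome = "QIDS all items 1", scale = "QIDS",
           variant = "all_items_1", t1 = "week6"),
      list(outcome = "QIDS all items 2", scale = "QIDS",
           variant = "all_items_2", t1 = "week5"),
      list(outcome = "QIDS all items 2", scale = "QIDS",
           variant = "all_items_2", t1 = "week6")))
  rows <- lapply(specs, function(sp) {
    score_tp <- function(tp) {
      if (sp$variant == "mean")
        scale_mean_score(cube, sp$scale, tp, mode = mode)
      else qids_mean_variant(cube, tp, sp$variant, na_rm_patients = TRUE,
                             mode = mode)
    }
    s <- rbind(score_tp("baseline"), score_tp(sp$t1))
    res <- fit_time_condition(s[c("patient_id", "timepoint", "value")],
                              cube$arms, t0 = "baseline", t1 = sp$t1,
                              outcome_id = sp$outcome)
    base <- s$value[s$timepoint == "baseline"]
    wide <- merge(s[s$timepoint == "baseline", c("patient_id", "value")],
                  s[s$timepoint == sp$t1, c("patient_id", "value")],
                  by = "patient_id")
    data.frame(outcome = sp$outcome, t1 = sp$t1,
               se_interaction = res$terms$SE_B[res$terms$term ==
                                                 "Time x Condition"],
               sd_baseline = stats::sd(base),
               sd_change = stats::sd(wide$value.y - wide$value.x),
               n_patients = res$n_patients, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  qids <- tab[grepl("^QIDS", tab$outcome), ]
  others <- tab[!grepl("^QIDS", tab$outcome), ]
  pct <- do.call(rbind, lapply(seq_len(nrow(qids)), function(i)
    do.call(rbind, lapply(seq_len(nrow(others)), function(j)
      data.frame(qids_outcome = qids$outcome[i], qids_t1 = qids$t1[i],
                 versus = others$outcome[j],
                 se_pct = 100 * (qids$se_interaction[i] /
                                   others$se_interaction[j] - 1),
                 sd_baseline_pct = 100 * (qids$sd_baseline[i] /
                                            others$sd_baseline[j] - 1),
                 sd_change_pct = 100 * (qids$sd_change[i] /
                                          others$sd_change[j] - 1),
                 row.names = NULL)))))
  list(table = tab, pct_excess = pct)
}
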