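#' Default arm-specific facet changes for the generator
#'
#' Change in expected rescaled item score (0-1 metric) between baseline and
#' week 6, per facet: `et_change` is the change in the escitalopram arm and
#' `pt_extra` the additional change in the psilocybin arm (so the facet's
#' difference-in-differences estimand equals `pt_extra`). Defaults place
#' the differential response in DepressedMood and Anhedonia with modest,
#' arm-equal improvement elsewhere; `Other` covers items allocated to no
#' facet.
#'
#' @return `data.frame` with columns `facet`, `et_change`, `pt_extra`.
#' @export
default_arm_effects <- function() {
  data.frame(
    facet = c("DepressedMood", "Anhedonia", "Amotivation",
              "NegativeCognition", "ImpairedSleep", "ReducedAppetite",
              "SuicidalThoughts", "Tension", "Other"),
    et_change = c(-0.14, -0.08, -0.12, -0.12, -0.10, -0.08, -0.08,
                  -0.10, -0.10),
    pt_extra = c(-0.11, -0.12, 0, 0, 0, 0, 0, 0, 0))
}

#' Configuration for the synthetic trial-cohort generator
#'
#' Defaults emulate the two-arm trial the package's analyses are shaped
#' for: 30 PT + 29 ET patients, baseline / week-5 / week-6 assessments with
#' week 5 restricted to the QIDS, ordinal items produced by thresholding a
#' latent severity (core factor + correlated facet deviations + item
#' noise), arm-specific facet change at follow-up, and 0-100 expectancy
#' ratings correlated with individual improvement.
#'
#' @param n_pt,n_et Arm sizes.
#' @param timepoints Assessment occasions, baseline first.
#' @param week5_scales Scales measured at week 5 (default QIDS only).
#' @param core_loading,facet_loading Loadings of the shared core factor and
#'   the item's facet deviation on the latent severity (both in [0, 1]).
#' @param noise_sd Item-level latent noise SD.
#' @param inter_facet_cor Correlation between facet deviations.
#' @param change_het_sd Patient-level heterogeneity (latent SD) in
#'   follow-up change, shared across items; links improvement to
#'   expectancy.
#' @param arm_effects `data.frame` as [default_arm_effects()]: follow-up
#'   change per facet per arm on the 0-1 rescaled-score scale. The
#'   generator solves for the latent shift that realises each configured
#'   change exactly in expectation, so `pt_extra` is the exact
#'   difference-in-differences estimand of the facet score.
#' @param severity Binomial probability governing baseline response-option
#'   frequencies (per-item thresholds); `population = "clinical"` uses
#'   `severity` as given, `"community"` replaces it with a floor-heavy
#'   0.12, reproducing the strongly floor-concentrated response shapes seen
#'   in general-population screening data.
#' @param population `"clinical"` (default) or `"community"`.
#' @param allocation Item -> facet table (see
#'   [default_facet_allocation()]); items with facet `NA` are generated
#'   under the `Other` facet.
#' @param expectancy List: `mu_pt`, `sd_pt`, `mu_et`, `sd_et` (0-100
#'   rating moments) and `cor_improve` (correlation of the PT rating's
#'   latent with individual improvement).
#' @param scales Scale definitions to generate items for.
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_pt = 30L, n_et = 29L,
                             timepoints = c("baseline", "week5", "week6"),
                             week5_scales = "QIDS",
                             core_loading = 0.5, facet_loading = 0.6,
                             noise_sd = 0.62, inter_facet_cor = 0.3,
                             change_het_sd = 0.25,
                             arm_effects = default_arm_effects(),
                             severity = 0.6,
                             population = c("clinical", "community"),
                             allocation = default_facet_allocation(),
                             expectancy = list(mu_pt = 65, sd_pt = 20,
                                               mu_et = 45, sd_et = 20,
                                               cor_improve = 0.25),
                             scales = builtin_scales()) {
  population <- match.arg(population)
  stopifnot(n_pt >= 1L, n_et >= 1L,
            core_loading >= 0, core_loading <= 1,
            facet_loading >= 0, facet_loading <= 1,
            noise_sd > 0, inter_facet_cor >= 0, inter_facet_cor < 1,
            change_het_sd >= 0, severity > 0, severity < 1,
            abs(expectancy$cor_improve) <= 1)
  structure(list(
    n_pt = as.integer(n_pt), n_et = as.integer(n_et),
    timepoints = timepoints, week5_scales = week5_scales,
    core_loading = core_loading, facet_loading = facet_loading,
    noise_sd = noise_sd, inter_facet_cor = inter_facet_cor,
    change_het_sd = change_het_sd, arm_effects = arm_effects,
    severity = if (population == "community") 0.12 else severity,
    population = population, allocation = allocation,
    expectancy = expectancy, scales = scales),
    class = "generator_config")
}

# expected rescaled score of a thresholded latent N(mu, sd):
# E[(min + #{cuts < z}) / K]
expected_rescaled <- function(mu, sd, cuts, n_options, min_score) {
  (min_score + sum(1 - stats::pnorm((cuts - mu) / sd))) / n_options
}

# latent shift realising a configured change (0-1 scale) in expected
# rescaled score, accounting for extra follow-up marginal variance
solve_latent_shift <- function(effect, cuts, n_options, min_score,
                               sd0, sd1) {
  base <- expected_rescaled(0, sd0, cuts, n_options, min_score)
  target <- base + effect
  lo <- (min_score + 1e-9) / n_options
  hi <- (min_score + n_options - 1 - 1e-9) / n_options
  if (target < lo || target > hi)
    stop("configured effect ", effect, " pushes the expected score out of ",
         "the attainable range", call. = FALSE)
  stats::uniroot(function(d)
    expected_rescaled(d, sd1, cuts, n_options, min_score) - target,
    lower = -8 * sd1, upper = 8 * sd1, tol = 1e-10)$root
}

# per-option baseline probabilities for a K-option item
option_probs <- function(n_options, severity) {
  stats::dbinom(0:(n_options - 1L), n_options - 1L, severity)
}

#' Generate a synthetic trial cohort
#'
#' Latent model per patient: severity = core factor (shared across all
#' items) + facet deviation (multivariate normal across facets with the
#' configured inter-facet correlation) + item noise; at follow-up the
#' latent mean shifts by the arm's calibrated facet effect plus a
#' patient-level change-heterogeneity term. Ordinal scores arise by
#' thresholding the latent at cut-points matching the configured baseline
#' option frequencies. Expectancy ratings are drawn per arm with the PT
#' rating's latent correlated with individual improvement. Fully
#' reproducible from `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return List with `cube` (a validated [response_cube()]) and `truth`
#'   (ground-truth record: `core`, `facet_dev`, `gamma` per patient,
#'   `shifts` table of calibrated latent shifts, and the `config`).
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  n <- config$n_pt + config$n_et
  pids <- sprintf("P%03d", seq_len(n))
  arms <- c(rep("PT", config$n_pt), rep("ET", config$n_et))
  names(arms) <- pids

  it <- item_table(config$scales)
  alloc <- config$allocation
  facet_of <- alloc$facet[match(it$item_id, alloc$item_id)]
  facet_of[is.na(facet_of)] <- "Other"
  facets <- unique(facet_of)

  lc <- config$core_loading; lf <- config$facet_loading
  sd0 <- sqrt(lc^2 + lf^2 + config$noise_sd^2)
  sd1 <- sqrt(sd0^2 + config$change_het_sd^2)

  # per-item thresholds from configured baseline option frequencies
  cuts_of <- lapply(seq_len(nrow(it)), function(j) {
    p <- option_probs(it$n_options[j], config$severity)
    sd0 * stats::qnorm(cumsum(p)[-it$n_options[j]])
  })

  eff <- config$arm_effects
  eff_row <- match(facet_of, eff$facet)
  if (anyNA(eff_row))
    stop("arm_effects missing facet(s): ",
         paste(unique(facet_of[is.na(eff_row)]), collapse = ", "),
         call. = FALSE)
  shifts <- do.call(rbind, lapply(seq_len(nrow(it)), function(j) {
    et <- eff$et_change[eff_row[j]]
    pt <- et + eff$pt_extra[eff_row[j]]
    data.frame(
      item_id = it$item_id[j], facet = facet_of[j],
      delta_et = solve_latent_shift(et, cuts_of[[j]], it$n_options[j],
                                    it$min_score[j], sd0, sd1),
      delta_pt = solve_latent_shift(pt, cuts_of[[j]], it$n_options[j],
                                    it$min_score[j], sd0, sd1),
      row.names = NULL)
  }))

  core <- stats::rnorm(n)
  rho <- config$inter_facet_cor
  nf <- length(facets)
  sigma <- matrix(rho, nf, nf); diag(sigma) <- 1
  dev <- matrix(stats::rnorm(n * nf), n, nf) %*% chol(sigma)
  colnames(dev) <- facets
  gamma <- stats::rnorm(n)

  fidx <- match(facet_of, facets)
  rows <- list()
  for (tp in config$timepoints) {
    follow <- tp != config$timepoints[1L]
    jset <- if (identical(tp, "week5"))
      which(it$scale_id %in% config$week5_scales) else seq_len(nrow(it))
    if (!length(jset)) next
    struct <- lc * core %o% rep(1, length(jset)) +
      lf * dev[, fidx[jset], drop = FALSE]
    if (follow) {
      delta <- (arms == "PT") %o% shifts$delta_pt[jset] +
        (arms == "ET") %o% shifts$delta_et[jset]
      struct <- struct + delta + config$change_het_sd * gamma
    }
    z <- struct + matrix(stats::rnorm(n * length(jset), sd = config$noise_sd),
                         n, length(jset))
    level <- vapply(seq_along(jset), function(k)
      findInterval(z[, k], cuts_of[[jset[k]]]), integer(n))
    rows[[tp]] <- data.frame(
      patient_id = rep(pids, times = length(jset)),
      timepoint = tp,
      item_id = rep(it$item_id[jset], each = n),
      score = as.integer(it$min_score[jset][rep(seq_along(jset),
                                                each = n)] + as.vector(level)))
  }

  ex <- config$expectancy
  w_pt <- ex$cor_improve * (-gamma) +
    sqrt(1 - ex$cor_improve^2) * stats::rnorm(n)
  e_pt <- pmin(pmax(round(ex$mu_pt + ex$sd_pt * w_pt), 0), 100)
  e_et <- pmin(pmax(round(ex$mu_et + ex$sd_et * stats::rnorm(n)), 0), 100)
  expectancy <- data.frame(patient_id = pids, expectancy_pt = e_pt,
                           expectancy_et = e_et)

  cube <- response_cube(do.call(rbind, rows),
                        arms = data.frame(patient_id = pids, arm = arms),
                        expectancy = expectancy, scales = config$scales,
                        timepoints = config$timepoints)
  truth <- list(core = stats::setNames(core, pids),
                facet_dev = `rownames<-`(dev, pids),
                gamma = stats::setNames(gamma, pids),
                shifts = shifts, sd_baseline = sd0, sd_followup = sd1,
                config = config, seed = as.integer(seed))
  list(cube = cube, truth = truth)
}

#' Deterministic 8-patient miniature fixture
#'
#' A hand-checkable cube for unit tests: 8 patients (4 PT, 4 ET), baseline
#' and week 6, all 78 built-in items, with scores following the explicit
#' pattern `level = (i + j + 2 t) mod K` for patient index i, item index j
#' (order of [item_table()]) and time t (0, 1). No randomness.
#'
#' @return A validated [response_cube()].
#' @export
fixture_small <- function() {
  it <- item_table(builtin_scales())
  pids <- paste0("F", 1:8)
  rows <- do.call(rbind, lapply(0:1, function(t)
    do.call(rbind, lapply(seq_len(nrow(it)), function(j)
      data.frame(patient_id = pids,
                 timepoint = c("baseline", "week6")[t + 1L],
                 item_id = it$item_id[j],
                 score = it$min_score[j] +
                   (seq_len(8L) + j + 2L * t) %% it$n_options[j])))))
  response_cube(
    rows,
    arms = data.frame(patient_id = pids,
                      arm = rep(c("PT", "ET"), each = 4L)),
    expectancy = data.frame(patient_id = pids,
                            expectancy_pt = 50 + 5 * (1:8),
                            expectancy_et = 40 + 5 * (1:8)))
}
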