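test_that("generation is fully reproducible from the seed", {
  g1 <- generate_cohort(generator_config(), seed = 99L)
  g2 <- generate_cohort(generator_config(), seed = 99L)
  expect_identical(g1$cube$responses, g2$cube$responses)
  expect_identical(g1$cube$expectancy, g2$cube$expectancy)
  expect_identical(g1$truth$core, g2$truth$core)
  g3 <- generate_cohort(generator_config(), seed = 100L)
  expect_false(identical(g1$cube$responses, g3$cube$responses))
})

test_that("marginal item distributions respect the configured thresholds", {
  cfg <- generator_config(n_pt = 5000L, n_et = 5000L,
                          timepoints = "baseline")
  g <- generate_cohort(cfg, seed = 12L)
  it <- item_table(builtin_scales())
  for (id in c("QIDS5", "MADRS1", "HAMD4", "SHAPS1")) {
    row <- it[it$item_id == id, ]
    p <- depfacet:::option_probs(row$n_options, cfg$severity)
    s <- score_matrix(g$cube, id, "baseline")[, 1L]
    obs <- tabulate(s - row$min_score + 1L, nbins = row$n_options)
    expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.01)
  }
})

test_that("latent shifts realise configured effects exactly in expectation", {
  g <- generate_cohort(generator_config(), seed = 1L)
  tr <- g$truth
  eff <- tr$config$arm_effects
  it <- item_table(builtin_scales())
  for (id in c("QIDS5", "BDI1", "SHAPS3", "HAMD1")) {
    row <- it[it$item_id == id, ]
    sh <- tr$shifts[tr$shifts$item_id == id, ]
    p <- depfacet:::option_probs(row$n_options, tr$config$severity)
    cuts <- tr$sd_baseline * qnorm(cumsum(p)[-row$n_options])
    er <- function(mu, sd) depfacet:::expected_rescaled(
      mu, sd, cuts, row$n_options, row$min_score)
    base <- er(0, tr$sd_baseline)
    e_row <- eff[eff$facet == sh$facet, ]
    expect_equal(er(sh$delta_et, tr$sd_followup) - base, e_row$et_change,
                 tolerance = 1e-8)
    expect_equal(er(sh$delta_pt, tr$sd_followup) - base,
                 e_row$et_change + e_row$pt_extra, tolerance = 1e-8)
  }
  expect_error(
    generate_cohort(generator_config(arm_effects = within(
      default_arm_effects(), et_change <- -2))),
    "attainable")
})

test_that("larger configured arm effects yield larger recovered interactions", {
  did_at <- function(extra) {
    eff <- default_arm_effects()
    eff$pt_extra[eff$facet == "DepressedMood"] <- extra
    cfg <- generator_config(n_pt = 400L, n_et = 400L, arm_effects = eff,
                            timepoints = c("baseline", "week6"))
    g <- generate_cohort(cfg, seed = 21L)
    alloc <- default_facet_allocation()
    items <- alloc$item_id[!is.na(alloc$facet) &
                             alloc$facet == "DepressedMood"]
    m0 <- depfacet:::rescaled_matrix(g$cube, items, "baseline")
    m1 <- depfacet:::rescaled_matrix(g$cube, items, "week6")
    arm <- g$cube$arms[rownames(m0)]
    d <- rowMeans(m1) - rowMeans(m0)
    mean(d[arm == "PT"]) - mean(d[arm == "ET"])
  }
  est <- vapply(c(0, -0.06, -0.12), did_at, numeric(1))
  expect_true(all(diff(abs(est)) > 0))
})

test_that("the configured facet effect is recovered without bias at large n", {
  cfg <- generator_config(n_pt = 1000L, n_et = 1000L,
                          timepoints = c("baseline", "week6"))
  alloc <- default_facet_allocation()
  items <- alloc$item_id[!is.na(alloc$facet) & alloc$facet == "DepressedMood"]
  ests <- vapply(1:30, function(i) {
    g <- generate_cohort(cfg, seed = 7000L + i)
    m0 <- depfacet:::rescaled_matrix(g$cube, items, "baseline")
    m1 <- depfacet:::rescaled_matrix(g$cube, items, "week6")
    arm <- g$cube$arms[rownames(m0)]
    d <- rowMeans(m1) - rowMeans(m0)
    mean(d[arm == "PT"]) - mean(d[arm == "ET"])
  }, numeric(1))
  target <- default_arm_effects()
  target <- target$pt_extra[target$facet == "DepressedMood"]
  expect_lt(abs(mean(ests) - target), 0.02)
})

test_that("the trial schedule is honoured: week 5 is QIDS-only", {
  g <- generate_cohort(generator_config(), seed = 3L)
  r <- g$cube$responses
  w5 <- unique(r$item_id[r$timepoint == "week5"])
  expect_true(all(grepl("^QIDS", w5)))
  expect_length(w5, 16L)
  expect_identical(length(unique(r$item_id[r$timepoint == "baseline"])), 78L)
  # arm sizes match the configured cohort
  expect_identical(sum(g$cube$arms == "PT"), 30L)
  expect_identical(sum(g$cube$arms == "ET"), 29L)
})

test_that("expectancy ratings are bounded and linked to improvement", {
  cfg <- generator_config(n_pt = 1000L, n_et = 1000L,
                          timepoints = c("baseline", "week6"))
  g <- generate_cohort(cfg, seed = 17L)
  ex <- g$cube$expectancy
  expect_true(all(ex$expectancy_pt >= 0 & ex$expectancy_pt <= 100))
  expect_true(all(ex$expectancy_et >= 0 & ex$expectancy_et <= 100))
  # patients with higher PT-relative expectancy improve more (gamma < 0)
  rexp <- relative_expectancy(g$cube)
  expect_gt(cor(rexp[names(g$truth$gamma)], -g$truth$gamma), 0.1)
})

test_that("the miniature fixture is valid and hand-checkable", {
  fx <- fixture_small()
  expect_silent(validate_cube(fx))
  expect_identical(length(fx$patients), 8L)
  expect_identical(fx$timepoints, c("baseline", "week6"))
  # hand-computed QIDS sum for patient F1 at baseline:
  # levels (i=1): QIDS1..16 = 2,3,0,1,2,3,0,1,2,3,0,1,2,3,0,1
  # criteria: max(2,3,0,1)=3; max(3,0,1,2)=3; max(0,1)=1;
  # singles: QIDS5=2, QIDS10=3, QIDS11=0, QIDS12=1, QIDS13=2, QIDS14=3
  expect_identical(
    qids_sum_score(fx, "baseline", patients = "F1")$value, 18)
  vals <- rescale_responses(fx)$value
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("community threshold preset is floor-heavy", {
  p <- depfacet:::option_probs(4L, generator_config(
    population = "community")$severity)
  expect_gt(p[1], 0.6)                # most mass at the floor
  expect_true(all(diff(p) < 0))       # monotone decreasing endorsement
  expect_identical(nrow(ordinality_check(round(1e4 * p))), 0L)
})
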