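# balanced complete two-timepoint outcome from the generator
facet_outcome <- function(g, facet = "DepressedMood", t1 = "week6") {
  alloc <- default_facet_allocation()
  items <- alloc$item_id[!is.na(alloc$facet) & alloc$facet == facet]
  m0 <- depfacet:::rescaled_matrix(g$cube, items, "baseline")
  m1 <- depfacet:::rescaled_matrix(g$cube, items, t1)
  rbind(data.frame(patient_id = rownames(m0), timepoint = "baseline",
                   value = rowMeans(m0)),
        data.frame(patient_id = rownames(m1), timepoint = t1,
                   value = rowMeans(m1)))
}

test_that("the mixed-model interaction equals difference-in-differences", {
  for (seed in c(101L, 102L, 103L)) {
    g <- generate_cohort(generator_config(n_pt = 15L, n_et = 15L),
                         seed = seed)
    s <- facet_outcome(g)
    res <- fit_time_condition(s, g$cube$arms)
    expect_equal(interaction_B(res),
                 oracle_did(s, g$cube$arms, "baseline", "week6"),
                 tolerance = 1e-8)
  }
})

test_that("identical change in both arms gives a zero interaction", {
  n <- 20
  base <- rnorm(n, 0.5, 0.1)
  change <- rep(c(-0.1, -0.2), n / 2)       # same multiset in both arms
  pid <- sprintf("p%02d", 1:n)
  arms <- setNames(rep(c("PT", "ET"), each = n / 2), pid)
  change <- c(change[1:(n / 2)], change[1:(n / 2)])
  s <- rbind(data.frame(patient_id = pid, timepoint = "baseline",
                        value = base),
             data.frame(patient_id = pid, timepoint = "week6",
                        value = base + change))
  res <- fit_time_condition(s, arms)
  expect_equal(interaction_B(res), 0, tolerance = 1e-8)
})

test_that("standardized and unstandardized coefficients share t and p", {
  g <- generate_cohort(generator_config(), seed = 104L)
  s <- facet_outcome(g)
  res <- fit_time_condition(s, g$cube$arms)
  expect_equal(res$terms$B / res$terms$SE_B, res$terms$t, tolerance = 1e-10)
  # slopes share t across scalings; the intercept's standardized version
  # is location-shifted (baseline-centered) so only the slopes must agree
  expect_equal((res$terms$b / res$terms$SE_b)[-1], res$terms$t[-1],
               tolerance = 1e-10)
  expect_true(all(res$terms$p >= 0 & res$terms$p <= 1))
  # containment DF: within-patient terms get N-2
  expect_identical(
    res$terms$DF[res$terms$term %in% c("Time", "Time x Condition")],
    rep(57L, 2))

  # linearity: doubling the outcome doubles B and SE, t unchanged
  s2 <- s; s2$value <- 2 * s$value
  res2 <- fit_time_condition(s2, g$cube$arms)
  expect_equal(res2$terms$B[-1], 2 * res$terms$B[-1], tolerance = 1e-8)
  expect_equal(res2$terms$t, res$terms$t, tolerance = 1e-6)
})

test_that("degenerate designs fail loudly", {
  s <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                  timepoint = rep(c("baseline", "week6"), 2),
                  value = c(0.1, 0.2, 0.3, 0.4))
  expect_error(fit_time_condition(s, c(a = "PT", b = "PT")), "both arms")
  s0 <- s; s0$value <- 0.5
  expect_error(fit_time_condition(s0, c(a = "PT", b = "ET")),
               "zero variance")
})

test_that("item profiles are deterministic and follow the timing convention", {
  g <- generate_cohort(generator_config(n_pt = 15L, n_et = 14L), seed = 7L)
  prof <- item_response_profile(g$cube, items = c("QIDS1", "BDI1", "MADRS1"))
  expect_identical(prof$t1[prof$outcome_id == "QIDS1"], c("week5", "week6"))
  expect_identical(prof$t1[prof$outcome_id == "BDI1"], "week6")
  prof2 <- item_response_profile(g$cube, items = c("QIDS1", "BDI1", "MADRS1"))
  expect_identical(prof, prof2)

  # two ids carrying identical data yield identical rows
  set.seed(450)
  m <- matrix(sample(0:3, 20 * 2, TRUE), 20, 2)
  m[, 2] <- m[, 1]
  colnames(m) <- c("T1", "T2")
  rownames(m) <- sprintf("p%02d", 1:20)
  m1 <- matrix(sample(0:3, 20 * 2, TRUE), 20, 2)
  m1[, 2] <- m1[, 1]
  dimnames(m1) <- dimnames(m)
  cube <- cube_from_scores(list(baseline = m, week6 = m1),
                           rep(c("PT", "ET"), 10), scales = toy_scales(2L))
  prof3 <- item_response_profile(cube, items = c("T1", "T2"),
                                 comparisons = list(TOY = "week6"))
  expect_equal(prof3[prof3$outcome_id == "T1", -1],
               prof3[prof3$outcome_id == "T2", -1], ignore_attr = TRUE)
})

test_that("null items give interaction estimates centered on zero", {
  eff <- default_arm_effects(); eff$et_change <- -0.1; eff$pt_extra <- 0
  cfg <- generator_config(arm_effects = eff,
                          timepoints = c("baseline", "week6"))
  set.seed(451)
  seeds <- sample.int(2^31 - 1, 60)
  Bs <- vapply(seeds, function(sd) {
    g <- generate_cohort(cfg, seed = sd)
    s <- facet_outcome(g, "NegativeCognition")
    oracle_did(s, g$cube$arms, "baseline", "week6")
  }, numeric(1))
  expect_lt(abs(mean(Bs)), 2.5 * sd(Bs) / sqrt(length(Bs)))
})

test_that("expectancy moderation is centering-invariant and guards degeneracy", {
  g <- generate_cohort(generator_config(), seed = 106L)
  s <- facet_outcome(g)
  rexp <- relative_expectancy(g$cube)
  em_c <- expectancy_moderation(s, g$cube$arms, rexp, center = TRUE)
  em_u <- expectancy_moderation(s, g$cube$arms, rexp, center = FALSE)
  three_way <- function(em) em$terms$B[em$terms$term == "time:cond:rexp"]
  expect_equal(three_way(em_c), three_way(em_u), tolerance = 1e-6)
  # lower-order Condition term does change under centering
  cond <- function(em) em$terms$B[em$terms$term == "cond"]
  expect_false(isTRUE(all.equal(cond(em_c), cond(em_u), tolerance = 1e-8)))

  # expectancy unrelated to outcome: Time x Condition barely moves
  two_way <- fit_time_condition(s, g$cube$arms)
  noise_exp <- setNames(rnorm(59, 0, 10), g$cube$patients)
  em_n <- expectancy_moderation(s, g$cube$arms, noise_exp)
  b2 <- interaction_B(two_way)
  b3 <- em_n$terms$B[em_n$terms$term == "time:cond"]
  se <- two_way$terms$SE_B[two_way$terms$term == "Time x Condition"]
  expect_lt(abs(b3 - b2), 2 * se)

  const_exp <- setNames(rep(10, 59), g$cube$patients)
  expect_error(expectancy_moderation(s, g$cube$arms, const_exp), "constant")
  all_na <- setNames(rep(NA_real_, 59), g$cube$patients)
  expect_error(expectancy_moderation(s, g$cube$arms, all_na),
               "no patients")
})

test_that("variance diagnostics match two-pass SD oracles", {
  g <- generate_cohort(generator_config(), seed = 107L)
  vd <- variance_diagnostics(g$cube)
  expect_true(all(vd$table$se_interaction >= 0))
  expect_true(all(vd$table$sd_baseline >= 0))
  row <- vd$table[vd$table$outcome == "BDI mean-score", ]
  s0 <- scale_mean_score(g$cube, "BDI", "baseline")
  s1 <- scale_mean_score(g$cube, "BDI", "week6")
  expect_equal(row$sd_baseline, oracle_sd(s0$value), tolerance = 1e-12)
  w <- merge(s0[c("patient_id", "value")], s1[c("patient_id", "value")],
             by = "patient_id")
  expect_equal(row$sd_change, oracle_sd(w$value.y - w$value.x),
               tolerance = 1e-12)
  # QIDS appears at both follow-up weeks; mean-score plus both variants
  expect_identical(sum(grepl("^QIDS", vd$table$outcome)), 6L)
  expect_true(all(c("week5", "week6") %in%
                    vd$table$t1[vd$table$outcome == "QIDS mean-score"]))
  expect_identical(nrow(vd$pct_excess), 6L * 3L)
})

test_that("identical scales produce identical diagnostics", {
  set.seed(452)
  n <- 24
  mk <- function() matrix(sample(0:3, n * 4, TRUE), n, 4)
  b <- mk(); e <- mk()
  two_same <- function(m) cbind(m, m)
  sc <- list(A = scale_definition("A", lapply(1:4, function(i)
    item_definition(paste0("A", i), "a", 4L))),
    B = scale_definition("B", lapply(1:4, function(i)
      item_definition(paste0("B", i), "b", 4L))))
  nm <- c(paste0("A", 1:4), paste0("B", 1:4))
  mb <- two_same(b); me <- two_same(e)
  colnames(mb) <- colnames(me) <- nm
  rownames(mb) <- rownames(me) <- sprintf("p%02d", 1:n)
  cube <- cube_from_scores(list(baseline = mb, week6 = me),
                           rep(c("PT", "ET"), n / 2), scales = sc)
  rows <- lapply(c("A", "B"), function(sid) {
    s <- rbind(scale_mean_score(cube, sid, "baseline"),
               scale_mean_score(cube, sid, "week6"))
    res <- fit_time_condition(s[c("patient_id", "timepoint", "value")],
                              cube$arms)
    c(se = res$terms$SE_B[4], sd0 = oracle_sd(
      s$value[s$timepoint == "baseline"]))
  })
  expect_equal(rows[[1]], rows[[2]], tolerance = 1e-10)
})
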