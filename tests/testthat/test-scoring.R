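test_that("points-possible rescaling is literal and order-preserving", {
  it14 <- item_definition("S1", "1-4 item", n_options = 4L, min_score = 1L)
  it03 <- item_definition("Q", "0-3 item", n_options = 4L)
  expect_identical(rescale_item(2L, it14), 0.5)
  expect_identical(rescale_item(1L, it14), 0.25)   # minimum = min/points
  expect_identical(rescale_item(0L, it03), 0)
  expect_identical(rescale_item(3L, it03), 0.75)   # literal: max < 1
  # normalized mode maps the admissible range onto [0, 1] exactly
  expect_identical(rescale_item(1L, it14, mode = "minmax"), 0)
  expect_identical(rescale_item(4L, it14, mode = "minmax"), 1)
  expect_true(all(diff(rescale_item(1:4, it14)) > 0))
  expect_error(rescale_item(5L, it14), "out of range")
})

test_that("QIDS sum-score matches the brute-force criterion oracle", {
  # floor and ceiling
  z <- matrix(0L, 1, 16, dimnames = list("p", NULL))
  expect_identical(
    qids_sum_score(qids_cube(list(baseline = z), "PT"), "baseline")$value, 0)
  expect_identical(
    qids_sum_score(qids_cube(list(baseline = z + 3L), "PT"),
                   "baseline")$value, 27)

  # exhaustive over all 4^4 sleep-item combinations, other items fixed
  sleep <- as.matrix(expand.grid(0:3, 0:3, 0:3, 0:3))
  fixed <- matrix(rep(c(2L, 1L, 0L, 3L, 2L, 1L, 0L, 3L, 2L, 1L, 0L, 2L),
                      each = nrow(sleep)), nrow(sleep))
  m <- cbind(sleep, fixed)
  rownames(m) <- sprintf("e%03d", seq_len(nrow(m)))
  got <- qids_sum_score(qids_cube(list(baseline = m),
                                  rep(c("PT", "ET"), length.out = nrow(m))),
                        "baseline")
  want <- apply(m, 1L, oracle_qids_sum)
  expect_identical(got$value, as.numeric(want[got$patient_id]))

  # 1,000 seeded random draws
  set.seed(401)
  r <- matrix(sample(0:3, 16000, replace = TRUE), 1000, 16,
              dimnames = list(sprintf("r%04d", 1:1000), NULL))
  got <- qids_sum_score(qids_cube(list(baseline = r),
                                  rep(c("PT", "ET"), 500)), "baseline")
  expect_identical(got$value,
                   as.numeric(apply(r, 1L, oracle_qids_sum)[got$patient_id]))

  # missing items are named
  holey <- m[1:2, ]; holey[1L, 5L] <- NA
  expect_error(
    qids_sum_score(qids_cube(list(baseline = holey), c("PT", "ET")),
                   "baseline"),
    "QIDS5")
})

test_that("de-compounded mean variants average exactly 13 rescaled items", {
  set.seed(402)
  m <- matrix(sample(0:3, 16 * 50, replace = TRUE), 50, 16,
              dimnames = list(sprintf("p%02d", 1:50), NULL))
  cube <- qids_cube(list(baseline = m), rep(c("PT", "ET"), 25))
  for (v in c("all_items_1", "all_items_2")) {
    excl <- if (v == "all_items_1") c(4, 7, 9) else c(4, 6, 8)
    keep <- setdiff(1:16, excl)
    expect_length(keep, 13L)
    got <- qids_mean_variant(cube, "baseline", v)
    want <- rowMeans(m[, keep] / 4)
    expect_equal(got$value, unname(want[got$patient_id]), tolerance = 1e-12)
  }
  # symmetric exclusion: variants agree when QIDS6=QIDS7 and QIDS8=QIDS9
  m2 <- m; m2[, 7] <- m2[, 6]; m2[, 9] <- m2[, 8]
  cube2 <- qids_cube(list(baseline = m2), rep(c("PT", "ET"), 25))
  expect_equal(qids_mean_variant(cube2, "baseline", "all_items_1")$value,
               qids_mean_variant(cube2, "baseline", "all_items_2")$value)
  # constant responses: mean equals the rescaled constant
  expect_equal(
    qids_mean_variant(qids_cube(list(baseline = matrix(
      2L, 1, 16, dimnames = list("p", NULL))), "PT"),
      "baseline", "all_items_1")$value, 0.5)
})

test_that("scale mean-scores match the brute-force rescaled mean", {
  g <- generate_cohort(generator_config(n_pt = 8L, n_et = 8L), seed = 5L)
  for (sid in c("QIDS", "MADRS", "HRS", "BDI", "SHAPS")) {
    got <- scale_mean_score(g$cube, sid, "baseline")
    items <- names(g$cube$scales[[sid]]$items)
    it <- g$cube$items
    m <- score_matrix(g$cube, items, "baseline")
    want <- rowMeans(sweep(m, 2L,
                           it$points_possible[match(items, it$item_id)],
                           "/"))
    expect_equal(got$value, unname(want[got$patient_id]), tolerance = 1e-12)
    expect_true(all(got$value >= 0 & got$value <= 1))
  }
  # single-item scale passes the rescaled value through; max maps to 1
  # under the minmax convention
  one <- list(ONE = scale_definition(
    "ONE", list(item_definition("O1", "only", 4L))))
  m <- matrix(3L, 2, 1, dimnames = list(c("a", "b"), "O1"))
  cube1 <- cube_from_scores(list(baseline = m), c("PT", "ET"), scales = one)
  expect_equal(scale_mean_score(cube1, "ONE", "baseline")$value,
               c(0.75, 0.75))
  expect_equal(
    scale_mean_score(cube1, "ONE", "baseline", mode = "minmax")$value,
    c(1, 1))
})

test_that("Cronbach's alpha and r.drop behave at the closed-form anchors", {
  # two perfectly correlated items with equal variance
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cronbach_alpha(cbind(a = x, b = x))$alpha, 1)

  # k independent items: alpha near 0 at n = 10,000
  set.seed(403)
  ind <- matrix(rnorm(10000 * 6), 10000, 6,
                dimnames = list(NULL, paste0("i", 1:6)))
  expect_lt(abs(cronbach_alpha(ind)$alpha), 0.05)

  # degenerate inputs error rather than silently coerce
  expect_error(cronbach_alpha(cbind(a = x, b = rep(2, 5))), "zero variance")
  expect_error(cronbach_alpha(cbind(a = x)), "2 items")
  expect_error(cronbach_alpha(cbind(a = x, b = x)[1:2, ]), "3 complete")

  # listwise deletion is counted
  withna <- cbind(a = x, b = x + c(0.1, -0.2, 0.3, 0, 0.1))
  withna[1L, 1L] <- NA
  expect_identical(cronbach_alpha(withna)$n_dropped, 1L)
  expect_identical(cronbach_alpha(withna)$n_patients, 4L)

  # raw vs standardized alpha differ under unequal item variances
  set.seed(404)
  u <- rnorm(200); a <- u + rnorm(200, sd = 0.5)
  b <- 10 * (u + rnorm(200, sd = 0.5))
  raw <- cronbach_alpha(cbind(a = a, b = b))$alpha
  std <- cronbach_alpha(cbind(a = scale(a)[, 1], b = scale(b)[, 1]))$alpha
  expect_gt(abs(raw - std), 0.01)

  # r.drop is invariant to positive affine rescaling of the item set
  set.seed(405)
  m <- matrix(sample(0:3, 200 * 4, replace = TRUE), 200, 4,
              dimnames = list(NULL, paste0("q", 1:4)))
  expect_equal(cronbach_alpha(m)$r_drop, cronbach_alpha(m / 4)$r_drop,
               tolerance = 1e-12)
})

test_that("ordinality check flags only strict endorsement reversals", {
  v <- ordinality_check(c(1518, 532, 100, 393))
  expect_identical(nrow(v), 1L)
  expect_identical(v$option_from, "2")
  expect_identical(v$option_to, "3")
  expect_identical(nrow(ordinality_check(c(900, 500, 200, 10))), 0L)
  expect_identical(nrow(ordinality_check(c(100, 100, 100))), 0L)  # ties ok
  expect_error(ordinality_check(c(5)), "2 options")
})
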