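test_that("simple random sampling draws the right number, uniformly", {
  plan <- plan_srs(1:140, 0.5, seed = 1)
  expect_equal(length(plan$selected), 70)
  expect_true(all(plan$selected %in% 1:140))
  expect_false(anyDuplicated(plan$selected) > 0)

  expect_setequal(plan_srs(1:140, 1.0, seed = 2)$selected, 1:140)
  expect_error(plan_srs(integer(0), 0.5, seed = 1), "empty")
  expect_error(plan_srs(1:10, 0, seed = 1), "fraction")

  # inclusion frequency ~ 0.5 per facility over many seeds (binomial oracle)
  inc <- rowMeans(vapply(1:1000, function(s) 1:140 %in% plan_srs(1:140, 0.5, seed = s)$selected,
                         logical(140)))
  expect_true(all(abs(inc - 0.5) < 3.5 * sqrt(0.25 / 1000)))
})

test_that("stratified sampling allocates round-half-up per district", {
  pop <- 1:10
  dist <- rep(c("A", "B"), c(4, 6))
  plan <- plan_stratified_srs(pop, dist, 0.5, seed = 3)
  expect_equal(sum(plan$selected %in% 1:4), 2)
  expect_equal(sum(plan$selected %in% 5:10), 3)

  expect_setequal(plan_stratified_srs(pop, dist, 1.0, seed = 3)$selected, pop)

  # allocation per district is deterministic across seeds
  panel <- default_panel()
  facs <- unique(panel$facility_id)
  d <- panel$district_id[match(facs, panel$facility_id)]
  alloc <- vapply(1:50, function(s) {
    sel <- plan_stratified_srs(facs, d, 0.5, seed = s)$selected
    as.vector(table(d[match(sel, facs)]))
  }, numeric(18))
  expect_true(all(alloc == alloc[, 1]))
})

test_that("mixed offender sampling splits the target and reallocates shortfall", {
  pop <- 1:140
  off26 <- 1:26
  plan <- plan_offender_mixed(pop, off26, 28, seed = 5)
  expect_equal(sum(plan$selected %in% off26), 14)
  expect_equal(length(plan$selected), 28)

  off5 <- 1:5
  plan <- plan_offender_mixed(pop, off5, 28, seed = 5)
  expect_true(all(off5 %in% plan$selected))
  expect_equal(length(plan$selected), 28)
  expect_equal(sum(!(plan$selected %in% off5)), 23)

  plan <- plan_offender_mixed(pop, integer(0), 28, seed = 5)
  expect_equal(length(plan$selected), 28)

  expect_error(plan_offender_mixed(pop, c(1, 999), 28, seed = 5), "not in population")
})

test_that("offenders-first sampling exhausts prior offenders before filling", {
  pop <- 1:140
  plan <- plan_offenders_first(pop, 1:26, 28, seed = 5)
  expect_true(all(1:26 %in% plan$selected))
  expect_equal(length(plan$selected), 28)

  plan <- plan_offenders_first(pop, 1:30, 28, seed = 5)
  expect_equal(length(plan$selected), 28)
  expect_true(all(plan$selected %in% 1:30))

  plan <- plan_offenders_first(pop, 1:28, 28, seed = 5)
  expect_setequal(plan$selected, 1:28)

  expect_error(plan_offenders_first(pop, 1:5, 300, seed = 5), "exceeds")
})

test_that("model-ranked targeting picks the top scores with seeded tie-breaks", {
  pop <- letters[1:10]
  scores <- setNames(10:1, pop)
  expect_setequal(plan_model_ranked(pop, scores, 3, seed = 1)$selected,
                  c("a", "b", "c"))

  tied <- setNames(rep(1, 10), pop)
  p1 <- plan_model_ranked(pop, tied, 3, seed = 7)
  p2 <- plan_model_ranked(pop, tied, 3, seed = 7)
  expect_identical(p1$selected, p2$selected)
  expect_equal(length(p1$selected), 3)

  expect_error(plan_model_ranked(pop, setNames(c(NA, rep(1, 9)), pop), 3),
               "non-finite")

  # perfect oracle: score = label -> full yield while target <= flagged count
  flagged <- c("b", "d", "f")
  oracle <- setNames(as.numeric(pop %in% flagged), pop)
  sel <- plan_model_ranked(pop, oracle, 3, seed = 1)$selected
  expect_setequal(sel, flagged)
})

test_that("SRS detection yield matches the hypergeometric mean", {
  pop <- 1:140
  flagged <- withr::with_seed(4, sample(pop, 28))
  res <- sampling_yield(function(s) plan_srs(pop, 0.5, s), flagged,
                        reps = 1000, seed = 11)
  # closed-form mean K/N = 0.2; SE of the mean of 1000 draws of 70
  se <- sqrt(0.2 * 0.8 * (140 - 70) / (140 - 1) / 70) / sqrt(1000)
  expect_lt(abs(res$mean_yield - 0.2), 4 * se)
})
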