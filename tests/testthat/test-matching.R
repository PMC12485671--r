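test_that("optimal matching solves small instances exactly", {
  # treated {0, 1}, controls {0.1, 0.9, 5.0}: enumerate -> (0,0.1), (1,0.9)
  s <- make_scores(c(0, 1, 0.1, 0.9, 5.0),
                   c("t", "t", "c", "c", "c"))
  r <- optimal_match(s, spec = match_spec())
  expect_equal(r$total_distance, 0.2, tolerance = 1e-12)
  expect_equal(r$pairs$control_id[r$pairs$treated_id == "s01"], "s03")
  expect_equal(r$pairs$control_id[r$pairs$treated_id == "s02"], "s04")
  expect_equal(nrow(r$discarded), 0)
})

test_that("identical logits give zero distance and lexicographic pairing", {
  s <- make_scores(c(0.5, 0.5, 0.5, 0.5), c("t", "t", "c", "c"))
  r <- optimal_match(s)
  expect_equal(r$total_distance, 0)
  expect_equal(r$pairs$treated_id, c("s01", "s02"))
  expect_equal(r$pairs$control_id, c("s03", "s04"))
})

test_that("caliper constrains admissible pairs and discards per the flag", {
  s <- make_scores(c(0, 1, 0.1, 0.9, 5.0), c("t", "t", "c", "c", "c"))
  # wide caliper: result unchanged
  r <- optimal_match(s, spec = match_spec(caliper_sd = 10))
  expect_equal(r$total_distance, 0.2, tolerance = 1e-12)
  # individually infeasible treated: logit 10 has no control within caliper
  s2 <- make_scores(c(0, 10, 0.1, 0.9), c("t", "t", "c", "c"))
  sd2 <- sqrt((var(c(0, 10)) + var(c(0.1, 0.9))) / 2)
  tight2 <- 1 / sd2   # caliper width 1: control 0.9 is 9.1 away from 10
  expect_error(optimal_match(s2, spec = match_spec(caliper_sd = tight2)),
               class = "qcmatch_capacity_error")
  rd <- optimal_match(s2, spec = match_spec(caliper_sd = tight2,
                                            discard_unmatchable = TRUE))
  expect_equal(rd$pairs$treated_id, "s01")
  expect_equal(rd$discarded$subject_id, "s02")
  expect_equal(rd$discarded$reason, "no_candidate_in_caliper")
  # jointly infeasible: both treated admissible only to the same control
  s3 <- make_scores(c(0, 0.05, 0, 4, 5), c("t", "t", "c", "c", "c"))
  sd3 <- sqrt((var(c(0, 0.05)) + var(c(0, 4, 5))) / 2)
  tight3 <- 0.2 / sd3
  expect_error(optimal_match(s3, spec = match_spec(caliper_sd = tight3)),
               class = "qcmatch_capacity_error")
  rj <- optimal_match(s3, spec = match_spec(caliper_sd = tight3,
                                            discard_unmatchable = TRUE))
  expect_equal(rj$pairs$treated_id, "s01")   # minimum-cost retention
  expect_equal(rj$pairs$control_id, "s03")
  expect_equal(rj$discarded$subject_id, "s02")
  expect_equal(rj$discarded$reason, "no_candidate_in_caliper")
})

test_that("greedy nearest matching can be suboptimal but never beats optimal", {
  s <- make_scores(c(0, 0.5, 0.4, 1.0), c("t", "t", "c", "c"))
  rg <- nearest_match(s)
  ro <- optimal_match(s)
  expect_equal(rg$total_distance, 1.1, tolerance = 1e-12)
  expect_equal(ro$total_distance, 0.9, tolerance = 1e-12)
  # property: optimal <= nearest on random instances
  set.seed(77)
  for (i in 1:25) {
    nt <- sample(2:6, 1); nc <- nt + sample(0:4, 1)
    sr <- make_scores(runif(nt + nc, -2, 2), rep(c("t", "c"), c(nt, nc)))
    expect_lte(optimal_match(sr)$total_distance,
               nearest_match(sr)$total_distance + 1e-12)
  }
  # single treated / single control: the only pair
  s1 <- make_scores(c(0.3, 0.8), c("t", "c"))
  expect_equal(nrow(nearest_match(s1)$pairs), 1)
})

test_that("controls are never reused and capacity violations error", {
  set.seed(11)
  s <- make_scores(runif(12), rep(c("t", "c"), c(5, 7)))
  r <- optimal_match(s)
  expect_equal(anyDuplicated(r$pairs$control_id), 0)
  expect_equal(nrow(r$pairs), 5)
  s2 <- make_scores(runif(8), rep(c("t", "c"), c(5, 3)))
  # smaller group becomes the 'from' side: pairs = 3, all controls used
  r2 <- optimal_match(s2)
  expect_equal(nrow(r2$pairs), 3)
  expect_error(optimal_match(s2[0, ], groups = character(0)),
               class = "qcmatch_validation_error")
})

test_that("exact matching keeps pairs within strata", {
  co <- make_toy_cohort(6, 8, seed = 21)
  co$site <- rep(c("A", "B"), length.out = 14)
  m <- fit_propensity(co)
  s <- compute_scores(m, co)
  r <- optimal_match(s, co$group, match_spec(exact_vars = "site"), co)
  site_of <- setNames(co$site, co$subject_id)
  expect_true(all(site_of[r$pairs$treated_id] == site_of[r$pairs$control_id]))
  expect_error(optimal_match(s, co$group, match_spec(exact_vars = "site")),
               class = "qcmatch_schema_error")
})

test_that("common support trimming discards extreme treated subjects", {
  s <- make_scores(c(-5, 0, 0.5, -0.2, 0.2, 0.6),
                   c("t", "t", "t", "c", "c", "c"))
  r <- optimal_match(s, spec = match_spec(common_support = TRUE,
                                          discard_unmatchable = TRUE))
  expect_true("s01" %in% r$discarded$subject_id)
  expect_equal(r$discarded$reason[r$discarded$subject_id == "s01"],
               "outside_common_support")
  expect_equal(nrow(r$pairs), 2)
})

test_that("tiered matching reduces to single-stage and respects tier structure", {
  co <- make_toy_cohort(10, 14, seed = 31)
  single <- tiered_match(co, list(c("iqr_pct", "euler", "defect_pct")))
  m <- fit_propensity(co); s <- compute_scores(m, co)
  direct <- optimal_match(s, co$group, match_spec(), co)
  expect_setequal(paste(single$pairs$treated_id, single$pairs$control_id),
                  paste(direct$pairs$treated_id, direct$pairs$control_id))
  # a perfectly balanced tier-1 covariate leaves the result driven by tier 2
  co2 <- make_toy_cohort(6, 6, seed = 32)
  co2$iqr_pct <- rep(c(70, 75, 80), 4)  # identical multisets per group
  two <- tiered_match(co2, list("iqr_pct", "euler"))
  only2 <- tiered_match(co2, list("euler"))
  expect_setequal(paste(two$pairs$treated_id, two$pairs$control_id),
                  paste(only2$pairs$treated_id, only2$pairs$control_id))
  expect_error(tiered_match(co, list("iqr_pct", "nope")),
               class = "qcmatch_schema_error")
  expect_error(tiered_match(co, list("iqr_pct", "iqr_pct")),
               class = "qcmatch_config_error")
  expect_length(attr(two, "tier_balance"), 2)
})

test_that("apply_match subsets to paired subjects in pair order", {
  co <- make_toy_cohort(5, 8, seed = 41)
  m <- fit_propensity(co); s <- compute_scores(m, co)
  r <- optimal_match(s, co$group, match_spec(), co)
  out <- apply_match(co, r)
  expect_equal(nrow(out), 2 * nrow(r$pairs))
  expect_equal(sum(is_treated(out)), sum(!is_treated(out)))  # equal sizes
  expect_identical(out$subject_id,
                   c(r$pairs$treated_id, r$pairs$control_id))
  bad <- r; bad$pairs$treated_id[1] <- "ghost"
  expect_error(apply_match(co, bad), class = "qcmatch_consistency_error")
})
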