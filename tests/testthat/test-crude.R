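test_that("weighted proportion, Kish n_eff and SE match hand computation", {
  # unweighted reduction
  est <- weighted_cell_estimate(c(rep(1, 3), rep(0, 7)))
  expect_equal(est$p_hat, 0.3)
  expect_equal(est$n_eff, 10)
  expect_equal(est$se, sqrt(0.3 * 0.7 / 10))
  # weights (2,1,1), values (1,0,0): p = 2/4, n_eff = 16/6
  est2 <- weighted_cell_estimate(c(1, 0, 0), c(2, 1, 1))
  expect_equal(est2$p_hat, 0.5)
  expect_equal(est2$n_eff, 16 / 6)
  expect_equal(est2$se, sqrt(0.25 / (16 / 6)))
  # degenerate cell: all successes
  est3 <- weighted_cell_estimate(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_equal(est3$p_hat, 1)
  expect_equal(est3$se, 0)
  expect_equal(est3$n_raw, 4L)
})

test_that("empty cells yield no estimate and small cells are flagged", {
  expect_null(weighted_cell_estimate(numeric(0)))
  expect_null(weighted_cell_estimate(c(NA, NA)))
  expect_true(weighted_cell_estimate(c(1, 0), min_n = 25)$flagged)
  expect_false(weighted_cell_estimate(rep(0:1, 20), min_n = 25)$flagged)
})

test_that("equal weights reproduce unweighted proportions exactly", {
  set.seed(3)
  for (i in 1:20) {
    y <- rbinom(50, 1, runif(1))
    w <- rep(runif(1, 0.1, 10), 50)
    est <- weighted_cell_estimate(y, w)
    expect_equal(est$p_hat, mean(y), tolerance = 1e-14)
    expect_equal(est$n_eff, 50)
  }
})

test_that("study estimates nest cascade denominators inside prevalence", {
  # 100 people aged 50-54: 60 normotensive, 20 hypertensive untreated,
  # 20 hypertensive treated (still above threshold)
  md <- make_records(
    sbp = c(rep(120, 60), rep(155, 40)),
    dbp = rep(70, 100),
    meds = c(rep(FALSE, 80), rep(TRUE, 20)),
    diagnosed = c(rep(FALSE, 80), rep(TRUE, 20)))
  meta <- list(study_id = "st1", country = "AAA", year = 2005,
               coverage = "national", scope = "both")
  cells <- build_study_estimates(md, meta)
  prev <- cells[cells$outcome == "prevalence", ]
  trt <- cells[cells$outcome == "treatment", ]
  expect_equal(prev$p_hat, 0.4)
  expect_equal(prev$n_raw, 100L)
  expect_equal(trt$p_hat, 0.5)
  expect_equal(trt$n_raw, 40L)
  # control p_hat <= treatment p_hat wherever both exist
  ctl <- cells[cells$outcome == "control", ]
  expect_true(all(ctl$p_hat <= trt$p_hat))
})

test_that("a study without the diagnosis question emits no detection cells", {
  md <- make_records(sbp = rep(c(120, 160), 25), dbp = 70,
                     meds = FALSE, diagnosed = NA)
  cells <- build_study_estimates(md, list(study_id = "s", country = "X",
                                          year = 2000))
  expect_false("detection" %in% cells$outcome)
  expect_true(all(c("prevalence", "treatment") %in% cells$outcome))
})

test_that("eligibility is ages 30-79 with half-open five-year bands", {
  md <- make_records(sbp = 150, dbp = 80, meds = FALSE,
                     age = c(29, 30, 79, 80, 55))
  cells <- build_study_estimates(md, list(study_id = "s", country = "X",
                                          year = 2000))
  prev <- cells[cells$outcome == "prevalence", ]
  expect_equal(sum(prev$n_raw), 3L)          # 29 and 80 excluded
  expect_true(75 %in% prev$age_group_lower)  # the 79-year-old sits in [75,80)
  expect_equal(age_band_of(c(34, 35, 79)), c(30L, 35L, 75L))
})

test_that("prevalence denominators partition eligible records", {
  set.seed(5)
  n <- 300
  md <- make_records(sbp = runif(n, 100, 200), dbp = runif(n, 60, 110),
                     meds = runif(n) < 0.2, age = sample(30:79, n, TRUE))
  md$dbp <- pmin(md$dbp, md$sbp - 1)
  cells <- build_study_estimates(md, list(study_id = "s", country = "X",
                                          year = 2000))
  prev <- cells[cells$outcome == "prevalence", ]
  expect_equal(sum(prev$n_raw), n)
})

test_that("crude estimates recover known cell probabilities from microdata", {
  w <- make_world(small_world_config(), seed = 21)
  plan1 <- make_survey_plan(w, seed = 1)[1, ]
  md <- make_microdata(w, plan1, seed = 2, n_per_cell = 400L, weight_sd = 0.3)
  cells <- build_study_estimates(md, plan1)
  prev <- cells[cells$outcome == "prevalence", ]
  off <- htncascade:::plan_offset(w$config, plan1$coverage, plan1$scope)
  miss <- 0
  for (i in seq_len(nrow(prev))) {
    tr <- expit(logit(w$surfaces[[prev$sex[i]]]$prevalence[
      plan1$country, as.character(plan1$year),
      as.character(prev$age_group_lower[i] + 2.5)]) + off)
    se_or <- sqrt(tr * (1 - tr) / prev$n_eff[i])
    if (abs(prev$p_hat[i] - tr) > 3 * se_or) miss <- miss + 1
  }
  expect_lte(miss, 1)   # ~0.3% expected failure rate over 20 cells
})
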