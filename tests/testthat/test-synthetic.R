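test_that("worlds are bit-reproducible given the seed", {
  w1 <- make_world(small_world_config(), seed = 5)
  w2 <- make_world(small_world_config(), seed = 5)
  expect_identical(w1$surfaces, w2$surfaces)
  expect_identical(w1$populations, w2$populations)
  w3 <- make_world(small_world_config(), seed = 6)
  expect_false(identical(w1$surfaces, w3$surfaces))
})

test_that("true surfaces respect the cascade ordering and allowed range", {
  w <- make_world(small_world_config(), seed = 8)
  for (sx in cascade_sexes()) {
    s <- w$surfaces[[sx]]
    expect_true(all(s$control <= s$treatment))
    expect_true(all(s$treatment <= s$detection))
    for (oc in cascade_outcomes())
      expect_true(all(s[[oc]] > 0.0099 & s[[oc]] < 0.9901))
  }
})

test_that("vanishing variance scales collapse all countries onto one surface", {
  cfg <- small_world_config(
    sd_a = c(super = 1e-12, region = 1e-12, country = 1e-12),
    sd_b = c(super = 1e-12, region = 1e-12, country = 1e-12),
    sd_rw = c(global = 1e-12, super = 1e-12, region = 1e-12, country = 1e-12),
    g1 = c(level = 0.4, trend = 0.03, age = 0.015, country_sd = 0),
    g2 = c(level = 0.1, trend = 0.02, age = -0.005, country_sd = 0),
    g3 = c(level = -0.8, trend = -0.015, age = 0.01, country_sd = 0))
  w <- make_world(cfg, seed = 9)
  prev <- w$surfaces$female$prevalence
  for (i in 2:dim(prev)[1])
    expect_equal(prev[i, , ], prev[1, , ], tolerance = 1e-8)
})

test_that("country intercept draws average to their configured mean", {
  # law-of-large-numbers check on the generative prior itself
  cfg <- world_config(n_countries = 1000L, n_regions = 10L,
                      n_super_regions = 2L)
  h <- htncascade:::synthetic_hierarchy(cfg)
  lay <- htncascade:::param_layout(htncascade:::hierarchy_maps(h),
                                   htncascade:::world_model_spec(cfg))
  set.seed(10)
  x <- htncascade:::draw_true_params(lay, cfg, "prevalence", "female")
  devs <- x[lay$par$block == "dev_a" & lay$par$level == "country"]
  expect_equal(length(devs), 1000L)
  se <- cfg$sd_a[["country"]] / sqrt(1000)
  expect_lt(abs(mean(devs) - 0), 3 * se)
})

test_that("sampled cells concentrate on the offset-shifted truth", {
  cfg <- small_world_config(cell_n_range = c(20000, 20000), tau = 1e-6,
                            kappa = c(national = 1e-6, subnational = 1e-6,
                                      community = 1e-6))
  w <- make_world(cfg, seed = 11)
  plan <- make_survey_plan(w, seed = 12)
  cells <- sample_surveys(w, plan, seed = 13)
  prev <- cells$outcome == "prevalence"
  # with huge n and no extra noise, p_hat must sit on the offset-shifted truth
  offs <- vapply(seq_len(nrow(cells)), function(i)
    htncascade:::plan_offset(cfg, cells$coverage[i], cells$scope[i]),
    numeric(1))
  truth_shift <- vapply(which(prev), function(i) expit(
    logit(w$surfaces[[cells$sex[i]]]$prevalence[
      cells$country[i], as.character(cells$year[i]),
      as.character(cells$age_group_lower[i] + 2.5)]) + offs[i]), numeric(1))
  err <- abs(cells$p_hat[prev] - truth_shift)
  bound <- 4 * sqrt(truth_shift * (1 - truth_shift) / 20000)
  expect_gt(mean(err <= bound), 0.98)
})

test_that("community studies spread wider around truth than national ones", {
  cfg <- small_world_config(cell_n_range = c(20000, 20000), tau = 1e-6,
                            kappa = c(national = 0.02, subnational = 0.1,
                                      community = 0.4),
                            frac_zero_study = 0, studies_range = c(6L, 8L))
  w <- make_world(cfg, seed = 14)
  plan <- make_survey_plan(w, seed = 15)
  cells <- sample_surveys(w, plan, seed = 16)
  prev <- cells[cells$outcome == "prevalence" & cells$scope == "both", ]
  res <- vapply(seq_len(nrow(prev)), function(i) {
    tr <- w$surfaces[[prev$sex[i]]]$prevalence[
      prev$country[i], as.character(prev$year[i]),
      as.character(prev$age_group_lower[i] + 2.5)]
    off <- htncascade:::plan_offset(cfg, prev$coverage[i], prev$scope[i])
    logit(prev$p_hat[i]) - (logit(tr) + off)
  }, numeric(1))
  sd_nat <- sd(res[prev$coverage == "national"])
  sd_com <- sd(res[prev$coverage == "community"])
  expect_gt(sd_com, sd_nat)
})

test_that("zero-study countries contribute no cells and plans cover regions", {
  w <- make_world(small_world_config(frac_zero_study = 0.4), seed = 17)
  plan <- make_survey_plan(w, seed = 18)
  cells <- sample_surveys(w, plan, seed = 19)
  expect_true(all(unique(cells$country) %in% plan$country))
  # every region has at least one national study
  hm <- htncascade:::hierarchy_maps(w$hierarchy)
  nat <- plan[plan$coverage == "national", ]
  nat_regions <- unique(w$hierarchy$region[match(nat$country,
                                                 w$hierarchy$country)])
  expect_setequal(nat_regions, hm$regions)
})

test_that("diagnosis availability tracks its configured share", {
  w <- make_world(world_config(), seed = 20)
  plans <- do.call(rbind, lapply(1:8, function(s) make_survey_plan(w, seed = s)))
  frac <- mean(plans$has_diagnosis)
  expect_gt(frac, 0.75); expect_lt(frac, 0.89)   # around the 0.82 share
})

test_that("microdata with unit weights give identical weighted estimates", {
  w <- make_world(small_world_config(), seed = 21)
  st <- make_survey_plan(w, seed = 1)[1, ]
  md <- make_microdata(w, st, seed = 2, n_per_cell = 120L, weight_sd = 0)
  expect_true(all(md$weight == 1))
  cells <- build_study_estimates(md, st)
  sub <- md[md$sex == "female" & htncascade:::age_band_of(md$age) == 50, ]
  cl <- classify_records(sub)
  expect_equal(cells$p_hat[cells$outcome == "prevalence" &
                             cells$sex == "female" &
                             cells$age_group_lower == 50],
               mean(cl$hypertensive))
})

test_that("a null treatment effect lowers realised control rates", {
  w <- make_world(small_world_config(), seed = 22)
  st <- make_survey_plan(w, seed = 3)[1, ]
  md_eff <- make_microdata(w, st, seed = 4, n_per_cell = 400L)
  md_null <- make_microdata(w, st, seed = 4, n_per_cell = 400L,
                            treatment_effect = c(sbp = 0, dbp = 0))
  rate <- function(md) {
    cl <- classify_records(md)
    mean(cl$controlled[cl$hypertensive])
  }
  expect_gt(rate(md_eff), rate(md_null))
})

test_that("out-of-range configurations regenerate with shrunken scales", {
  cfg <- small_world_config(sd_a = c(super = 6, region = 4, country = 4))
  expect_message(w <- make_world(cfg, seed = 23), "shrunken")
  expect_gt(w$regenerated, 0)
})
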