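# helper: wrap a [unit, year, age, draw] array as a posterior_surface
as_ps <- function(arr, sex = "female", outcome = "prevalence") {
  structure(list(arr = arr, countries = dimnames(arr)[[1]],
                 years = as.integer(dimnames(arr)[[2]]),
                 ages = as.numeric(dimnames(arr)[[3]]),
                 outcome = outcome, sex = sex, n_draws = dim(arr)[4]),
            class = "posterior_surface")
}

toy_surface <- function(vals, units = "u1", years = 2000, draws = 1) {
  ages <- age_band_midpoints()[seq_along(vals)]
  arr <- array(rep(vals, each = length(units) * length(years)),
               dim = c(length(units), length(years), length(vals), draws),
               dimnames = list(units, years, ages, NULL))
  arr
}

test_that("age standardisation is a convex combination with exact toy values", {
  # constant rates are invariant for any weights
  arr <- toy_surface(rep(0.3, 10))
  expect_equal(as.vector(age_standardise_prevalence(arr)), 0.3)
  # two-band toy: equal weights, p = (0.2, 0.4) -> 0.3
  arr2 <- toy_surface(c(0.2, 0.4))
  std2 <- data.frame(age_group_lower = c(30, 35), weight = c(0.5, 0.5))
  expect_equal(as.vector(age_standardise_prevalence(arr2, std2)), 0.3)
  # always inside the age-specific range, invariant to weight rescaling
  set.seed(1)
  for (i in 1:20) {
    p <- runif(10)
    wts <- runif(10, 0.1, 2)
    std <- data.frame(age_group_lower = age_bands(), weight = wts)
    std_scaled <- transform(std, weight = weight * 37.5)
    v <- as.vector(age_standardise_prevalence(toy_surface(p), std))
    expect_gte(v, min(p)); expect_lte(v, max(p))
    expect_equal(v, as.vector(age_standardise_prevalence(toy_surface(p),
                                                         std_scaled)))
  }
  # a missing band is an error naming the band
  expect_error(age_standardise_prevalence(toy_surface(c(0.2, 0.4)),
                                          data.frame(age_group_lower = 30,
                                                     weight = 1)),
               "37.5")
})

test_that("cascade standardisation uses the prevalence-weighted denominator", {
  # two bands, equal weights, q=(0.1,0.3), r=(0.5,0.7):
  # (0.5*0.05 + 0.7*0.15) / 0.20 = 0.65
  q <- toy_surface(c(0.1, 0.3)); r <- toy_surface(c(0.5, 0.7))
  std2 <- data.frame(age_group_lower = c(30, 35), weight = c(1, 1))
  expect_equal(as.vector(age_standardise_cascade(r, q, std2)), 0.65)
  # constant rate r is returned regardless of prevalence pattern
  rc <- toy_surface(rep(0.42, 10))
  qv <- toy_surface(runif(10, 0.1, 0.6))
  expect_equal(as.vector(age_standardise_cascade(rc, qv)), 0.42)
  # age-constant prevalence reduces to plain standardisation
  set.seed(2)
  rr <- toy_surface(runif(10, 0.2, 0.8))
  qc <- toy_surface(rep(0.33, 10))
  expect_equal(age_standardise_cascade(rr, qc),
               age_standardise_prevalence(rr), tolerance = 1e-12)
})

test_that("aggregation weights age-specific draws by population", {
  units <- c("X", "Y")
  arr <- toy_surface(rep(0.2, 10), units = units, draws = 3)
  arr["Y", , , ] <- 0.4
  surf <- as_ps(arr)
  pop <- expand.grid(country = units, year = 2000,
                     sex = "female", age_group_lower = age_bands(),
                     stringsAsFactors = FALSE)
  pop$population <- 1000
  agg <- aggregate_units(surf, pop, list(reg = units))
  expect_equal(unique(as.vector(agg$arr)), 0.3)
  # single-member aggregation is the identity
  agg1 <- aggregate_units(surf, pop, list(only = "X"))
  expect_equal(agg1$arr["only", , , ], arr["X", , , ], ignore_attr = TRUE)
  # missing members and populations are errors
  expect_error(aggregate_units(surf, pop, list(bad = c("X", "Z"))), "Z")
  expect_error(aggregate_units(surf, pop[pop$country == "X", ],
                               list(reg = units)), "population")
})

test_that("counts scale with population and partition across stages", {
  arr <- toy_surface(0.25, draws = 2)   # one band
  pop <- data.frame(country = "u1", year = 2000, sex = "female",
                    age_group_lower = 30, population = 1000)
  surf <- as_ps(arr[, , 1, , drop = FALSE])
  cnt <- count_people(surf, pop)
  expect_equal(as.vector(cnt), c(250, 250))
  pop2 <- transform(pop, population = population * 2)
  expect_equal(as.vector(count_people(surf, pop2)), c(500, 500))

  # stage counts partition the hypertensive count exactly
  set.seed(3)
  d <- array(runif(20, 0.4, 0.8), dim = c(1, 2, 2, 5))
  m <- d * runif(20, 0.4, 0.9)
  cc <- m * runif(20, 0.3, 0.9)
  stages <- cascade_stream(d, m, cc)
  tot <- Reduce(`+`, stages)
  expect_equal(tot, array(1, dim = dim(d)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cascade stream reproduces the published global pattern and clips", {
  st <- cascade_stream(0.59, 0.47, 0.23)
  expect_equal(st$undiagnosed, 0.41)
  expect_equal(st$diagnosed_untreated, 0.12)
  expect_equal(st$treated_uncontrolled, 0.24)
  expect_equal(st$controlled, 0.23)
  expect_equal(attr(st, "clipped"), 0)
  # everyone undiagnosed
  st0 <- cascade_stream(0, 0, 0)
  expect_equal(st0$undiagnosed, 1)
  # crossings are clipped, reported and still partition
  stx <- cascade_stream(0.5, 0.6, 0.4)
  expect_gt(attr(stx, "clipped"), 0)
  expect_equal(Reduce(`+`, stx), 1)
  expect_equal(stx$diagnosed_untreated, 0)
})

test_that("change statistics summarise matched draw differences", {
  expect_error(change_stats(1:5 / 10, 1:4 / 10), "mismatch")
  up <- change_stats(rep(0.2, 100), rep(0.25, 100))
  expect_equal(up$pp_increase, 1)
  expect_equal(up$delta, 5)            # percentage points
  expect_equal(up$posterior_sd, 0)
  sym <- change_stats(rep(0.3, 4), c(0.28, 0.32, 0.29, 0.31))
  expect_equal(sym$pp_increase, 0.5)
  expect_equal(sym$pp_increase + sym$pp_decrease, 1)
  # ties split evenly
  tie <- change_stats(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(tie$pp_increase, 0.5)
  set.seed(4)
  a <- runif(200); b <- runif(200)
  cs <- change_stats(a, b)
  expect_equal(cs$pp_increase + cs$pp_decrease, 1)
  expect_equal(cs$pp_change, max(cs$pp_increase, cs$pp_decrease))
})

test_that("summary rows bracket the posterior mean with 95% intervals", {
  set.seed(5)
  x <- array(rbeta(2 * 3 * 400, 4, 6), dim = c(2, 3, 400),
             dimnames = list(c("a", "b"), 2000:2002, NULL))
  rows <- summarise_surface(x, outcome = "prevalence", sex = "female")
  expect_equal(nrow(rows), 6L)
  expect_true(all(rows$ci_low <= rows$estimate & rows$estimate <= rows$ci_high))
  r1 <- rows[rows$unit == "a" & rows$year == 2000, ]
  expect_equal(r1$estimate, mean(x["a", "2000", ]))
  expect_equal(r1$ci_low, unname(quantile(x["a", "2000", ], 0.025)))
})

test_that("world counts equal the sum of super-region counts per draw", {
  set.seed(6)
  h <- tiny_hierarchy()
  arr <- toy_surface(runif(10, 0.2, 0.5), units = h$country, draws = 7)
  arr[] <- runif(length(arr), 0.1, 0.6)
  surf <- as_ps(arr)
  pop <- expand.grid(country = h$country, year = 2000, sex = "female",
                     age_group_lower = age_bands(), stringsAsFactors = FALSE)
  pop$population <- sample(1e4:1e6, nrow(pop))
  sup <- aggregate_units(surf, pop, hierarchy_members(h, "super_region"))
  wld <- aggregate_units(surf, pop, hierarchy_members(h, "world"))
  cnt_sup <- count_people(sup, aggregate_populations(pop, h, "super_region"))
  cnt_wld <- count_people(wld, aggregate_populations(pop, h, "world"))
  expect_equal(as.vector(colSums(cnt_sup)), as.vector(cnt_wld["world", , ]),
               tolerance = 1e-9)
})
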