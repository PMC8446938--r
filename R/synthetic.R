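# Synthetic multi-country survey worlds with known ground truth. The
# generator composes outcome surfaces with the same basis code used for
# fitting (one source of truth), then simulates heterogeneous surveys with
# coverage/scope offsets, study effects, non-sampling noise and binomial
# sampling.

#' Configuration of a synthetic world
#'
#' Defaults describe the standard validation world: 24 countries in 6
#' regions and 3 super-regions over 1990-2019, with heterogeneous survey
#' availability (a fifth of countries without any study, 2-6 studies
#' elsewhere), 82% of studies carrying the diagnosis question, and
#' log-uniform cell sample sizes between 100 and 2000. True variance
#' components, coverage/scope offsets and outcome levels are fixed, stated
#' values (the model's generative scales), chosen to give realistic
#' hypertension surfaces: prevalence rising steeply with age around a
#' global level of roughly a third, detection around a half and improving
#' over time, treatment and control successively lower.
#'
#' A `full_scale_shape = TRUE` preset (200 countries / 21 regions / 9
#' super-regions) exists for profiling only.
#'
#' @param n_countries,n_regions,n_super_regions hierarchy sizes.
#' @param years estimation window.
#' @param full_scale_shape use the real-world hierarchy shape.
#' @param ... overrides for any default component.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_countries = 24L, n_regions = 6L,
                         n_super_regions = 3L, years = 1990:2019,
                         full_scale_shape = FALSE, ...) {
  if (full_scale_shape) {
    n_countries <- 200L; n_regions <- 21L; n_super_regions <- 9L
  }
  cfg <- list(
    n_countries = as.integer(n_countries),
    n_regions = as.integer(n_regions),
    n_super_regions = as.integer(n_super_regions),
    years = as.integer(years),
    rw_dim = 12L,
    # true variance components (SD scale)
    sd_a = c(super = 0.5, region = 0.3, country = 0.3),
    sd_b = c(super = 0.010, region = 0.008, country = 0.006),
    sd_rw = c(global = 0.010, super = 0.008, region = 0.006, country = 0.005),
    kappa = c(national = 0.05, subnational = 0.10, community = 0.15),
    tau = 0.05,
    # true systematic offsets (logit scale)
    offsets = c(beta_subnational = -0.10, beta_community = -0.30,
                beta_urban = 0.20, beta_rural = -0.20),
    # outcome levels: global logit intercepts and per-year slopes by sex
    intercept = list(prevalence = c(female = logit(0.30), male = logit(0.34)),
                     detection = c(female = logit(0.55), male = logit(0.45))),
    slope = list(prevalence = c(female = -0.004, male = -0.002),
                 detection = c(female = 0.012, male = 0.012)),
    theta = list(prevalence = -4e-4, detection = 6e-4),
    # target age curves on the logit scale (change from age 55, per year of age)
    age_slope = list(prevalence = 0.055, detection = 0.010),
    age_curv = list(prevalence = -6e-4, detection = -3e-4),
    # cascade links: treatment = detection * expit(g1), control =
    # treatment * expit(g2), severe_unmanaged = (1 - treatment) * expit(g3)
    g1 = c(level = 0.4, trend = 0.030, age = 0.015, country_sd = 0.15),
    g2 = c(level = 0.1, trend = 0.020, age = -0.005, country_sd = 0.15),
    g3 = c(level = -0.8, trend = -0.015, age = 0.010, country_sd = 0.15),
    # survey plan
    frac_zero_study = 0.2, studies_range = c(2L, 6L),
    p_has_diagnosis = 0.82,
    coverage_probs = c(national = 0.5, subnational = 0.3, community = 0.2),
    p_urban_only = 0.1, p_rural_only = 0.1,
    cell_n_range = c(100, 2000),
    # populations (aged 30-79): country base sizes and age structure
    pop_range = c(2e5, 5e7), pop_growth = 0.015, pop_age_decay = 0.025,
    surface_range = c(0.01, 0.99)
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  class(cfg) <- "world_config"
  cfg
}

synthetic_hierarchy <- function(cfg) {
  cty <- sprintf("C%02d", seq_len(cfg$n_countries))
  reg <- sprintf("R%02d", rep(seq_len(cfg$n_regions),
                              length.out = cfg$n_countries))
  sup_of_reg <- sprintf("S%d", rep(seq_len(cfg$n_super_regions),
                                   length.out = cfg$n_regions))
  as_hierarchy(data.frame(country = cty, region = sort(reg),
                          super_region = sup_of_reg[as.integer(sub("R", "", sort(reg)))]))
}

# model spec matching a world config (same bases, centering, window)
world_model_spec <- function(cfg, ...) {
  model_spec(years = cfg$years, rw_dim = cfg$rw_dim, ...)
}

# draw a true structural parameter vector from the generative priors with
# the config's scales
draw_true_params <- function(layout, cfg, outcome, sex, shrink = 1) {
  par <- layout$par
  x <- setNames(rep(0, nrow(par)), par$name)
  ages <- age_band_midpoints()
  AB <- layout$age_basis
  target <- cfg$age_slope[[outcome]] * (ages - 55) +
    cfg$age_curv[[outcome]] * (ages - 55)^2
  gamma <- qr.solve(cbind(1, AB), target)   # intercept absorbed below
  x["a_global"] <- cfg$intercept[[outcome]][[sex]] + gamma[1]
  x[paste0("age", seq_len(layout$n_age))] <- gamma[-1]
  x["b_global"] <- cfg$slope[[outcome]][[sex]]
  x["theta"] <- cfg$theta[[outcome]]
  x[FIXED_OFFSETS] <- cfg$offsets[FIXED_OFFSETS]
  for (lv in c("super", "region", "country")) {
    ia <- par$block == "dev_a" & par$level == lv
    ib <- par$block == "dev_b" & par$level == lv
    x[ia] <- stats::rnorm(sum(ia), 0, shrink * cfg$sd_a[[lv]])
    x[ib] <- stats::rnorm(sum(ib), 0, shrink * cfg$sd_b[[lv]])
  }
  lam <- layout$rw$lambda
  for (lv in c("global", "super", "region", "country")) {
    iw <- which(par$block == paste0("walk_", lv))
    nunit <- length(iw) / layout$kw
    x[iw] <- stats::rnorm(length(iw), 0,
                          shrink * cfg$sd_rw[[lv]] / sqrt(rep(lam, nunit)))
  }
  x
}

#' Generate a synthetic world with known truth
#'
#' Draws true model parameters from the generative priors at the config's
#' stated scales and composes outcome surfaces through the same spline/RW2
#' basis code used for fitting. Prevalence and detection are generated
#' directly from the model; cascade ordering is enforced by construction:
#' `treatment = detection * expit(g1)`, `control = treatment * expit(g2)`,
#' and `severe_unmanaged = (1 - treatment) * expit(g3)`, with `g1`, `g2`,
#' `g3` smooth in year and age. If a draw produces surfaces outside the
#' allowed range, the random-effect scales are shrunk by 20% and the world
#' redrawn (recorded in `$regenerated`).
#'
#' @param config a [world_config()].
#' @param seed integer seed; worlds are bit-reproducible given the seed.
#' @return object of class `true_world`: hierarchy, spec, per-outcome/sex
#'   true surfaces (`[country, year, age]` arrays), true parameters,
#'   population and standard-population tables.
#' @export
make_world <- function(config = world_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  h <- synthetic_hierarchy(cfg)
  hm <- hierarchy_maps(h)
  spec <- world_model_spec(cfg)
  layout <- param_layout(hm, spec)
  ages <- age_band_midpoints()
  M <- build_prediction_matrix(layout, spec, hm$countries, spec$years, ages)
  dimc <- c(length(hm$countries), length(spec$years), length(ages))
  dnames <- list(hm$countries, spec$years, ages)

  compose <- function(x) {
    arr <- array(as.vector(M %*% x), dim = dimc, dimnames = dnames)
    expit(arr)
  }
  rng <- cfg$surface_range
  regen <- 0L
  repeat {
    shrink <- 0.8^regen
    params <- list()
    surf_pd <- list()
    ok <- TRUE
    for (oc in c("prevalence", "detection")) {
      surf_pd[[oc]] <- list()
      for (sx in cascade_sexes()) {
        x <- draw_true_params(layout, cfg, oc, sx, shrink = shrink)
        params[[paste(oc, sx, sep = ".")]] <- x
        s <- compose(x)
        if (min(s) <= rng[1] || max(s) >= rng[2]) ok <- FALSE
        surf_pd[[oc]][[sx]] <- s
      }
    }
    if (ok || regen >= 10L) break
    regen <- regen + 1L
  }
  if (regen > 0L)
    message("make_world: surfaces out of range; redrew with shrunken scales (",
            regen, "x)")

  t_c <- spec$years - spec$center_year
  z_c <- ages - spec$center_age
  gsurf <- function(g) {
    cty_eff <- stats::rnorm(dimc[1], 0, g[["country_sd"]])
    base <- outer(t_c * g[["trend"]], z_c * g[["age"]], `+`) + g[["level"]]
    arr <- array(0, dim = dimc, dimnames = dnames)
    for (i in seq_len(dimc[1])) arr[i, , ] <- base + cty_eff[i]
    expit(arr)
  }
  surfaces <- list()
  clipped <- 0L
  for (sx in cascade_sexes()) {
    det <- surf_pd$detection[[sx]]
    trt <- det * gsurf(cfg$g1)
    ctl <- trt * gsurf(cfg$g2)
    sev <- (1 - trt) * gsurf(cfg$g3)
    clip <- function(a) {
      n <- sum(a <= rng[1] | a >= rng[2])
      clipped <<- clipped + n
      pmin(pmax(a, rng[1] + 1e-4), rng[2] - 1e-4)
    }
    surfaces[[sx]] <- list(prevalence = clip(surf_pd$prevalence[[sx]]),
                           detection = clip(det), treatment = clip(trt),
                           control = clip(ctl), severe_unmanaged = clip(sev))
  }

  pop <- synthetic_populations(cfg, hm$countries)
  structure(list(hierarchy = h, spec = spec, config = cfg, layout = layout,
                 surfaces = surfaces, true_params = params,
                 populations = pop, standard_population = who_standard_weights(),
                 seed = seed, regenerated = regen, clipped = clipped),
            class = "true_world")
}

#' @export
print.true_world <- function(x, ...) {
  cat("<true_world> ", length(unique(x$hierarchy$country)), " countries, ",
      min(x$spec$years), "-", max(x$spec$years), ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

synthetic_populations <- function(cfg, countries) {
  bands <- age_bands()
  base <- exp(stats::runif(length(countries), log(cfg$pop_range[1]),
                           log(cfg$pop_range[2])))
  age_share <- exp(-cfg$pop_age_decay * (bands - 30))
  age_share <- age_share / sum(age_share)
  grid <- expand.grid(country = countries, year = cfg$years,
                      sex = cascade_sexes(), age_group_lower = bands,
                      stringsAsFactors = FALSE)
  i_c <- match(grid$country, countries)
  growth <- (1 + cfg$pop_growth)^(grid$year - cfg$years[1])
  share <- age_share[match(grid$age_group_lower, bands)]
  sex_frac <- ifelse(grid$sex == "female", 0.51, 0.49)
  grid$population <- round(base[i_c] * growth * share * sex_frac)
  grid
}

#' True age-standardised outcome for a synthetic world
#'
#' Ground-truth counterpart of the estimation pipeline: WHO-standard
#' weighting of the true age-specific surfaces, with the prevalence-weighted
#' denominator for cascade outcomes.
#'
#' @param world a `true_world`.
#' @param outcome,sex which surface.
#' @return matrix `[country, year]` of true age-standardised values.
#' @export
true_age_standardised <- function(world, outcome = "prevalence",
                                  sex = "female") {
  s <- world$surfaces[[sex]][[outcome]]
  wv <- std_weights_for(world$standard_population, dimnames(s)[[3]])
  if (outcome == "prevalence") {
    apply(s, c(1, 2), function(p) sum(wv * p))
  } else {
    q <- world$surfaces[[sex]]$prevalence
    num <- apply(q * s, c(1, 2), function(p) sum(wv * p))
    den <- apply(q, c(1, 2), function(p) sum(wv * p))
    num / den
  }
}

#' Survey plan for a synthetic world
#'
#' Samples which countries have studies (a configured fraction has none),
#' how many, their midpoint years, coverage (national / sub-national /
#' community), scope (urban-only / rural-only studies among the non-national
#' ones), and whether the diagnosis question was asked. Each region is
#' guaranteed at least one national study.
#'
#' @param world a `true_world`.
#' @param seed integer seed.
#' @return data.frame with one row per study.
#' @export
make_survey_plan <- function(world, seed = 1L) {
  cfg <- world$config
  set.seed(seed)
  hm <- hierarchy_maps(world$hierarchy)
  n_cty <- length(hm$countries)
  zero <- stats::runif(n_cty) < cfg$frac_zero_study
  rows <- list()
  sid <- 0L
  for (i in seq_len(n_cty)) {
    if (zero[i]) next
    n_st <- sample(cfg$studies_range[1]:cfg$studies_range[2], 1)
    for (s in seq_len(n_st)) {
      sid <- sid + 1L
      coverage <- sample(coverage_levels(), 1, prob = cfg$coverage_probs)
      scope <- "both"
      if (coverage != "national") {
        u <- stats::runif(1)
        if (u < cfg$p_urban_only) scope <- "urban_only"
        else if (u < cfg$p_urban_only + cfg$p_rural_only) scope <- "rural_only"
      }
      rows[[sid]] <- data.frame(
        study_id = sprintf("%s_s%02d", hm$countries[i], s),
        country = hm$countries[i],
        year = sample(cfg$years, 1),
        coverage = coverage, scope = scope,
        has_diagnosis = stats::runif(1) < cfg$p_has_diagnosis,
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  # guarantee a national study in every region
  for (r in hm$regions) {
    in_reg <- plan$country %in% hm$countries[hm$reg_of_cty == match(r, hm$regions)]
    if (!any(in_reg & plan$coverage == "national")) {
      cand <- which(in_reg)
      if (!length(cand)) {
        ctys <- hm$countries[hm$reg_of_cty == match(r, hm$regions)]
        sid <- sid + 1L
        plan <- rbind(plan, data.frame(
          study_id = sprintf("%s_s%02d", ctys[1], 99L), country = ctys[1],
          year = sample(cfg$years, 1), coverage = "national", scope = "both",
          has_diagnosis = TRUE, stringsAsFactors = FALSE))
      } else {
        plan$coverage[cand[1]] <- "national"
        plan$scope[cand[1]] <- "both"
      }
    }
  }
  rownames(plan) <- NULL
  plan
}

# logit shift applied to a study's cells: coverage + scope offsets
plan_offset <- function(cfg, coverage, scope) {
  off <- 0
  if (coverage == "subnational") off <- off + cfg$offsets[["beta_subnational"]]
  if (coverage == "community") off <- off + cfg$offsets[["beta_community"]]
  if (scope == "urban_only") off <- off + cfg$offsets[["beta_urban"]]
  if (scope == "rural_only") off <- off + cfg$offsets[["beta_rural"]]
  off
}

#' Simulate crude survey cells from a world and plan
#'
#' For each study, sex and age band, draws a log-uniform sample size,
#' shifts the true outcome proportions on the logit scale by the study's
#' coverage/scope offsets, a study-level random effect with
#' coverage-specific SD, and cell-level non-sampling noise, then draws
#' binomial counts. Cascade outcomes are drawn from the realised
#' hypertensive subset; detection cells exist only for studies that asked
#' the diagnosis question.
#'
#' @param world a `true_world`.
#' @param plan a [make_survey_plan()] table.
#' @param seed integer seed.
#' @return crude-cell data.frame (the same dialect as
#'   [build_study_estimates()]); attribute `"truth"` carries the shifted
#'   probability each binomial count was drawn from.
#' @export
sample_surveys <- function(world, plan, seed = 1L) {
  cfg <- world$config
  set.seed(seed)
  bands <- age_bands()
  out <- vector("list", nrow(plan) * 20L)
  truth <- vector("list", nrow(plan) * 20L)
  k <- 0L
  for (i in seq_len(nrow(plan))) {
    st <- plan[i, ]
    off <- plan_offset(cfg, st$coverage, st$scope)
    yr <- as.character(st$year)
    for (sx in cascade_sexes()) {
      e_study <- stats::rnorm(length(cascade_outcomes()), 0,
                              cfg$kappa[[st$coverage]])
      names(e_study) <- cascade_outcomes()
      for (b in seq_along(bands)) {
        n <- round(exp(stats::runif(1, log(cfg$cell_n_range[1]),
                                    log(cfg$cell_n_range[2]))))
        p_prev <- world$surfaces[[sx]]$prevalence[st$country, yr, b]
        p1 <- expit(logit(p_prev) + off + e_study[["prevalence"]] +
                      stats::rnorm(1, 0, cfg$tau))
        x <- stats::rbinom(1, n, p1)
        k <- k + 1L
        out[[k]] <- cell_row(st, sx, bands[b], "prevalence", x, n)
        truth[[k]] <- p1
        if (x == 0) next
        for (oc in setdiff(cascade_outcomes(), "prevalence")) {
          if (oc == "detection" && !st$has_diagnosis) next
          p_true <- world$surfaces[[sx]][[oc]][st$country, yr, b]
          p2 <- expit(logit(p_true) + off + e_study[[oc]] +
                        stats::rnorm(1, 0, cfg$tau))
          x2 <- stats::rbinom(1, x, p2)
          k <- k + 1L
          out[[k]] <- cell_row(st, sx, bands[b], oc, x2, x)
          truth[[k]] <- p2
        }
      }
    }
  }
  cells <- do.call(rbind, out[seq_len(k)])
  rownames(cells) <- NULL
  attr(cells, "truth") <- unlist(truth[seq_len(k)])
  cells
}

cell_row <- function(st, sx, band, outcome, x, n) {
  p <- x / n
  data.frame(study_id = st$study_id, country = st$country, year = st$year,
             coverage = st$coverage, scope = st$scope, sex = sx,
             age_group_lower = band, outcome = outcome, p_hat = p,
             n_eff = n, se = sqrt(p * (1 - p) / n), n_raw = as.integer(n),
             flagged = FALSE, stringsAsFactors = FALSE)
}

# P(SBP < s_thr & DBP < d_thr) for bivariate normal BP with the generator's
# dispersion; used to solve the SBP mean that hits a target prevalence
bp_joint_below <- function(mu_s, s_thr, d_thr, sd_s, sd_d, rho) {
  mu_d <- 45 + 0.3 * mu_s
  f <- function(s) {
    cm <- mu_d + rho * (sd_d / sd_s) * (s - mu_s)
    stats::dnorm(s, mu_s, sd_s) *
      stats::pnorm((d_thr - cm) / (sd_d * sqrt(1 - rho^2)))
  }
  stats::integrate(f, mu_s - 8 * sd_s, s_thr)$value
}

#' Simulate individual-level blood-pressure microdata
#'
#' Generates survey participants whose classified outcomes reproduce a
#' world's cell probabilities mechanistically. Per sex and age band, the
#' mean SBP is solved so that the bivariate-normal blood pressure
#' distribution (SD 18/11 mm Hg, correlation 0.7, DBP mean linked to SBP)
#' yields the target hypertension prevalence at the 140/90 thresholds.
#' Medication is assigned among hypertensives at the target treatment rate
#' and shifts blood pressure by the treatment effect (default -12/-7 mm Hg),
#' so realised control rates emerge from the BP distribution rather than
#' being imposed. Diagnosis is a superset of treatment, topped up among
#' untreated hypertensives to hit the target detection rate; when the study
#' did not ask the question, `diagnosed` is `NA` throughout.
#'
#' @param world a `true_world`.
#' @param study one row of a [make_survey_plan()] table (or an equivalent
#'   list with `study_id`, `country`, `year`, `coverage`, `scope`,
#'   `has_diagnosis`).
#' @param seed integer seed.
#' @param n_per_cell participants per sex x age band (default 150).
#' @param treatment_effect named shift `c(sbp=, dbp=)` applied to treated
#'   individuals' blood pressure.
#' @param weight_sd SD of log-normal survey weights (0 = equal weights).
#' @return data.frame of individual records (`study_id`, `country`, `year`,
#'   `sex`, `age`, `sbp`, `dbp`, `on_medication`, `diagnosed`, `weight`,
#'   `stratum`, `psu`).
#' @export
make_microdata <- function(world, study, seed = 1L, n_per_cell = 150L,
                           treatment_effect = c(sbp = -12, dbp = -7),
                           weight_sd = 0.5) {
  st <- as.list(study)
  cfg <- world$config
  set.seed(seed)
  off <- plan_offset(cfg, st$coverage, st$scope)
  sd_s <- 18; sd_d <- 11; rho <- 0.7
  yr <- as.character(st$year)
  bands <- age_bands()
  rows <- list()
  for (sx in cascade_sexes()) {
    for (b in seq_along(bands)) {
      p_prev <- expit(logit(world$surfaces[[sx]]$prevalence[st$country, yr, b]) + off)
      p_det <- expit(logit(world$surfaces[[sx]]$detection[st$country, yr, b]) + off)
      p_trt <- expit(logit(world$surfaces[[sx]]$treatment[st$country, yr, b]) + off)
      mu_s <- stats::uniroot(function(m)
        (1 - bp_joint_below(m, 140, 90, sd_s, sd_d, rho)) - p_prev,
        c(80, 190), tol = 1e-6)$root
      mu_d <- 45 + 0.3 * mu_s
      n <- n_per_cell
      sbp <- stats::rnorm(n, mu_s, sd_s)
      dbp <- mu_d + rho * (sd_d / sd_s) * (sbp - mu_s) +
        stats::rnorm(n, 0, sd_d * sqrt(1 - rho^2))
      dbp <- pmin(dbp, sbp - 5)   # physiological: diastolic below systolic
      hyp_bp <- sbp >= 140 | dbp >= 90
      meds <- hyp_bp & stats::runif(n) < p_trt
      sbp[meds] <- sbp[meds] + treatment_effect[["sbp"]]
      dbp[meds] <- dbp[meds] + treatment_effect[["dbp"]]
      p_extra <- max(0, min(1, (p_det - p_trt) / (1 - p_trt)))
      diagnosed <- meds | (hyp_bp & !meds & stats::runif(n) < p_extra)
      if (!isTRUE(st$has_diagnosis)) diagnosed <- rep(NA, n)
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = st$study_id, country = st$country, year = st$year,
        sex = sx, age = bands[b] + sample(0:4, n, TRUE),
        sbp = round(sbp, 1), dbp = round(dbp, 1),
        on_medication = meds, diagnosed = diagnosed,
        weight = if (weight_sd > 0) stats::rlnorm(n, 0, weight_sd) else rep(1, n),
        stratum = bands[b], psu = sample(1:20, n, TRUE),
        stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  md
}
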