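# independently coded term-by-term evaluation of the model density on a
# small instance, used as the oracle for log_posterior()
oracle_log_posterior <- function(state, cells, hierarchy, spec) {
  hm <- htncascade:::hierarchy_maps(hierarchy)
  kw <- min(spec$rw_dim, length(spec$years) - 2L)
  rb <- rw2_basis(length(spec$years), kw)
  x <- state$params
  sds <- state$sds
  g <- function(nm) if (nm %in% names(x)) x[[nm]] else 0

  ll <- 0
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    t_c <- ci$year - spec$center_year
    z_mid <- ci$age_group_lower + 2.5
    z_c <- z_mid - spec$center_age
    ns_row <- splines::ns(z_mid, knots = spec$knots,
                          Boundary.knots = spec$boundary)
    reg <- hierarchy$region[hierarchy$country == ci$country]
    sup <- hierarchy$super_region[hierarchy$country == ci$country]
    eta <- g("a_global") + g("b_global") * t_c +
      sum(vapply(seq_along(ns_row), function(k)
        g(paste0("age", k)) * ns_row[k], numeric(1))) +
      g("theta") * z_c * t_c +
      (ci$coverage == "subnational") * g("beta_subnational") +
      (ci$coverage == "community") * g("beta_community") +
      (ci$scope == "urban_only") * g("beta_urban") +
      (ci$scope == "rural_only") * g("beta_rural") +
      g(paste0("a_super[", sup, "]")) + g(paste0("b_super[", sup, "]")) * t_c +
      g(paste0("a_region[", reg, "]")) + g(paste0("b_region[", reg, "]")) * t_c +
      g(paste0("a_country[", ci$country, "]")) +
      g(paste0("b_country[", ci$country, "]")) * t_c +
      g(paste0("e[", ci$study_id, "]"))
    ti <- match(ci$year, spec$years)
    for (lv_u in list(c("global", "world"), c("super", sup), c("region", reg),
                      c("country", ci$country))) {
      for (k in seq_len(kw))
        eta <- eta + rb$B[ti, k] * g(paste0("w_", lv_u[1], "[", lv_u[2], ",", k, "]"))
    }
    ll <- ll + dnorm(cells$y[i], eta, sqrt(cells$v[i] + sds[["tau"]]^2),
                     log = TRUE)
  }
  # location priors
  lp <- 0
  fixed <- c("a_global", "b_global", paste0("age", seq_along(
    splines::ns(50, knots = spec$knots, Boundary.knots = spec$boundary))),
    "theta", "beta_subnational", "beta_community", "beta_urban", "beta_rural")
  for (nm in fixed) lp <- lp + dnorm(g(nm), 0, spec$fixed_sd, log = TRUE)
  for (lv in c("super", "region", "country")) {
    units <- switch(lv, super = hm$supers, region = hm$regions,
                    country = hm$countries)
    for (u in units) {
      lp <- lp + dnorm(g(paste0("a_", lv, "[", u, "]")), 0,
                       sds[[paste0("sd_a_", lv)]], log = TRUE)
      lp <- lp + dnorm(g(paste0("b_", lv, "[", u, "]")), 0,
                       sds[[paste0("sd_b_", lv)]], log = TRUE)
    }
  }
  wunits <- list(global = "world", super = hm$supers, region = hm$regions,
                 country = hm$countries)
  for (lv in names(wunits)) for (u in wunits[[lv]]) for (k in seq_len(kw))
    lp <- lp + dnorm(g(paste0("w_", lv, "[", u, ",", k, "]")), 0,
                     sds[[paste0("sd_rw_", lv)]] / sqrt(rb$lambda[k]),
                     log = TRUE)
  study_cov <- unique(cells[, c("study_id", "coverage")])
  for (i in seq_len(nrow(study_cov)))
    lp <- lp + dnorm(g(paste0("e[", study_cov$study_id[i], "]")), 0,
                     sds[[paste0("kappa_", study_cov$coverage[i])]], log = TRUE)
  # hyperpriors
  hc <- function(v, s) log(2 / (pi * s)) - log1p((v / s)^2)
  scales <- c(sd_a_super = spec$sd_scale_intercept[["super"]],
              sd_a_region = spec$sd_scale_intercept[["region"]],
              sd_a_country = spec$sd_scale_intercept[["country"]],
              sd_b_super = spec$sd_scale_slope[["super"]],
              sd_b_region = spec$sd_scale_slope[["region"]],
              sd_b_country = spec$sd_scale_slope[["country"]],
              sd_rw_global = spec$sd_scale_rw[["global"]],
              sd_rw_super = spec$sd_scale_rw[["super"]],
              sd_rw_region = spec$sd_scale_rw[["region"]],
              sd_rw_country = spec$sd_scale_rw[["country"]],
              kappa_national = spec$kappa_scale[["national"]],
              kappa_subnational = spec$kappa_scale[["subnational"]],
              kappa_community = spec$kappa_scale[["community"]],
              tau = spec$tau_scale)
  for (nm in names(scales)) lp <- lp + hc(sds[[nm]], scales[[nm]])
  ll + lp
}

toy_instance <- function(seed = 42) {
  set.seed(seed)
  h <- tiny_hierarchy()[1:3, ]   # three countries, two regions, one super
  h <- as_hierarchy(h)
  spec <- tiny_spec()
  cells <- rbind(
    make_cells("s1", "AAA", c(2002, 2002, 2007), p = c(0.3, 0.45, 0.35),
               n = c(200, 150, 300), age = c(40, 60, 50)),
    make_cells("s2", "ABA", c(2005, 2005), p = c(0.25, 0.5), n = c(80, 120),
               age = c(45, 70), coverage = "community", scope = "urban_only"))
  tc <- logit_transform(cells, center_year = spec$center_year,
                        center_age = spec$center_age)
  # a dense random state touching every block
  lay <- htncascade:::param_layout(htncascade:::hierarchy_maps(h), spec,
                                   c("s1", "s2"))
  params <- setNames(rnorm(nrow(lay$par), 0, 0.3), lay$par$name)
  sds <- abs(default_sds() * exp(rnorm(14, 0, 0.2)))
  list(state = list(params = params, sds = sds), cells = tc, hierarchy = h,
       spec = spec)
}
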