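#' Hierarchical model specification
#'
#' Fixes the structure and priors of the Bayesian hierarchical model fitted
#' separately to each outcome x sex. On the logit scale the mean for study
#' cell i in country c is
#'
#' `eta_i = a_c + b_c * t + u_global(t) + u_super(t) + u_region(t) +
#'   u_country(t) + gamma(z) + theta * z * t + beta_off' X_i + e_i`
#'
#' where `t` is the centered year, `z` the centered age-band midpoint,
#' `gamma()` a natural cubic spline, `theta` a linear age-by-time interaction
#' (time trends vary by age), `X_i` indicators for sub-national, community,
#' urban-only and rural-only studies, and `e_i` a study random effect with
#' coverage-specific variance. Intercepts and slopes are nested
#' country-in-region-in-super-region-in-world Gaussians; each level also
#' carries second-order random-walk deviations over years. Observations are
#' `y_i ~ N(eta_i, v_i + tau^2)` with `v_i` the design-based sampling
#' variance and `tau^2` a shared non-sampling variance.
#'
#' Priors: N(0, `fixed_sd^2`) on fixed effects; half-Cauchy (given scales) on
#' all standard deviations, with coverage scales ordered national <=
#' subnational <= community.
#'
#' @param knots,boundary age-spline configuration, see [age_spline_basis()].
#' @param years estimation window (default 1990:2019).
#' @param rw_dim retained RW2 spectral modes per walk, see [rw2_basis()].
#' @param center_year,center_age covariate centering (defaults: window
#'   midpoint 2004.5 and mean band midpoint 55).
#' @param fixed_sd prior SD of fixed effects (default 10).
#' @param sd_scale_intercept,sd_scale_slope,sd_scale_rw half-Cauchy scales of
#'   the random intercept / slope / walk SDs, named by level.
#' @param kappa_scale half-Cauchy scales of the study-effect SDs by coverage.
#' @param tau_scale half-Cauchy scale of the shared non-sampling SD.
#' @param link observation link, `"logit"` (default) or `"probit"`.
#' @return object of class `cascade_model_spec`.
#' @export
model_spec <- function(knots = c(42.5, 55, 67.5), boundary = c(32.5, 77.5),
                       years = 1990:2019, rw_dim = 12L,
                       center_year = 2004.5, center_age = 55,
                       fixed_sd = 10,
                       sd_scale_intercept = c(super = 1, region = 1, country = 1),
                       sd_scale_slope = c(super = 0.05, region = 0.05, country = 0.05),
                       sd_scale_rw = c(global = 0.05, super = 0.05,
                                       region = 0.05, country = 0.05),
                       kappa_scale = c(national = 0.1, subnational = 0.15,
                                       community = 0.25),
                       tau_scale = 0.15,
                       link = c("logit", "probit")) {
  link <- match.arg(link)
  stopifnot(all(diff(knots) > 0), all(knots > boundary[1]),
            all(knots < boundary[2]),
            fixed_sd > 0, all(sd_scale_intercept > 0), all(sd_scale_slope > 0),
            all(sd_scale_rw > 0), all(kappa_scale > 0), tau_scale > 0,
            kappa_scale["national"] <= kappa_scale["subnational"],
            kappa_scale["subnational"] <= kappa_scale["community"])
  structure(list(
    knots = knots, boundary = boundary, years = as.integer(years),
    rw_dim = as.integer(rw_dim), center_year = center_year,
    center_age = center_age, fixed_sd = fixed_sd,
    sd_scale_intercept = sd_scale_intercept,
    sd_scale_slope = sd_scale_slope, sd_scale_rw = sd_scale_rw,
    kappa_scale = kappa_scale, tau_scale = tau_scale, link = link
  ), class = "cascade_model_spec")
}

link_fun <- function(spec) {
  if (spec$link == "logit") list(linkinv = expit, linkfun = logit)
  else list(linkinv = stats::pnorm, linkfun = stats::qnorm)
}

#' MCMC configuration
#'
#' Desk-scale defaults: 4 chains, 2000 burn-in iterations and 5000 post-burn
#' iterations thinned by 10, i.e. 500 retained draws per chain (2000 total).
#'
#' @param burn_in discarded iterations per chain.
#' @param samples post-burn-in iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of (sequential) chains.
#' @param seed integer RNG seed; runs are bit-reproducible given the seed.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 2000L, samples = 5000L, thin = 10L,
                        chains = 4L, seed = 1L) {
  stopifnot(burn_in >= 0, samples >= thin, thin >= 1, chains >= 1)
  structure(list(burn_in = as.integer(burn_in), samples = as.integer(samples),
                 thin = as.integer(thin), chains = as.integer(chains),
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Publication-scale MCMC preset
#'
#' 50 000 post-burn-in samples per chain kept every 10th (5000 retained per
#' chain).
#'
#' @param seed RNG seed.
#' @param chains number of chains.
#' @return an [mcmc_config()].
#' @export
mcmc_config_publication <- function(seed = 1L, chains = 4L) {
  mcmc_config(burn_in = 5000L, samples = 50000L, thin = 10L,
              chains = chains, seed = seed)
}
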