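#' Logit and inverse-logit
#'
#' Log-odds transform and its inverse, used as the observation-scale link for
#' all outcome proportions.
#'
#' @param p proportion in (0, 1)
#' @param x real number
#' @return `logit()` returns log(p / (1 - p)); `expit()` returns
#'   1 / (1 + exp(-x)).
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Five-year age bands of the 30-79 year analysis range
#'
#' The analysis is restricted to ages 30-79 years, split into ten half-open
#' five-year bands \[30,35), ..., \[75,80); a 79-year-old belongs to \[75,80).
#'
#' @return integer vector of band lower bounds: 30, 35, ..., 75.
#' @export
age_bands <- function() seq(30L, 75L, by = 5L)

#' Midpoints of the ten five-year age bands (32.5, ..., 77.5).
#' @rdname age_bands
#' @export
age_band_midpoints <- function() age_bands() + 2.5

#' Assign ages to five-year bands
#'
#' @param age numeric ages in years.
#' @return integer lower bound of the band, or `NA` outside 30-79.
#' @export
age_band_of <- function(age) {
  band <- 5L * (as.integer(age) %/% 5L)
  band[age < 30 | age >= 80] <- NA_integer_
  band
}

#' Names of the five estimated outcomes
#'
#' Prevalence of hypertension plus, among people with hypertension, detection
#' (reported previous diagnosis), treatment (taking medication), control
#' (on medication with blood pressure below 140/90 mm Hg), and the proportion
#' with severe uncontrolled hypertension (at least 160/100 mm Hg) that is
#' undiagnosed or untreated.
#'
#' @return character vector of outcome identifiers.
#' @export
cascade_outcomes <- function() {
  c("prevalence", "detection", "treatment", "control", "severe_unmanaged")
}

#' @rdname cascade_outcomes
#' @export
cascade_sexes <- function() c("female", "male")

coverage_levels <- function() c("national", "subnational", "community")
scope_levels <- function() c("both", "urban_only", "rural_only")

#' WHO standard population weights for ages 30-79
#'
#' The WHO world standard population shares for the ten five-year bands from
#' 30-34 to 75-79 (per cent of the all-ages standard). Weights are normalised
#' internally wherever they are used, so the absolute scale is irrelevant.
#'
#' @return data.frame with columns `age_group_lower` and `weight`.
#' @export
who_standard_weights <- function() {
  data.frame(
    age_group_lower = age_bands(),
    weight = c(7.61, 7.15, 6.59, 6.04, 5.37, 4.55, 3.72, 2.96, 2.21, 1.52)
  )
}

#' Posterior summary of a draw vector
#'
#' Mean with an equal-tailed 95% credible interval taken as the 2.5th to
#' 97.5th percentiles of the draws.
#'
#' @param draws numeric vector of posterior draws.
#' @return named numeric vector `estimate`, `ci_low`, `ci_high`.
#' @export
summarise_draws <- function(draws) {
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(estimate = mean(draws), ci_low = q[1], ci_high = q[2])
}

half_cauchy_logpdf <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2 / (pi * scale)) - log1p((x / scale)^2))
}

rhalf_cauchy <- function(n, scale) abs(stats::rcauchy(n, 0, scale))

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}
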