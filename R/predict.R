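#' Posterior outcome surfaces on a country-year-age grid
#'
#' Composes, for every retained draw, the model's linear predictor at each
#' (country, year, age-band) grid point with study-level terms at their
#' national reference (coverage/scope offsets and study effects zero), then
#' applies the inverse link. Countries never observed in the data still have
#' country-level parameters: the sampler draws them from their conditional
#' (region-level) prior, so their surfaces correctly carry the extra
#' uncertainty of having no data.
#'
#' @param fit a `cascade_fit` from [run_mcmc()].
#' @param countries countries to predict (default: all in the hierarchy);
#'   unknown countries are an error.
#' @param years years (default: the spec's full window).
#' @param ages age-band midpoints (default: all ten).
#' @return object of class `posterior_surface`: list with `arr`, a 4-d array
#'   `[country, year, age, draw]` of proportions in (0,1), plus the grid
#'   vectors and fit metadata.
#' @export
predict_surface <- function(fit, countries = NULL, years = NULL, ages = NULL) {
  stopifnot(inherits(fit, "cascade_fit"))
  hm <- fit$layout$hmaps
  if (is.null(countries)) countries <- hm$countries
  unknown <- setdiff(countries, hm$countries)
  if (length(unknown))
    stop("countries missing from hierarchy: ", paste(unknown, collapse = ", "))
  if (is.null(years)) years <- fit$spec$years
  if (is.null(ages)) ages <- age_band_midpoints()

  M <- build_prediction_matrix(fit$layout, fit$spec, countries, years, ages)
  eta <- as.matrix(M %*% t(fit$draws))
  p <- link_fun(fit$spec)$linkinv(eta)
  # keep the open interval (0,1) even for extreme prior-dominated draws
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  arr <- array(p, dim = c(length(countries), length(years), length(ages),
                          nrow(fit$draws)),
               dimnames = list(countries, years, ages, NULL))
  structure(list(arr = arr, countries = countries, years = as.integer(years),
                 ages = ages, outcome = fit$outcome, sex = fit$sex,
                 n_draws = nrow(fit$draws)),
            class = "posterior_surface")
}

#' @export
print.posterior_surface <- function(x, ...) {
  cat("<posterior_surface> ", x$outcome, "/", x$sex, ": ",
      length(x$countries), " countries x ", length(x$years), " years x ",
      length(x$ages), " age bands x ", x$n_draws, " draws\n", sep = "")
  invisible(x)
}
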