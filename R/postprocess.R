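# Post-processing: age-standardisation, aggregation, counts, cascade
# streams and change statistics, all draw-wise.

# accept either a posterior_surface or a bare [unit, year, age, draw] array
surface_array <- function(x) {
  if (inherits(x, "posterior_surface")) return(x$arr)
  stopifnot(is.array(x), length(dim(x)) == 4)
  x
}

# normalised standard-population weights for the given bands (by midpoint or
# lower bound); errors name any band missing from the table
std_weights_for <- function(std, age_dimnames) {
  if (is.data.frame(std)) {
    stopifnot(all(c("age_group_lower", "weight") %in% names(std)))
    w <- setNames(std$weight, std$age_group_lower)
  } else w <- std
  ages <- as.numeric(age_dimnames)
  # surface age dimension holds midpoints; the standard table holds band
  # lower bounds — match on either
  key <- as.numeric(names(w))
  pos <- match(ages, key)
  pos[is.na(pos)] <- match(ages - 2.5, key)[is.na(pos)]
  if (anyNA(pos))
    stop("standard population has no weight for age band(s): ",
         paste(ages[is.na(pos)], collapse = ", "))
  wv <- as.numeric(w[pos])
  stopifnot(all(wv > 0))
  wv / sum(wv)
}

#' Age-standardised prevalence draws
#'
#' Per draw, unit and year, the weighted mean of age-specific proportions
#' using (internally normalised) standard-population weights: a convex
#' combination, so the result always lies inside the age-specific range and
#' is invariant to rescaling the weights.
#'
#' @param surface a `posterior_surface` or `[unit, year, age, draw]` array.
#' @param std standard population: data.frame (`age_group_lower`, `weight`)
#'   or named numeric vector; see [who_standard_weights()].
#' @return array `[unit, year, draw]`.
#' @export
age_standardise_prevalence <- function(surface, std = who_standard_weights()) {
  arr <- surface_array(surface)
  wv <- std_weights_for(std, dimnames(arr)[[3]])
  out <- apply_age_weighted(arr, wv)
  out
}

# sum over the age dimension with weights, preserving [unit, year, draw]
apply_age_weighted <- function(arr, wv) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(3, 1, 2, 4)), nrow = d[3])
  res <- colSums(m * wv)
  array(res, dim = d[c(1, 2, 4)],
        dimnames = dimnames(arr)[c(1, 2, 4)])
}

#' Age-standardised cascade rate draws
#'
#' Detection, treatment and control are proportions of the hypertensive
#' population, whose age pattern appears in the denominator: the
#' age-standardised rate is `sum_h(W_h q_h r_h) / sum_h(W_h q_h)` per draw,
#' with `W` the normalised standard weights and `q` the age-specific
#' hypertension prevalence of the same unit, year and draw. When prevalence
#' is constant in age this reduces exactly to
#' [age_standardise_prevalence()] of the rates.
#'
#' @param rate_surface,prevalence_surface aligned surfaces (same units,
#'   years, ages, draws).
#' @param std standard population, as in [age_standardise_prevalence()].
#' @return array `[unit, year, draw]`.
#' @export
age_standardise_cascade <- function(rate_surface, prevalence_surface,
                                    std = who_standard_weights()) {
  r <- surface_array(rate_surface)
  q <- surface_array(prevalence_surface)
  stopifnot(identical(dim(r), dim(q)))
  wv <- std_weights_for(std, dimnames(r)[[3]])
  num <- apply_age_weighted(q * r, wv)
  den <- apply_age_weighted(q, wv)
  if (any(den <= 0))
    stop("all-zero prevalence denominator in age standardisation")
  num / den
}

# population count array N[unit, year, age] aligned to a surface
population_array <- function(populations, countries, years, age_mid,
                             sex = NULL) {
  pop <- as.data.frame(populations)
  stopifnot(all(c("country", "year", "age_group_lower", "population")
                %in% names(pop)))
  if (!is.null(sex) && "sex" %in% names(pop) && sex %in% pop$sex)
    pop <- pop[pop$sex == sex, , drop = FALSE]
  key <- paste(pop$country, pop$year, pop$age_group_lower)
  grid <- expand.grid(country = countries, year = years,
                      age = as.numeric(age_mid) - 2.5,
                      stringsAsFactors = FALSE)
  m <- match(paste(grid$country, grid$year, grid$age), key)
  if (anyNA(m)) {
    bad <- unique(grid$country[is.na(m)])
    stop("population rows missing for: ", paste(head(bad, 5), collapse = ", "))
  }
  N <- pop$population[m]
  if (any(is.na(N) | N < 0)) stop("negative or missing population counts")
  array(N, dim = c(length(countries), length(years), length(age_mid)),
        dimnames = list(countries, years, age_mid))
}

#' Population-weighted aggregation of country surfaces
#'
#' Aggregates age-specific posterior draws of member countries into a
#' region, super-region or world surface: per draw, year and age band,
#' `p_agg = sum_j(N_j * p_j) / sum_j(N_j)` over member countries `j`, with
#' `N` the country-year-age(-sex) population. Aggregation happens on
#' age-specific draws, before any age-standardisation.
#'
#' @param surface country-level `posterior_surface`.
#' @param populations data.frame `country`, `year`, `sex` (optional),
#'   `age_group_lower`, `population`.
#' @param members named list: aggregate unit name -> character vector of
#'   member countries. See [hierarchy_members()].
#' @return a `posterior_surface` whose unit dimension holds the aggregates.
#' @export
aggregate_units <- function(surface, populations, members) {
  stopifnot(inherits(surface, "posterior_surface"), is.list(members))
  arr <- surface$arr
  N <- population_array(populations, surface$countries, surface$years,
                        surface$ages, surface$sex)
  d <- dim(arr)
  out <- array(NA_real_, dim = c(length(members), d[2], d[3], d[4]),
               dimnames = c(list(names(members)), dimnames(arr)[2:4]))
  for (i in seq_along(members)) {
    mem <- members[[i]]
    missing_mem <- setdiff(mem, surface$countries)
    if (length(missing_mem))
      stop("aggregate '", names(members)[i], "' has members without surfaces: ",
           paste(missing_mem, collapse = ", "))
    idx <- match(mem, surface$countries)
    Nm <- N[idx, , , drop = FALSE]
    num <- colSums(arr[idx, , , , drop = FALSE] *
                     as.vector(Nm))          # recycles N over draws
    den <- colSums(Nm)
    out[i, , , ] <- num / as.vector(den)
  }
  structure(list(arr = out, countries = names(members),
                 years = surface$years, ages = surface$ages,
                 outcome = surface$outcome, sex = surface$sex,
                 n_draws = surface$n_draws),
            class = "posterior_surface")
}

#' Member lists for regions, super-regions and the world
#'
#' @param hierarchy an [as_hierarchy()] table.
#' @param level `"region"`, `"super_region"` or `"world"`.
#' @return named list of member-country vectors, suitable for
#'   [aggregate_units()].
#' @export
hierarchy_members <- function(hierarchy,
                              level = c("region", "super_region", "world")) {
  level <- match.arg(level)
  if (level == "world") return(list(world = unique(hierarchy$country)))
  split(hierarchy$country, hierarchy[[level]])
}

#' Aggregate population tables to regions, super-regions or the world
#'
#' Sums country populations over members of each aggregate unit, returning
#' a table in the same dialect (the `country` column holds the aggregate
#' names), so aggregated surfaces can be passed to [count_people()].
#'
#' @param populations population table as in [aggregate_units()].
#' @param hierarchy an [as_hierarchy()] table.
#' @param level `"region"`, `"super_region"` or `"world"`.
#' @return aggregated population data.frame.
#' @export
aggregate_populations <- function(populations, hierarchy,
                                  level = c("region", "super_region",
                                            "world")) {
  level <- match.arg(level)
  pop <- as.data.frame(populations)
  grp <- if (level == "world") "world"
  else hierarchy[[level]][match(pop$country, hierarchy$country)]
  has_sex <- "sex" %in% names(pop)
  by_cols <- c("unit", "year", if (has_sex) "sex", "age_group_lower")
  pop$unit <- grp
  agg <- stats::aggregate(pop["population"], pop[by_cols], sum)
  names(agg)[names(agg) == "unit"] <- "country"
  agg
}

#' People counts from prevalence draws
#'
#' Per draw, unit and year, `sum_h(N_h * p_h)`: the number of people in the
#' unit with the condition. For a cascade stage, pass the stage proportions
#' (of hypertensives) as `surface` and the hypertension prevalence draws as
#' `prevalence`; counts are then `sum_h(N_h * q_h * stage_h)`.
#'
#' @param surface `posterior_surface` or 4-d array of proportions.
#' @param populations population table as in [aggregate_units()].
#' @param prevalence optional aligned prevalence surface (for stage counts).
#' @param sex population sex to use when `surface` is a bare array.
#' @return array `[unit, year, draw]` of people counts.
#' @export
count_people <- function(surface, populations, prevalence = NULL, sex = NULL) {
  arr <- surface_array(surface)
  if (inherits(surface, "posterior_surface")) {
    countries <- surface$countries; years <- surface$years
    ages <- surface$ages; sex <- sex %||% surface$sex
  } else {
    countries <- dimnames(arr)[[1]]; years <- as.integer(dimnames(arr)[[2]])
    ages <- as.numeric(dimnames(arr)[[3]])
  }
  if (!is.null(prevalence)) {
    q <- surface_array(prevalence)
    stopifnot(identical(dim(q), dim(arr)))
    arr <- arr * q
  }
  N <- population_array(populations, countries, years, ages, sex)
  apply_age_weighted(arr * as.vector(N), rep(1, dim(arr)[3]))
}

#' Cascade stage proportions per draw
#'
#' Partitions people with hypertension into the four cascade stages:
#' undiagnosed, diagnosed-but-untreated, treated-but-uncontrolled, and
#' controlled. Because the three rates are fitted independently, draws can
#' cross (treatment above detection, or control above treatment); crossings
#' are resolved by enforcing the cascade ordering per draw
#' (`m <- min(m, d)`, `c <- min(c, m)`) so the four stages always form an
#' exact partition (sum to 1 per draw). The number of clipped values is
#' reported in the `"clipped"` attribute.
#'
#' @param detection,treatment,control aligned draw arrays (any shape) of
#'   rates among hypertensives.
#' @return list of four arrays (`undiagnosed`, `diagnosed_untreated`,
#'   `treated_uncontrolled`, `controlled`) with attribute `"clipped"`.
#' @export
cascade_stream <- function(detection, treatment, control) {
  d <- surface_array_or_vec(detection)
  m <- surface_array_or_vec(treatment)
  cc <- surface_array_or_vec(control)
  stopifnot(identical(dim2(d), dim2(m)), identical(dim2(d), dim2(cc)))
  clipped <- sum(m > d) + sum(cc > pmin(m, d))
  m2 <- pmin(m, d)
  c2 <- pmin(cc, m2)
  out <- list(undiagnosed = 1 - d,
              diagnosed_untreated = d - m2,
              treated_uncontrolled = m2 - c2,
              controlled = c2)
  attr(out, "clipped") <- clipped
  out
}

surface_array_or_vec <- function(x)
  if (inherits(x, "posterior_surface")) x$arr else x
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Change between two years with posterior probability of direction
#'
#' Matched per-draw differences between an end and a start year. `delta` is
#' the posterior mean difference in percentage points, `posterior_sd` the SD
#' of the per-draw differences, and `pp_increase` the fraction of positive
#' differences (draws exactly zero split evenly between the directions), so
#' `pp_increase + pp_decrease = 1`. `pp_change` is
#' `max(pp_increase, pp_decrease)`: the posterior probability that the
#' estimated direction of change is the true direction.
#'
#' @param draws_start,draws_end matched draw vectors (proportions).
#' @param scale multiplier applied to differences (default 100: percentage
#'   points).
#' @return one-row data.frame `delta`, `posterior_sd`, `pp_increase`,
#'   `pp_decrease`, `pp_change`.
#' @export
change_stats <- function(draws_start, draws_end, scale = 100) {
  if (length(draws_start) != length(draws_end))
    stop("mismatched draw counts: ", length(draws_start), " vs ",
         length(draws_end))
  diff <- (as.vector(draws_end) - as.vector(draws_start)) * scale
  ppi <- (sum(diff > 0) + 0.5 * sum(diff == 0)) / length(diff)
  data.frame(delta = mean(diff), posterior_sd = stats::sd(diff),
             pp_increase = ppi, pp_decrease = 1 - ppi,
             pp_change = max(ppi, 1 - ppi))
}

#' Tidy summary rows from standardised draws
#'
#' @param std_draws array `[unit, year, draw]` (e.g. from
#'   [age_standardise_prevalence()]).
#' @param outcome,sex metadata columns to attach.
#' @return data.frame `unit`, `sex`, `outcome`, `year`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
summarise_surface <- function(std_draws, outcome = NA, sex = NA) {
  dn <- dimnames(std_draws)
  rows <- expand.grid(unit = dn[[1]], year = as.integer(dn[[2]]),
                      stringsAsFactors = FALSE)
  stats_m <- t(apply(matrix(std_draws, nrow = prod(dim(std_draws)[1:2])),
                     1, summarise_draws))
  data.frame(unit = rows$unit, sex = sex, outcome = outcome, year = rows$year,
             estimate = stats_m[, 1], ci_low = stats_m[, 2],
             ci_high = stats_m[, 3], stringsAsFactors = FALSE)
}
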