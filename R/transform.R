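#' Transform crude cells to the model's observation scale
#'
#' Converts crude proportions to logits with delta-method sampling variances.
#' Exact 0 or 1 proportions receive the continuity correction
#' `p* = (x + 0.5) / (n_eff + 1)` with `x = p_hat * n_eff`, and the standard
#' error is recomputed from `p*`, guaranteeing finite `y` and positive `v`.
#' Variances are floored at `var_floor`.
#'
#' The centered covariates carried along are `t_c = year - center_year` and
#' `z_c = midpoint - center_age`, where the age-band midpoint is its lower
#' bound + 2.5.
#'
#' @param cells crude-cell data.frame (see [build_study_estimates()]).
#' @param var_floor minimum observation-scale variance (default 1e-6).
#' @param center_year year subtracted from `year` (default 2004.5, the
#'   midpoint of the 1990-2019 window).
#' @param center_age age subtracted from band midpoints (default 55, the mean
#'   of the ten midpoints 32.5...77.5).
#' @return the input with columns `y`, `v`, `t_c`, `z_c` appended.
#' @export
logit_transform <- function(cells, var_floor = 1e-6,
                            center_year = 2004.5, center_age = 55) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("p_hat", "n_eff", "se", "n_raw", "year", "age_group_lower")
                %in% names(cells)))
  if (any(cells$n_raw < 1) || any(cells$n_eff <= 0))
    stop("cells with n_raw < 1 or n_eff <= 0 cannot be transformed")
  p <- cells$p_hat
  n <- cells$n_eff
  boundary <- p <= 0 | p >= 1
  p_star <- ifelse(boundary, (p * n + 0.5) / (n + 1), p)
  se <- ifelse(boundary, sqrt(p_star * (1 - p_star) / n), cells$se)
  cells$y <- logit(p_star)
  cells$v <- pmax((se / (p_star * (1 - p_star)))^2, var_floor)
  cells$t_c <- cells$year - center_year
  cells$z_c <- cells$age_group_lower + 2.5 - center_age
  cells
}

#' Validate model inputs
#'
#' Checks crude cells against the hierarchy (and optionally population
#' tables) and classifies problems as fatal or warning. Fatal issues: unknown
#' countries, duplicated study x sex x age x outcome cells, years outside the
#' estimation window. Warnings: cascade cells without a matching prevalence
#' cell, control exceeding treatment in the same cell, missing populations.
#'
#' @param cells crude-cell data.frame.
#' @param hierarchy a [as_hierarchy()] table.
#' @param populations optional population data.frame (`country`, `year`,
#'   `sex`, `age_group_lower`, `population`).
#' @param years estimation window as `c(first, last)` (default 1990-2019).
#' @return a `validation_report`: data.frame of `severity`, `issue`, `detail`
#'   rows (zero rows = clean) with a print method.
#' @export
validate_inputs <- function(cells, hierarchy, populations = NULL,
                            years = c(1990, 2019)) {
  issues <- list()
  add <- function(severity, issue, detail)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, issue = issue, detail = detail,
      stringsAsFactors = FALSE)

  unknown <- setdiff(unique(cells$country), hierarchy$country)
  for (u in unknown) add("fatal", "unknown_country", u)

  bad_years <- unique(cells$year[cells$year < years[1] | cells$year > years[2]])
  for (y in bad_years)
    add("fatal", "year_outside_window", as.character(y))

  key <- paste(cells$study_id, cells$sex, cells$age_group_lower, cells$outcome)
  dups <- unique(key[duplicated(key)])
  for (d in dups) add("fatal", "duplicated_cell", d)

  prev_key <- with(cells[cells$outcome == "prevalence", , drop = FALSE],
                   paste(study_id, sex, age_group_lower))
  casc <- cells[cells$outcome != "prevalence", , drop = FALSE]
  orphan <- unique(with(casc, paste(study_id, sex, age_group_lower))[
    !with(casc, paste(study_id, sex, age_group_lower)) %in% prev_key])
  for (o in orphan) add("warning", "cascade_cell_without_prevalence", o)

  trt <- cells[cells$outcome == "treatment", , drop = FALSE]
  ctl <- cells[cells$outcome == "control", , drop = FALSE]
  if (nrow(trt) && nrow(ctl)) {
    k_t <- paste(trt$study_id, trt$sex, trt$age_group_lower)
    k_c <- paste(ctl$study_id, ctl$sex, ctl$age_group_lower)
    m <- match(k_c, k_t)
    bad <- which(!is.na(m) & ctl$p_hat > trt$p_hat[m])
    for (b in bad)
      add("warning", "control_exceeds_treatment", k_c[b])
  }

  if (!is.null(populations)) {
    missing_pop <- setdiff(hierarchy$country, unique(populations$country))
    for (m in missing_pop) add("warning", "country_without_population", m)
  }

  rep <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), issue = character(),
               detail = character(), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  nf <- sum(x$severity == "fatal")
  nw <- sum(x$severity == "warning")
  cat("<validation_report> ", nf, " fatal, ", nw, " warning issue(s)\n", sep = "")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' @rdname validate_inputs
#' @param report a `validation_report`.
#' @return `has_fatal()` returns TRUE if any fatal issue is present.
#' @export
has_fatal <- function(report) any(report$severity == "fatal")
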