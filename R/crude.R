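#' Survey-weighted proportion with Kish effective sample size
#'
#' Design-based estimate of a proportion from 0/1 values with survey weights:
#' `p_hat = sum(w * y) / sum(w)`, effective sample size by the Kish
#' approximation `n_eff = sum(w)^2 / sum(w^2)`, and
#' `se = sqrt(p_hat * (1 - p_hat) / n_eff)`. With equal weights this reduces
#' exactly to the unweighted proportion and raw sample size.
#'
#' @param values numeric or logical vector of 0/1 outcomes.
#' @param weights positive survey weights (default equal).
#' @param min_n cells with fewer than `min_n` raw observations are flagged
#'   (`flagged = TRUE`), not dropped. Default 1; 25 is recommended before
#'   model fitting.
#' @return a one-row data.frame `p_hat`, `n_eff`, `se`, `n_raw`, `flagged`,
#'   or `NULL` for an empty cell (an empty cell is never a zero-filled
#'   estimate).
#' @export
weighted_cell_estimate <- function(values, weights = NULL, min_n = 1L) {
  values <- as.numeric(values)
  keep <- !is.na(values)
  values <- values[keep]
  if (!length(values)) return(NULL)
  if (is.null(weights)) weights <- rep(1, length(values))
  else weights <- as.numeric(weights)[keep]
  stopifnot(length(weights) == length(values), all(weights > 0))
  sw <- sum(weights)
  p_hat <- sum(weights * values) / sw
  n_eff <- sw^2 / sum(weights^2)
  se <- sqrt(max(p_hat * (1 - p_hat), 0) / n_eff)
  data.frame(p_hat = p_hat, n_eff = n_eff, se = se,
             n_raw = length(values), flagged = length(values) < min_n)
}

#' Crude age-sex-specific estimates for one study
#'
#' Applies the outcome definitions to a study's microdata and produces one
#' design-based crude cell per non-empty sex x five-year age band x outcome.
#' Individuals outside ages 30-79 are excluded. Prevalence cells use all
#' eligible participants; detection, treatment, control and severe-unmanaged
#' cells are restricted to the hypertensive subset. Studies in which the
#' diagnosis question was never asked emit no detection cells.
#'
#' @param microdata data.frame with columns `age`, `sex`, `sbp`, `dbp`,
#'   `on_medication`, optionally `diagnosed`, `weight`, `stratum`, `psu`.
#' @param meta list or one-row data.frame with `study_id`, `country`, `year`
#'   (midpoint year of fieldwork), `coverage` (`national`, `subnational` or
#'   `community`) and `scope` (`both`, `urban_only`, `rural_only`).
#' @param thresholds a [bp_thresholds()] object.
#' @param min_cell_n flag threshold passed to [weighted_cell_estimate()].
#' @param severe_variant passed to [classify_records()].
#' @return data.frame of crude cells with columns `study_id`, `country`,
#'   `year`, `coverage`, `scope`, `sex`, `age_group_lower`, `outcome`,
#'   `p_hat`, `n_eff`, `se`, `n_raw`, `flagged`; attribute `"rejected"`
#'   carries dropped records with reasons.
#' @export
build_study_estimates <- function(microdata, meta, thresholds = bp_thresholds(),
                                  min_cell_n = 1L,
                                  severe_variant = "undiagnosed_or_untreated") {
  meta <- as.list(meta)
  stopifnot(!is.null(meta$study_id), !is.null(meta$country), !is.null(meta$year))
  coverage <- match.arg(as.character(meta$coverage %||% "national"),
                        coverage_levels())
  scope <- match.arg(as.character(meta$scope %||% "both"), scope_levels())
  md <- average_bp_readings(as.data.frame(microdata))
  stopifnot(all(c("age", "sex") %in% names(md)))
  if (!"weight" %in% names(md)) md$weight <- 1
  stopifnot(all(is.na(md$weight) | md$weight > 0))

  md$age_group_lower <- age_band_of(md$age)
  md <- md[!is.na(md$age_group_lower) & md$sex %in% cascade_sexes() &
             !is.na(md$weight), , drop = FALSE]
  cl <- classify_records(md, thresholds, severe_variant)
  rejected <- attr(cl, "rejected")

  flag_col <- c(prevalence = "hypertensive", detection = "detected",
                treatment = "treated", control = "controlled",
                severe_unmanaged = "severe_unmanaged")
  out <- list()
  for (sx in unique(cl$sex)) {
    for (band in sort(unique(cl$age_group_lower[cl$sex == sx]))) {
      cell <- cl[cl$sex == sx & cl$age_group_lower == band, , drop = FALSE]
      hyp <- cell[cell$hypertensive, , drop = FALSE]
      for (oc in cascade_outcomes()) {
        sub <- if (oc == "prevalence") cell else hyp
        est <- weighted_cell_estimate(sub[[flag_col[[oc]]]], sub$weight,
                                      min_n = min_cell_n)
        if (is.null(est)) next
        out[[length(out) + 1L]] <- cbind(
          data.frame(study_id = meta$study_id, country = meta$country,
                     year = as.integer(meta$year), coverage = coverage,
                     scope = scope, sex = sx, age_group_lower = band,
                     outcome = oc, stringsAsFactors = FALSE),
          est)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_crude_cells()
  rownames(res) <- NULL
  attr(res, "rejected") <- rejected
  res
}

empty_crude_cells <- function() {
  data.frame(study_id = character(), country = character(), year = integer(),
             coverage = character(), scope = character(), sex = character(),
             age_group_lower = integer(), outcome = character(),
             p_hat = numeric(), n_eff = numeric(), se = numeric(),
             n_raw = integer(), flagged = logical(), stringsAsFactors = FALSE)
}

#' Crude estimates for many studies
#'
#' Convenience wrapper applying [build_study_estimates()] study by study.
#'
#' @param microdata data.frame of pooled microdata including a `study_id`
#'   column.
#' @param meta data.frame with one row per study (`study_id`, `country`,
#'   `year`, `coverage`, `scope`).
#' @param ... passed to [build_study_estimates()].
#' @return combined crude-cell data.frame.
#' @export
build_all_study_estimates <- function(microdata, meta, ...) {
  meta <- as.data.frame(meta)
  parts <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, , drop = FALSE]
    build_study_estimates(microdata[microdata$study_id == m$study_id, , drop = FALSE],
                          m, ...)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
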