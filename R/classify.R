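#' Blood-pressure thresholds for outcome definitions
#'
#' Hypertension is defined as systolic blood pressure (SBP) at or above
#' `sbp`, diastolic blood pressure (DBP) at or above `dbp`, or current use of
#' medication for hypertension. The severe-unmanaged outcome uses the higher
#' pair `severe_sbp`/`severe_dbp`.
#'
#' @param sbp,dbp hypertension thresholds in mm Hg (default 140/90).
#' @param severe_sbp,severe_dbp severe-hypertension thresholds in mm Hg
#'   (default 160/100).
#' @return object of class `bp_thresholds`.
#' @export
bp_thresholds <- function(sbp = 140, dbp = 90, severe_sbp = 160, severe_dbp = 100) {
  stopifnot(sbp > 0, dbp > 0, severe_sbp >= sbp, severe_dbp >= dbp)
  structure(list(sbp = sbp, dbp = dbp,
                 severe_sbp = severe_sbp, severe_dbp = severe_dbp),
            class = "bp_thresholds")
}

#' Classify survey participants into cascade outcome flags
#'
#' Applies the outcome definitions to individual records:
#' * `hypertensive`: SBP >= 140, DBP >= 90, or on medication for hypertension;
#' * `detected`: hypertensive and reporting a previous diagnosis (`NA` when
#'   the diagnosis question was not asked);
#' * `treated`: hypertensive and on medication;
#' * `controlled`: on medication with SBP < 140 and DBP < 90;
#' * `severe_unmanaged`: hypertensive, undiagnosed or untreated (by default;
#'   see `severe_variant`), with SBP >= 160 or DBP >= 100.
#'
#' Cascade flags (`detected`, `treated`, `controlled`, `severe_unmanaged`) are
#' `NA` for non-hypertensive individuals: they are defined only on the
#' hypertensive subset.
#'
#' Records with non-positive blood pressure, DBP >= SBP, or missing
#' SBP/DBP/medication status are rejected (dropped, with the reasons returned
#' in the `"rejected"` attribute), never imputed.
#'
#' @param records data.frame with columns `sbp`, `dbp`, `on_medication` and
#'   optionally `diagnosed` (logical, `NA` = question not asked). Extra
#'   columns are carried through.
#' @param thresholds a [bp_thresholds()] object.
#' @param severe_variant `"undiagnosed_or_untreated"` (default) counts people
#'   who are either undiagnosed or untreated; `"untreated_only"` requires only
#'   that they are untreated.
#' @return the accepted rows of `records` with logical columns `hypertensive`,
#'   `detected`, `treated`, `controlled`, `severe_unmanaged` appended, and an
#'   attribute `"rejected"` (data.frame of dropped rows with a `reason`
#'   column).
#' @export
classify_records <- function(records, thresholds = bp_thresholds(),
                             severe_variant = c("undiagnosed_or_untreated",
                                                "untreated_only")) {
  severe_variant <- match.arg(severe_variant)
  stopifnot(is.data.frame(records),
            all(c("sbp", "dbp", "on_medication") %in% names(records)))
  df <- as.data.frame(records)
  if (!"diagnosed" %in% names(df)) df$diagnosed <- NA

  reason <- rep(NA_character_, nrow(df))
  bad <- is.na(df$sbp) | is.na(df$dbp)
  reason[bad] <- "missing blood pressure"
  bad2 <- !bad & (df$sbp <= 0 | df$dbp <= 0)
  reason[bad2] <- "non-positive blood pressure"
  bad3 <- !bad & !bad2 & df$dbp >= df$sbp
  reason[bad3] <- "diastolic >= systolic"
  bad4 <- is.na(reason) & is.na(df$on_medication)
  reason[bad4] <- "missing medication status"

  rejected <- df[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  keep <- df[is.na(reason), , drop = FALSE]

  th <- thresholds
  high_bp <- keep$sbp >= th$sbp | keep$dbp >= th$dbp
  keep$hypertensive <- high_bp | keep$on_medication
  keep$treated <- ifelse(keep$hypertensive, keep$on_medication, NA)
  keep$controlled <- ifelse(keep$hypertensive,
                            keep$on_medication & keep$sbp < th$sbp & keep$dbp < th$dbp,
                            NA)
  keep$detected <- ifelse(keep$hypertensive,
                          ifelse(is.na(keep$diagnosed), NA, keep$diagnosed),
                          NA)
  severe_bp <- keep$sbp >= th$severe_sbp | keep$dbp >= th$severe_dbp
  unmanaged <- if (severe_variant == "undiagnosed_or_untreated") {
    # undiagnosed or untreated; a missing diagnosis answer falls back to the
    # treatment flag alone so the outcome stays defined for such studies
    ifelse(is.na(keep$diagnosed), !keep$on_medication,
           !keep$diagnosed | !keep$on_medication)
  } else {
    !keep$on_medication
  }
  keep$severe_unmanaged <- ifelse(keep$hypertensive, unmanaged & severe_bp, NA)

  keep$treated <- as.logical(keep$treated)
  keep$controlled <- as.logical(keep$controlled)
  keep$detected <- as.logical(keep$detected)
  keep$severe_unmanaged <- as.logical(keep$severe_unmanaged)
  attr(keep, "rejected") <- rejected
  keep
}

# average repeated BP readings: with >= 3 readings the first is dropped
# (protocols that take multiple measurements typically discard the first);
# with 1-2 readings all are averaged.
average_bp_readings <- function(df) {
  sbp_cols <- grep("^sbp[0-9]*$", names(df), value = TRUE)
  dbp_cols <- grep("^dbp[0-9]*$", names(df), value = TRUE)
  if (length(sbp_cols) <= 1 && length(dbp_cols) <= 1) return(df)
  pick <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    apply(m, 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) return(NA_real_)
      if (length(r) >= 3) r <- r[-1]
      mean(r)
    })
  }
  df$sbp <- pick(sbp_cols)
  df$dbp <- pick(dbp_cols)
  df[, setdiff(names(df), c(setdiff(sbp_cols, "sbp"), setdiff(dbp_cols, "dbp"))),
     drop = FALSE]
}
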