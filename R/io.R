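# CSV dialects for every pipeline artifact. All readers enforce required
# headers, warn on unknown columns, reject decimal commas, and report
# malformed rows with line numbers. All writers produce locale-independent
# plain CSV; write-then-read round-trips are exact on valid files.

read_checked_csv <- function(path, required, numeric_cols = character(),
                             integer_cols = character(),
                             logical_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(path), ": missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(basename(path), ": ignoring unknown column(s): ",
            paste(extra, collapse = ", "))
  for (cl in intersect(c(numeric_cols, integer_cols), names(df))) {
    v <- df[[cl]]
    commas <- grepl("^\\s*-?[0-9]+,[0-9]+\\s*$", v)
    if (any(commas, na.rm = TRUE))
      stop(basename(path), ": column '", cl, "' uses decimal commas (rows ",
           paste(head(which(commas) + 1L, 5), collapse = ", "),
           "); numbers must use '.' as the decimal separator")
    conv <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(conv)
    if (any(bad))
      stop(basename(path), ": malformed numeric value(s) in column '", cl,
           "' at row(s) ", paste(head(which(bad) + 1L, 5), collapse = ", "))
    df[[cl]] <- if (cl %in% integer_cols) as.integer(round(conv)) else conv
  }
  for (cl in intersect(logical_cols, names(df))) {
    v <- toupper(trimws(df[[cl]]))
    conv <- ifelse(is.na(v), NA, v %in% c("TRUE", "T", "1"))
    bad <- !is.na(v) & !v %in% c("TRUE", "T", "1", "FALSE", "F", "0")
    if (any(bad))
      stop(basename(path), ": malformed logical value(s) in column '", cl,
           "' at row(s) ", paste(head(which(bad) + 1L, 5), collapse = ", "))
    df[[cl]] <- conv
  }
  df[required]
}

write_plain_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write crude-estimate CSV files
#'
#' Columns: `study_id`, `country`, `year`, `coverage`, `scope`, `sex`,
#' `age_group_lower`, `outcome`, `p_hat`, `n_eff`, `se`, `n_raw`.
#'
#' @param path CSV file path.
#' @param cells crude-cell data.frame.
#' @return `read_crude_cells()` returns the validated data.frame;
#'   `write_crude_cells()` returns `path` invisibly.
#' @export
read_crude_cells <- function(path) {
  read_checked_csv(path,
    required = c("study_id", "country", "year", "coverage", "scope", "sex",
                 "age_group_lower", "outcome", "p_hat", "n_eff", "se", "n_raw"),
    numeric_cols = c("p_hat", "n_eff", "se"),
    integer_cols = c("year", "age_group_lower", "n_raw"))
}

#' @rdname read_crude_cells
#' @export
write_crude_cells <- function(cells, path) {
  cols <- c("study_id", "country", "year", "coverage", "scope", "sex",
            "age_group_lower", "outcome", "p_hat", "n_eff", "se", "n_raw")
  write_plain_csv(as.data.frame(cells)[cols], path)
}

#' Read and write survey microdata CSV files
#'
#' Columns: `study_id`, `country`, `year`, `sex`, `age`, `sbp`, `dbp`,
#' `on_medication`, `diagnosed`, `weight`, `stratum`, `psu`; empty fields
#' are missing values.
#'
#' @param path CSV file path.
#' @param microdata data.frame of individual records.
#' @return the data.frame (read) or `path` invisibly (write).
#' @export
read_microdata <- function(path) {
  read_checked_csv(path,
    required = c("study_id", "country", "year", "sex", "age", "sbp", "dbp",
                 "on_medication", "diagnosed", "weight", "stratum", "psu"),
    numeric_cols = c("sbp", "dbp", "weight"),
    integer_cols = c("year", "age"),
    logical_cols = c("on_medication", "diagnosed"))
}

#' @rdname read_microdata
#' @export
write_microdata <- function(microdata, path) {
  cols <- c("study_id", "country", "year", "sex", "age", "sbp", "dbp",
            "on_medication", "diagnosed", "weight", "stratum", "psu")
  write_plain_csv(as.data.frame(microdata)[cols], path)
}

#' Read and write the country hierarchy CSV (`country`, `region`,
#' `super_region`)
#' @param path CSV file path.
#' @param hierarchy an [as_hierarchy()] table.
#' @return a validated `cascade_hierarchy` (read) or `path` (write).
#' @export
read_hierarchy <- function(path) {
  as_hierarchy(read_checked_csv(path, c("country", "region", "super_region")))
}

#' @rdname read_hierarchy
#' @export
write_hierarchy <- function(hierarchy, path) {
  write_plain_csv(as.data.frame(hierarchy), path)
}

#' Read and write population CSVs (`country`, `year`, `sex`,
#' `age_group_lower`, `population`)
#' @param path CSV file path.
#' @param populations population data.frame.
#' @return data.frame (read) or `path` (write).
#' @export
read_populations <- function(path) {
  read_checked_csv(path,
    required = c("country", "year", "sex", "age_group_lower", "population"),
    numeric_cols = "population",
    integer_cols = c("year", "age_group_lower"))
}

#' @rdname read_populations
#' @export
write_populations <- function(populations, path) {
  cols <- c("country", "year", "sex", "age_group_lower", "population")
  write_plain_csv(as.data.frame(populations)[cols], path)
}

#' Read and write standard-population CSVs (`age_group_lower`, `weight`;
#' weights need not be pre-normalised)
#' @param path CSV file path.
#' @param std standard-population data.frame.
#' @return data.frame (read) or `path` (write).
#' @export
read_standard_population <- function(path) {
  read_checked_csv(path, c("age_group_lower", "weight"),
                   numeric_cols = "weight", integer_cols = "age_group_lower")
}

#' @rdname read_standard_population
#' @export
write_standard_population <- function(std, path) {
  write_plain_csv(as.data.frame(std)[c("age_group_lower", "weight")], path)
}

#' Write and read posterior draws in long CSV layout
#'
#' Columns `draw`, `chain`, `parameter`, `value`, covering both location
#' parameters and standard deviations.
#'
#' @param fit a `cascade_fit`.
#' @param path CSV file path.
#' @return `write_draws()` returns `path`; `read_draws()` the long
#'   data.frame.
#' @export
write_draws <- function(fit, path) {
  all_draws <- cbind(fit$draws, fit$sd_draws)
  long <- data.frame(
    draw = rep(seq_len(nrow(all_draws)), ncol(all_draws)),
    chain = rep(fit$chain, ncol(all_draws)),
    parameter = rep(colnames(all_draws), each = nrow(all_draws)),
    value = as.vector(all_draws), stringsAsFactors = FALSE)
  write_plain_csv(long, path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  read_checked_csv(path, c("draw", "chain", "parameter", "value"),
                   numeric_cols = "value", integer_cols = c("draw", "chain"))
}

#' Write tidy summary rows (`unit`, `sex`, `outcome`, `year`, `estimate`,
#' `ci_low`, `ci_high`)
#' @param rows summary data.frame from [summarise_surface()].
#' @param path CSV file path.
#' @return `path` invisibly; the reader returns the data.frame.
#' @export
write_summary_rows <- function(rows, path) {
  cols <- c("unit", "sex", "outcome", "year", "estimate", "ci_low", "ci_high")
  write_plain_csv(as.data.frame(rows)[cols], path)
}

#' @rdname write_summary_rows
#' @export
read_summary_rows <- function(path) {
  read_checked_csv(path,
    required = c("unit", "sex", "outcome", "year", "estimate", "ci_low",
                 "ci_high"),
    numeric_cols = c("estimate", "ci_low", "ci_high"),
    integer_cols = "year")
}
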