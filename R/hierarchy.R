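#' Country / region / super-region hierarchy
#'
#' Validates a nesting table used both for partial pooling in the model and
#' for population-weighted aggregation. Every country must map to exactly one
#' region and every region to exactly one super-region.
#'
#' @param df data.frame with character columns `country`, `region`,
#'   `super_region`.
#' @return the validated data.frame with class `cascade_hierarchy`.
#' @export
as_hierarchy <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("country", "region", "super_region") %in% names(df)))
  df <- unique(df[, c("country", "region", "super_region")])
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$country))
    stop("countries mapped to more than one region: ",
         paste(unique(df$country[duplicated(df$country)]), collapse = ", "))
  reg <- unique(df[, c("region", "super_region")])
  if (anyDuplicated(reg$region))
    stop("regions mapped to more than one super-region: ",
         paste(unique(reg$region[duplicated(reg$region)]), collapse = ", "))
  df <- df[order(df$super_region, df$region, df$country), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cascade_hierarchy", "data.frame")
  df
}

#' @export
print.cascade_hierarchy <- function(x, ...) {
  cat("<cascade_hierarchy> ", length(unique(x$country)), " countries / ",
      length(unique(x$region)), " regions / ",
      length(unique(x$super_region)), " super-regions\n", sep = "")
  invisible(x)
}

hierarchy_maps <- function(h) {
  countries <- unique(h$country)
  regions <- unique(h$region)
  supers <- unique(h$super_region)
  reg_of_cty <- setNames(match(h$region[match(countries, h$country)], regions),
                         countries)
  sup_of_reg <- setNames(
    match(h$super_region[match(regions, h$region)], supers), regions)
  list(countries = countries, regions = regions, supers = supers,
       reg_of_cty = reg_of_cty, sup_of_reg = sup_of_reg,
       sup_of_cty = setNames(sup_of_reg[reg_of_cty], countries))
}
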