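#' Census-unit tables
#'
#' Census units (blocks or tracts) are carried as a tibble with one row per
#' unit: identifier columns (`unit_id`, `level`, `county_id`), a
#' `total_population` column, a `geometry` list-column of [rect_set()]
#' polygons, one column per catalog variable present at that level, and a
#' `moe_<variable>` column for every variable that publishes a margin of
#' error.
#'
#' @param df a data frame with the columns above (`geometry` a list of
#'   rect sets).
#' @param catalog a [variable_catalog()]; validation is restricted to the
#'   catalog variables present at each row's level.
#' @param validate validate value ranges (default `TRUE`).
#' @return a tibble of class `census_units`.
#' @export
census_units <- function(df, catalog = default_catalog(), validate = TRUE) {
  need <- c("unit_id", "level", "county_id", "total_population", "geometry")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_validation("census_units: missing column(s) %s",
                     paste(miss, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$unit_id)) {
    abort_validation("census_units: duplicated unit_id '%s'",
                     df$unit_id[duplicated(df$unit_id)][1])
  }
  if (validate) validate_units(df, catalog)
  class(df) <- unique(c("census_units", class(df)))
  df
}

validate_units <- function(df, catalog) {
  if (any(!is.finite(df$total_population) | df$total_population < 0)) {
    bad <- df$unit_id[which(!is.finite(df$total_population) |
                              df$total_population < 0)[1]]
    abort_validation("unit '%s': total_population must be a nonnegative number",
                     bad)
  }
  for (lv in unique(df$level)) {
    sub <- df[df$level == lv, ]
    specs <- catalog[catalog$level == lv, ]
    for (i in seq_len(nrow(specs))) {
      s <- as.list(specs[i, ])
      if (!s$name %in% names(sub)) next
      v <- sub[[s$name]]
      ok <- switch(s$measure,
        count = is.na(v) | (v >= 0 & v <= sub$total_population),
        percentage = is.na(v) | (v >= 0 & v <= 100),
        currency = is.na(v) | v > 0,
        percentile_rank = is.na(v) | (v >= 0 & v <= 1)
      )
      if (!all(ok)) {
        abort_validation("unit '%s': variable '%s' out of range (value %s)",
                         sub$unit_id[which(!ok)[1]], s$name,
                         format(v[which(!ok)[1]]))
      }
      if (isTRUE(s$has_moe) && moe_col(s$name) %in% names(sub)) {
        m <- sub[[moe_col(s$name)]]
        bad <- !is.na(m) & m < 0
        if (any(bad)) {
          abort_validation("unit '%s': negative MOE for '%s'",
                           sub$unit_id[which(bad)[1]], s$name)
        }
      }
    }
  }
  invisible(df)
}

unit_centroids <- function(units) {
  g <- units$geometry
  cx <- vapply(g, function(r) {
    r <- rs_normalize(r)
    a <- (r$xmax - r$xmin) * (r$ymax - r$ymin)
    sum((r$xmin + r$xmax) / 2 * a) / sum(a)
  }, numeric(1))
  cy <- vapply(g, function(r) {
    r <- rs_normalize(r)
    a <- (r$xmax - r$xmin) * (r$ymax - r$ymin)
    sum((r$ymin + r$ymax) / 2 * a) / sum(a)
  }, numeric(1))
  cbind(x = cx, y = cy)
}
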