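VARIABLE_DOMAINS <- c("demographics", "health", "housing_transportation",
                      "svi", "ses")
VARIABLE_MEASURES <- c("count", "percentage", "currency", "percentile_rank")
VARIABLE_AGGREGATIONS <- c("sum_then_ratio", "mean", "population_weighted_mean")
VARIABLE_COMPARISONS <- c("pp_difference", "percent_difference")

#' Variable catalog
#'
#' The analysis is driven by a catalog of variable specifications. Each
#' variable belongs to one of five conceptual domains (demographics, health,
#' housing & transportation, social vulnerability indices, socio-economic
#' status), lives at one census geography level, and carries its measure
#' kind, aggregation rule and comparison rule:
#'
#' * `count` variables (decennial-census block counts, e.g. race/ethnicity,
#'   group quarters) are summed over selected blocks and expressed as a
#'   percentage of a denominator count (`sum_then_ratio`); compared in
#'   percentage points.
#' * `percentage` variables (ACS tract estimates with margins of error) are
#'   averaged over selected tracts; compared in percentage points.
#' * the single `currency` variable (median household income) is averaged
#'   (an average of tract medians); compared as a percent difference.
#' * `percentile_rank` variables (overall SVI and its four themes, in
#'   `[0, 1]`) are population-weighted averages; compared in rank
#'   percentile points (rank difference × 100), without significance tests
#'   because published SVI carries no margins of error.
#'
#' @param name,domain,level,measure,aggregation,comparison,has_moe,denominator
#'   vectors defining one spec per element; see Details.
#' @return a tibble of class `variable_catalog`.
#' @seealso [default_catalog()]
#' @export
variable_catalog <- function(name, domain, level, measure, aggregation,
                             comparison, has_moe, denominator = NA_character_) {
  cat <- tibble::tibble(
    name = as.character(name),
    domain = as.character(domain),
    level = as.character(level),
    measure = as.character(measure),
    aggregation = as.character(aggregation),
    comparison = as.character(comparison),
    has_moe = as.logical(has_moe),
    denominator = rep_len(as.character(denominator), length(name))
  )
  validate_catalog(cat)
  class(cat) <- c("variable_catalog", class(tibble::tibble()))
  cat
}

validate_catalog <- function(cat) {
  if (anyDuplicated(cat$name)) {
    abort_validation("catalog: duplicated variable name '%s'",
                     cat$name[duplicated(cat$name)][1])
  }
  chk <- function(col, allowed) {
    bad <- setdiff(unique(cat[[col]]), allowed)
    if (length(bad)) abort_validation("catalog: invalid %s '%s'", col, bad[1])
  }
  chk("domain", VARIABLE_DOMAINS)
  chk("level", c("block", "tract"))
  chk("measure", VARIABLE_MEASURES)
  chk("aggregation", VARIABLE_AGGREGATIONS)
  chk("comparison", VARIABLE_COMPARISONS)
  cnt <- cat$measure == "count"
  if (any(cnt & (cat$level != "block" | cat$aggregation != "sum_then_ratio" |
                   cat$comparison != "pp_difference"))) {
    abort_validation(
      "catalog: count variables must be block-level, sum_then_ratio, pp_difference")
  }
  if (any(cnt & (is.na(cat$denominator) | cat$denominator == ""))) {
    abort_validation("catalog: count variables need a denominator")
  }
  pr <- cat$measure == "percentile_rank"
  if (any(pr & (cat$aggregation != "population_weighted_mean" | cat$has_moe))) {
    abort_validation(
      "catalog: percentile_rank variables must be population_weighted_mean without MOE")
  }
  if (any(cat$measure == "currency" & cat$comparison != "percent_difference")) {
    abort_validation("catalog: currency variables must use percent_difference")
  }
  invisible(cat)
}

#' The default 23-variable catalog
#'
#' The built-in data model: 23 variables across the five domains.
#' Block-level decennial counts cover race/ethnicity (White, African
#' American, Asian, American Indian/Alaska Native, Native Hawaiian or
#' Pacific Islander, Hispanic) and group quarters; tract-level ACS
#' percentage estimates (with MOEs) cover sex, age 65+, disability, health
#' insurance, vehicle access, housing in 5+ unit structures, educational
#' attainment, poverty, unemployment and limited English proficiency;
#' median household income is the single currency variable; the overall
#' SVI percentile rank and its four theme ranks (socioeconomic status,
#' household composition & disability, minority status & language, housing
#' type & transportation) complete the set.
#'
#' @return a `variable_catalog` with 23 rows.
#' @examples
#' cat23 <- default_catalog()
#' nrow(cat23)            # 23
#' table(cat23$domain)
#' @export
default_catalog <- function() {
  race <- c("white", "african_american", "asian",
            "american_indian_alaska_native",
            "native_hawaiian_pacific_islander", "hispanic")
  variable_catalog(
    name = c(race, "group_quarters",
             "pct_female", "pct_age_65_plus",
             "pct_disability", "pct_no_insurance",
             "pct_no_vehicle", "pct_housing_5plus_units",
             "pct_bachelors_degree", "pct_below_poverty", "pct_unemployed",
             "pct_limited_english",
             "median_household_income",
             "svi_overall", "svi_socioeconomic", "svi_household_disability",
             "svi_minority_language", "svi_housing_transportation"),
    domain = c(rep("demographics", 6), "housing_transportation",
               "demographics", "demographics",
               "health", "health",
               "housing_transportation", "housing_transportation",
               "ses", "ses", "ses", "ses",
               "ses",
               rep("svi", 5)),
    level = c(rep("block", 7), rep("tract", 16)),
    measure = c(rep("count", 7), rep("percentage", 10), "currency",
                rep("percentile_rank", 5)),
    aggregation = c(rep("sum_then_ratio", 7), rep("mean", 11),
                    rep("population_weighted_mean", 5)),
    comparison = c(rep("pp_difference", 17), "percent_difference",
                   rep("pp_difference", 5)),
    has_moe = c(rep(FALSE, 7), rep(TRUE, 11), rep(FALSE, 5)),
    denominator = c(rep("total_population", 7), rep(NA_character_, 16))
  )
}

catalog_get <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) abort_validation("unknown variable '%s'", name)
  as.list(catalog[i, ])
}

# Name of the moe column for a variable in a wide census-unit table.
moe_col <- function(name) paste0("moe_", name)
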