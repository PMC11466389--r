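FRAMINGS <- c("sewersheds_vs_state", "combined_sewersheds_vs_county",
              "individual_sewershed_vs_county", "sewered_vs_unsewered")
STAR_THRESHOLDS <- c("*" = 1.96, "**" = 2.58, "***" = 3.29)

#' Percentage-point difference
#'
#' @param value_a,value_b percentages in `[0, 100]` (or rank percentile
#'   points in `[0, 100]`).
#' @return `value_a - value_b`, in percentage points; antisymmetric.
#' @export
pp_difference <- function(value_a, value_b) value_a - value_b

#' Percent (relative) difference
#'
#' Used for the continuous variable (median household income):
#' `100 * (value_a - value_b) / value_b`.
#'
#' @param value_a numeric.
#' @param value_b positive reference value.
#' @return signed percent difference.
#' @export
percent_difference <- function(value_a, value_b) {
  if (any(is.na(value_b) | value_b <= 0)) {
    abort_validation("percent_difference: reference value must be positive")
  }
  100 * (value_a - value_b) / value_b
}

#' Flag a meaningful difference
#'
#' A difference is flagged meaningful when its absolute value strictly
#' exceeds the threshold (default 5, i.e. ±5 pp for categorical variables
#' and ±5% for income). The boundary value itself is *not* meaningful:
#' "greater than ±5" is read strictly, so `flag_meaningful(5)` is `FALSE`.
#'
#' @param diff signed difference (pp or %).
#' @param threshold positive threshold (default 5).
#' @return logical.
#' @export
flag_meaningful <- function(diff, threshold = 5) {
  if (any(is.na(threshold)) || any(threshold <= 0)) {
    abort_validation("flag_meaningful: threshold must be positive")
  }
  !is.na(diff) & abs(diff) > threshold
}

#' Z statistic from margins of error
#'
#' Published MOEs are converted to standard errors by dividing by the
#' confidence multiplier (1.645 for 90%-confidence ACS MOEs); the standard
#' error of the difference combines the two by root sum of squares, and
#' stars follow the standard-normal thresholds |Z| > 1.96 (*), 2.58 (**),
#' 3.29 (***).
#'
#' @param diff the difference between the two estimates, on the estimates'
#'   own scale (pp for percentages, dollars for income).
#' @param moe_a,moe_b nonnegative margins of error (not both zero).
#' @param moe_confidence MOE-to-SE divisor (default 1.645).
#' @return list with `z` and `stars` (`"none"`, `"*"`, `"**"`, `"***"`).
#' @examples
#' z_statistic(5, 1.645, 1.645)  # z = 5/sqrt(2) = 3.54, stars "***"
#' @export
z_statistic <- function(diff, moe_a, moe_b, moe_confidence = 1.645) {
  if (is.na(moe_a) || is.na(moe_b) || moe_a < 0 || moe_b < 0) {
    abort_validation("z_statistic: margins of error must be nonnegative")
  }
  if (moe_a == 0 && moe_b == 0) {
    abort_validation("z_statistic: both margins of error are zero (SE undefined)")
  }
  if (moe_confidence <= 0) {
    abort_validation("z_statistic: moe_confidence must be positive")
  }
  se <- combine_moes(c(moe_a, moe_b)) / moe_confidence
  z <- diff / se
  list(z = z, stars = stars_for(z))
}

stars_for <- function(z) {
  az <- abs(z)
  if (is.na(az)) return(NA_character_)
  if (az > STAR_THRESHOLDS[["***"]]) return("***")
  if (az > STAR_THRESHOLDS[["**"]]) return("**")
  if (az > STAR_THRESHOLDS[["*"]]) return("*")
  "none"
}

#' Twice-the-MOE significance rule
#'
#' The simple screening rule of calling a difference significant when it
#' exceeds twice the (combined) margin of error:
#' `|diff| > 2 * sqrt(moe_a^2 + moe_b^2)` (strict). An alternative reading —
#' twice each MOE separately — would be `|diff| > 2 * max(moe_a, moe_b)`;
#' the combined form is used because it matches the root-sum-of-squares
#' MOE algebra used everywhere else.
#'
#' @param diff difference on the estimates' own scale.
#' @param moe_a,moe_b nonnegative margins of error.
#' @return logical.
#' @export
significant_2moe <- function(diff, moe_a, moe_b) {
  if (is.na(moe_a) || is.na(moe_b)) return(NA)
  !is.na(diff) & abs(diff) > 2 * combine_moes(c(moe_a, moe_b))
}

#' Compare two population profiles
#'
#' Produces one comparison record per catalog variable present in both
#' profiles, in catalog order. The difference convention is monitored /
#' sewered side minus reference side (`profile_a - profile_b`):
#'
#' * percentage and count variables: percentage-point difference;
#' * percentile ranks: rank difference × 100 (rank percentile points), so
#'   the same ±5 threshold applies;
#' * median household income: percent difference.
#'
#' Z statistics and stars are computed only where both sides publish a
#' margin of error, always on the estimates' own scale (pp for
#' percentages, dollars for income) so that the MOE algebra is
#' dimensionally consistent; variables without MOEs (decennial counts, SVI
#' ranks) get meaningful flags only.
#'
#' @param profile_a,profile_b `population_profile`s built against the same
#'   catalog (a = monitored/sewered side, b = reference side).
#' @param catalog the shared [variable_catalog()].
#' @param framing one of `"sewersheds_vs_state"`,
#'   `"combined_sewersheds_vs_county"`, `"individual_sewershed_vs_county"`,
#'   `"sewered_vs_unsewered"`.
#' @param threshold meaningful-difference threshold (default 5).
#' @param moe_confidence MOE-to-SE divisor (default 1.645).
#' @return tibble of comparison records.
#' @export
compare_profiles <- function(profile_a, profile_b,
                             catalog = default_catalog(),
                             framing = FRAMINGS, threshold = 5,
                             moe_confidence = 1.645) {
  framing <- match.arg(framing)
  if (!setequal(names(profile_a$values), catalog$name) ||
        !setequal(names(profile_b$values), catalog$name)) {
    abort_validation("compare_profiles: profiles do not match the catalog")
  }
  rows <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    s <- as.list(catalog[i, ])
    va <- profile_a$values[[s$name]]
    vb <- profile_b$values[[s$name]]
    if (is.na(va) || is.na(vb)) next
    if (s$measure == "percentile_rank") {
      diff <- 100 * pp_difference(va, vb)
      raw_diff <- diff
      units <- "pp"
    } else if (s$comparison == "percent_difference") {
      diff <- percent_difference(va, vb)
      raw_diff <- va - vb
      units <- "percent"
    } else {
      diff <- pp_difference(va, vb)
      raw_diff <- diff
      units <- "pp"
    }
    moe_a <- moe_b <- NA_real_
    if (isTRUE(s$has_moe)) {
      moe_a <- profile_a$moes[[s$name]]
      moe_b <- profile_b$moes[[s$name]]
    }
    has_both <- !is.na(moe_a) && !is.na(moe_b) && (moe_a > 0 || moe_b > 0)
    if (has_both) {
      zs <- z_statistic(raw_diff, moe_a, moe_b, moe_confidence)
      moe_comb <- combine_moes(c(moe_a, moe_b))
      sig2 <- significant_2moe(raw_diff, moe_a, moe_b)
    } else {
      zs <- list(z = NA_real_, stars = NA_character_)
      moe_comb <- NA_real_
      sig2 <- NA
    }
    rows[[i]] <- tibble::tibble(
      framing = framing,
      region_a = profile_a$region_id, region_b = profile_b$region_id,
      variable = s$name, domain = s$domain,
      value_a = va, value_b = vb,
      diff = diff, diff_units = units,
      meaningful = flag_meaningful(diff, threshold),
      moe_combined = moe_comb, z = zs$z, stars = zs$stars,
      significant_2moe = sig2)
  }
  dplyr::bind_rows(rows)
}

#' Summarize comparison records into a difference matrix
#'
#' Mirrors the heatmap-style summaries: within each framing, keeps only the
#' variables that are meaningful in at least one region pair, classifies
#' each retained cell by sign (higher on the monitored/sewered side vs the
#' reference side), and marks cells that are both meaningful and
#' statistically significant (`outlined`). Also reports, per framing, how
#' many catalog variables showed no meaningful difference in any region
#' pair (the "X of N variables" summaries).
#'
#' @param records comparison records from [compare_profiles()] (possibly
#'   several framings bound together).
#' @return list with `cells` (tibble: framing, region pair, variable,
#'   domain, diff, sign, meaningful, significant, outlined) and `counts`
#'   (tibble: framing, n_variables, n_meaningful, n_not_meaningful).
#' @export
summarize_matrix <- function(records) {
  if (nrow(records) == 0L) {
    return(list(cells = tibble::tibble(), counts = tibble::tibble()))
  }
  counts <- dplyr::summarise(
    dplyr::group_by(
      dplyr::summarise(dplyr::group_by(records, .data$framing, .data$variable),
                       any_meaningful = any(.data$meaningful), .groups = "drop"),
      .data$framing),
    n_variables = dplyr::n(),
    n_meaningful = sum(.data$any_meaningful),
    n_not_meaningful = sum(!.data$any_meaningful), .groups = "drop")

  keep <- dplyr::filter(
    dplyr::group_by(records, .data$framing, .data$variable),
    any(.data$meaningful))
  cells <- dplyr::ungroup(dplyr::mutate(
    keep,
    sign = dplyr::case_when(.data$diff > 0 ~ "higher_in_a",
                            .data$diff < 0 ~ "higher_in_b",
                            TRUE ~ "equal"),
    significant = !is.na(.data$stars) & .data$stars != "none",
    outlined = .data$meaningful & .data$significant))
  cells <- cells[, c("framing", "region_a", "region_b", "variable", "domain",
                     "diff", "diff_units", "sign", "meaningful",
                     "significant", "outlined")]
  list(cells = cells, counts = counts)
}
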