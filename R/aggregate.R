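#' Combine margins of error by root sum of squares
#'
#' The standard rule for the margin of error of a sum of independent survey
#' estimates: `sqrt(sum(moe^2))`. The MOE of an *average* of k estimates is
#' this quantity divided by k (handled by the aggregation functions).
#'
#' @param moes numeric vector of nonnegative margins of error (NAs dropped).
#' @return a single nonnegative margin of error.
#' @examples
#' combine_moes(c(3, 4))  # 5
#' @export
combine_moes <- function(moes) {
  moes <- moes[!is.na(moes)]
  if (length(moes) == 0L) {
    abort_validation("combine_moes: no margins of error supplied")
  }
  if (any(moes < 0)) abort_validation("combine_moes: negative margin of error")
  sqrt(sum(moes^2))
}

# join selection weights onto a unit table; returns units restricted to the
# selection with a `.w` column
selection_join <- function(units, selection, level) {
  sel <- selection$units[selection$units$level == level, , drop = FALSE]
  m <- match(sel$unit_id, units$unit_id)
  if (anyNA(m)) {
    abort_validation("selection references unknown unit '%s'",
                     sel$unit_id[which(is.na(m))[1]])
  }
  out <- units[m, , drop = FALSE]
  out$.w <- sel$weight
  out
}

#' Aggregate block-level count variables
#'
#' For each count variable `v` with denominator `d`, the aggregate is
#' `100 * sum(w * v) / sum(w * d)` over the selected blocks: counts are
#' summed (weighted under area apportionment) and only then turned into a
#' share of the aggregated denominator.
#'
#' @param blocks block-level [census_units()].
#' @param selection a [select_units()] result.
#' @param catalog a [variable_catalog()]; its count variables are
#'   aggregated.
#' @return list with `values` (named numeric, NA when the denominator is
#'   zero), `total_population` (`sum(w * pop)`) and `n_units`.
#' @export
aggregate_counts <- function(blocks, selection, catalog = default_catalog()) {
  specs <- catalog[catalog$measure == "count", , drop = FALSE]
  u <- selection_join(blocks, selection, "block")
  w <- u$.w
  values <- stats::setNames(rep(NA_real_, nrow(specs)), specs$name)
  for (i in seq_len(nrow(specs))) {
    s <- as.list(specs[i, ])
    if (!s$name %in% names(u)) next
    v <- u[[s$name]]
    d <- if (s$denominator == "total_population") {
      u$total_population
    } else u[[s$denominator]]
    if (any(!is.na(v) & v < 0)) {
      abort_validation("aggregate_counts: negative count in '%s'", s$name)
    }
    ok <- !is.na(v) & !is.na(d)
    den <- sum(w[ok] * d[ok])
    values[s$name] <- if (den > 0) 100 * sum(w[ok] * v[ok]) / den else NA_real_
  }
  list(values = values,
       total_population = sum(w * u$total_population),
       n_units = nrow(u))
}

#' Aggregate tract-level percentage variables
#'
#' The default replicates the dissolve rule of averaging tract percentages
#' (each selected tract counts once, regardless of population); the
#' `population_weighted` option weights each tract by `w * population`,
#' which estimates the true person-level share. Margins of error combine as
#' `sqrt(sum((w * moe)^2)) / sum(w)` — the root-sum-of-squares rule for the
#' weighted mean, reducing to `combine_moes(moes) / k` for an unweighted
#' mean of k tracts.
#'
#' @param tracts tract-level [census_units()].
#' @param selection a [select_units()] result.
#' @param catalog a [variable_catalog()]; its percentage variables are
#'   aggregated.
#' @param weighting `"unweighted"` (default) or `"population_weighted"`.
#' @return list with `values`, `moes`, `n_units`.
#' @export
aggregate_percentages <- function(tracts, selection,
                                  catalog = default_catalog(),
                                  weighting = c("unweighted",
                                                "population_weighted")) {
  weighting <- match.arg(weighting)
  specs <- catalog[catalog$measure == "percentage", , drop = FALSE]
  u <- selection_join(tracts, selection, "tract")
  agg_mean_family(u, specs, weighting)
}

#' Aggregate median household income
#'
#' The aggregate is the average of tract medians over the selected tracts
#' (an "average median", not a pooled median), with the MOE combined by the
#' root-sum-of-squares rule for a mean.
#'
#' @inheritParams aggregate_percentages
#' @return list with `values`, `moes`, `n_units`.
#' @export
aggregate_income <- function(tracts, selection, catalog = default_catalog()) {
  specs <- catalog[catalog$measure == "currency", , drop = FALSE]
  u <- selection_join(tracts, selection, "tract")
  agg_mean_family(u, specs, "unweighted")
}

agg_mean_family <- function(u, specs, weighting) {
  values <- stats::setNames(rep(NA_real_, nrow(specs)), specs$name)
  moes <- stats::setNames(rep(NA_real_, nrow(specs)), specs$name)
  for (i in seq_len(nrow(specs))) {
    s <- as.list(specs[i, ])
    if (!s$name %in% names(u)) next
    v <- u[[s$name]]
    ok <- !is.na(v)
    if (!any(ok)) next
    w <- u$.w[ok]
    if (weighting == "population_weighted") w <- w * u$total_population[ok]
    if (sum(w) <= 0) next
    values[s$name] <- sum(w * v[ok]) / sum(w)
    mc <- moe_col(s$name)
    if (isTRUE(s$has_moe) && mc %in% names(u)) {
      m <- u[[mc]][ok]
      if (!all(is.na(m))) {
        wm <- ifelse(is.na(m), 0, w * m)
        moes[s$name] <- sqrt(sum(wm^2)) / sum(w)
      }
    }
  }
  list(values = values, moes = moes, n_units = nrow(u))
}

#' Aggregate SVI percentile ranks
#'
#' Population-weighted averages of tract percentile ranks:
#' `sum(w * pop * rank) / sum(w * pop)`. The result always lies within the
#' min/max rank of the contributing tracts. SVI publishes no margins of
#' error, so none are produced.
#'
#' @inheritParams aggregate_percentages
#' @return list with `values`, `n_units`.
#' @export
aggregate_ranks <- function(tracts, selection, catalog = default_catalog()) {
  specs <- catalog[catalog$measure == "percentile_rank", , drop = FALSE]
  u <- selection_join(tracts, selection, "tract")
  values <- stats::setNames(rep(NA_real_, nrow(specs)), specs$name)
  for (i in seq_len(nrow(specs))) {
    s <- as.list(specs[i, ])
    if (!s$name %in% names(u)) next
    r <- u[[s$name]]
    ok <- !is.na(r)
    wp <- u$.w[ok] * u$total_population[ok]
    if (sum(wp) > 0) values[s$name] <- sum(wp * r[ok]) / sum(wp)
  }
  list(values = values, n_units = nrow(u))
}

#' Build a region's population profile
#'
#' Dispatches every catalog variable to its aggregation rule and assembles
#' the per-region profile: one value per variable (NA where every
#' contributing unit was missing it), margins of error where published, the
#' region's total population (from the block selection, or the
#' tract-weighted population when no block layer is supplied) and the
#' number of contributing units per level.
#'
#' @param target a [region()].
#' @param blocks,tracts [census_units()] tables (either may be `NULL`).
#' @param block_selection,tract_selection [select_units()] results built
#'   against `target` for the respective level.
#' @param catalog a [variable_catalog()].
#' @param weighting percentage-averaging mode, see
#'   [aggregate_percentages()].
#' @return an object of class `population_profile`.
#' @export
build_profile <- function(target, blocks = NULL, tracts = NULL,
                          block_selection = NULL, tract_selection = NULL,
                          catalog = default_catalog(),
                          weighting = c("unweighted", "population_weighted")) {
  weighting <- match.arg(weighting)
  for (sel in list(block_selection, tract_selection)) {
    if (!is.null(sel) && !identical(sel$region_id, target$region_id)) {
      abort_validation(
        "build_profile: selection for '%s' used with region '%s'",
        sel$region_id, target$region_id)
    }
  }
  values <- stats::setNames(rep(NA_real_, nrow(catalog)), catalog$name)
  moes <- stats::setNames(rep(NA_real_, sum(catalog$has_moe)),
                          catalog$name[catalog$has_moe])
  n_units <- c(block = 0L, tract = 0L)
  total_pop <- NA_real_
  if (!is.null(blocks) && !is.null(block_selection)) {
    a <- aggregate_counts(blocks, block_selection, catalog)
    values[names(a$values)] <- a$values
    total_pop <- a$total_population
    n_units["block"] <- a$n_units
  }
  if (!is.null(tracts) && !is.null(tract_selection)) {
    p <- aggregate_percentages(tracts, tract_selection, catalog, weighting)
    values[names(p$values)] <- p$values
    moes[intersect(names(p$moes), names(moes))] <-
      p$moes[intersect(names(p$moes), names(moes))]
    inc <- aggregate_income(tracts, tract_selection, catalog)
    values[names(inc$values)] <- inc$values
    moes[intersect(names(inc$moes), names(moes))] <-
      inc$moes[intersect(names(inc$moes), names(moes))]
    r <- aggregate_ranks(tracts, tract_selection, catalog)
    values[names(r$values)] <- r$values
    n_units["tract"] <- p$n_units
    if (is.na(total_pop)) {
      tu <- selection_join(tracts, tract_selection, "tract")
      total_pop <- sum(tu$.w * tu$total_population)
    }
  }
  structure(list(region_id = target$region_id, kind = target$kind,
                 total_population = if (is.na(total_pop)) 0 else total_pop,
                 values = values, moes = moes, n_units = n_units,
                 weighting = weighting,
                 selection_mode = (block_selection %||% tract_selection)$mode),
            class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf("<population_profile '%s' (%s): pop %.0f, %d block(s), %d tract(s)>\n",
              x$region_id, x$kind, x$total_population,
              x$n_units["block"], x$n_units["tract"]))
  present <- x$values[!is.na(x$values)]
  if (length(present)) {
    print(utils::head(round(present, 3), 23))
  }
  invisible(x)
}

#' Integer percent of a county population monitored
#'
#' Coverage arithmetic for the monitoring table: the sewershed service
#' population as a share of the county population, rounded half away from
#' zero to an integer percent. Several sewershed populations may be summed
#' first for combined county coverage.
#'
#' @param sewershed_pop nonnegative service population(s); vectors are
#'   recycled against `county_pop`.
#' @param county_pop positive county population.
#' @return integer percent(s).
#' @examples
#' percent_monitored(49384, 81801)  # 60
#' @export
percent_monitored <- function(sewershed_pop, county_pop) {
  if (any(is.na(county_pop) | county_pop <= 0)) {
    abort_validation("percent_monitored: county population must be positive")
  }
  if (any(is.na(sewershed_pop) | sewershed_pop < 0)) {
    abort_validation("percent_monitored: sewershed population must be nonnegative")
  }
  round_half_away(100 * sewershed_pop / county_pop)
}

#' Flatten profiles to a long tibble
#'
#' @param profiles list of `population_profile` objects.
#' @return tibble with one row per (region, variable).
#' @export
profiles_long <- function(profiles) {
  dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::tibble(region_id = p$region_id, kind = p$kind,
                   total_population = p$total_population,
                   variable = names(p$values),
                   value = unname(p$values),
                   moe = unname(p$moes[names(p$values)]),
                   n_blocks = unname(p$n_units["block"]),
                   n_tracts = unname(p$n_units["tract"]),
                   weighting = p$weighting,
                   selection_mode = p$selection_mode %||% NA_character_)
  }))
}
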