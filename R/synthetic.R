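#' Configuration for the synthetic census geography
#'
#' Builds the configuration for [generate_state()], which creates a fully
#' synthetic "state" of nested census geography: square blocks tiling square
#' tracts tiling square counties laid out side by side, plus rectangular
#' sewershed polygons anchored at each county's urban-core (lower-left)
#' corner. Attribute generation mimics the statistical structure of the real
#' inputs: block-level decennial counts (multinomial race/ethnicity
#' composition, binomial group quarters), tract-level ACS-style percentage
#' estimates with 90%-confidence margins of error, a log-normal median
#' household income, and five SVI percentile ranks computed by ranking
#' composite vulnerability scores across all tracts.
#'
#' `gradient_spec` injects sewered-vs-unsewered contrasts: for count and
#' percentage variables the value is a signed percentage-point shift applied
#' inside sewershed polygons, for `median_household_income` a signed percent
#' shift, and for `svi_*` variables a shift (in standard deviations) of the
#' latent vulnerability score. The default gradient encodes the study
#' conditions this generator emulates: sewered populations with larger
#' African American and Hispanic shares, more poverty and multi-unit
#' housing, less vehicle access, slightly lower educational attainment,
#' lower median household income, and higher social vulnerability.
#'
#' @param n_counties number of counties (default 9, matching a small-state
#'   sewered/unsewered study design).
#' @param tracts_per_county tracts per county; perfect square (grid layout).
#' @param blocks_per_tract blocks per tract; perfect square.
#' @param mean_block_population Poisson mean of block population.
#' @param sewered_fraction fraction of each county's area covered by its
#'   sewershed polygons, strictly in (0, 1).
#' @param sewersheds_per_county number of sewershed polygons per county
#'   (vertical strips partitioning the county's sewered rectangle).
#' @param gradient_spec named numeric vector of injected effects (see
#'   Details); use `numeric(0)` for a null (zero-gradient) state.
#' @param moe_model list with `confidence` (MOE = confidence × SE; 1.645
#'   mimics ACS 90% MOEs), `n_eff_scale` (effective sample size =
#'   `n_eff_scale` × tract population), `income_se_scale` (relative
#'   standard error of the income estimate = `income_se_scale` /
#'   sqrt(n_eff)) and `income_sigma_log` (sd of log cross-tract income
#'   heterogeneity).
#' @param baseline_shares race/ethnicity composition in unsewered areas
#'   (exhaustive, sums to 1).
#' @param baseline_pct named vector of baseline tract percentages (in %).
#' @param base_income baseline median household income (USD).
#' @param group_quarters_rate baseline share of population in group quarters.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_counties = 9,
                             tracts_per_county = 16,
                             blocks_per_tract = 16,
                             mean_block_population = 250,
                             sewered_fraction = 0.3,
                             sewersheds_per_county = 1,
                             gradient_spec = default_gradient(),
                             moe_model = list(),
                             baseline_shares = c(
                               white = 0.624, african_american = 0.21,
                               asian = 0.03,
                               american_indian_alaska_native = 0.012,
                               native_hawaiian_pacific_islander = 0.001,
                               hispanic = 0.123),
                             baseline_pct = c(
                               pct_female = 51, pct_age_65_plus = 17,
                               pct_disability = 14, pct_no_insurance = 11,
                               pct_no_vehicle = 6,
                               pct_housing_5plus_units = 9,
                               pct_bachelors_degree = 32,
                               pct_below_poverty = 14, pct_unemployed = 5,
                               pct_limited_english = 2.5),
                             base_income = 55000,
                             group_quarters_rate = 0.025,
                             seed = 1L) {
  moe_defaults <- list(confidence = 1.645, n_eff_scale = 0.25,
                       income_se_scale = 0.9, income_sigma_log = 0.10)
  moe_model <- utils::modifyList(moe_defaults, moe_model)
  cfg <- list(n_counties = as.integer(n_counties),
              tracts_per_county = as.integer(tracts_per_county),
              blocks_per_tract = as.integer(blocks_per_tract),
              mean_block_population = mean_block_population,
              sewered_fraction = sewered_fraction,
              sewersheds_per_county = as.integer(sewersheds_per_county),
              gradient_spec = gradient_spec,
              moe_model = moe_model,
              baseline_shares = baseline_shares,
              baseline_pct = baseline_pct,
              base_income = base_income,
              group_quarters_rate = group_quarters_rate,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @rdname synthetic_config
#' @export
default_gradient <- function() {
  c(african_american = 10, hispanic = 8,
    pct_below_poverty = 6, pct_housing_5plus_units = 8,
    pct_no_vehicle = 3, pct_bachelors_degree = -3,
    median_household_income = -15,
    svi_overall = 1, svi_socioeconomic = 1, svi_household_disability = 0.7,
    svi_minority_language = 1.2, svi_housing_transportation = 0.8)
}

is_perfect_square <- function(n) {
  s <- round(sqrt(n))
  s * s == n
}

validate_synthetic_config <- function(cfg) {
  pos_int <- function(x, what) {
    if (length(x) != 1L || is.na(x) || x < 1) {
      abort_validation("synthetic_config: %s must be a positive integer", what)
    }
  }
  pos_int(cfg$n_counties, "n_counties")
  pos_int(cfg$tracts_per_county, "tracts_per_county")
  pos_int(cfg$blocks_per_tract, "blocks_per_tract")
  pos_int(cfg$sewersheds_per_county, "sewersheds_per_county")
  if (!is_perfect_square(cfg$tracts_per_county)) {
    abort_validation("synthetic_config: tracts_per_county must be a perfect square")
  }
  if (!is_perfect_square(cfg$blocks_per_tract)) {
    abort_validation("synthetic_config: blocks_per_tract must be a perfect square")
  }
  if (cfg$mean_block_population <= 0) {
    abort_validation("synthetic_config: mean_block_population must be positive")
  }
  if (!(cfg$sewered_fraction > 0 && cfg$sewered_fraction < 1)) {
    abort_validation("synthetic_config: sewered_fraction must be strictly inside (0,1)")
  }
  if (cfg$n_counties * cfg$tracts_per_county < 2L) {
    abort_validation("synthetic_config: need at least 2 tracts to rank")
  }
  if (abs(sum(cfg$baseline_shares) - 1) > 1e-8) {
    abort_validation("synthetic_config: baseline_shares must sum to 1")
  }
  # degenerate-gradient checks: shifted compositions/percentages must stay
  # inside their supports
  shifted <- shift_composition(cfg$baseline_shares, cfg$gradient_spec)
  if (any(shifted < 0) || any(shifted > 1)) {
    abort_validation(
      "synthetic_config: race gradient pushes a composition share outside [0,1]")
  }
  g <- cfg$gradient_spec
  for (v in names(cfg$baseline_pct)) {
    p <- cfg$baseline_pct[[v]] + (if (v %in% names(g)) g[[v]] else 0)
    if (cfg$baseline_pct[[v]] < 0 || cfg$baseline_pct[[v]] > 100 ||
          p < 0 || p > 100) {
      abort_validation(
        "synthetic_config: gradient pushes '%s' outside [0,100]", v)
    }
  }
  gq <- cfg$group_quarters_rate +
    (if ("group_quarters" %in% names(g)) g[["group_quarters"]] / 100 else 0)
  if (cfg$group_quarters_rate < 0 || cfg$group_quarters_rate > 1 ||
        gq < 0 || gq > 1) {
    abort_validation("synthetic_config: group-quarters gradient outside [0,1]")
  }
  if ("median_household_income" %in% names(g) &&
        1 + g[["median_household_income"]] / 100 <= 0) {
    abort_validation("synthetic_config: income gradient implies non-positive income")
  }
  invisible(cfg)
}

# Apply signed pp shifts to named race categories and renormalize the
# unshifted categories so the composition still sums to 1.
shift_composition <- function(shares, gradient) {
  race <- intersect(names(gradient), names(shares))
  if (length(race) == 0L) return(shares)
  out <- shares
  out[race] <- shares[race] + gradient[race] / 100
  rest <- setdiff(names(shares), race)
  rest_old <- sum(shares[rest])
  rest_new <- 1 - sum(out[race])
  if (length(rest) > 0L && rest_old > 0) {
    out[rest] <- shares[rest] * rest_new / rest_old
  }
  out
}

#' Generate a synthetic state
#'
#' Produces nested census units (blocks and tracts), analysis regions
#' (counties, state, sewersheds) and exported ground truth under the design
#' described in [synthetic_config()]. A block's attributes follow the
#' sewered regime when its centroid falls inside its county's sewershed
#' polygons; tract-level estimates mix the two regimes by the tract's latent
#' sewered population share, so tracts straddling a sewershed boundary are
#' intermediate — exactly the apportionment problem the pipeline has to
#' handle.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_state` with elements `blocks` and
#'   `tracts` ([census_units()] tables), `regions` (named list of
#'   [region()]s: counties, `state`, sewersheds), `truth` (list of tibbles
#'   `variables` and `populations`) and `config`.
#' @export
generate_state <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort_validation("generate_state: config must be a synthetic_config")
  }
  validate_synthetic_config(config)
  set.seed(config$seed)

  nb_side <- as.integer(round(sqrt(config$blocks_per_tract)))
  nt_side <- as.integer(round(sqrt(config$tracts_per_county)))
  t_side <- nb_side                     # block side = 1 km
  c_side <- nt_side * t_side
  nc <- config$n_counties

  county_ids <- sprintf("C%02d", seq_len(nc))

  # --- geometry -----------------------------------------------------------
  regions <- list()
  for (i in seq_len(nc)) {
    x0 <- (i - 1) * c_side
    regions[[county_ids[i]]] <-
      region(county_ids[i], "county",
             rect_set(x0, 0, x0 + c_side, c_side), county_id = county_ids[i])
  }
  regions[["state"]] <- region(
    "state", "state", rect_set(0, 0, nc * c_side, c_side))

  # sewershed rectangles: anchored at the county's lower-left corner; the
  # 1.07 width stretch keeps edges off the block lattice so straddling
  # census units always exist
  f <- config$sewered_fraction
  sew_ids <- character(0)
  sew_geoms <- list()
  for (i in seq_len(nc)) {
    x0 <- (i - 1) * c_side
    w <- min(c_side, c_side * sqrt(f) * 1.07)
    h <- f * c_side^2 / w
    k <- config$sewersheds_per_county
    cuts <- x0 + w * seq(0, 1, length.out = k + 1L)
    for (j in seq_len(k)) {
      sid <- sprintf("%s-S%d", county_ids[i], j)
      sew_ids <- c(sew_ids, sid)
      sew_geoms[[sid]] <- rect_set(cuts[j], 0, cuts[j + 1L], h)
    }
  }

  # --- blocks -------------------------------------------------------------
  blk <- expand.grid(bx = seq_len(nb_side), by = seq_len(nb_side),
                     tx = seq_len(nt_side), ty = seq_len(nt_side),
                     county = seq_len(nc), KEEP.OUT.ATTRS = FALSE)
  blk$tract_idx <- (blk$ty - 1L) * nt_side + blk$tx
  blk$block_idx <- (blk$by - 1L) * nb_side + blk$bx
  blk$county_id <- county_ids[blk$county]
  blk$tract_id <- sprintf("%sT%03d", blk$county_id, blk$tract_idx)
  blk$unit_id <- sprintf("%sB%02d", blk$tract_id, blk$block_idx)
  blk$xmin <- (blk$county - 1L) * c_side + (blk$tx - 1L) * t_side + blk$bx - 1L
  blk$ymin <- (blk$ty - 1L) * t_side + blk$by - 1L
  blk <- blk[order(blk$unit_id), , drop = FALSE]
  rownames(blk) <- NULL
  nblk <- nrow(blk)

  cx <- blk$xmin + 0.5
  cy <- blk$ymin + 0.5
  sew_union_by_county <- lapply(county_ids, function(cid) {
    ids <- sew_ids[startsWith(sew_ids, paste0(cid, "-S"))]
    Reduce(rs_union, sew_geoms[ids])
  })
  names(sew_union_by_county) <- county_ids
  blk$sewered <- mapply(function(x, y, cid) {
    rs_contains_points(x, y, sew_union_by_county[[cid]])
  }, cx, cy, blk$county_id)

  pop <- stats::rpois(nblk, config$mean_block_population)

  p_unsew <- config$baseline_shares
  p_sew <- shift_composition(config$baseline_shares, config$gradient_spec)
  race_names <- names(config$baseline_shares)
  counts <- matrix(0L, nblk, length(race_names),
                   dimnames = list(NULL, race_names))
  for (i in seq_len(nblk)) {
    if (pop[i] > 0) {
      counts[i, ] <- stats::rmultinom(
        1, pop[i], if (blk$sewered[i]) p_sew else p_unsew)[, 1]
    }
  }

  g <- config$gradient_spec
  gq_shift <- if ("group_quarters" %in% names(g)) g[["group_quarters"]] / 100 else 0
  gq_rate <- config$group_quarters_rate + ifelse(blk$sewered, gq_shift, 0)
  gq <- stats::rbinom(nblk, pop, gq_rate)

  block_geoms <- lapply(seq_len(nblk), function(i) {
    rect_set(blk$xmin[i], blk$ymin[i], blk$xmin[i] + 1, blk$ymin[i] + 1)
  })
  blocks <- tibble::tibble(
    unit_id = blk$unit_id, level = "block", county_id = blk$county_id,
    tract_id = blk$tract_id, total_population = as.numeric(pop),
    geometry = block_geoms)
  for (rn in race_names) blocks[[rn]] <- as.numeric(counts[, rn])
  blocks$group_quarters <- as.numeric(gq)

  # --- tracts -------------------------------------------------------------
  tr_pop <- tapply(pop, blk$tract_id, sum)
  tr_sew_pop <- tapply(pop * blk$sewered, blk$tract_id, sum)
  tract_ids <- sort(unique(blk$tract_id))
  tr_pop <- as.numeric(tr_pop[tract_ids])
  tr_sew_pop <- as.numeric(tr_sew_pop[tract_ids])
  s_t <- ifelse(tr_pop > 0, tr_sew_pop / tr_pop, 0)
  ntr <- length(tract_ids)
  tr_county <- substr(tract_ids, 1, 3)

  mm <- config$moe_model
  n_eff <- pmax(1, tr_pop * mm$n_eff_scale)

  tract_geoms <- vector("list", ntr)
  tr_first <- match(tract_ids, blk$tract_id)
  for (i in seq_len(ntr)) {
    j <- tr_first[i]
    x0 <- (blk$county[j] - 1L) * c_side + (blk$tx[j] - 1L) * t_side
    y0 <- (blk$ty[j] - 1L) * t_side
    tract_geoms[[i]] <- rect_set(x0, y0, x0 + t_side, y0 + t_side)
  }

  tracts <- tibble::tibble(
    unit_id = tract_ids, level = "tract", county_id = tr_county,
    total_population = tr_pop, geometry = tract_geoms)

  for (v in names(config$baseline_pct)) {
    shift <- if (v %in% names(g)) g[[v]] else 0
    p_true <- (config$baseline_pct[[v]] + shift * s_t) / 100
    se <- sqrt(p_true * (1 - p_true) / n_eff)
    p_hat <- pmin(pmax(p_true + stats::rnorm(ntr, 0, se), 0), 1)
    p_moe <- pmin(pmax(p_hat, 1 / (2 * n_eff)), 1 - 1 / (2 * n_eff))
    tracts[[v]] <- 100 * p_hat
    tracts[[moe_col(v)]] <-
      100 * mm$confidence * sqrt(p_moe * (1 - p_moe) / n_eff)
  }

  g_inc <- if ("median_household_income" %in% names(g)) {
    g[["median_household_income"]]
  } else 0
  inc_true <- config$base_income * (1 + g_inc / 100 * s_t) *
    exp(stats::rnorm(ntr, 0, mm$income_sigma_log))
  inc_rel_se <- mm$income_se_scale / sqrt(n_eff)
  inc_hat <- pmax(inc_true * (1 + stats::rnorm(ntr, 0, inc_rel_se)), 1)
  tracts$median_household_income <- inc_hat
  tracts[[moe_col("median_household_income")]] <-
    mm$confidence * inc_hat * inc_rel_se

  theme_vars <- c("svi_socioeconomic", "svi_household_disability",
                  "svi_minority_language", "svi_housing_transportation")
  theme_scores <- matrix(0, ntr, length(theme_vars),
                         dimnames = list(NULL, theme_vars))
  for (v in theme_vars) {
    shift <- if (v %in% names(g)) g[[v]] else 0
    theme_scores[, v] <- stats::rnorm(ntr) + shift * s_t
  }
  ov_shift <- if ("svi_overall" %in% names(g)) g[["svi_overall"]] else 0
  overall_score <- rowSums(theme_scores) / 2 + ov_shift * s_t
  to_rank <- function(score) {
    (rank(score, ties.method = "first") - 1) / (ntr - 1)
  }
  for (v in theme_vars) tracts[[v]] <- to_rank(theme_scores[, v])
  tracts$svi_overall <- to_rank(overall_score)

  catalog <- default_catalog()
  blocks <- census_units(blocks, catalog)
  tracts <- census_units(tracts, catalog)

  # --- sewershed regions with service-population metadata -----------------
  for (sid in sew_ids) {
    cid <- substr(sid, 1, 3)
    inside <- blk$county_id == cid &
      rs_contains_points(cx, cy, sew_geoms[[sid]])
    svc <- sum(pop[inside])
    regions[[sid]] <- region(
      sid, "sewershed", sew_geoms[[sid]], county_id = cid,
      attrs = list(service_population = svc, monitored = TRUE,
                   # generated plants represent qualifying municipal WWTPs:
                   # ~106 gal/person/day with a 0.6 MGD design floor
                   design_flow_mgd = round(0.6 + svc * 1.06e-4, 3)))
  }

  truth <- make_ground_truth(config, blk, pop, counts, gq, tracts, s_t,
                             county_ids, sew_ids)
  structure(list(blocks = blocks, tracts = tracts, regions = regions,
                 truth = truth, config = config),
            class = "synthetic_state")
}

make_ground_truth <- function(config, blk, pop, counts, gq, tracts, s_t,
                              county_ids, sew_ids) {
  g <- config$gradient_spec
  sew <- blk$sewered
  pop_s <- sum(pop[sew]); pop_u <- sum(pop[!sew])

  vars <- character(); vs <- numeric(); vu <- numeric()
  dif <- numeric(); un <- character()
  add <- function(name, a, b, d, units) {
    vars <<- c(vars, name); vs <<- c(vs, a); vu <<- c(vu, b)
    dif <<- c(dif, d); un <<- c(un, units)
  }
  for (rn in colnames(counts)) {
    a <- if (pop_s > 0) 100 * sum(counts[sew, rn]) / pop_s else NA_real_
    b <- if (pop_u > 0) 100 * sum(counts[!sew, rn]) / pop_u else NA_real_
    add(rn, a, b, a - b, "pp")
  }
  a <- if (pop_s > 0) 100 * sum(gq[sew]) / pop_s else NA_real_
  b <- if (pop_u > 0) 100 * sum(gq[!sew]) / pop_u else NA_real_
  add("group_quarters", a, b, a - b, "pp")
  for (v in names(config$baseline_pct)) {
    shift <- if (v %in% names(g)) g[[v]] else 0
    add(v, config$baseline_pct[[v]] + shift, config$baseline_pct[[v]],
        shift, "pp")
  }
  g_inc <- if ("median_household_income" %in% names(g)) {
    g[["median_household_income"]]
  } else 0
  lnf <- exp(config$moe_model$income_sigma_log^2 / 2)
  add("median_household_income",
      config$base_income * (1 + g_inc / 100) * lnf,
      config$base_income * lnf, g_inc, "percent")
  tp <- tracts$total_population
  for (v in c("svi_overall", "svi_socioeconomic", "svi_household_disability",
              "svi_minority_language", "svi_housing_transportation")) {
    r <- tracts[[v]]
    a <- if (sum(tp * s_t) > 0) sum(tp * s_t * r) / sum(tp * s_t) else NA_real_
    b <- if (sum(tp * (1 - s_t)) > 0) {
      sum(tp * (1 - s_t) * r) / sum(tp * (1 - s_t))
    } else NA_real_
    add(v, a, b, 100 * (a - b), "pp")
  }
  variables <- tibble::tibble(variable = vars, sewered_value = vs,
                              unsewered_value = vu, diff = dif,
                              diff_units = un)

  pops <- tibble::tibble(region_id = "state", population = sum(pop))
  for (cid in county_ids) {
    in_c <- blk$county_id == cid
    pops <- dplyr::bind_rows(
      pops,
      tibble::tibble(region_id = cid, population = sum(pop[in_c])),
      tibble::tibble(region_id = paste0(cid, "-sewered"),
                     population = sum(pop[in_c & sew])),
      tibble::tibble(region_id = paste0(cid, "-unsewered"),
                     population = sum(pop[in_c & !sew])))
  }
  list(variables = variables, populations = pops)
}

#' @export
print.synthetic_state <- function(x, ...) {
  cat(sprintf(
    "<synthetic_state: %d blocks, %d tracts, %d counties, %d sewershed(s)>\n",
    nrow(x$blocks), nrow(x$tracts), x$config$n_counties,
    sum(vapply(x$regions, function(r) r$kind == "sewershed", logical(1)))))
  invisible(x)
}
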