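# Shared test helpers: independent oracles and small hand-built fixtures.

# Raster-counting area oracle: counts cell centers falling inside any
# rectangle of the (possibly overlapping, un-normalized) rect list.
raster_area <- function(rects, cell = 0.001, pad = 0.05) {
  xmin <- min(rects$xmin) - pad; xmax <- max(rects$xmax) + pad
  ymin <- min(rects$ymin) - pad; ymax <- max(rects$ymax) + pad
  xs <- seq(xmin + cell / 2, xmax, by = cell)
  ys <- seq(ymin + cell / 2, ymax, by = cell)
  inside <- matrix(FALSE, length(xs), length(ys))
  for (i in seq_len(nrow(rects))) {
    ix <- xs > rects$xmin[i] & xs < rects$xmax[i]
    iy <- ys > rects$ymin[i] & ys < rects$ymax[i]
    inside[ix, iy] <- TRUE
  }
  sum(inside) * cell^2
}

# Random rectangle arrangement inside the unit square.
random_rects <- function(n, min_side = 0.05) {
  x1 <- runif(n, 0, 1 - min_side); y1 <- runif(n, 0, 1 - min_side)
  w <- runif(n, min_side, 1 - x1); h <- runif(n, min_side, 1 - y1)
  data.frame(xmin = x1, ymin = y1, xmax = x1 + w, ymax = y1 + h)
}

as_rs <- function(df) rect_set(df$xmin, df$ymin, df$xmax, df$ymax)

# Minimal hand-built tract table: percentages/income/ranks with MOEs.
make_tracts <- function(values, pops, moes = NULL, var = "pct_below_poverty",
                        county = "C01") {
  n <- length(values)
  geoms <- lapply(seq_len(n) - 1, function(i) rect_set(i, 0, i + 1, 1))
  df <- tibble::tibble(
    unit_id = sprintf("%sT%03d", county, seq_len(n)), level = "tract",
    county_id = county, total_population = pops, geometry = geoms)
  df[[var]] <- values
  if (!is.null(moes)) df[[paste0("moe_", var)]] <- moes
  census_units(df)
}

# Selection with explicit weights over given unit ids.
make_selection <- function(units, weights = 1, region_id = "R",
                           mode = "intersect") {
  sewershedpop:::new_selection(
    region_id, mode,
    tibble::tibble(unit_id = units$unit_id, level = units$level,
                   weight = rep_len(weights, nrow(units))))
}

# A complete two-sided profile pair over the default catalog, built from
# explicit value vectors (for comparison-layer tests).
make_profile <- function(values, moes = NULL, region_id = "A",
                         kind = "sewered_area") {
  catalog <- default_catalog()
  v <- stats::setNames(rep(NA_real_, nrow(catalog)), catalog$name)
  v[names(values)] <- unlist(values)
  m <- stats::setNames(rep(NA_real_, sum(catalog$has_moe)),
                       catalog$name[catalog$has_moe])
  if (!is.null(moes)) m[names(moes)] <- unlist(moes)
  structure(list(region_id = region_id, kind = kind, total_population = 1000,
                 values = v, moes = m, n_units = c(block = 1L, tract = 1L),
                 weighting = "unweighted", selection_mode = "intersect"),
            class = "population_profile")
}

small_config <- function(seed = 1L, ...) {
  synthetic_config(n_counties = 2, tracts_per_county = 4, blocks_per_tract = 4,
                   mean_block_population = 120, seed = seed, ...)
}
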