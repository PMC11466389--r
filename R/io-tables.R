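#' Write a synthetic state to a fixture directory
#'
#' Writes the standard seven-file layout: `blocks.geojson`,
#' `tracts.geojson`, `counties.geojson`, `sewersheds.geojson`,
#' `block_attrs.csv`, `tract_attrs.csv` and `truth.csv`. The files
#' round-trip losslessly through [read_fixture()] / [read_units()].
#'
#' @param state a `synthetic_state` from [generate_state()].
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(state, directory) {
  if (!inherits(state, "synthetic_state")) {
    abort_validation("write_fixture: state must be a synthetic_state")
  }
  if (nrow(state$blocks) == 0L || nrow(state$tracts) == 0L) {
    abort_validation("write_fixture: state has no census units")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io("cannot create fixture directory %s", directory)
  }

  write_units_layer <- function(units, stem) {
    props <- units[, intersect(c("unit_id", "county_id", "tract_id"),
                               names(units))]
    write_geojson(units$geometry, props,
                  file.path(directory, paste0(stem, ".geojson")))
    attrs <- units[, setdiff(names(units), "geometry")]
    write_atomic(file.path(directory, paste0(stem, "_attrs.csv")),
                 function(tmp) readr::write_csv(attrs, tmp, progress = FALSE))
  }
  write_units_layer(state$blocks, "block")
  file.rename(file.path(directory, "block.geojson"),
              file.path(directory, "blocks.geojson"))
  write_units_layer(state$tracts, "tract")
  file.rename(file.path(directory, "tract.geojson"),
              file.path(directory, "tracts.geojson"))

  regs <- state$regions
  kinds <- vapply(regs, function(r) r$kind, character(1))
  write_region_layer <- function(sel, file) {
    rs <- regs[sel]
    props <- dplyr::bind_rows(lapply(rs, function(r) {
      base <- tibble::tibble(region_id = r$region_id, kind = r$kind,
                             county_id = r$county_id)
      for (a in names(r$attrs)) base[[a]] <- r$attrs[[a]]
      base
    }))
    write_geojson(lapply(rs, function(r) r$geometry), props,
                  file.path(directory, file), id_field = "region_id")
  }
  write_region_layer(kinds == "county", "counties.geojson")
  write_region_layer(kinds == "sewershed", "sewersheds.geojson")

  tr <- state$truth
  truth_tab <- dplyr::bind_rows(
    dplyr::mutate(tr$variables, kind = "variable", population = NA_real_,
                  .before = 1),
    tibble::tibble(kind = "region_population",
                   variable = tr$populations$region_id,
                   sewered_value = NA_real_, unsewered_value = NA_real_,
                   diff = NA_real_, diff_units = NA_character_,
                   population = tr$populations$population))
  write_atomic(file.path(directory, "truth.csv"),
               function(tmp) readr::write_csv(truth_tab, tmp, progress = FALSE))
  invisible(directory)
}

#' Read census units from a polygon layer plus attribute table
#'
#' Joins a CSV attribute table to a GeoJSON polygon layer by id and
#' validates the result against the catalog. In strict mode (default) any
#' polygon without a matching attribute row is an error; in lenient mode
#' such polygons are dropped with a message reporting the count.
#'
#' @param polygon_file GeoJSON file of unit polygons.
#' @param attribute_file CSV with a header and an id column matching the
#'   polygon ids.
#' @param catalog a [variable_catalog()].
#' @param level `"block"` or `"tract"`.
#' @param strict error (TRUE, default) or drop-with-message (FALSE) on
#'   polygons lacking attributes.
#' @param id_col id column name (default `"unit_id"`).
#' @return a [census_units()] table.
#' @export
read_units <- function(polygon_file, attribute_file,
                       catalog = default_catalog(),
                       level = c("block", "tract"),
                       strict = TRUE, id_col = "unit_id") {
  level <- match.arg(level)
  gj <- read_geojson(polygon_file)
  if (!id_col %in% names(gj$properties)) {
    abort_validation("%s: missing id property '%s'", polygon_file, id_col)
  }
  ids <- as.character(gj$properties[[id_col]])
  if (anyDuplicated(ids)) {
    abort_validation("%s: duplicated id '%s'", polygon_file,
                     ids[duplicated(ids)][1])
  }
  if (!file.exists(attribute_file)) {
    abort_io("attribute file not found: %s", attribute_file)
  }
  attrs <- readr::read_csv(attribute_file, show_col_types = FALSE,
                           progress = FALSE)
  if (!id_col %in% names(attrs)) {
    abort_validation("%s: missing id column '%s'", attribute_file, id_col)
  }
  if (anyDuplicated(attrs[[id_col]])) {
    abort_validation("%s: duplicated id '%s'", attribute_file,
                     attrs[[id_col]][duplicated(attrs[[id_col]])][1])
  }
  m <- match(ids, attrs[[id_col]])
  if (anyNA(m)) {
    n_miss <- sum(is.na(m))
    if (strict) {
      abort_validation(
        "%d polygon(s) lack attribute rows (first: '%s'); use strict = FALSE to drop them",
        n_miss, ids[which(is.na(m))[1]])
    }
    message(sprintf("read_units: dropping %d polygon(s) without attributes",
                    n_miss))
  }
  keep <- !is.na(m)
  df <- attrs[m[keep], , drop = FALSE]
  df$unit_id <- ids[keep]
  df$level <- level
  if (!"county_id" %in% names(df)) {
    cid <- gj$properties$county_id
    df$county_id <- if (is.null(cid)) NA_character_ else
      as.character(cid)[keep]
  }
  df$geometry <- gj$geoms[keep]
  census_units(df, catalog)
}

#' Read analysis regions from a GeoJSON layer
#'
#' @param polygon_file GeoJSON layer with `region_id`, `kind` and optional
#'   `county_id` plus metadata properties.
#' @param kind if given, overrides/validates the layer's `kind` property.
#' @return named list of [region()]s.
#' @export
read_regions <- function(polygon_file, kind = NULL) {
  gj <- read_geojson(polygon_file)
  p <- gj$properties
  if (!"region_id" %in% names(p)) {
    abort_validation("%s: missing 'region_id' property", polygon_file)
  }
  ks <- if (!is.null(kind)) rep(kind, nrow(p)) else as.character(p$kind)
  meta_cols <- setdiff(names(p), c("region_id", "kind", "county_id"))
  out <- lapply(seq_len(nrow(p)), function(i) {
    attrs <- lapply(meta_cols, function(cl) p[[cl]][[i]])
    names(attrs) <- meta_cols
    attrs <- attrs[!vapply(attrs, function(v) all(is.na(v)), logical(1))]
    region(p$region_id[i], ks[i], gj$geoms[[i]],
           county_id = if ("county_id" %in% names(p)) {
             as.character(p$county_id[i])
           } else NA_character_,
           attrs = attrs)
  })
  names(out) <- p$region_id
  out
}

#' Read back a fixture directory
#'
#' @param directory a directory written by [write_fixture()].
#' @param catalog a [variable_catalog()].
#' @return list with `blocks`, `tracts`, `regions` (counties, state as the
#'   union of counties, sewersheds) and `truth`.
#' @export
read_fixture <- function(directory, catalog = default_catalog()) {
  fp <- function(f) file.path(directory, f)
  blocks <- read_units(fp("blocks.geojson"), fp("block_attrs.csv"),
                       catalog, "block")
  tracts <- read_units(fp("tracts.geojson"), fp("tract_attrs.csv"),
                       catalog, "tract")
  counties <- read_regions(fp("counties.geojson"))
  sewersheds <- read_regions(fp("sewersheds.geojson"))
  state_geom <- Reduce(rs_union, lapply(counties, function(r) r$geometry))
  regions <- c(counties, list(state = region("state", "state", state_geom)),
               sewersheds)
  truth_tab <- readr::read_csv(fp("truth.csv"), show_col_types = FALSE,
                               progress = FALSE)
  truth <- list(
    variables = dplyr::select(
      dplyr::filter(truth_tab, .data$kind == "variable"),
      "variable", "sewered_value", "unsewered_value", "diff", "diff_units"),
    populations = tibble::tibble(
      region_id = truth_tab$variable[truth_tab$kind == "region_population"],
      population = truth_tab$population[truth_tab$kind == "region_population"]))
  list(blocks = blocks, tracts = tracts, regions = regions, truth = truth)
}

#' Write and read the long comparison table
#'
#' One tidy row per (framing, region pair, variable): values on both sides,
#' the difference with its units, the meaningful flag, combined MOE, Z
#' statistic, significance stars and the twice-MOE significance indicator.
#'
#' @param records tibble of comparison records from [compare_profiles()].
#' @param path CSV path.
#' @return `write_long_table()`: `path`, invisibly. `read_long_table()`:
#'   the records tibble.
#' @export
write_long_table <- function(records, path) {
  if (nrow(records) == 0L) {
    abort_validation("write_long_table: no records to write")
  }
  write_atomic(path, function(tmp) {
    readr::write_csv(records, tmp, progress = FALSE)
  })
  invisible(path)
}

#' @rdname write_long_table
#' @export
read_long_table <- function(path) {
  if (!file.exists(path)) abort_io("comparison table not found: %s", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    framing = readr::col_character(),
                    region_a = readr::col_character(),
                    region_b = readr::col_character(),
                    variable = readr::col_character(),
                    domain = readr::col_character(),
                    diff_units = readr::col_character(),
                    stars = readr::col_character(),
                    meaningful = readr::col_logical(),
                    significant_2moe = readr::col_logical(),
                    .default = readr::col_double()))
}
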