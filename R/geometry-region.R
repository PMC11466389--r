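REGION_KINDS <- c("sewershed", "county", "state", "sewered_area",
                  "unsewered_area")

#' Analysis regions
#'
#' A region is a named polygon used as an aggregation target: a sewershed
#' (the catchment draining to one wastewater treatment plant), a county, the
#' state, or a derived sewered/unsewered county area. Geometry is a
#' [rect_set()] in the shared planar coordinate system.
#'
#' @param region_id character scalar, unique region name.
#' @param kind one of `"sewershed"`, `"county"`, `"state"`,
#'   `"sewered_area"`, `"unsewered_area"`.
#' @param geometry a [rect_set()]; may be empty only for a derived
#'   `unsewered_area`.
#' @param county_id parent county id, or `NA` where not applicable.
#' @param attrs named list of metadata (e.g. `design_flow_mgd`, `monitored`
#'   for sewersheds).
#' @return an object of class `region`.
#' @export
region <- function(region_id, kind, geometry, county_id = NA_character_,
                   attrs = list()) {
  kind <- match.arg(kind, REGION_KINDS)
  geometry <- rs_normalize(geometry)
  if (rs_is_empty(geometry) && kind != "unsewered_area") {
    abort_geometry("region '%s' (%s) has empty geometry", region_id, kind)
  }
  structure(list(region_id = as.character(region_id), kind = kind,
                 county_id = as.character(county_id),
                 geometry = geometry, attrs = attrs),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region '%s' kind=%s county=%s area=%.6g>\n",
              x$region_id, x$kind, x$county_id, rs_area(x$geometry)))
  invisible(x)
}

#' @param x a region.
#' @rdname region
#' @export
region_area <- function(x) rs_area(x$geometry)

#' Merge sewersheds into a county sewered-area polygon
#'
#' Unions the sewershed geometries and clips the union to the county
#' boundary, yielding the county's single sewered-area polygon. The erase
#' complement is produced by [derive_unsewered()].
#'
#' @param sewersheds list of sewershed [region()]s; must be non-empty and
#'   every sewershed must overlap the county with positive area.
#' @param county the county [region()].
#' @return a [region()] of kind `sewered_area` with
#'   `region_id = "<county>-sewered"`.
#' @export
merge_sewersheds <- function(sewersheds, county) {
  if (length(sewersheds) == 0L) {
    abort_validation("merge_sewersheds: at least one sewershed is required")
  }
  if (county$kind != "county") {
    abort_validation("merge_sewersheds: second argument must be a county region")
  }
  geoms <- lapply(sewersheds, function(s) {
    clipped <- rs_intersect(s$geometry, county$geometry)
    if (rs_is_empty(clipped)) {
      abort_validation(
        "sewershed '%s' does not overlap county '%s'",
        s$region_id, county$region_id)
    }
    clipped
  })
  merged <- Reduce(rs_union, geoms)
  region(paste0(county$region_id, "-sewered"), "sewered_area", merged,
         county_id = county$region_id)
}

#' Derive the unsewered county area by erase
#'
#' Erases the sewered area from its county polygon. The result may be empty
#' (a fully sewered county). Area conservation
#' `area(sewered) + area(unsewered) == area(county)` is asserted to a
#' relative tolerance of 1e-9.
#'
#' @param county the county [region()].
#' @param sewered the county's sewered-area [region()], as produced by
#'   [merge_sewersheds()] (already clipped to the county).
#' @return a [region()] of kind `unsewered_area`.
#' @export
derive_unsewered <- function(county, sewered) {
  if (county$kind != "county" || sewered$kind != "sewered_area") {
    abort_validation("derive_unsewered: expects (county, sewered_area) regions")
  }
  if (!identical(sewered$county_id, county$region_id)) {
    abort_validation(
      "derive_unsewered: sewered area belongs to county '%s', not '%s'",
      sewered$county_id, county$region_id)
  }
  geom <- rs_difference(county$geometry, sewered$geometry)
  a_c <- rs_area(county$geometry)
  gap <- abs(rs_area(geom) + rs_area(sewered$geometry) - a_c)
  if (gap > 1e-9 * max(a_c, 1)) {
    abort_geometry(
      "derive_unsewered: area not conserved for county '%s' (gap %g)",
      county$region_id, gap)
  }
  region(paste0(county$region_id, "-unsewered"), "unsewered_area", geom,
         county_id = county$region_id)
}

#' Area fraction of a census unit inside a region
#'
#' @param unit_geometry the unit's [rect_set()] geometry (positive area).
#' @param target a [region()] (or bare rect set).
#' @return `area(unit ∩ region) / area(unit)` in `[0, 1]`.
#' @export
area_fraction <- function(unit_geometry, target) {
  g <- if (inherits(target, "region")) target$geometry else as_rect_set(target)
  a_u <- rs_area(unit_geometry)
  if (a_u <= 0) abort_geometry("area_fraction: unit has zero area")
  min(rs_area(rs_intersect(unit_geometry, g)) / a_u, 1)
}

#' Select census units intersecting a region
#'
#' Implements the spatial-intersect selection used to attach census units to
#' an analysis region. A unit is selected when its geometric intersection
#' with the region has strictly positive area; units that merely share a
#' boundary line are excluded unless `include_touching = TRUE` (provided for
#' sensitivity analysis, since desktop-GIS select-by-intersect semantics
#' differ on edge-touching units).
#'
#' Under `mode = "intersect"` every selected unit gets weight 1, which is
#' the classic whole-unit rule and double-counts units that straddle a
#' boundary between adjacent regions. Under `mode = "area_weighted"` the
#' weight is the unit's area fraction inside the region, which conserves
#' population across a partition of a county.
#'
#' @param units a [census_units()] table.
#' @param target a [region()].
#' @param mode `"intersect"` (whole-unit weights, default) or
#'   `"area_weighted"`.
#' @param include_touching also select units whose closed boundaries touch
#'   the region with zero overlap area (weight 0 would be meaningless, so
#'   these get weight 1 in both modes). Default `FALSE`.
#' @return an object of class `selection`: list with `region_id`, `mode`,
#'   and `units`, a tibble of `unit_id`, `level`, `weight`.
#' @export
select_units <- function(units, target,
                         mode = c("intersect", "area_weighted"),
                         include_touching = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(target, "region")) {
    abort_validation("select_units: target must be a region")
  }
  if (rs_area(target$geometry) <= 0) {
    abort_geometry("select_units: region '%s' has zero area", target$region_id)
  }
  n <- nrow(units)
  if (n == 0L) {
    return(new_selection(target$region_id, mode,
                         tibble::tibble(unit_id = character(),
                                        level = character(),
                                        weight = numeric())))
  }
  geoms <- units$geometry
  single <- vapply(geoms, nrow, integer(1)) == 1L
  ov <- numeric(n)
  ua <- numeric(n)
  if (any(single)) {
    xmin <- vapply(geoms[single], function(g) g$xmin, numeric(1))
    ymin <- vapply(geoms[single], function(g) g$ymin, numeric(1))
    xmax <- vapply(geoms[single], function(g) g$xmax, numeric(1))
    ymax <- vapply(geoms[single], function(g) g$ymax, numeric(1))
    ov[single] <- rect_overlap_area(xmin, ymin, xmax, ymax, target$geometry)
    ua[single] <- (xmax - xmin) * (ymax - ymin)
  }
  for (i in which(!single)) {
    ov[i] <- rs_area(rs_intersect(geoms[[i]], target$geometry))
    ua[i] <- rs_area(geoms[[i]])
  }
  if (any(ua <= 0)) {
    abort_geometry("select_units: unit '%s' has zero area",
                   units$unit_id[which(ua <= 0)[1]])
  }
  # positive-area predicate with a relative guard against slab round-off
  tol <- 1e-12
  sel <- ov > tol * ua
  w <- ifelse(sel, if (mode == "intersect") 1 else pmin(ov / ua, 1), 0)
  if (include_touching) {
    touch <- !sel & vapply(seq_len(n), function(i) {
      rs_touches_or_overlaps(geoms[[i]], target$geometry)
    }, logical(1))
    sel <- sel | touch
    w[touch] <- 1
  }
  new_selection(target$region_id, mode,
                tibble::tibble(unit_id = units$unit_id[sel],
                               level = units$level[sel],
                               weight = w[sel]))
}

new_selection <- function(region_id, mode, units) {
  structure(list(region_id = region_id, mode = mode, units = units),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection for '%s' mode=%s: %d unit(s)>\n",
              x$region_id, x$mode, nrow(x$units)))
  invisible(x)
}
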