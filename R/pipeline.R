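#' Pipeline configuration
#'
#' One configuration object drives the four pipeline stages
#' ([run_simulate()], [run_profile()], [run_compare()], [run_report()]).
#' Configurations can be built in code or loaded from YAML/JSON with
#' [read_pipeline_config()].
#'
#' @param data_dir directory holding (or receiving) the fixture layers.
#' @param out_dir output directory (must differ from `data_dir`).
#' @param selection_mode `"intersect"` (whole-unit spatial intersect,
#'   default) or `"area_weighted"`.
#' @param weighting percentage averaging: `"unweighted"` (default) or
#'   `"population_weighted"`.
#' @param threshold meaningful-difference threshold (default 5).
#' @param moe_confidence MOE-to-SE divisor (default 1.645).
#' @param framings subset of the four comparison framings to run.
#' @param min_design_flow_mgd minimum treatment-plant design flow (million
#'   gallons per day) for a sewershed to enter the sewered-area merge
#'   (default 0.5); applied when the sewershed layer carries a
#'   `design_flow_mgd` attribute.
#' @param synthetic named list of [synthetic_config()] arguments for
#'   [run_simulate()].
#' @param seed integer seed for the synthetic stage (overrides
#'   `synthetic$seed` when given).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            selection_mode = c("intersect", "area_weighted"),
                            weighting = c("unweighted", "population_weighted"),
                            threshold = 5, moe_confidence = 1.645,
                            framings = FRAMINGS,
                            min_design_flow_mgd = 0.5,
                            synthetic = list(), seed = NULL) {
  selection_mode <- match.arg(selection_mode)
  weighting <- match.arg(weighting)
  if (length(framings) == 0L) {
    abort_validation("pipeline_config: at least one framing must be selected")
  }
  framings <- match.arg(framings, choices = FRAMINGS, several.ok = TRUE)
  if (threshold <= 0) {
    abort_validation("pipeline_config: threshold must be positive")
  }
  if (normalizePath(data_dir, mustWork = FALSE) ==
        normalizePath(out_dir, mustWork = FALSE)) {
    abort_validation("pipeline_config: out_dir must differ from data_dir")
  }
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 selection_mode = selection_mode, weighting = weighting,
                 threshold = threshold, moe_confidence = moe_confidence,
                 framings = framings,
                 min_design_flow_mgd = min_design_flow_mgd,
                 synthetic = synthetic),
            class = "pipeline_config")
}

#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file
#'   whose keys are the arguments of [pipeline_config()].
#' @param ... overrides applied on top of the file (flags beat file values).
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) abort_io("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  overrides <- list(...)
  for (k in names(overrides)) raw[[k]] <- overrides[[k]]
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_validation("config: unknown key(s) %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    ok <- dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io("cannot create output directory %s", config$out_dir)
  }
}

write_manifest <- function(config, path, counts = list(),
                           extra = list()) {
  inputs <- list.files(config$data_dir, full.names = TRUE)
  inputs <- inputs[!dir.exists(inputs)]
  checksums <- as.list(tools::md5sum(inputs))
  names(checksums) <- basename(inputs)
  manifest <- c(list(
    package = "sewershedpop",
    version = as.character(utils::packageVersion("sewershedpop")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    input_checksums = checksums,
    record_counts = counts), extra)
  write_atomic(path, function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  })
  invisible(path)
}

#' Run the synthetic-data stage
#'
#' Generates the synthetic state from `config$synthetic` and writes the
#' seven fixture files plus a manifest into `config$data_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the generated `synthetic_state`, invisibly.
#' @export
run_simulate <- function(config) {
  scfg <- do.call(synthetic_config, config$synthetic)
  state <- generate_state(scfg)
  write_fixture(state, config$data_dir)
  write_manifest(config, file.path(config$data_dir, "manifest.json"),
                 counts = list(blocks = nrow(state$blocks),
                               tracts = nrow(state$tracts),
                               regions = length(state$regions)))
  message(sprintf("simulate: wrote %d blocks, %d tracts to %s",
                  nrow(state$blocks), nrow(state$tracts), config$data_dir))
  invisible(state)
}

profile_region <- function(target, blocks, tracts, config,
                           catalog = default_catalog()) {
  bs <- select_units(blocks, target, config$selection_mode)
  ts <- select_units(tracts, target, config$selection_mode)
  build_profile(target, blocks, tracts, bs, ts, catalog,
                weighting = config$weighting)
}

filter_by_flow <- function(sewersheds, min_flow) {
  keep <- vapply(sewersheds, function(s) {
    flow <- s$attrs$design_flow_mgd
    is.null(flow) || is.na(flow) || flow >= min_flow
  }, logical(1))
  sewersheds[keep]
}

# The analysis regions of a fixture, grouped by role.
fixture_regions <- function(regions) {
  kinds <- vapply(regions, function(r) r$kind, character(1))
  list(counties = regions[kinds == "county"],
       state = regions[kinds == "state"][[1]],
       sewersheds = regions[kinds == "sewershed"])
}

#' Build all region profiles and the coverage table
#'
#' Reads the fixture in `config$data_dir` and profiles every analysis
#' region: each sewershed, each county, the state, and each county's
#' sewered and unsewered areas (from the capacity-filtered sewershed merge
#' and its erase complement). Writes `profiles.csv` and `coverage.csv`
#' (region, service/census population, county population, integer percent
#' monitored) plus a manifest to `config$out_dir`.
#'
#' For coverage, the sewershed population is the utility-reported
#' `service_population` attribute when the sewershed layer carries one,
#' else the census-derived selection total; the source used is recorded in
#' the table and the manifest. Service populations and census-derived
#' profiles are never mixed inside one computation.
#'
#' @param config a [pipeline_config()].
#' @return list with `profiles` (named list) and `coverage` (tibble),
#'   invisibly.
#' @export
run_profile <- function(config) {
  ensure_out_dir(config)
  fx <- read_fixture(config$data_dir)
  rr <- fixture_regions(fx$regions)
  catalog <- default_catalog()

  profiles <- list()
  for (r in c(rr$counties, list(rr$state), rr$sewersheds)) {
    profiles[[r$region_id]] <- profile_region(r, fx$blocks, fx$tracts, config,
                                              catalog)
  }
  for (cty in rr$counties) {
    shed_in <- Filter(function(s) identical(s$county_id, cty$region_id),
                      rr$sewersheds)
    shed_in <- filter_by_flow(shed_in, config$min_design_flow_mgd)
    if (length(shed_in) == 0L) next
    sewered <- merge_sewersheds(shed_in, cty)
    unsewered <- derive_unsewered(cty, sewered)
    profiles[[sewered$region_id]] <-
      profile_region(sewered, fx$blocks, fx$tracts, config, catalog)
    if (!rs_is_empty(unsewered$geometry)) {
      profiles[[unsewered$region_id]] <-
        profile_region(unsewered, fx$blocks, fx$tracts, config, catalog)
    }
  }

  coverage <- coverage_table(rr$sewersheds, profiles)
  write_atomic(file.path(config$out_dir, "profiles.csv"), function(tmp) {
    readr::write_csv(profiles_long(profiles), tmp, progress = FALSE)
  })
  write_atomic(file.path(config$out_dir, "coverage.csv"), function(tmp) {
    readr::write_csv(coverage, tmp, progress = FALSE)
  })
  write_manifest(config, file.path(config$out_dir, "manifest_profile.json"),
                 counts = list(profiles = length(profiles),
                               coverage_rows = nrow(coverage)),
                 extra = list(coverage_population_source =
                                unique(coverage$population_source)))
  message(sprintf("profile: %d region profiles, %d coverage rows",
                  length(profiles), nrow(coverage)))
  invisible(list(profiles = profiles, coverage = coverage))
}

# Coverage rows per sewershed plus a combined row per county with >1
# sewershed; populations are utility service populations when available.
coverage_table <- function(sewersheds, profiles) {
  rows <- lapply(sewersheds, function(s) {
    svc <- s$attrs$service_population
    src <- if (!is.null(svc) && !is.na(svc)) "service_population" else "census"
    pop <- if (src == "service_population") as.numeric(svc) else
      profiles[[s$region_id]]$total_population
    cpop <- profiles[[s$county_id]]$total_population
    tibble::tibble(region_id = s$region_id, county_id = s$county_id,
                   combined = FALSE, sewershed_population = pop,
                   county_population = cpop,
                   pct_monitored = percent_monitored(pop, cpop),
                   population_source = src)
  })
  tab <- dplyr::bind_rows(rows)
  combined <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(tab, .data$county_id),
                     region_id = paste0(.data$county_id[1], "-combined"),
                     combined = TRUE,
                     sewershed_population = sum(.data$sewershed_population),
                     county_population = .data$county_population[1],
                     population_source = .data$population_source[1],
                     n = dplyr::n(), .groups = "drop"),
    .data$n > 1)
  if (nrow(combined)) {
    combined$pct_monitored <- percent_monitored(
      combined$sewershed_population, combined$county_population)
    combined$n <- NULL
    tab <- dplyr::bind_rows(tab, combined[, names(tab)])
  }
  tab
}

#' Run the comparison framings
#'
#' Executes the configured framings against the fixture in
#' `config$data_dir`:
#'
#' * `sewersheds_vs_state` — all monitored sewersheds unioned and profiled
#'   as one region, against the state profile;
#' * `combined_sewersheds_vs_county` — each county's monitored sewersheds
#'   unioned (geometry union before selection), against the county;
#' * `individual_sewershed_vs_county` — each monitored sewershed against
#'   its county;
#' * `sewered_vs_unsewered` — each county's sewered area (union of *all*
#'   its sewersheds passing the capacity filter) against the erase
#'   remainder. Counties whose sewershed geometry cannot be delineated
#'   (no sewershed passes the filter) abort with a message, because the
#'   sewered/unsewered split requires complete sewershed coverage.
#'
#' Writes `comparisons.csv`, `matrix.csv`, `matrix_counts.csv` and a
#' manifest to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the comparison records tibble, invisibly.
#' @export
run_compare <- function(config) {
  ensure_out_dir(config)
  fx <- read_fixture(config$data_dir)
  rr <- fixture_regions(fx$regions)
  catalog <- default_catalog()
  prof <- function(r) profile_region(r, fx$blocks, fx$tracts, config, catalog)
  cmp <- function(a, b, framing) {
    compare_profiles(a, b, catalog, framing,
                     threshold = config$threshold,
                     moe_confidence = config$moe_confidence)
  }
  monitored <- Filter(function(s) isTRUE(s$attrs$monitored %||% TRUE),
                      rr$sewersheds)
  county_profiles <- lapply(rr$counties, prof)
  records <- list()

  if ("sewersheds_vs_state" %in% config$framings) {
    geom <- Reduce(rs_union, lapply(monitored, function(s) s$geometry))
    all_mon <- region("monitored-sewersheds", "sewered_area", geom)
    records[["A"]] <- cmp(prof(all_mon), prof(rr$state), "sewersheds_vs_state")
  }
  if ("combined_sewersheds_vs_county" %in% config$framings) {
    recs <- lapply(rr$counties, function(cty) {
      shed_in <- Filter(function(s) identical(s$county_id, cty$region_id),
                        monitored)
      if (length(shed_in) == 0L) return(NULL)
      combined <- merge_sewersheds(shed_in, cty)
      combined$region_id <- paste0(cty$region_id, "-combined")
      cmp(prof(combined), county_profiles[[cty$region_id]],
          "combined_sewersheds_vs_county")
    })
    records[["B"]] <- dplyr::bind_rows(recs)
  }
  if ("individual_sewershed_vs_county" %in% config$framings) {
    recs <- lapply(monitored, function(s) {
      cmp(prof(s), county_profiles[[s$county_id]],
          "individual_sewershed_vs_county")
    })
    records[["C"]] <- dplyr::bind_rows(recs)
  }
  if ("sewered_vs_unsewered" %in% config$framings) {
    recs <- lapply(rr$counties, function(cty) {
      shed_in <- Filter(function(s) identical(s$county_id, cty$region_id),
                        rr$sewersheds)
      shed_in <- filter_by_flow(shed_in, config$min_design_flow_mgd)
      if (length(shed_in) == 0L) {
        abort_validation(
          "sewered_vs_unsewered: county '%s' has no delineable sewershed geometry (complete sewershed coverage is required for the sewered/unsewered split)",
          cty$region_id)
      }
      sewered <- merge_sewersheds(shed_in, cty)
      unsewered <- derive_unsewered(cty, sewered)
      if (rs_is_empty(unsewered$geometry)) return(NULL)
      cmp(prof(sewered), prof(unsewered), "sewered_vs_unsewered")
    })
    records[["D"]] <- dplyr::bind_rows(recs)
  }

  records <- dplyr::bind_rows(records)
  write_long_table(records, file.path(config$out_dir, "comparisons.csv"))
  ms <- summarize_matrix(records)
  write_atomic(file.path(config$out_dir, "matrix.csv"), function(tmp) {
    readr::write_csv(ms$cells, tmp, progress = FALSE)
  })
  write_atomic(file.path(config$out_dir, "matrix_counts.csv"), function(tmp) {
    readr::write_csv(ms$counts, tmp, progress = FALSE)
  })
  write_manifest(config, file.path(config$out_dir, "manifest_compare.json"),
                 counts = as.list(table(records$framing)))
  message(sprintf("compare: %d records across %d framing(s)",
                  nrow(records), length(unique(records$framing))))
  invisible(records)
}

#' Render a plain-text report from the pipeline CSVs
#'
#' Derives a Markdown summary — per-framing "X of N variables not
#' meaningfully different" counts, the list of meaningful cells with signs
#' and stars, and the coverage table — solely from `comparisons.csv` and
#' `coverage.csv` in `config$out_dir`. Regenerating from unchanged CSVs is
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return the report path, invisibly.
#' @export
run_report <- function(config) {
  cmp_path <- file.path(config$out_dir, "comparisons.csv")
  cov_path <- file.path(config$out_dir, "coverage.csv")
  if (!file.exists(cmp_path)) {
    abort_io("run_report: %s not found (run_compare first)", cmp_path)
  }
  records <- read_long_table(cmp_path)
  ms <- summarize_matrix(records)
  lines <- c("# Sewershed population comparison report", "")
  for (i in seq_len(nrow(ms$counts))) {
    ct <- ms$counts[i, ]
    lines <- c(lines, sprintf(
      "* %s: %d of %d variables not meaningfully different in any region pair.",
      ct$framing, ct$n_not_meaningful, ct$n_variables))
  }
  mcells <- ms$cells[ms$cells$meaningful, , drop = FALSE]
  lines <- c(lines, "", "## Meaningful differences", "")
  if (nrow(mcells) == 0L) {
    lines <- c(lines, "(none)")
  } else {
    lines <- c(lines, vapply(seq_len(nrow(mcells)), function(i) {
      r <- mcells[i, ]
      sprintf("* [%s] %s vs %s — %s: %+.1f %s (%s)%s", r$framing,
              r$region_a, r$region_b, r$variable, r$diff, r$diff_units,
              r$sign, if (r$outlined) " [significant]" else "")
    }, character(1)))
  }
  if (file.exists(cov_path)) {
    cov <- readr::read_csv(cov_path, show_col_types = FALSE, progress = FALSE)
    lines <- c(lines, "", "## Coverage", "",
               "| region | county | population | county population | % monitored |",
               "|---|---|---:|---:|---:|",
               vapply(seq_len(nrow(cov)), function(i) {
                 r <- cov[i, ]
                 sprintf("| %s | %s | %.0f | %.0f | %d%% |", r$region_id,
                         r$county_id, r$sewershed_population,
                         r$county_population, r$pct_monitored)
               }, character(1)))
  }
  path <- file.path(config$out_dir, "report.md")
  write_atomic(path, function(tmp) {
    writeLines(lines, tmp)
  })
  invisible(path)
}

#' Bundled NCWMN June-2022 coverage populations
#'
#' The published service populations of the 25 wastewater treatment plant
#' sewersheds monitored by the North Carolina Wastewater Monitoring Network
#' as of June 2022, with their county populations and the published integer
#' percent-monitored column. Used as reference input for coverage
#' arithmetic.
#'
#' @return tibble with columns `sewershed`, `county`,
#'   `sewershed_population`, `county_population`, `pct_monitored`.
#' @export
ncwmn_coverage <- function() {
  path <- system.file("extdata", "ncwmn_table1.csv", package = "sewershedpop",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
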