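test_that("unit counts are forced by the configuration", {
  cfg <- synthetic_config(n_counties = 4, tracts_per_county = 16,
                          blocks_per_tract = 4, mean_block_population = 50,
                          seed = 2)
  st <- generate_state(cfg)
  kinds <- vapply(st$regions, function(r) r$kind, character(1))
  expect_equal(sum(kinds == "county"), 4)
  expect_equal(nrow(st$tracts), 64)
  expect_equal(nrow(st$blocks), 256)
  # counties tile the state rectangle without gaps or overlaps
  cty_geoms <- lapply(st$regions[kinds == "county"], function(r) r$geometry)
  expect_equal(sum(vapply(cty_geoms, rs_area, numeric(1))),
               rs_area(st$regions$state$geometry))
  # blocks tile each tract
  tr <- st$tracts$geometry[[1]]
  blks <- st$blocks[st$blocks$tract_id == st$tracts$unit_id[1], ]
  expect_equal(sum(vapply(blks$geometry, rs_area, numeric(1))), rs_area(tr))
})

test_that("generation is deterministic for a fixed seed and config", {
  a <- generate_state(small_config(seed = 7))
  b <- generate_state(small_config(seed = 7))
  expect_identical(a$blocks, b$blocks)
  expect_identical(a$tracts, b$tracts)
  expect_identical(a$truth, b$truth)
  c_ <- generate_state(small_config(seed = 8))
  expect_false(identical(a$blocks, c_$blocks))
})

test_that("race categories are exhaustive and sum to the block population", {
  st <- generate_state(small_config(seed = 3))
  race <- c("white", "african_american", "asian",
            "american_indian_alaska_native",
            "native_hawaiian_pacific_islander", "hispanic")
  sums <- rowSums(as.matrix(st$blocks[, race]))
  expect_equal(sums, st$blocks$total_population)
  expect_true(all(st$blocks$group_quarters <= st$blocks$total_population))
})

test_that("percentile ranks are exactly uniform on {0, 1/(T-1), ..., 1}", {
  st <- generate_state(small_config(seed = 4))
  T_ <- nrow(st$tracts)
  grid <- (seq_len(T_) - 1) / (T_ - 1)
  for (v in c("svi_overall", "svi_socioeconomic", "svi_household_disability",
              "svi_minority_language", "svi_housing_transportation")) {
    expect_equal(sort(st$tracts[[v]]), grid)
  }
})

test_that("margins of error are positive and shrink with tract population", {
  st <- generate_state(synthetic_config(
    n_counties = 4, tracts_per_county = 16, blocks_per_tract = 4,
    mean_block_population = 150, seed = 5))
  moe_cols <- grep("^moe_", names(st$tracts), value = TRUE)
  for (mc in moe_cols) expect_true(all(st$tracts[[mc]] > 0))
  # at (nearly) fixed estimate, MOE scales as 1/sqrt(n_eff): strong negative
  # rank correlation with population
  rho <- stats::cor(log(st$tracts$moe_pct_female),
                    log(st$tracts$total_population), method = "spearman")
  expect_lt(rho, -0.8)
})

test_that("zero gradient leaves no systematic sewered-unsewered difference", {
  diffs <- NULL
  for (seed in 1:50) {
    st <- generate_state(synthetic_config(
      n_counties = 1, tracts_per_county = 4, blocks_per_tract = 4,
      mean_block_population = 80, gradient_spec = numeric(0), seed = seed))
    diffs <- rbind(diffs, stats::setNames(st$truth$variables$diff,
                                          st$truth$variables$variable))
  }
  for (v in colnames(diffs)) {
    m <- mean(diffs[, v])
    se <- stats::sd(diffs[, v]) / sqrt(nrow(diffs))
    expect_lte(abs(m), max(3 * se, 1e-12))
  }
})

test_that("invalid configurations fail with configuration errors", {
  expect_error(synthetic_config(tracts_per_county = 5),
               "perfect square", class = "sewershedpop_validation_error")
  expect_error(synthetic_config(blocks_per_tract = 3), "perfect square")
  expect_error(synthetic_config(sewered_fraction = 1.2), "sewered_fraction")
  expect_error(synthetic_config(sewered_fraction = 0), "sewered_fraction")
  expect_error(synthetic_config(mean_block_population = -4),
               "mean_block_population")
  # degenerate gradients that push values outside their supports
  expect_error(synthetic_config(gradient_spec = c(african_american = 90)),
               "composition")
  expect_error(synthetic_config(gradient_spec = c(pct_below_poverty = 95)),
               "outside \\[0,100\\]")
  expect_error(synthetic_config(gradient_spec = c(median_household_income = -120)),
               "income")
})

test_that("an injected composition gradient is recovered by the pipeline", {
  # +10 pp African American share inside sewersheds; recovery via the
  # area-weighted sewered-vs-unsewered contrast should land within ±1 pp
  cfg <- synthetic_config(
    n_counties = 4, tracts_per_county = 64, blocks_per_tract = 4,
    mean_block_population = 800, sewered_fraction = 0.35,
    gradient_spec = c(african_american = 10), seed = 11)
  st <- generate_state(cfg)
  catalog <- default_catalog()
  kinds <- vapply(st$regions, function(r) r$kind, character(1))
  diffs <- vapply(names(st$regions)[kinds == "county"], function(cid) {
    cty <- st$regions[[cid]]
    sheds <- Filter(function(s) identical(s$county_id, cid),
                    st$regions[kinds == "sewershed"])
    sew <- merge_sewersheds(sheds, cty)
    un <- derive_unsewered(cty, sew)
    ps <- build_profile(sew, st$blocks, st$tracts,
                        select_units(st$blocks, sew, "area_weighted"),
                        select_units(st$tracts, sew, "area_weighted"), catalog)
    pu <- build_profile(un, st$blocks, st$tracts,
                        select_units(st$blocks, un, "area_weighted"),
                        select_units(st$tracts, un, "area_weighted"), catalog)
    rec <- compare_profiles(ps, pu, catalog, "sewered_vs_unsewered")
    rec$diff[rec$variable == "african_american"]
  }, numeric(1))
  expect_equal(mean(diffs), 10, tolerance = 0.1)  # ±1 pp on 10
  # and the exported truth reflects the design effect
  tr <- st$truth$variables
  expect_equal(tr$diff[tr$variable == "african_american"], 10,
               tolerance = 0.1)
})
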