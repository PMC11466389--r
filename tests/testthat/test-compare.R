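test_that("difference statistics match their definitions", {
  expect_equal(pp_difference(20, 20), 0)
  expect_equal(pp_difference(12, 18), -6)
  # antisymmetry
  set.seed(61)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  expect_equal(pp_difference(a, b), -pp_difference(b, a))

  expect_equal(percent_difference(50000, 50000), 0)
  expect_equal(percent_difference(80000, 100000), -20)
  expect_equal(percent_difference(105000, 100000), 5)
  expect_error(percent_difference(1, 0), class = "sewershedpop_validation_error")
})

test_that("the meaningful flag is strict at the threshold", {
  expect_false(flag_meaningful(4.9))
  expect_true(flag_meaningful(-6.0))
  expect_false(flag_meaningful(5.0))        # boundary excluded
  expect_false(flag_meaningful(-5.0))
  expect_true(flag_meaningful(5.0000001))
  expect_true(flag_meaningful(3, threshold = 2.5))
  expect_error(flag_meaningful(1, threshold = 0),
               class = "sewershedpop_validation_error")
  # raising the threshold never adds flags
  d <- seq(-15, 15, by = 0.5)
  for (th in c(2, 5, 8, 12)) {
    expect_true(all(flag_meaningful(d, th + 1) <= flag_meaningful(d, th)))
  }
})

test_that("z statistics and stars follow the MOE-to-SE conversion", {
  expect_equal(z_statistic(0, 1, 1)$z, 0)
  expect_equal(z_statistic(0, 1, 1)$stars, "none")

  z1 <- z_statistic(2, 1.645, 1.645)
  expect_equal(z1$z, 2 / sqrt(2), tolerance = 1e-6)   # 1.41421
  expect_equal(z1$stars, "none")

  z2 <- z_statistic(5, 1.645, 1.645)
  expect_equal(z2$z, 5 / sqrt(2), tolerance = 1e-6)   # 3.5355 > 3.29
  expect_equal(z2$stars, "***")

  expect_equal(z_statistic(3, 1.645, 1.645)$stars, "*")
  expect_equal(z_statistic(4, 1.645, 1.645)$stars, "**")
  expect_error(z_statistic(1, 0, 0), class = "sewershedpop_validation_error")

  # a different confidence multiplier rescales z linearly
  expect_equal(z_statistic(2, 1, 1, moe_confidence = 1.96)$z,
               1.96 * 2 / sqrt(2))
})

test_that("the twice-MOE rule uses the combined margin", {
  expect_false(significant_2moe(10, 3, 4))   # 10 > 2*5 is false
  expect_true(significant_2moe(10.1, 3, 4))
  expect_false(significant_2moe(0, 3, 4))
})

test_that("compare_profiles dispatches rules per variable", {
  vals <- list(african_american = 22, pct_below_poverty = 15,
               median_household_income = 50000, svi_overall = 0.55)
  moes <- list(pct_below_poverty = 2, median_household_income = 2000)
  a <- make_profile(vals, moes)
  b <- make_profile(vals, moes, region_id = "B", kind = "county")
  same <- compare_profiles(a, b, framing = "sewersheds_vs_state")
  expect_equal(nrow(same), 4)
  expect_true(all(same$diff == 0))
  expect_false(any(same$meaningful))
  expect_true(all(same$stars[!is.na(same$stars)] == "none"))
  # records come out in catalog order
  cat_order <- default_catalog()$name
  expect_equal(same$variable, cat_order[cat_order %in% same$variable])

  # one variable shifted by +13 pp: exactly one meaningful record
  vals2 <- vals; vals2$african_american <- 35
  shifted <- compare_profiles(make_profile(vals2, moes), b,
                              framing = "sewersheds_vs_state")
  expect_equal(sum(shifted$meaningful), 1)
  expect_equal(shifted$diff[shifted$variable == "african_american"], 13)

  # rank differences are reported in rank percentile points
  vals3 <- vals; vals3$svi_overall <- 0.62
  r <- compare_profiles(make_profile(vals3, moes), b,
                        framing = "sewered_vs_unsewered")
  expect_equal(r$diff[r$variable == "svi_overall"], 7, tolerance = 1e-9)
  expect_true(is.na(r$z[r$variable == "svi_overall"]))   # SVI has no MOE

  # income: % difference reported, z computed on the dollar scale
  vals4 <- vals; vals4$median_household_income <- 40000
  ri <- compare_profiles(make_profile(vals4, moes), b,
                         framing = "sewered_vs_unsewered")
  inc <- ri[ri$variable == "median_household_income", ]
  expect_equal(inc$diff, -20)
  expect_equal(inc$diff_units, "percent")
  expect_equal(inc$z, -10000 / (sqrt(2000^2 + 2000^2) / 1.645),
               tolerance = 1e-9)
})

test_that("swapping profile roles negates differences but keeps flags", {
  set.seed(77)
  st <- generate_state(small_config(seed = 77))
  catalog <- default_catalog()
  prof <- function(r) {
    build_profile(r, st$blocks, st$tracts, select_units(st$blocks, r),
                  select_units(st$tracts, r), catalog)
  }
  pa <- prof(st$regions$C01)
  pb <- prof(st$regions$C02)
  ab <- compare_profiles(pa, pb, catalog, "sewered_vs_unsewered")
  ba <- compare_profiles(pb, pa, catalog, "sewered_vs_unsewered")
  pp <- ab$diff_units == "pp"
  expect_equal(ab$diff[pp], -ba$diff[pp])
  expect_equal(ab$meaningful[pp], ba$meaningful[pp])
  expect_equal(ab$z[pp], -ba$z[pp])
  # every record's diff recomputes from its stored values
  for (i in seq_len(nrow(ab))) {
    expected <- if (ab$diff_units[i] == "percent") {
      percent_difference(ab$value_a[i], ab$value_b[i])
    } else if (startsWith(ab$variable[i], "svi_")) {
      100 * (ab$value_a[i] - ab$value_b[i])
    } else {
      ab$value_a[i] - ab$value_b[i]
    }
    expect_equal(ab$diff[i], expected, tolerance = 1e-12)
  }
})

test_that("summarize_matrix counts meaningful variables per framing", {
  vals <- list(african_american = 22, pct_below_poverty = 15,
               svi_overall = 0.5)
  b <- make_profile(vals, region_id = "B", kind = "county")
  none <- compare_profiles(make_profile(vals), b,
                           framing = "sewersheds_vs_state")
  ms0 <- summarize_matrix(none)
  expect_equal(nrow(ms0$cells), 0)
  expect_equal(ms0$counts$n_not_meaningful, 3)
  expect_equal(ms0$counts$n_variables, 3)

  # a full 23-variable profile pair with 8 variables pushed over threshold
  catalog <- default_catalog()
  full_vals <- as.list(stats::setNames(rep(20, 18), setdiff(
    catalog$name, c(catalog$name[catalog$measure == "percentile_rank"]))))
  full_vals$median_household_income <- 50000
  for (v in catalog$name[catalog$measure == "percentile_rank"]) {
    full_vals[[v]] <- 0.5
  }
  shift <- full_vals
  up <- c("white", "african_american", "hispanic", "pct_below_poverty",
          "pct_no_vehicle", "pct_housing_5plus_units", "svi_overall")
  for (v in up) shift[[v]] <- if (v == "svi_overall") 0.58 else 27
  shift$median_household_income <- 61000   # +22%
  ms <- summarize_matrix(compare_profiles(
    make_profile(shift), make_profile(full_vals, region_id = "B",
                                      kind = "county"),
    framing = "combined_sewersheds_vs_county"))
  expect_equal(ms$counts$n_meaningful, 8)
  expect_equal(ms$counts$n_not_meaningful, 15)
  expect_true(all(ms$cells$sign == "higher_in_a"))
  # outlined cells are exactly the meaningful-and-starred ones
  expect_equal(ms$cells$outlined, ms$cells$meaningful & ms$cells$significant)
})
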