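make_blocks <- function(v, d, var = "african_american", county = "C01") {
  n <- length(v)
  geoms <- lapply(seq_len(n) - 1, function(i) rect_set(i, 0, i + 1, 1))
  df <- tibble::tibble(
    unit_id = sprintf("%sB%02d", county, seq_len(n)), level = "block",
    county_id = county, total_population = d, geometry = geoms)
  df[[var]] <- v
  census_units(df)
}

test_that("combine_moes is the root sum of squares", {
  expect_equal(combine_moes(7), 7)
  expect_equal(combine_moes(c(3, 4)), 5)
  expect_equal(combine_moes(c(0, 0, 0)), 0)
  expect_equal(combine_moes(c(2, NA, 3)), sqrt(13))
  expect_error(combine_moes(numeric(0)),
               class = "sewershedpop_validation_error")
  expect_error(combine_moes(c(1, -1)), "negative")
})

test_that("count aggregation sums then forms the ratio", {
  b <- make_blocks(c(10, 30), c(100, 100))
  a <- aggregate_counts(b, make_selection(b))
  expect_equal(unname(a$values["african_american"]), 20)
  expect_equal(a$total_population, 200)

  one <- make_blocks(25, 100)
  expect_equal(
    unname(aggregate_counts(one, make_selection(one))$values["african_american"]),
    25)

  # weighted brute-force enumeration oracle
  set.seed(21)
  d <- sample(50:500, 50)
  v <- vapply(d, function(n) sample(0:n, 1), numeric(1))
  w <- runif(50)
  b50 <- make_blocks(v, d)
  a50 <- aggregate_counts(b50, make_selection(b50, weights = w,
                                              mode = "area_weighted"))
  num <- 0; den <- 0; pw <- 0
  for (i in 1:50) {
    num <- num + w[i] * v[i]; den <- den + w[i] * d[i]; pw <- pw + w[i] * d[i]
  }
  expect_equal(unname(a50$values["african_american"]), 100 * num / den,
               tolerance = 1e-12)
  expect_equal(a50$total_population, pw, tolerance = 1e-12)

  # zero denominator is absent, not zero
  z <- make_blocks(c(0, 0), c(0, 0))
  expect_true(is.na(aggregate_counts(z, make_selection(z))$values["african_american"]))
})

test_that("percentage aggregation honors both weighting modes", {
  t1 <- make_tracts(c(10, 30), c(500, 500))
  sel <- make_selection(t1)
  expect_equal(unname(aggregate_percentages(t1, sel)$values["pct_below_poverty"]),
               20)
  expect_equal(
    unname(aggregate_percentages(t1, sel,
             weighting = "population_weighted")$values["pct_below_poverty"]),
    20)

  t2 <- make_tracts(c(10, 30), c(900, 100))
  sel2 <- make_selection(t2)
  expect_equal(unname(aggregate_percentages(t2, sel2)$values["pct_below_poverty"]),
               20)
  expect_equal(
    unname(aggregate_percentages(t2, sel2,
             weighting = "population_weighted")$values["pct_below_poverty"]),
    12)

  # enumeration oracle, 40 random tracts
  set.seed(33)
  v <- runif(40, 0, 100); p <- sample(100:5000, 40)
  t40 <- make_tracts(v, p)
  acc <- 0
  for (x in v) acc <- acc + x
  expect_equal(
    unname(aggregate_percentages(t40, make_selection(t40))$values["pct_below_poverty"]),
    acc / 40, tolerance = 1e-12)

  # MOE of an unweighted mean of k estimates is rss/k
  t3 <- make_tracts(c(10, 20, 30), c(1, 1, 1), moes = c(3, 4, 12))
  a3 <- aggregate_percentages(t3, make_selection(t3))
  expect_equal(unname(a3$moes["pct_below_poverty"]), 13 / 3)
})

test_that("income aggregation is the unweighted mean of tract medians", {
  t1 <- make_tracts(c(40000, 60000), c(10, 99999),
                    var = "median_household_income", moes = c(300, 400))
  a <- aggregate_income(t1, make_selection(t1))
  expect_equal(unname(a$values["median_household_income"]), 50000)
  expect_equal(unname(a$moes["median_household_income"]), 250)

  one <- make_tracts(48000, 5, var = "median_household_income")
  expect_equal(
    unname(aggregate_income(one, make_selection(one))$values["median_household_income"]),
    48000)

  set.seed(44)
  v <- runif(30, 2e4, 2e5)
  t30 <- make_tracts(v, rep(1, 30), var = "median_household_income")
  expect_equal(
    unname(aggregate_income(t30, make_selection(t30))$values["median_household_income"]),
    mean(v), tolerance = 1e-9)
})

test_that("rank aggregation is population-weighted and bounded", {
  t1 <- make_tracts(c(0.2, 0.6), c(100, 300), var = "svi_overall")
  expect_equal(
    unname(aggregate_ranks(t1, make_selection(t1))$values["svi_overall"]), 0.5)

  tc <- make_tracts(rep(0.37, 5), c(10, 20, 30, 40, 50), var = "svi_overall")
  expect_equal(
    unname(aggregate_ranks(tc, make_selection(tc))$values["svi_overall"]), 0.37)

  set.seed(55)
  r <- runif(25); p <- sample(100:9000, 25); w <- runif(25)
  t25 <- make_tracts(r, p, var = "svi_overall")
  a <- aggregate_ranks(t25, make_selection(t25, weights = w,
                                           mode = "area_weighted"))
  num <- 0; den <- 0
  for (i in 1:25) {
    num <- num + w[i] * p[i] * r[i]; den <- den + w[i] * p[i]
  }
  got <- unname(a$values["svi_overall"])
  expect_equal(got, num / den, tolerance = 1e-12)
  expect_gte(got, min(r)); expect_lte(got, max(r))
})

test_that("profile building dispatches, is permutation-invariant, and empties cleanly", {
  st <- generate_state(small_config(seed = 12))
  catalog <- default_catalog()
  cty <- st$regions$C01
  p <- build_profile(cty, st$blocks, st$tracts,
                     select_units(st$blocks, cty),
                     select_units(st$tracts, cty), catalog)
  expect_setequal(names(p$values), catalog$name)
  expect_true(all(!is.na(p$values)))

  # permutation invariance in unit order
  perm_b <- st$blocks[rev(seq_len(nrow(st$blocks))), ]
  perm_t <- st$tracts[sample(nrow(st$tracts)), ]
  p2 <- build_profile(cty, perm_b, perm_t,
                      select_units(perm_b, cty),
                      select_units(perm_t, cty), catalog)
  expect_equal(p2$values, p$values)
  expect_equal(p2$total_population, p$total_population)

  # a region selecting zero units: all values absent, population 0
  far <- region("far", "sewershed", rect_set(999, 999, 1000, 1000))
  p0 <- build_profile(far, st$blocks, st$tracts,
                      select_units(st$blocks, far),
                      select_units(st$tracts, far), catalog)
  expect_true(all(is.na(p0$values)))
  expect_equal(p0$total_population, 0)

  # mismatched selection/region is refused
  expect_error(build_profile(far, st$blocks, st$tracts,
                             select_units(st$blocks, cty), NULL, catalog),
               class = "sewershedpop_validation_error")
})

test_that("area-weighted partition conserves count numerators and denominators", {
  st <- generate_state(small_config(seed = 13))
  catalog <- default_catalog()
  kinds <- vapply(st$regions, function(r) r$kind, character(1))
  cty <- st$regions$C01
  sheds <- Filter(function(s) identical(s$county_id, "C01"),
                  st$regions[kinds == "sewershed"])
  sew <- merge_sewersheds(sheds, cty)
  un <- derive_unsewered(cty, sew)
  pop_of <- function(r) {
    aggregate_counts(st$blocks, select_units(st$blocks, r, "area_weighted"),
                     catalog)$total_population
  }
  expect_equal(pop_of(sew) + pop_of(un), pop_of(cty), tolerance = 1e-9)

  # under plain intersect selection, straddling blocks are double counted:
  # the two parts sum to at least the county
  pop_int <- function(r) {
    aggregate_counts(st$blocks, select_units(st$blocks, r), catalog)$total_population
  }
  straddlers <- intersect(select_units(st$blocks, sew)$units$unit_id,
                          select_units(st$blocks, un)$units$unit_id)
  expect_gt(length(straddlers), 0)
  expect_gt(pop_int(sew) + pop_int(un), pop_int(cty))
})

test_that("percent_monitored reproduces published coverage arithmetic", {
  expect_equal(percent_monitored(15527, 34823), 45L)   # Laurinburg / Scotland
  expect_equal(percent_monitored(49384, 81801), 60L)   # City of Wilson
  expect_equal(percent_monitored(3500, 69473), 5L)     # Beaufort / Carteret
  expect_equal(percent_monitored(7648, 1111761), 1L)   # Raleigh 3 / Wake
  expect_equal(percent_monitored(0, 12345), 0L)
  # halves round away from zero, not to even
  expect_equal(percent_monitored(105, 1000), 11L)
  expect_equal(percent_monitored(125, 1000), 13L)
  # combined coverage sums sewershed populations first
  expect_equal(percent_monitored(sum(c(68685, 182501, 120000)), 1110356), 33L)
  expect_error(percent_monitored(10, 0),
               class = "sewershedpop_validation_error")
})
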