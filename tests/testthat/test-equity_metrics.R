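china <- builtin_china_2020()
china_tot <- province_totals(china)

test_that("per-1,000 rates reproduce the published national values", {
  expect_within(rate_per_thousand(38158, china_tot$population_65plus), 0.20,
                0.005)
  expect_within(rate_per_thousand(4882366, china_tot$population_65plus), 25.61,
                0.005)
  expect_equal(rate_per_thousand(0, 1000), 0)
  expect_error(rate_per_thousand(5, 0), "positive")
})

test_that("agglomeration degrees match published anchors", {
  expect_within(hrad(669, 0.63, 38158, china_tot$area), 26.803, 0.0005)
  expect_within(hrad(23, 122.84, 38158, china_tot$area), 0.005, 0.0005)
  expect_within(pad(4049012, 0.63, china_tot$population_65plus,
                    china_tot$area), 32.471, 0.0005)
  expect_within(pad(206963, 122.84, china_tot$population_65plus,
                    china_tot$area), 0.009, 0.0005)
  expect_within(hrad_over_pad(1498, 3757224, 38158,
                              china_tot$population_65plus), 1.992, 0.0005)
  expect_within(hrad_over_pad(48, 1051500, 38158,
                              china_tot$population_65plus), 0.228, 0.0005)
  expect_error(hrad(5, 0, 100, 10), "positive")
  expect_error(hrad_over_pad(5, 100, 0, 1000), "positive")
})

test_that("unit at the national density has agglomeration degree exactly 1", {
  tab <- uniform_table()
  agg <- agglomeration(tab)
  expect_true(all(abs(agg$hrad - 1) < 1e-12))
  expect_true(all(abs(agg$pad - 1) < 1e-12))
  expect_true(all(abs(agg$hrad_over_pad - 1) < 1e-12))
  expect_true(all(agg$area_class == "absolute_equity"))
  expect_true(all(agg$population_class == "absolute_equity"))
})

test_that("agglomeration classification follows the >1/=1/<1 criteria", {
  expect_equal(classify_agglomeration(26.803), "over_allocated")
  expect_equal(classify_agglomeration(1.0), "absolute_equity")
  expect_equal(classify_agglomeration(1 + 1e-12), "absolute_equity")
  expect_equal(classify_agglomeration(0.005), "under_allocated")
  expect_error(classify_agglomeration(-0.1), "non-negative")
})

test_that("hrad_over_pad is consistent with hrad/pad and both normalize", {
  agg <- agglomeration(china)
  expect_true(all(abs(agg$hrad_over_pad - agg$hrad / agg$pad) < 1e-9))
  # weighted means are exactly 1: sum HRAD_i * (A_i/A_n) = 1, likewise HRAD/PAD
  w_area <- china$area / china_tot$area
  w_pop <- china$population_65plus / china_tot$population_65plus
  for (rc in resource_names(china)) {
    sub <- agg[agg$resource == rc, ]
    expect_equal(sum(sub$hrad * w_area), 1, tolerance = 1e-12)
    expect_equal(sum(sub$hrad_over_pad * w_pop), 1, tolerance = 1e-12)
  }
})

test_that("lorenz curve construction sorts ascending and satisfies its invariants", {
  # hand-built: A has 80% of population but 50% of resource -> kink at (0.8, 0.5)
  tab <- province_table(data.frame(
    name = c("A", "B"), region = "r", area = c(1, 1),
    population_65plus = c(800L, 200L), beds = c(50L, 50L)))
  lc <- lorenz_curve(tab, "beds", "population")
  expect_equal(lc$x, c(0, 0.8, 1))
  expect_equal(lc$y, c(0, 0.5, 1))
  expect_equal(lc$unit, c("", "A", "B"))

  # zero-holder sorts first with density 0
  tab0 <- province_table(data.frame(
    name = c("A", "B"), region = "r", area = c(1, 1),
    population_65plus = c(500L, 500L), beds = c(0L, 80L)))
  lc0 <- lorenz_curve(tab0, "beds", "population")
  expect_equal(lc0$x, c(0, 0.5, 1))
  expect_equal(lc0$y, c(0, 0, 1))

  # on the real data the curve lies on/below the diagonal in both dimensions
  for (dim in c("area", "population")) {
    for (rc in resource_names(china)) {
      lc <- lorenz_curve(china, rc, dim)
      expect_true(all(diff(lc$x) > 0))
      expect_true(all(diff(lc$y) >= 0))
      expect_true(all(lc$y <= lc$x + 1e-12))
    }
  }
  expect_error(lorenz_curve(china, "nurses", "area"), "unknown resource")
})

test_that("trapezoid Gini reproduces published values and closed forms", {
  expect_within(gini(china, "institutions", "area")$gini, 0.685, 0.005)
  expect_within(gini(china, "beds", "population")$gini, 0.159, 0.005)
  # perfectly equal allocation
  expect_equal(gini(uniform_table(), "beds", "area")$gini, 0)
  # one-kink curve: G = p - q
  g <- gini(two_group_table(0.8, 0.5, "population"), "resource", "population")
  expect_equal(g$gini, 0.3, tolerance = 1e-12)
  # invalid curves are rejected
  bad <- data.frame(x = c(0, 0.5, 0.4, 1), y = c(0, 0.2, 0.3, 1))
  expect_error(gini_trapezoid(bad), "strictly increasing")
  expect_error(gini_trapezoid(data.frame(x = c(0, 1), y = c(0.5, 1))),
               "\\(0,0\\) to \\(1,1\\)")
})

test_that("pairwise oracle agrees with the trapezoid formula", {
  for (rc in resource_names(china)) {
    expect_equal(gini(china, rc, "area")$gini,
                 gini_pairwise_oracle(china[[rc]], china$area),
                 tolerance = 1e-12)
    expect_equal(gini(china, rc, "population")$gini,
                 gini_pairwise_oracle(china[[rc]], china$population_65plus),
                 tolerance = 1e-12)
  }
  expect_equal(gini_pairwise_oracle(c(10, 20, 30), c(1, 2, 3)), 0)
  expect_equal(gini_pairwise_oracle(c(5e7, 5e7), c(8e7, 2e7)), 0.3,
               tolerance = 1e-12)
  expect_error(gini_pairwise_oracle(c(0, 0), c(1, 1)), "all values zero")
})

test_that("Gini is invariant to row order, tie order and count scaling", {
  set.seed(404)
  g0 <- gini(china, "beds", "area")$gini
  for (i in 1:5) {
    shuffled <- province_table(
      as.data.frame(china)[sample(nrow(china)), , drop = FALSE],
      resources = resource_names(china))
    expect_equal(gini(shuffled, "beds", "area")$gini, g0, tolerance = 1e-14)
  }
  scaled <- as.data.frame(china)
  scaled$beds <- scaled$beds * 7L
  expect_equal(gini(province_table(scaled, resources = resource_names(china)),
                    "beds", "area")$gini, g0, tolerance = 1e-14)

  # exact density ties: permuting tied rows leaves G unchanged
  tied <- data.frame(
    name = c("A", "B", "C"), region = "r", area = c(2, 1, 1),
    population_65plus = c(100L, 100L, 100L), beds = c(10L, 5L, 40L))
  g1 <- gini(province_table(tied), "beds", "area")$gini
  g2 <- gini(province_table(tied[c(2, 1, 3), ]), "beds", "area")$gini
  expect_equal(g1, g2, tolerance = 1e-15)
})

test_that("transferring resource from lowest- to highest-density unit never decreases G", {
  set.seed(77)
  for (i in 1:20) {
    tab <- random_table()
    dens <- tab$beds / tab$area
    lo <- which.min(dens)
    hi <- which.max(dens)
    if (lo == hi || tab$beds[lo] == 0) next
    g_before <- gini(tab, "beds", "area")$gini
    moved <- as.data.frame(tab)
    k <- max(1L, floor(moved$beds[lo] / 2))
    moved$beds[lo] <- moved$beds[lo] - k
    moved$beds[hi] <- moved$beds[hi] + k
    g_after <- gini(province_table(moved), "beds", "area")$gini
    expect_gte(g_after, g_before - 1e-12)
  }
})

test_that("Gini bands follow the five-level equity scale", {
  expect_equal(classify_gini(0.685), "high_inequity")
  expect_equal(classify_gini(0.159), "absolute_equity")
  expect_equal(classify_gini(0.35), "basic_equity")
  expect_equal(classify_gini(c(0, 0.2, 0.3, 0.4, 0.5)),
               c("absolute_equity", "equity", "basic_equity", "inequity",
                 "high_inequity"))
  expect_error(classify_gini(1.2), "\\[0, 1\\)")
  expect_error(classify_gini(-0.1), "\\[0, 1\\)")
})

test_that("staff proportions reproduce published percentages", {
  sp <- staff_proportions(china)
  expect_true(all(sp$available))
  expect_within(sp$age_le35_pct[sp$unit == "Tibet"], 68.13, 0.005)
  # national structure from the column totals
  expect_within(100 * sum(china$age_46_55) / china_tot$employees, 34.82,
                0.005)
  # age percentages sum to 100 where bins sum to the employee total
  age_cols <- c("age_le35_pct", "age_36_45_pct", "age_46_55_pct",
                "age_ge56_pct")
  expect_equal(rowSums(sp[age_cols]), rep(100, nrow(sp)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # tables without staff columns yield an unavailable result, not an error
  sp0 <- staff_proportions(toy_table())
  expect_false(any(sp0$available))
  expect_true(all(is.na(sp0$age_le35_pct)))
})
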