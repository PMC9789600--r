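std_grid <- function(est = c(2, 4, 6), lower = est - 1, upper = est + 1,
                     province = "Iran", year = 2000, sex = "both",
                     index = "dmft") {
  data.frame(province = province, year = year,
             age_group = c("1-4", "5-9", "10-14"), sex = sex, index = index,
             estimate = est, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

test_that("direct age standardisation is the share-weighted average", {
  w_eq <- as_population_weights(c("1-4", "5-9", "10-14"), c(1, 1, 1))
  s <- age_standardize(std_grid(), w_eq)
  expect_equal(s$estimate, 4)
  expect_equal(s$lower, 3)
  expect_equal(s$upper, 5)

  w_first <- as_population_weights(c("1-4", "5-9", "10-14"), c(1, 0, 0))
  expect_equal(age_standardize(std_grid(), w_first)$estimate, 2)

  w <- as_population_weights(c("1-4", "5-9", "10-14"), c(0.2, 0.3, 0.5))
  s3 <- age_standardize(std_grid(est = c(3.01, 5.06, 7.06)), w)
  expect_equal(s3$estimate, 0.2 * 3.01 + 0.3 * 5.06 + 0.5 * 7.06)  # 5.650

  expect_error(age_standardize(std_grid(), as_population_weights("1-4", 1)),
               "no population weight")
})

test_that("standardisation is idempotent on constants and linear", {
  w <- as_population_weights(c("1-4", "5-9", "10-14"), c(2, 5, 3))
  expect_equal(age_standardize(std_grid(est = rep(3.3, 3)), w)$estimate, 3.3)
  g1 <- std_grid(est = c(1, 2, 3))
  g2 <- std_grid(est = c(5, 1, 4))
  gl <- std_grid(est = 2 * g1$estimate + 0.5 * g2$estimate)
  expect_equal(age_standardize(gl, w)$estimate,
               2 * age_standardize(g1, w)$estimate +
                 0.5 * age_standardize(g2, w)$estimate)
})

test_that("percent change, component share and experience fraction", {
  expect_equal(percent_change(4.37, 5.03), 15.103, tolerance = 1e-4)
  expect_equal(percent_change(3.64, 4.27), 17.308, tolerance = 1e-4)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 1), "v_start")

  expect_equal(component_share(3.64, 4.37), 83.295, tolerance = 1e-3)
  expect_equal(component_share(0.30, 4.37), 6.865, tolerance = 1e-3)
  expect_equal(component_share(0, 5), 0)
  expect_error(component_share(1, 0), "total")

  expect_equal(experience_fraction(4.37), 21.85)
  expect_equal(experience_fraction(0), 0)
  expect_equal(experience_fraction(20), 100)
  expect_error(experience_fraction(21), "\\[0, 20\\]")
})

test_that("provincial range finds the extremes with documented tie-breaks", {
  tab <- data.frame(province = c("Ardabil", "Bushehr", "Markazi"),
                    year = 1990, sex = "both", index = "dmft",
                    estimate = c(5.30, 2.91, 4.0), stringsAsFactors = FALSE)
  r <- provincial_range(tab, 1990, "both", "dmft")
  expect_equal(r$max_province, "Ardabil")
  expect_equal(r$min_province, "Bushehr")
  expect_equal(r$difference, 2.39)
  expect_false(r$tie)

  tab17 <- data.frame(province = c("Kurdistan", "Bushehr"), year = 2017,
                      sex = "both", index = "dmft",
                      estimate = c(6.03, 3.89), stringsAsFactors = FALSE)
  expect_equal(provincial_range(tab17, 2017, "both", "dmft")$difference, 2.14)

  # permutation invariance of the result
  perm <- tab[c(3, 1, 2), ]
  expect_identical(provincial_range(perm, 1990, "both", "dmft"),
                   provincial_range(tab, 1990, "both", "dmft"))

  ties <- transform(tab, estimate = 1)
  rt <- provincial_range(ties, 1990, "both", "dmft")
  expect_true(rt$tie)
  expect_equal(rt$difference, 0)
  expect_equal(rt$max_province, "Ardabil")   # first canonical label
  expect_error(provincial_range(tab[1, ], 1990, "both", "dmft"),
               "at least two")
})

test_that("the trend table formats point (lower, upper) cells", {
  g <- load_table1_fixture()
  tt <- make_trend_table(g, years = c(1990, 2017))
  expect_equal(tt$dmft_both[tt$age_group == "all" & tt$year == 1990],
               "4.37 (2.23, 6.62)")
  expect_equal(tt$dt_both[tt$age_group == "all" & tt$year == 2017],
               "4.27 (1.96, 6.57)")
  expect_equal(tt$mt_both[tt$age_group == "10-14" & tt$year == 1990],
               "0.90 (0.48, 1.32)")
  expect_setequal(tt$age_group, c("1-4", "5-9", "10-14", "all"))
  expect_error(make_trend_table(g, years = 1995), "absent")
})

test_that("a single-age grid reports itself as the all-ages row", {
  g <- std_grid()[1, ]
  tt <- make_trend_table(g, years = 2000, sexes = "both", indices = "dmft")
  expect_equal(tt$dmft_both[tt$age_group == "all"],
               tt$dmft_both[tt$age_group == "1-4"])
})

test_that("all-ages rows aggregate by population shares when absent", {
  w <- as_population_weights(c("1-4", "5-9", "10-14"), c(0.25, 0.5, 0.25))
  g <- std_grid(est = c(2, 4, 6))
  tt <- make_trend_table(g, years = 2000, weights = w, sexes = "both",
                         indices = "dmft")
  expect_equal(tt$dmft_both[tt$age_group == "all"], "4.00 (3.00, 5.00)")
  expect_error(make_trend_table(g, years = 2000, sexes = "both",
                                indices = "dmft"), "population weights")
})

test_that("national aggregation averages provinces with optional weights", {
  g <- rbind(std_grid(province = "A", est = c(2, 4, 6)),
             std_grid(province = "B", est = c(4, 6, 8)))
  nat <- aggregate_national(g)
  expect_equal(nat$estimate[nat$age_group == "1-4"], 3)
  natw <- aggregate_national(g, province_weights = c(A = 3, B = 1))
  expect_equal(natw$estimate[natw$age_group == "1-4"], 2.5)
  expect_error(aggregate_national(g, province_weights = c(A = 1)), "weight")
})
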