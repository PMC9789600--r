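kp3 <- function(years = 1990:2017, lambda = 2, varpi = 1,
                labels = c("A", "B", "C"))
  kernel_params(path_adjacency(labels), years = years, lambda = lambda,
                varpi = varpi)

test_that("temporal weights follow the tricube closed form", {
  kp <- kp3()                                  # normaliser 28
  expect_equal(temporal_weight(2000, 2000, kp), 1)
  expect_equal(temporal_weight(1990, 2017, kp),
               (1 - (27 / 28)^2)^3, tolerance = 1e-12)
  expect_equal(temporal_weight(1990, 2017, kp), 3.4534e-4, tolerance = 1e-3)
  expect_equal(temporal_weight(1990, 2004, kp), (1 - 0.25)^3)   # 0.421875
  # bounds and strict monotonicity over every lag in range
  w <- temporal_weight(1990, 1990:2017, kp)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w) < 0))
})

test_that("age weights decay exponentially in group distance", {
  kp <- kp3()
  expect_equal(age_weight("1-4", "1-4", kp), 1)
  expect_equal(age_weight("1-4", "5-9", kp), exp(-1))
  expect_equal(age_weight("1-4", "10-14", kp), exp(-2))
  expect_equal(age_weight(1, 3, kp), exp(-2))  # integer positions too
  kp5 <- kp3(varpi = 0.5)
  expect_equal(age_weight("1-4", "10-14", kp5), exp(-1))
  w <- age_weight(1, 1:3, kp)
  expect_true(all(w > 0 & w <= 1) && all(diff(w) < 0))
})

test_that("spatial weights are binary, symmetric, with unit self-weight", {
  adj <- path_adjacency(c("A", "B", "C"))
  expect_equal(spatial_weight("A", "A", adj), 1)
  expect_equal(spatial_weight("A", "B", adj), 1)
  expect_equal(spatial_weight("A", "C", adj), 0)
  expect_error(spatial_weight("A", "Z", adj), "unknown province")
  radj <- synthetic_adjacency(10, seed = 5)
  p <- radj$provinces
  for (a in p) for (b in p)
    expect_identical(spatial_weight(a, b, radj), spatial_weight(b, a, radj))
})

test_that("combined weights normalise the kernel product over sources", {
  kp <- kp3()
  target <- list(province = "A", year = 2000, age_group = "1-4")
  # single source identical to the target gets all the weight
  src1 <- data.frame(province = "A", year = 2000, age_group = "1-4")
  expect_equal(combined_weights(target, src1, kp)$weights, 1)
  # two sources with equal raw weight split it evenly
  src2 <- data.frame(province = c("A", "A"), year = c(2001, 1999),
                     age_group = "1-4")
  expect_equal(combined_weights(target, src2, kp)$weights, c(0.5, 0.5))
  # raw weights (1, e^-1, 0) -> (0.731, 0.269, 0)
  src3 <- data.frame(province = c("A", "A", "C"), year = 2000,
                     age_group = c("1-4", "5-9", "1-4"))
  w <- combined_weights(target, src3, kp)
  expect_false(w$fallback)
  expect_equal(w$weights,
               c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1)), 0),
               tolerance = 1e-12)
  expect_equal(round(w$weights, 3), c(0.731, 0.269, 0))
  expect_error(combined_weights(target, src3[0, ], kp), "no source")
})

test_that("targets with no spatially reachable source fall back and flag", {
  kp <- kp3()
  target <- list(province = "C", year = 2000, age_group = "1-4")
  src <- data.frame(province = "A", year = c(2000, 2001), age_group = "1-4")
  w <- combined_weights(target, src, kp)       # C only borders B
  expect_true(w$fallback)
  expect_equal(sum(w$weights), 1)
  raw <- temporal_weight(2000, c(2000, 2001), kp)
  expect_equal(w$weights, raw / sum(raw))
})

test_that("the vectorised smoother equals an explicit loop to 1e-12", {
  set.seed(31)
  for (rep in 1:3) {
    labels <- sprintf("P%d", 1:5)
    lat <- small_lattice(labels = labels, years = 2001:2005,
                         age_groups = c("1-4", "5-9", "10-14"),
                         adjacency = synthetic_adjacency(labels,
                                                         seed = 100 + rep))
    kp <- kernel_params(lat$adjacency, years = lat$years)
    cells <- expand.grid(province = labels, year = lat$years,
                         age_group = lat$age_groups, stringsAsFactors = FALSE)
    picked <- cells[sample(nrow(cells), 18), ]
    res <- data.frame(picked, sex = "female", index = "dmft",
                      residual = rnorm(18), stringsAsFactors = FALSE)
    fast <- smooth_residuals(res, lat, kp)
    slow <- naive_smooth(res, lat, kp)
    key <- function(d) paste(d$province, d$year, d$age_group)
    m <- match(key(fast), key(slow))
    expect_lt(max(abs(fast$smoothed - slow$smoothed[m])), 1e-12)
    expect_identical(fast$fallback, slow$fallback[m])
  }
})

test_that("smoothing preserves constants and is linear", {
  lat <- small_lattice(years = 2000:2004)
  kp <- kernel_params(lat$adjacency, years = lat$years,
                      age_groups = lat$age_groups)
  base <- data.frame(province = c("A", "B", "C", "A"),
                     year = c(2000, 2001, 2003, 2004),
                     age_group = c("1-4", "5-9", "1-4", "5-9"),
                     sex = "male", index = "dmft", stringsAsFactors = FALSE)
  const <- transform(base, residual = 2.5)
  sc <- smooth_residuals(const, lat, kp)
  expect_equal(sc$smoothed, rep(2.5, nrow(sc)), tolerance = 1e-12)

  set.seed(5)
  r1 <- transform(base, residual = rnorm(4))
  r2 <- transform(base, residual = rnorm(4))
  lin <- transform(base, residual = 1.5 * r1$residual - 2 * r2$residual)
  s1 <- smooth_residuals(r1, lat, kp)$smoothed
  s2 <- smooth_residuals(r2, lat, kp)$smoothed
  s12 <- smooth_residuals(lin, lat, kp)$smoothed
  expect_equal(s12, 1.5 * s1 - 2 * s2, tolerance = 1e-12)
  expect_error(smooth_residuals(const[0, ], lat, kp), "empty residual")
})

test_that("concentrated kernels return an observed cell's own residual", {
  # temporal weight pinned to lag 0 (tiny lambda) and age weight pinned to
  # distance 0 (huge varpi); observed residuals only in province A, so the
  # target (A, 2001, 1-4) sees no same-year adjacent source either
  lat <- small_lattice(labels = c("A", "B"), years = 2000:2002,
                       adjacency = path_adjacency(c("A", "B")))
  kp <- kernel_params(lat$adjacency, years = lat$years, lambda = 1e-9,
                      varpi = 50, age_groups = lat$age_groups)
  res <- data.frame(province = "A", year = 2000:2002, age_group = "1-4",
                    sex = "female", index = "dmft",
                    residual = c(1.25, -0.5, 3), stringsAsFactors = FALSE)
  sm <- smooth_residuals(res, lat, kp)
  at <- function(y) sm$smoothed[sm$province == "A" & sm$year == y &
                                  sm$age_group == "1-4"]
  expect_equal(at(2000), 1.25, tolerance = 1e-6)
  expect_equal(at(2001), -0.5, tolerance = 1e-6)
  expect_equal(at(2002), 3, tolerance = 1e-6)
})
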