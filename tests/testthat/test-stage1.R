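# a hand-specified fit used for arithmetic-level prediction checks:
# beta = (1, 0.5) on covariate schooling, province effect 0.3, year effect -0.1
hand_fit <- function() {
  new_stage1_fit(beta = c("(Intercept)" = 1, schooling = 0.5),
                 vcov_beta = diag(0, 2),
                 re_province = c(A = 0.3), re_year = c("2000" = -0.1),
                 fixed_formula = ~schooling, index = "dmft")
}

hand_cells <- function(year = 2000, province = "A") {
  data.frame(province = province, year = year, age_group = "1-4",
             sex = "female", schooling = 2, wealth = 0, age_weight = 0.3,
             stringsAsFactors = FALSE)
}

test_that("prediction is fixed part plus both fitted intercepts", {
  lp <- dmftrend:::stage1_linpred(hand_fit(), hand_cells())
  expect_equal(lp$fitted, 1 + 0.5 * 2 + 0.3 - 0.1)    # 2.2
  expect_false(lp$novel_province)
  expect_false(lp$novel_year)
})

test_that("unseen levels predict at the population mean and are flagged", {
  lp <- dmftrend:::stage1_linpred(hand_fit(), hand_cells(year = 2005))
  expect_equal(lp$fitted, 1 + 0.5 * 2 + 0.3)          # year effect dropped
  expect_true(lp$novel_year)
  lp2 <- dmftrend:::stage1_linpred(hand_fit(), hand_cells(province = "B"))
  expect_true(lp2$novel_province)
  expect_equal(lp2$fitted, 1 + 0.5 * 2 - 0.1)
})

test_that("residuals are observation minus prediction", {
  fit <- new_stage1_fit(beta = c("(Intercept)" = 4.2), vcov_beta = matrix(0),
                        re_province = numeric(0), re_year = numeric(0),
                        fixed_formula = ~1, index = "dmft")
  obs <- as_observations(obs_rows(mean = 5.0, year = 2000), years = 2000)
  lat <- small_lattice(labels = "A", years = 2000,
                       adjacency = path_adjacency(c("A", "B")))
  res <- stage1_residuals(fit, obs, flat_covariates(lat))
  expect_equal(res$residual, 0.8)
  expect_equal(res$fitted, 4.2)
})

test_that("noise-free synthetic data recover beta exactly and kill the REs", {
  lat <- default_lattice(8, seed = 5)
  beta <- c(intercept = 3, sexmale = 0.4, schooling = -0.2, wealth = -0.5,
            age_weight = 2)
  tp <- truth_params(beta = beta, sigma_province = 0, sigma_year = 0,
                     sigma_eps = 0, field = list(sd = 0))
  tr <- generate_truth(tp, lat, seed = 6)
  obs <- sample_observations(tr, survey_design(coverage = 1, sigma_obs = 0.01),
                             seed = 7)
  fit <- fit_stage1(obs, tr$covariates, stage1_spec("dmft"))
  nm <- c("(Intercept)", "sexmale", "schooling", "wealth", "age_weight")
  expect_equal(unname(fit$beta[nm]), unname(beta), tolerance = 0.02)
  expect_lt(fit$sigma_province, 1e-2)
  expect_lt(fit$sigma_year, 1e-2)
  expect_true(fit$converged)
})

test_that("predictions plus residuals reproduce the observations exactly", {
  lat <- default_lattice(6, seed = 2)
  tr <- generate_truth(truth_params(), lat, seed = 3)
  obs <- sample_observations(tr, survey_design(), seed = 4)
  fit <- fit_stage1(obs, tr$covariates, stage1_spec("dmft"))
  res <- stage1_residuals(fit, obs, tr$covariates)
  expect_equal(res$fitted + res$residual, res$mean, tolerance = 1e-12)
})

test_that("adding a constant shifts only the intercept", {
  lat <- default_lattice(6, seed = 2)
  tr <- generate_truth(truth_params(sigma_eps = 0.3, field = list(sd = 0)),
                       lat, seed = 3)
  obs <- sample_observations(tr, survey_design(), seed = 4)
  fit0 <- fit_stage1(obs, tr$covariates, stage1_spec("dmft"))
  obs2 <- obs
  obs2$mean <- pmin(obs2$mean + 2, 20)
  fit2 <- fit_stage1(obs2, tr$covariates, stage1_spec("dmft"))
  expect_equal(fit2$beta[["(Intercept)"]] - fit0$beta[["(Intercept)"]], 2,
               tolerance = 1e-4)
  other <- setdiff(names(fit0$beta), "(Intercept)")
  expect_equal(fit2$beta[other], fit0$beta[other], tolerance = 1e-4)
})

test_that("unidentifiable or degenerate designs fail loudly", {
  lat <- small_lattice()
  covs <- flat_covariates(lat)
  one_prov <- as_observations(
    obs_rows(province = "A", year = c(2000, 2000, 2000),
             age_group = c("1-4", "5-9", "1-4"),
             sex = c("female", "female", "male"), mean = c(1, 2, 3)),
    years = 2000:2002)
  expect_error(fit_stage1(one_prov, covs, stage1_spec("dmft")),
               "single-province")

  # collinear fixed design: wealth duplicated into schooling
  lat6 <- default_lattice(6, seed = 2)
  tr <- generate_truth(truth_params(), lat6, seed = 3)
  obs <- sample_observations(tr, survey_design(), seed = 4)
  covs2 <- tr$covariates
  covs2$schooling <- covs2$wealth
  expect_error(fit_stage1(obs, covs2, stage1_spec("dmft")),
               "collinear.*wealth")

  # missing covariate cells are listed
  covs3 <- tr$covariates[tr$covariates$year != 1990, ]
  expect_error(fit_stage1(obs, covs3, stage1_spec("dmft")),
               "missing covariate cell")
  expect_error(stage1_spec(random = "province"), "province, year")
})

test_that("stage-1 residual variance tracks sigma_eps^2 + sigma_obs^2", {
  lat <- default_lattice(20, seed = 8)
  tp <- truth_params(sigma_eps = 0.5, field = list(sd = 0))
  tr <- generate_truth(tp, lat, seed = 9)
  des <- survey_design(coverage = 1, n_per_cell = 400, sigma_obs = 4)
  obs <- sample_observations(tr, des, seed = 10)
  fit <- fit_stage1(obs, tr$covariates, stage1_spec("dmft"))
  res <- stage1_residuals(fit, obs, tr$covariates)
  expected <- 0.5^2 + (4 / sqrt(400))^2        # 0.29
  expect_lt(abs(var(res$residual) / expected - 1), 0.15)
})
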