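# order age-group labels by their lower age bound
order_age_groups <- function(x) {
  x <- unique(canon_age(x))
  lo <- suppressWarnings(as.numeric(sub("-.*$", "", x)))
  x[order(lo, x)]
}

#' Specification of the stage-1 mixed-effects model
#'
#' One index is regressed on fixed covariates with crossed random intercepts
#' for province and year.  Sex enters as a fixed-effect indicator (reference
#' level `female`); age enters through age-group indicator terms plus the
#' continuous within-group age weight.
#'
#' @param index which index to model: one of `dmft`, `dt`, `mt`, `ft`.
#' @param fixed ordered fixed-effect terms (besides the intercept); any
#'   subset of `sex`, `schooling`, `wealth`, `age_weight`, `age_group`.
#' @param random random-intercept grouping terms; the default configuration
#'   is exactly `province` and `year`.
#' @param method `"REML"` (restricted likelihood, default) or `"ML"`.
#' @param weighted when `TRUE`, observations are weighted by `1/se^2`
#'   (inverse variance); default is equal weighting.
#' @return an object of class `dmft_stage1_spec`.
#' @export
stage1_spec <- function(index = "dmft",
                        fixed = c("sex", "schooling", "wealth", "age_weight",
                                  "age_group"),
                        random = c("province", "year"),
                        method = c("REML", "ML"), weighted = FALSE) {
  index <- match.arg(tolower(index), .indices)
  method <- match.arg(method)
  ok <- c("sex", "schooling", "wealth", "age_weight", "age_group")
  bad <- setdiff(fixed, ok)
  if (length(bad)) stop_dmft("unknown fixed term(s): ", paste(bad, collapse = ", "))
  if (!setequal(random, c("province", "year")))
    stop_dmft("random terms must be exactly {province, year}")
  structure(list(index = index, fixed = fixed, random = random,
                 method = method, weighted = isTRUE(weighted)),
            class = "dmft_stage1_spec")
}

#' Construct a stage-1 fit object from components
#'
#' Low-level constructor, used by [fit_stage1()] and useful for building
#' degenerate fits in worked examples.  `fixed_formula` is the one-sided
#' fixed-effects formula used to rebuild design matrices at prediction time.
#'
#' @param beta named fixed-effect coefficient vector.
#' @param vcov_beta its covariance matrix (symmetric PSD).
#' @param re_province,re_year named vectors of fitted random intercepts.
#' @param condsd_province,condsd_year conditional (posterior) sds of those
#'   intercepts, same names.
#' @param sigma_province,sigma_year,sigma_eps fitted sds (`>= 0`).
#' @param fixed_formula one-sided formula for the fixed design.
#' @param xlev factor levels used at fit time (as in [stats::model.matrix()]).
#' @param index index fitted.
#' @param method estimation method label.
#' @param converged logical convergence status.
#' @param logLik fit log-likelihood (or REML criterion).
#' @param n_obs number of observations used.
#' @return an object of class `dmft_stage1_fit`.
#' @export
new_stage1_fit <- function(beta, vcov_beta, re_province, re_year,
                           condsd_province = re_province * 0,
                           condsd_year = re_year * 0,
                           sigma_province = 0, sigma_year = 0, sigma_eps = 0,
                           fixed_formula = ~1, xlev = list(), index = "dmft",
                           method = "REML", converged = TRUE, logLik = NA_real_,
                           n_obs = NA_integer_) {
  vcov_beta <- as.matrix(vcov_beta)
  if (!isSymmetric(unname(vcov_beta), tol = 1e-8))
    stop_dmft("vcov_beta must be symmetric")
  if (min(sigma_province, sigma_year, sigma_eps) < 0)
    stop_dmft("variances must be >= 0")
  structure(list(beta = beta, vcov_beta = vcov_beta,
                 re_province = re_province, re_year = re_year,
                 condsd_province = condsd_province, condsd_year = condsd_year,
                 sigma_province = sigma_province, sigma_year = sigma_year,
                 sigma_eps = sigma_eps, fixed_formula = fixed_formula,
                 xlev = xlev, index = index, method = method,
                 converged = converged, logLik = logLik, n_obs = n_obs,
                 sex_coding = "indicator sexmale; reference level female"),
            class = "dmft_stage1_fit")
}

# merge observation rows with covariate values; error on missing cells
join_covariates <- function(x, covariates) {
  m <- match(cell_key(x$province, x$year, x$age_group),
             cell_key(covariates$province, covariates$year,
                      covariates$age_group))
  if (anyNA(m)) {
    miss <- unique(paste(x$province, x$year, x$age_group, sep = "/")[is.na(m)])
    stop_dmft("missing covariate cell(s): ",
              paste(utils::head(miss, 5), collapse = ", "),
              if (length(miss) > 5) ", ...")
  }
  cbind(x, covariates[m, c("schooling", "wealth", "age_weight"), drop = FALSE])
}

# prepare a modelling frame with stable factor codings
stage1_frame <- function(df, xlev = NULL) {
  df$sex <- factor(tolower(df$sex), levels = xlev$sex %||% .sexes)
  ag_lev <- xlev$age_group %||% order_age_groups(df$age_group)
  df$age_group <- factor(canon_age(df$age_group), levels = ag_lev)
  if (anyNA(df$sex) || anyNA(df$age_group))
    stop_dmft("factor level absent from the fitted model: cannot code cell")
  df
}

#' Fit the stage-1 random-intercept mixed-effects model
#'
#' Fits, for one index, `mean ~ fixed terms + (1 | province) + (1 | year)`
#' with crossed (not nested) random intercepts, via restricted likelihood by
#' default.  The fixed design is checked for rank deficiency before fitting
#' (collinear terms are named in the error), and random intercepts require at
#' least two provinces and two distinct years.  Non-convergence is reported
#' in the returned object, never silently accepted.
#'
#' @param obs a `dmft_obs` observation table (rows of other indices are
#'   ignored).
#' @param covariates a `dmft_covariates` table covering every observed cell.
#' @param spec a [stage1_spec()].
#' @return a `dmft_stage1_fit` (see [new_stage1_fit()] for the fields).
#' @examples
#' lat <- default_lattice(6, seed = 2)
#' tr <- generate_truth(truth_params(), lat, seed = 3)
#' obs <- sample_observations(tr, survey_design(), seed = 4)
#' fit <- fit_stage1(obs, tr$covariates, stage1_spec("dmft"))
#' fit$beta
#' @export
fit_stage1 <- function(obs, covariates, spec = stage1_spec()) {
  df <- as.data.frame(obs)[tolower(obs$index) == spec$index, , drop = FALSE]
  if (!nrow(df)) stop_dmft("no observations for index ", spec$index)
  if (length(unique(canon_label(df$province))) < 2L)
    stop_dmft("single-province data: province random intercept unidentifiable")
  if (length(unique(df$year)) < 2L)
    stop_dmft("single-year data: year random intercept unidentifiable")
  df <- join_covariates(df, covariates)
  df <- stage1_frame(df)
  df$yearf <- factor(df$year)

  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  fixed_formula <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(fixed_formula, df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_dmft("rank-deficient fixed design; collinear term(s): ",
              paste(dropped, collapse = ", "))
  }

  w <- NULL
  if (spec$weighted) {
    if (anyNA(df$se)) stop_dmft("weighted fit requested but se is missing")
    w <- 1 / df$se^2
  }
  form <- stats::as.formula(
    paste("mean ~", rhs, "+ (1 | province) + (1 | yearf)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- withCallingHandlers(
    lme4::lmer(form, data = df, REML = spec$method == "REML", weights = w,
               control = ctrl),
    warning = function(wng) invokeRestart("muffleWarning"))
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L

  re <- lme4::ranef(fit, condVar = TRUE)
  pull_re <- function(component) {
    eff <- stats::setNames(component[["(Intercept)"]], rownames(component))
    pv <- attr(component, "postVar")
    list(effect = eff, condsd = stats::setNames(sqrt(pv[1, 1, ]),
                                                rownames(component)))
  }
  rp <- pull_re(re$province)
  ry <- pull_re(re$yearf)
  vc <- lme4::VarCorr(fit)

  out <- new_stage1_fit(
    beta = lme4::fixef(fit),
    vcov_beta = as.matrix(stats::vcov(fit)),
    re_province = rp$effect, re_year = ry$effect,
    condsd_province = rp$condsd, condsd_year = ry$condsd,
    sigma_province = attr(vc$province, "stddev")[[1]],
    sigma_year = attr(vc$yearf, "stddev")[[1]],
    sigma_eps = stats::sigma(fit),
    fixed_formula = fixed_formula,
    xlev = list(sex = levels(df$sex), age_group = levels(df$age_group)),
    index = spec$index, method = spec$method, converged = conv,
    logLik = as.numeric(stats::logLik(fit)), n_obs = nrow(df))
  if (!conv)
    warning("fit_stage1: optimizer reported non-convergence for index ",
            spec$index, call. = FALSE)
  out
}

# linear predictor (fixed part + fitted random intercepts) on arbitrary cells
stage1_linpred <- function(fit, df) {
  df <- stage1_frame(df, fit$xlev)
  X <- stats::model.matrix(fit$fixed_formula, df)
  if (!all(colnames(X) %in% names(fit$beta)))
    stop_dmft("design columns not covered by fitted coefficients")
  fixed <- as.numeric(X %*% fit$beta[colnames(X)])
  u <- fit$re_province[as.character(df$province)]
  a <- fit$re_year[as.character(df$year)]
  novel_province <- is.na(u)
  novel_year <- is.na(a)
  u[novel_province] <- 0
  a[novel_year] <- 0
  list(fitted = fixed + as.numeric(u) + as.numeric(a),
       novel_province = novel_province, novel_year = novel_year)
}

#' Predict the stage-1 surface on a complete lattice
#'
#' Point prediction at every (province, year, age group, sex) cell: fixed
#' part plus fitted province and year intercepts.  Provinces or years unseen
#' at fit time receive a random-effect contribution of 0 (the population
#' mean) and are flagged.
#'
#' @param fit a `dmft_stage1_fit`.
#' @param covariates a `dmft_covariates` table, complete on the lattice.
#' @param lattice a [lattice_spec()].
#' @return data.frame with one row per lattice cell: `province`, `year`,
#'   `age_group`, `sex`, `index`, `fitted`, and logical flags
#'   `novel_province`, `novel_year`.
#' @export
predict_stage1 <- function(fit, covariates, lattice) {
  cells <- lattice_cells(lattice)
  full <- do.call(rbind, lapply(lattice$sexes, function(s)
    data.frame(cells, sex = s, stringsAsFactors = FALSE)))
  full <- join_covariates(full, covariates)
  lp <- stage1_linpred(fit, full)
  out <- data.frame(full[, c("province", "year", "age_group", "sex")],
                    index = fit$index, fitted = lp$fitted,
                    novel_province = lp$novel_province,
                    novel_year = lp$novel_year, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Stage-1 residuals at the observed cells
#'
#' `residual = observed mean - stage-1 prediction`, keyed like the
#' observation table; the input to [smooth_residuals()].
#'
#' @param fit a `dmft_stage1_fit`.
#' @param obs a `dmft_obs` table (rows of other indices are ignored).
#' @param covariates covariates for the observed cells.
#' @return data.frame with the observation keys plus `fitted` and `residual`.
#' @export
stage1_residuals <- function(fit, obs, covariates) {
  df <- as.data.frame(obs)[tolower(obs$index) == fit$index, , drop = FALSE]
  if (!nrow(df)) stop_dmft("no observations for index ", fit$index)
  dfc <- join_covariates(df, covariates)
  lp <- stage1_linpred(fit, dfc)
  out <- df[, c("province", "year", "age_group", "sex", "index", "mean",
                "se", "n")]
  out$fitted <- lp$fitted
  out$residual <- df$mean - lp$fitted
  rownames(out) <- NULL
  out
}
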