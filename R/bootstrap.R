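#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates (default 1000).  Fewer than 40
#'   replicates make 95% percentile endpoints unstable and trigger a warning
#'   at run time.
#' @param level interval level in `(0, 1)` (default 0.95).
#' @param seed integer RNG seed; the whole replicate stream is deterministic
#'   given it.
#' @param propagate_smoothing re-run the residual smoothing inside every
#'   replicate (default).  The kernel weights are deterministic, so this is a
#'   fixed linear map applied to each replicate's residual field; turning it
#'   off reuses the point-fit smoothed surface (cheaper for very large B).
#' @return an object of class `dmft_bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000L, level = 0.95, seed = 1L,
                             propagate_smoothing = TRUE) {
  if (!is.numeric(B) || B < 1) stop_dmft("B must be >= 1")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_dmft("level must lie in (0, 1)")
  structure(list(B = as.integer(B), level = level, seed = as.integer(seed),
                 propagate_smoothing = isTRUE(propagate_smoothing)),
            class = "dmft_bootstrap_config")
}

#' Percentile interval bounds from replicate values
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` using
#' linear interpolation between the closest order statistics
#' ([stats::quantile()] type 7), fixed for reproducibility.
#'
#' @param samples numeric vector of replicate values for one cell (length
#'   `>= 1`).
#' @param level interval level.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' percentile_bounds(1:100, 0.95)  # c(3.475, 97.525)
#' @export
percentile_bounds <- function(samples, level = 0.95) {
  if (!length(samples)) stop_dmft("percentile_bounds: empty sample vector")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, probs = c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

# eigenvalue check / repair of the fixed-effect covariance matrix
check_psd <- function(V, repair = FALSE) {
  dn <- dimnames(V)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ev$values), 1e-12)
  if (min(ev$values) < -tol) {
    if (!repair)
      stop_dmft("fixed-effect covariance is not positive semi-definite; ",
                "re-run with repair_vcov = TRUE to project onto the nearest ",
                "PSD matrix")
    ev$values <- pmax(ev$values, 0)
    V <- ev$vectors %*% diag(ev$values, length(ev$values)) %*% t(ev$vectors)
  }
  dimnames(V) <- dn
  V
}

#' Parametric multilevel-bootstrap uncertainty intervals
#'
#' Produces percentile uncertainty intervals for every lattice cell by
#' resampling the fitted stage-1 model: each replicate draws the fixed
#' effects from `MVN(beta_hat, Vcov)`, the fitted province and year
#' intercepts from normal distributions centred on their predicted values
#' with their conditional sds (random-effect levels absent from the fit --
#' e.g. unsurveyed years -- are drawn from the fitted population distribution
#' `N(0, sigma^2)` of that term), rebuilds the lattice surface, re-propagates
#' the residual smoothing (when `propagate_smoothing`), and adds a cell-level
#' residual draw `N(0, sigma_eps_hat)`.  Per-cell percentile bounds are taken
#' with [percentile_bounds()] and clipped to `[0, 20]`.
#'
#' @param fit a converged `dmft_stage1_fit` with a valid covariance matrix.
#' @param residuals residual table from [stage1_residuals()] for the same
#'   index.
#' @param covariates covariates, complete on the lattice.
#' @param lattice a [lattice_spec()].
#' @param kernels a [kernel_params()] object.
#' @param config a [bootstrap_config()].
#' @param repair_vcov project a slightly indefinite covariance matrix onto
#'   the nearest PSD matrix instead of failing.
#' @return data.frame of class `dmft_grid` with one row per lattice cell:
#'   `province`, `year`, `age_group`, `sex`, `index`, `estimate`, `lower`,
#'   `upper`, `B`, `fallback` (spatial-kernel fallback flag),
#'   `novel_province`, `novel_year`.  `lower <= upper` always; bounds and
#'   point are clipped to `[0, 20]`.
#' @export
bootstrap_ui <- function(fit, residuals, covariates, lattice, kernels,
                         config = bootstrap_config(), repair_vcov = FALSE) {
  if (!inherits(fit, "dmft_stage1_fit")) stop_dmft("fit must be a stage-1 fit")
  if (!isTRUE(fit$converged))
    warning("bootstrap_ui: stage-1 fit did not converge; intervals may be ",
            "unreliable", call. = FALSE)
  if (config$B < 40 && config$level >= 0.9)
    warning("bootstrap_ui: B = ", config$B, " is too small for stable ",
            config$level * 100, "% percentile endpoints", call. = FALSE)
  V <- check_psd(fit$vcov_beta, repair = repair_vcov)

  res <- residuals[tolower(residuals$index) == fit$index, , drop = FALSE]
  if (!nrow(res)) stop_dmft("empty residual table for index ", fit$index)

  # point surfaces
  pred <- predict_stage1(fit, covariates, lattice)
  sm_hat <- smooth_residuals(res, lattice, kernels)
  point <- compose_estimates(pred, sm_hat)

  full_key <- cell_key(pred$province, pred$year, pred$age_group, pred$sex)
  N <- nrow(pred); B <- config$B

  # design pieces reused across replicates
  frame <- join_covariates(pred[, c("province", "year", "age_group", "sex")],
                           covariates)
  X <- stats::model.matrix(fit$fixed_formula, stage1_frame(frame, fit$xlev))
  X <- X[, names(fit$beta), drop = FALSE]
  p_lab <- lattice$provinces
  y_lab <- as.character(lattice$years)
  p_idx <- match(as.character(pred$province), p_lab)
  y_idx <- match(as.character(pred$year), y_lab)

  # smoothing operator per sex stratum (kernel weights are deterministic)
  strata <- lapply(lattice$sexes, function(s) {
    src <- res[res$sex == s, , drop = FALSE]
    if (!nrow(src)) stop_dmft("no residuals for sex ", s)
    rows <- which(pred$sex == s)
    list(sex = s, src = src, rows = rows,
         obs_pos = match(cell_key(src$province, src$year, src$age_group, s),
                         full_key),
         W = smoothing_matrix(pred[rows, c("province", "year", "age_group")],
                              src, kernels)$W)
  })

  with_seed(config$seed, {
    Beta <- MASS::mvrnorm(B, mu = fit$beta, Sigma = V)
    if (B == 1L) Beta <- matrix(Beta, nrow = 1L,
                                dimnames = list(NULL, names(fit$beta)))
    draw_levels <- function(labels, effect, condsd, sigma_pop) {
      mu <- effect[labels]; sdv <- condsd[labels]
      unseen <- is.na(mu)
      mu[unseen] <- 0; sdv[unseen] <- sigma_pop
      matrix(stats::rnorm(length(labels) * B, mean = rep(mu, B),
                          sd = rep(sdv, B)),
             nrow = length(labels), ncol = B)
    }
    U <- draw_levels(p_lab, fit$re_province, fit$condsd_province,
                     fit$sigma_province)
    A <- draw_levels(y_lab, fit$re_year, fit$condsd_year, fit$sigma_year)
    E <- matrix(stats::rnorm(N * B, 0, fit$sigma_eps), nrow = N, ncol = B)

    Pred <- X %*% t(Beta) + U[p_idx, , drop = FALSE] + A[y_idx, , drop = FALSE]
    Est <- Pred
    for (st in strata) {
      if (config$propagate_smoothing) {
        Rb <- matrix(st$src$mean, nrow = nrow(st$src), ncol = B) -
          Pred[st$obs_pos, , drop = FALSE]
        Est[st$rows, ] <- Pred[st$rows, , drop = FALSE] + st$W %*% Rb
      } else {
        sm_fix <- point$estimate[st$rows] - point$fitted[st$rows]
        Est[st$rows, ] <- Pred[st$rows, , drop = FALSE] + sm_fix
      }
    }
    Est <- clip_teeth(Est + E)

    a <- (1 - config$level) / 2
    bounds <- t(apply(Est, 1L, stats::quantile, probs = c(a, 1 - a),
                      names = FALSE, type = 7))
    out <- data.frame(point[, c("province", "year", "age_group", "sex",
                                "index")],
                      estimate = point$estimate,
                      lower = clip_teeth(bounds[, 1]),
                      upper = clip_teeth(bounds[, 2]),
                      B = B, fallback = point$fallback,
                      novel_province = point$novel_province,
                      novel_year = point$novel_year,
                      stringsAsFactors = FALSE)
    class(out) <- c("dmft_grid", "data.frame")
    out
  })
}
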