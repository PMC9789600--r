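# run code with a private, seed-initialised RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Define the estimation lattice
#'
#' The complete grid over which estimates are produced: provinces (with their
#' adjacency graph), calendar years, age groups and sexes.
#'
#' @param provinces character vector of province labels.
#' @param adjacency a `dmft_adjacency` object over `provinces`.
#' @param years integer calendar years (closed range).
#' @param age_groups ordered age-group labels.
#' @param sexes sex labels.
#' @return an object of class `dmft_lattice`.
#' @export
lattice_spec <- function(provinces, adjacency, years = 1990:2017,
                         age_groups = c("1-4", "5-9", "10-14"),
                         sexes = c("female", "male")) {
  if (!inherits(adjacency, "dmft_adjacency"))
    stop_dmft("adjacency must be a dmft_adjacency object")
  if (!all(canon_label(provinces) %in% canon_label(adjacency$provinces)))
    stop_dmft("every lattice province must exist in the adjacency structure")
  structure(list(provinces = provinces, adjacency = adjacency,
                 years = sort(unique(as.integer(years))),
                 age_groups = canon_age(age_groups),
                 sexes = tolower(sexes)),
            class = "dmft_lattice")
}

# province x year x age grid (province varies fastest), shared by all modules
lattice_cells <- function(lattice) {
  expand.grid(province = lattice$provinces, year = lattice$years,
              age_group = lattice$age_groups,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Seeded synthetic province adjacency graph
#'
#' Builds a connected planar-like neighbour graph by placing provinces
#' uniformly at random in the unit square, joining each to its `k` nearest
#' neighbours, and bridging any remaining components through their closest
#' cross-component pair.  Mean degree around 4-5 mimics a real provincial
#' border graph.
#'
#' @param provinces province labels (or a single integer count, labelled
#'   `P01`, `P02`, ...).
#' @param seed integer RNG seed; the graph is deterministic given it.
#' @param k nearest-neighbour count (default 3).
#' @return a `dmft_adjacency` object.
#' @export
synthetic_adjacency <- function(provinces, seed = 1L, k = 3L) {
  if (is.numeric(provinces) && length(provinces) == 1L)
    provinces <- sprintf("P%02d", seq_len(provinces))
  n <- length(provinces)
  if (n < 2L) stop_dmft("need at least two provinces")
  with_seed(seed, {
    xy <- cbind(stats::runif(n), stats::runif(n))
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    ii <- jj <- integer(0)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[seq_len(min(k, n - 1L))]
      ii <- c(ii, rep(i, length(nb))); jj <- c(jj, nb)
    }
    # bridge disconnected components (rare for k = 3, but guaranteed here)
    repeat {
      adj <- matrix(FALSE, n, n)
      adj[cbind(ii, jj)] <- TRUE; adj[cbind(jj, ii)] <- TRUE
      comp <- rep(0L, n); c_id <- 0L
      for (s in seq_len(n)) {
        if (comp[s] > 0L) next
        c_id <- c_id + 1L; queue <- s; comp[s] <- c_id
        while (length(queue)) {
          v <- queue[1L]; queue <- queue[-1L]
          nxt <- which(adj[v, ] & comp == 0L)
          comp[nxt] <- c_id; queue <- c(queue, nxt)
        }
      }
      if (c_id == 1L) break
      out <- comp == comp[1L]
      dd <- d[out, !out, drop = FALSE]
      w <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
      ii <- c(ii, which(out)[w[1L]]); jj <- c(jj, which(!out)[w[2L]])
    }
    adjacency_from_edges(provinces[ii], provinces[jj], provinces = provinces)
  })
}

#' Default synthetic lattice
#'
#' 31 provinces with a seeded synthetic adjacency graph, years 1990-2017,
#' three age groups and both sexes -- the sparse national design the package
#' is built around.
#'
#' @param n_provinces number of provinces (default 31).
#' @param seed seed for the adjacency graph.
#' @return a `dmft_lattice`.
#' @export
default_lattice <- function(n_provinces = 31L, seed = 1L) {
  provinces <- sprintf("P%02d", seq_len(n_provinces))
  lattice_spec(provinces, synthetic_adjacency(provinces, seed = seed))
}

#' Generative parameters for synthetic truth surfaces
#'
#' The generative counterpart of the estimation model: a linear predictor
#' `beta . (1, male, schooling, wealth, age_weight)` plus province and year
#' random intercepts, a structured age-spatio-temporal residual field, and
#' cell-level residual noise.  The dmft surface is decomposed into dt/mt/ft
#' by fixed proportions, so additivity holds exactly by construction.
#'
#' @param beta named fixed-effect vector with elements `intercept`,
#'   `sexmale`, `schooling`, `wealth`, `age_weight` (teeth per covariate
#'   unit).
#' @param sigma_province,sigma_year standard deviations of the province and
#'   year random intercepts (teeth), `>= 0`.
#' @param sigma_eps cell-level residual standard deviation (teeth), `>= 0`.
#' @param field list with `sd` (marginal sd of the structured residual
#'   field; 0 disables it), `lambda` and `varpi` (kernel parameters used to
#'   correlate it, matching [kernel_params()]).
#' @param component_split proportions `c(dt, mt, ft)` decomposing dmft; must
#'   be non-negative and sum to 1.
#' @return an object of class `dmft_truth_params`.
#' @export
truth_params <- function(beta = c(intercept = 3.5, sexmale = 0.3,
                                  schooling = -0.1, wealth = -0.3,
                                  age_weight = 5),
                         sigma_province = 0.5, sigma_year = 0.2,
                         sigma_eps = 0.5,
                         field = list(sd = 0.4, lambda = 2, varpi = 1),
                         component_split = c(dt = 0.83, mt = 0.10, ft = 0.07)) {
  need <- c("intercept", "sexmale", "schooling", "wealth", "age_weight")
  if (!all(need %in% names(beta)))
    stop_dmft("beta must name ", paste(need, collapse = ", "))
  sds <- c(sigma_province = sigma_province, sigma_year = sigma_year,
           sigma_eps = sigma_eps, field_sd = field$sd %||% 0)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop_dmft("parameter error: standard deviations must be >= 0")
  if (!all(c("dt", "mt", "ft") %in% names(component_split)))
    stop_dmft("component_split must name dt, mt, ft")
  if (any(component_split < 0) || abs(sum(component_split) - 1) > 1e-8)
    stop_dmft("component_split entries must be >= 0 and sum to 1")
  structure(list(beta = beta[need], sigma_province = sigma_province,
                 sigma_year = sigma_year, sigma_eps = sigma_eps,
                 field = list(sd = field$sd %||% 0,
                              lambda = field$lambda %||% 2,
                              varpi = field$varpi %||% 1),
                 component_split = component_split[c("dt", "mt", "ft")]),
            class = "dmft_truth_params")
}

#' Generate a synthetic covariate table
#'
#' Mean years of schooling rise over the period with province-level
#' heterogeneity; the wealth index is standardised to mean 0, sd 1; the
#' within-group age weight sits near a group-specific centre with small
#' province-year variation (which keeps it linearly separable from age-group
#' indicator terms).
#'
#' @param lattice a `dmft_lattice`.
#' @param seed integer seed.
#' @return a `dmft_covariates` data.frame, complete over the lattice.
#' @export
generate_covariates <- function(lattice, seed = 1L) {
  with_seed(seed, {
    py <- expand.grid(province = lattice$provinces, year = lattice$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pbase_s <- stats::setNames(stats::rnorm(length(lattice$provinces), 6, 1),
                               lattice$provinces)
    pbase_w <- stats::setNames(stats::rnorm(length(lattice$provinces), 0, 0.8),
                               lattice$provinces)
    py$schooling <- pbase_s[py$province] +
      0.08 * (py$year - min(lattice$years)) + stats::rnorm(nrow(py), 0, 0.2)
    wealth_raw <- pbase_w[py$province] + stats::rnorm(nrow(py), 0, 0.6)
    py$wealth <- as.numeric(scale(wealth_raw))
    centre <- stats::setNames(
      seq(0.35, 0.65, length.out = length(lattice$age_groups)),
      lattice$age_groups)
    out <- do.call(rbind, lapply(lattice$age_groups, function(g) {
      z <- py
      z$age_group <- g
      z$age_weight <- pmin(pmax(
        centre[[g]] + stats::runif(nrow(py), -0.05, 0.05), 0), 1)
      z
    }))
    out <- out[, c("province", "year", "age_group", "schooling", "wealth",
                   "age_weight")]
    rownames(out) <- NULL
    class(out) <- c("dmft_covariates", "data.frame")
    out
  })
}

# fixed-effect design matrix of the generative model for one sex
truth_design <- function(covariates, sex) {
  cbind(intercept = 1,
        sexmale = as.numeric(sex == "male"),
        schooling = covariates$schooling,
        wealth = covariates$wealth,
        age_weight = covariates$age_weight)
}

#' Generate a complete synthetic truth surface
#'
#' Draws province and year random intercepts, a structured residual field
#' (white noise smoothed with the same age-spatio-temporal kernels the
#' estimator uses, rescaled to the requested marginal sd, independently per
#' sex), and cell-level residual noise; assembles the latent true dmft mean
#' at every (province, year, age group, sex) cell; clips to `[0, 20]`; and
#' decomposes it into dt/mt/ft by `component_split`.  Deterministic given
#' `seed`.
#'
#' @param params a [truth_params()] object.
#' @param lattice a [lattice_spec()].
#' @param seed integer seed.
#' @param covariates optional `dmft_covariates`; generated from `seed` when
#'   omitted.
#' @param field_operator optional precomputed smoothing operator from
#'   [truth_field_operator()]; with many replicate surfaces on one lattice,
#'   computing it once saves most of the generation cost.
#' @return an object of class `dmft_truth`: list with `surface` (data.frame
#'   with columns `province`, `year`, `age_group`, `sex`, `dmft`, `dt`, `mt`,
#'   `ft`), `covariates`, `random_effects`, `field`, `n_clipped`, `params`,
#'   `lattice`, `seed`.
#' @export
generate_truth <- function(params, lattice, seed = 1L, covariates = NULL,
                           field_operator = NULL) {
  if (!inherits(params, "dmft_truth_params"))
    stop_dmft("params must come from truth_params()")
  with_seed(seed, {
    if (is.null(covariates))
      covariates <- generate_covariates(lattice, seed = seed + 1L)
    check_covariate_completeness(covariates, lattice)
    cells <- lattice_cells(lattice)
    m <- match(cell_key(cells$province, cells$year, cells$age_group),
               cell_key(covariates$province, covariates$year,
                        covariates$age_group))
    cov_cells <- covariates[m, , drop = FALSE]

    u <- stats::setNames(
      stats::rnorm(length(lattice$provinces), 0, params$sigma_province),
      lattice$provinces)
    a <- stats::setNames(
      stats::rnorm(length(lattice$years), 0, params$sigma_year),
      lattice$years)

    # one structured province-year-age shock surface, shared by both sexes:
    # smoothed white noise, centred and rescaled to the requested marginal sd
    f <- 0
    if (params$field$sd > 0) {
      S <- field_operator %||% truth_field_operator(lattice, params)
      z <- stats::rnorm(nrow(cells))
      f <- as.numeric(S %*% z)
      f <- f - mean(f)
      s <- stats::sd(f)
      if (s > 0) f <- f * params$field$sd / s
    }

    n_clipped <- 0L
    surf <- list()
    for (sex in lattice$sexes) {
      lp <- as.numeric(truth_design(cov_cells, sex) %*% params$beta)
      eps <- if (params$sigma_eps > 0)
        stats::rnorm(nrow(cells), 0, params$sigma_eps) else 0
      raw <- lp + u[cells$province] + a[as.character(cells$year)] + f + eps
      dmft <- clip_teeth(raw)
      n_clipped <- n_clipped + sum(raw != dmft)
      surf[[sex]] <- data.frame(
        cells, sex = sex,
        dmft = dmft,
        dt = params$component_split[["dt"]] * dmft,
        mt = params$component_split[["mt"]] * dmft,
        ft = params$component_split[["ft"]] * dmft,
        stringsAsFactors = FALSE)
    }
    if (n_clipped > 0.01 * nrow(cells) * length(lattice$sexes))
      message("generate_truth: ", n_clipped, " cell(s) clipped to [0, 20]; ",
              "heavy clipping weakens parameter-recovery checks")
    surface <- do.call(rbind, c(unname(surf), make.row.names = FALSE))
    structure(list(surface = surface, covariates = covariates,
                   random_effects = list(province = u, year = a),
                   field = data.frame(cells,
                                      field = if (length(f) == 1L)
                                        rep(0, nrow(cells)) else f,
                                      stringsAsFactors = FALSE),
                   n_clipped = n_clipped, params = params, lattice = lattice,
                   seed = seed),
              class = "dmft_truth")
  })
}

#' Smoothing operator used to correlate the structured truth field
#'
#' The structured residual field of [generate_truth()] is white noise pushed
#' through the same age-spatio-temporal smoother the estimator uses; this
#' returns that (deterministic) operator over the full province x year x age
#' grid so it can be reused across many replicate surfaces.
#'
#' @param lattice a [lattice_spec()].
#' @param params a [truth_params()] object (its `field$lambda` / `field$varpi`
#'   are used).
#' @return a dense row-stochastic matrix.
#' @export
truth_field_operator <- function(lattice, params) {
  kp <- kernel_params(lattice$adjacency, years = lattice$years,
                      lambda = params$field$lambda,
                      varpi = params$field$varpi,
                      age_groups = lattice$age_groups)
  cells <- lattice_cells(lattice)
  smoothing_matrix(cells, cells, kp)$W
}

#' Sparse survey design for synthetic observations
#'
#' @param observed_years years in which a survey took place.  The default
#'   mirrors a design of five national oral health surveys (1998, 2002, 2004,
#'   2013, 2016) plus two multipurpose national health surveys with oral
#'   modules (1990, 1999).
#' @param coverage probability, in `(0, 1]`, that a given province is sampled
#'   in an observed year.
#' @param n_per_cell sample size behind each observed cell mean.
#' @param sigma_obs per-child standard deviation of the index (teeth); the
#'   cell-mean noise sd is `sigma_obs / sqrt(n_per_cell)` for dmft and is
#'   scaled by the component split for dt/mt/ft.
#' @return an object of class `dmft_survey_design`.
#' @export
survey_design <- function(observed_years = c(1990, 1998, 1999, 2002, 2004,
                                             2013, 2016),
                          coverage = 0.9, n_per_cell = 400, sigma_obs = 4) {
  observed_years <- sort(unique(as.integer(observed_years)))
  if (!length(observed_years)) stop_dmft("empty design: no observed years")
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    stop_dmft("coverage must lie in (0, 1]")
  if (n_per_cell <= 0) stop_dmft("n_per_cell must be positive")
  if (sigma_obs < 0) stop_dmft("sigma_obs must be >= 0")
  structure(list(observed_years = observed_years, coverage = coverage,
                 n_per_cell = n_per_cell, sigma_obs = sigma_obs),
            class = "dmft_survey_design")
}

#' Sample sparse survey-like observations from a truth surface
#'
#' Province inclusion is drawn once per (province, observed year) pair with
#' probability `coverage` -- a whole provincial survey is either fielded or
#' not, so all age groups, sexes and indices of an included pair are
#' observed together.  Observed means are the true cell values plus Gaussian
#' noise with sd `sigma_obs / sqrt(n)` (component indices scaled by their
#' split share), clipped to `[0, 20]`; the `se` column records that noise sd.
#'
#' The RNG stream is documented and stable: after `set.seed(seed)`, one
#' `runif` vector over the province x observed-year grid (province varying
#' fastest) decides inclusion, then a single `rnorm` vector supplies the
#' noise for the stacked rows (index-major: dmft, dt, mt, ft).
#'
#' @param truth a [generate_truth()] result.
#' @param design a [survey_design()].
#' @param seed integer seed.
#' @return a `dmft_obs` observation table.
#' @export
sample_observations <- function(truth, design, seed = 1L) {
  if (!inherits(design, "dmft_survey_design"))
    stop_dmft("design must come from survey_design()")
  lattice <- truth$lattice
  if (!all(design$observed_years %in% lattice$years))
    stop_dmft("observed_years must lie within the truth lattice years")
  with_seed(seed, {
    py <- expand.grid(province = lattice$provinces,
                      year = design$observed_years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    incl <- stats::runif(nrow(py)) <= design$coverage
    py <- py[incl, , drop = FALSE]
    if (!nrow(py)) stop_dmft("no cells sampled under this design/seed")
    surf <- truth$surface
    key_py <- paste(canon_label(py$province), py$year, sep = "|")
    hit <- paste(canon_label(surf$province), surf$year, sep = "|") %in% key_py
    base <- surf[hit, , drop = FALSE]
    split_sd <- c(dmft = 1, truth$params$component_split)
    rows <- do.call(rbind, lapply(.indices, function(k) {
      se <- design$sigma_obs * split_sd[[k]] / sqrt(design$n_per_cell)
      data.frame(province = base$province, year = base$year,
                 age_group = base$age_group, sex = base$sex, index = k,
                 truth = base[[k]], se = se, n = design$n_per_cell,
                 stringsAsFactors = FALSE)
    }))
    noise <- stats::rnorm(nrow(rows), 0, rows$se)
    rows$mean <- clip_teeth(rows$truth + noise)
    rows$se[rows$se == 0] <- NA_real_
    obs <- as_observations(rows[, c("province", "year", "age_group", "sex",
                                    "index", "mean", "se", "n")],
                           provinces = lattice$provinces,
                           years = lattice$years,
                           age_groups = lattice$age_groups)
    obs
  })
}
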