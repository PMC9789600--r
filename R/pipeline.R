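#' Run the full estimation pipeline for one or more indices
#'
#' Convenience wrapper chaining the four stages for each requested index:
#' [fit_stage1()] -> [stage1_residuals()] -> [smooth_residuals()] /
#' [compose_estimates()] -> [bootstrap_ui()].  Returns one combined estimate
#' grid with uncertainty bounds over the full lattice.
#'
#' @param obs a `dmft_obs` observation table.
#' @param covariates a `dmft_covariates` table, complete on the lattice.
#' @param lattice a [lattice_spec()].
#' @param kernels a [kernel_params()]; defaults to the standard kernels
#'   (`lambda = 2`, `varpi = 1`) over the lattice's adjacency and years.
#' @param indices indices to estimate (default: those present in `obs`).
#' @param spec_args extra arguments passed to [stage1_spec()] (besides
#'   `index`).
#' @param bootstrap a [bootstrap_config()]; set to `NULL` to skip interval
#'   estimation (the returned grid then has no bounds).
#' @return a `dmft_grid` data.frame; with `bootstrap`, the row layout of
#'   [bootstrap_ui()] stacked over indices, plus a `fits` attribute holding
#'   the per-index `dmft_stage1_fit` objects.
#' @examples
#' lat <- default_lattice(6, seed = 2)
#' tr <- generate_truth(truth_params(), lat, seed = 3)
#' obs <- sample_observations(tr, survey_design(), seed = 4)
#' g <- estimate_trends(obs, tr$covariates, lat, indices = "dmft",
#'                      bootstrap = bootstrap_config(B = 50, seed = 5))
#' head(g)
#' @export
estimate_trends <- function(obs, covariates, lattice, kernels = NULL,
                            indices = NULL, spec_args = list(),
                            bootstrap = bootstrap_config()) {
  if (is.null(kernels))
    kernels <- kernel_params(lattice$adjacency, years = lattice$years,
                             age_groups = lattice$age_groups)
  indices <- indices %||% intersect(.indices, unique(tolower(obs$index)))
  if (!length(indices)) stop_dmft("no indices to estimate")
  fits <- list()
  grids <- vector("list", length(indices))
  for (k in seq_along(indices)) {
    ix <- indices[k]
    spec <- do.call(stage1_spec, c(list(index = ix), spec_args))
    fit <- fit_stage1(obs, covariates, spec)
    res <- stage1_residuals(fit, obs, covariates)
    if (is.null(bootstrap)) {
      pred <- predict_stage1(fit, covariates, lattice)
      sm <- smooth_residuals(
        res[, c("province", "year", "age_group", "sex", "index", "residual")],
        lattice, kernels)
      grids[[k]] <- compose_estimates(pred, sm)
    } else {
      grids[[k]] <- bootstrap_ui(fit, res, covariates, lattice, kernels,
                                 config = bootstrap)
    }
    fits[[ix]] <- fit
  }
  out <- do.call(rbind, c(grids, make.row.names = FALSE))
  class(out) <- c("dmft_grid", "data.frame")
  attr(out, "fits") <- fits
  out
}

#' Aggregate a provincial grid to a national one
#'
#' Weighted average of the provincial estimates (and bounds, when present)
#' within each (year, age group, sex, index) cell.  Provinces are weighted
#' equally by default; supply `province_weights` (a named vector, e.g.
#' population counts) for a population-weighted aggregate.
#'
#' @param grid a `dmft_grid` with a `province` column.
#' @param province_weights optional named numeric vector over provinces.
#' @param label label for the aggregate pseudo-province (default `"national"`).
#' @return a `dmft_grid` with a single province.
#' @export
aggregate_national <- function(grid, province_weights = NULL,
                               label = "national") {
  grid <- as.data.frame(grid)
  provs <- unique(grid$province)
  if (is.null(province_weights))
    province_weights <- stats::setNames(rep(1, length(provs)), provs)
  miss <- setdiff(canon_label(provs), canon_label(names(province_weights)))
  if (length(miss))
    stop_dmft("no province weight for: ", paste(miss, collapse = ", "))
  w <- province_weights[match(canon_label(grid$province),
                              canon_label(names(province_weights)))]
  key <- paste(grid$year, canon_age(grid$age_group), tolower(grid$sex),
               tolower(grid$index), sep = "|")
  agg <- function(v) as.numeric(rowsum(v * w, key) / rowsum(as.numeric(w), key))
  first_idx <- which(!duplicated(key))
  base <- grid[first_idx[order(key[first_idx])],
               c("year", "age_group", "sex", "index"), drop = FALSE]
  out <- data.frame(province = label, base, estimate = agg(grid$estimate),
                    stringsAsFactors = FALSE)
  if (all(c("lower", "upper") %in% names(grid))) {
    out$lower <- agg(grid$lower)
    out$upper <- agg(grid$upper)
  }
  rownames(out) <- NULL
  class(out) <- c("dmft_grid", "data.frame")
  out
}
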