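#' Kernel parameters for age-spatio-temporal smoothing
#'
#' Bundles the three weighting components used to borrow strength across the
#' province x year x age lattice: a binary spatial weight over the province
#' adjacency graph, a tricube-type temporal weight
#' `(1 - (|i-j| / M)^lambda)^3` with normaliser `M = max|i-j| + 1` over the
#' configured year range, and an exponential age-distance weight
#' `exp(-varpi * |g-h|)` over age-group indices.
#'
#' @param adjacency a `dmft_adjacency` object ([read_adjacency()]).
#' @param years integer vector of calendar years covered by the lattice; the
#'   temporal normaliser is `max(years) - min(years) + 1` (28 for 1990-2017),
#'   which keeps the temporal weight strictly positive at the maximum lag.
#' @param lambda temporal smoothing exponent, `> 0`; larger values keep the
#'   temporal weight close to 1 over longer lags (less smoothing decay).
#'   Default 2.
#' @param varpi age decay rate, `> 0`; smaller values smooth more across age
#'   groups.  Default 1.
#' @param age_groups ordered age-group labels; distance between groups is the
#'   difference of their positions in this vector.
#' @return an object of class `dmft_kernels`.
#' @seealso [temporal_weight()], [age_weight()], [spatial_weight()],
#'   [smooth_residuals()]
#' @export
kernel_params <- function(adjacency, years = 1990:2017, lambda = 2, varpi = 1,
                          age_groups = c("1-4", "5-9", "10-14")) {
  if (!inherits(adjacency, "dmft_adjacency"))
    stop_dmft("adjacency must be a dmft_adjacency object")
  if (!is.numeric(lambda) || lambda <= 0) stop_dmft("lambda must be > 0")
  if (!is.numeric(varpi) || varpi <= 0) stop_dmft("varpi must be > 0")
  years <- sort(unique(as.integer(years)))
  M <- max(years) - min(years) + 1L
  structure(list(adjacency = adjacency, years = years,
                 lambda = lambda, varpi = varpi,
                 age_groups = canon_age(age_groups),
                 max_time_lag_plus_one = M),
            class = "dmft_kernels")
}

#' Spatial weighting component
#'
#' Binary adjacency weight: 1 when the two provinces are identical or share a
#' border, 0 otherwise.
#'
#' @param a,b province labels (vectorised).
#' @param adjacency a `dmft_adjacency` object.
#' @return numeric vector of 0/1 weights.
#' @export
spatial_weight <- function(a, b, adjacency) {
  same <- canon_label(a) == canon_label(b)
  known <- canon_label(adjacency$provinces)
  bad <- unique(c(a, b)[!(canon_label(c(a, b)) %in% known)])
  if (length(bad))
    stop_dmft("unknown province label(s): ", paste(bad, collapse = ", "))
  as.numeric(same | is_adjacent(adjacency, a, b))
}

#' Temporal weighting component
#'
#' LOESS-style tricube decay in the absolute year lag:
#' `(1 - (|i - j| / M)^lambda)^3` with `M` the maximum lag plus one.  Equals
#' 1 at lag zero and decreases strictly with the lag, staying positive within
#' the configured range.
#'
#' @param i,j calendar years (vectorised).
#' @param params a `dmft_kernels` object.
#' @return numeric weights in `(0, 1]`.
#' @export
temporal_weight <- function(i, j, params) {
  lag <- abs(as.numeric(i) - as.numeric(j))
  (1 - (lag / params$max_time_lag_plus_one)^params$lambda)^3
}

#' Age weighting component
#'
#' Exponential decay in the distance between age-group positions:
#' `exp(-varpi * |g - h|)`.  Lower `varpi` smooths more across age groups.
#'
#' @param g,h age-group labels or integer positions (vectorised).
#' @param params a `dmft_kernels` object.
#' @return numeric weights in `(0, 1]`.
#' @export
age_weight <- function(g, h, params) {
  pos <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    p <- match(canon_age(x), params$age_groups)
    if (anyNA(p)) stop_dmft("unknown age group label")
    as.numeric(p)
  }
  exp(-params$varpi * abs(pos(g) - pos(h)))
}

# component weight matrices over the lattice axes (row = target, col = source)
kernel_component_matrices <- function(params) {
  WL <- adjacency_matrix(params$adjacency)
  yrs <- params$years
  WT <- outer(yrs, yrs, function(i, j) temporal_weight(i, j, params))
  dimnames(WT) <- list(yrs, yrs)
  g <- seq_along(params$age_groups)
  WA <- outer(g, g, function(a, b) exp(-params$varpi * abs(a - b)))
  dimnames(WA) <- list(params$age_groups, params$age_groups)
  list(WL = WL, WT = WT, WA = WA)
}

#' Combined, normalised smoothing weights for one target cell
#'
#' Raw weight of each source cell is the product of the spatial, temporal and
#' age components; raw weights are then normalised to sum to one.  When every
#' raw weight is zero (the target province has no same-or-adjacent source,
#' e.g. an isolated province), the spatial component is dropped and the
#' temporal x age product is used instead, with `fallback = TRUE`.
#'
#' @param target list or one-row data.frame with `province`, `year`,
#'   `age_group`.
#' @param sources data.frame of source cells with columns `province`, `year`,
#'   `age_group` (one row per observed cell).
#' @param params a `dmft_kernels` object.
#' @return list with `weights` (numeric vector summing to 1, one per source
#'   row) and `fallback` (logical).
#' @export
combined_weights <- function(target, sources, params) {
  if (is.null(nrow(sources)) || nrow(sources) == 0L)
    stop_dmft("combined_weights: no source cells")
  wl <- spatial_weight(rep(target$province, nrow(sources)), sources$province,
                       params$adjacency)
  wt <- temporal_weight(rep(target$year, nrow(sources)), sources$year, params)
  wa <- age_weight(rep(target$age_group, nrow(sources)), sources$age_group,
                   params)
  raw <- wl * wt * wa
  fallback <- FALSE
  if (sum(raw) <= 0) {
    raw <- wt * wa
    fallback <- TRUE
  }
  list(weights = raw / sum(raw), fallback = fallback)
}

# full normalised weight matrix from source cells to target cells.
# targets/sources: data.frames with province, year, age_group.
smoothing_matrix <- function(targets, sources, params) {
  if (nrow(sources) == 0L) stop_dmft("no source cells to smooth from")
  comp <- kernel_component_matrices(params)
  pt <- match(canon_label(targets$province), canon_label(params$adjacency$provinces))
  ps <- match(canon_label(sources$province), canon_label(params$adjacency$provinces))
  yt <- match(targets$year, params$years)
  ys <- match(sources$year, params$years)
  at <- match(canon_age(targets$age_group), params$age_groups)
  as_ <- match(canon_age(sources$age_group), params$age_groups)
  if (anyNA(c(pt, ps))) stop_dmft("unknown province label(s) in smoothing cells")
  if (anyNA(c(yt, ys))) stop_dmft("year outside the kernel year range")
  if (anyNA(c(at, as_))) stop_dmft("unknown age group label in smoothing cells")
  ta <- comp$WT[yt, ys, drop = FALSE] * comp$WA[at, as_, drop = FALSE]
  raw <- comp$WL[pt, ps, drop = FALSE] * ta
  rs <- rowSums(raw)
  fallback <- rs <= 0
  if (any(fallback)) {
    raw[fallback, ] <- ta[fallback, , drop = FALSE]
    rs <- rowSums(raw)
  }
  list(W = raw / rs, fallback = fallback)
}

#' Smooth stage-1 residuals over the full lattice
#'
#' Computes, within each sex x index stratum, the kernel-weighted average of
#' the observed residuals at every lattice cell: the smoothed value at a
#' target cell is the normalised product-kernel weighted sum of all observed
#' residuals of that stratum (see [combined_weights()]).  Sex is never
#' smoothed over.
#'
#' @param residuals residual table from [stage1_residuals()] (columns
#'   `province`, `year`, `age_group`, `sex`, `index`, `residual`).
#' @param lattice a [lattice_spec()].
#' @param params a `dmft_kernels` object.
#' @return data.frame over the full lattice with columns `province`, `year`,
#'   `age_group`, `sex`, `index`, `smoothed` and logical `fallback` marking
#'   cells whose spatial component found no source.
#' @export
smooth_residuals <- function(residuals, lattice, params) {
  if (is.null(nrow(residuals)) || nrow(residuals) == 0L)
    stop_dmft("empty residual table")
  cells <- lattice_cells(lattice)          # province x year x age grid
  strata <- unique(residuals[, c("sex", "index"), drop = FALSE])
  out <- vector("list", nrow(strata))
  for (s in seq_len(nrow(strata))) {
    sub <- residuals[residuals$sex == strata$sex[s] &
                       residuals$index == strata$index[s], , drop = FALSE]
    sm <- smoothing_matrix(cells, sub, params)
    out[[s]] <- data.frame(cells,
                           sex = strata$sex[s], index = strata$index[s],
                           smoothed = as.numeric(sm$W %*% sub$residual),
                           fallback = sm$fallback,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}

#' Assemble final estimates from stage-1 predictions and smoothed residuals
#'
#' The final point surface is the stage-1 prediction plus the smoothed
#' residual, clipped to the admissible index range `[0, 20]`.
#'
#' @param prediction output of [predict_stage1()].
#' @param smoothed output of [smooth_residuals()] for the same index.
#' @return data.frame keyed like `prediction` with an `estimate` column and
#'   the `fallback` flag carried over.
#' @export
compose_estimates <- function(prediction, smoothed) {
  key_p <- cell_key(prediction$province, prediction$year, prediction$age_group,
                    prediction$sex)
  sm <- smoothed[smoothed$index == prediction$index[1], , drop = FALSE]
  key_s <- cell_key(sm$province, sm$year, sm$age_group, sm$sex)
  m <- match(key_p, key_s)
  if (anyNA(m)) stop_dmft("smoothed surface does not cover the prediction lattice")
  out <- prediction
  out$estimate <- clip_teeth(prediction$fitted + sm$smoothed[m])
  out$fallback <- sm$fallback[m]
  out
}
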