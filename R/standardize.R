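#' Direct age-standardisation of an estimate grid
#'
#' Collapses the age-group dimension of an estimate grid into a single
#' age-standardised value per (province, year, sex, index): the weighted
#' average of the age-specific estimates with the reference population's
#' normalised age shares.  The same weighted average is applied to the lower
#' and upper bound columns when present, so a grid of intervals standardises
#' to an interval.
#'
#' @param grid a `dmft_grid`-like data.frame with columns `province`, `year`,
#'   `age_group`, `sex`, `index`, `estimate` and optionally `lower`/`upper`.
#'   Every age group present must carry a weight; aggregate rows such as
#'   `"all"` must be removed by the caller first.
#' @param weights a `dmft_popweights` object (e.g.
#'   [load_default_population_weights()]).
#' @return data.frame of class `dmft_standardized` with one row per
#'   (province, year, sex, index).
#' @export
age_standardize <- function(grid, weights) {
  if (!inherits(weights, "dmft_popweights"))
    weights <- as_population_weights(weights$age_group, weights$weight)
  shares <- population_shares(weights)
  grid <- as.data.frame(grid)
  grid$age_group <- canon_age(grid$age_group)
  missing_w <- setdiff(unique(grid$age_group), names(shares))
  if (length(missing_w))
    stop_dmft("no population weight for age group(s): ",
              paste(missing_w, collapse = ", "))
  w <- shares[grid$age_group]
  has_bounds <- all(c("lower", "upper") %in% names(grid))

  key <- paste(canon_label(grid$province), grid$year, tolower(grid$sex),
               tolower(grid$index), sep = "|")
  agg <- function(v) {
    num <- rowsum(v * w, key)
    den <- rowsum(as.numeric(w), key)
    num / den  # shares re-normalised over the groups actually present
  }
  est <- agg(grid$estimate)              # rowsum orders rows by sorted key
  first_idx <- which(!duplicated(key))
  base <- grid[first_idx[order(key[first_idx])],
               c("province", "year", "sex", "index"), drop = FALSE]
  out <- data.frame(base, estimate = as.numeric(est),
                    stringsAsFactors = FALSE)
  if (has_bounds) {
    out$lower <- as.numeric(agg(grid$lower))
    out$upper <- as.numeric(agg(grid$upper))
  }
  rownames(out) <- NULL
  class(out) <- c("dmft_standardized", "data.frame")
  out
}

#' Percent change between two values
#'
#' `100 * (v_end - v_start) / v_start`, the change statistic used for trend
#' summaries (e.g. a national dmft moving from 4.37 to 5.03 is a 15.10%
#' increase).
#'
#' @param v_start baseline value, `> 0`.
#' @param v_end final value.
#' @return signed percentage.
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start <= 0)) stop_dmft("percent_change: v_start must be > 0")
  100 * (v_end - v_start) / v_start
}

#' Share of a component in its total
#'
#' `100 * component / total`; e.g. dt = 3.64 of dmft = 4.37 is an 83.30%
#' decayed-component share.  Not clipped at 100 (component indices are
#' modelled independently and may exceed their nominal total).
#'
#' @param component component value.
#' @param total total value, `> 0`.
#' @return percentage.
#' @export
component_share <- function(component, total) {
  if (any(total <= 0)) stop_dmft("component_share: total must be > 0")
  100 * component / total
}

#' Caries experience as a percentage of the deciduous dentition
#'
#' `100 * dmft / 20`: the fraction of the 20 deciduous teeth with caries
#' experience implied by a dmft value.
#'
#' @param dmft dmft value(s) in `[0, 20]`.
#' @return percentage in `[0, 100]`.
#' @export
experience_fraction <- function(dmft) {
  if (any(!is.finite(dmft)) || any(dmft < 0 | dmft > .teeth_max))
    stop_dmft("experience_fraction: dmft must lie in [0, 20]")
  100 * dmft / .teeth_max
}

#' Provincial extremes of a standardised index
#'
#' Finds the provinces with the highest and lowest standardised value for a
#' given year, sex and index, and their difference (the sub-national
#' divergence statistic).  Ties are broken by canonical (alphabetical,
#' case-folded) label order and flagged.
#'
#' @param table a `dmft_standardized` data.frame (or any grid with one row
#'   per province after filtering).
#' @param year,sex,index the slice to summarise.
#' @return list with `max_province`, `min_province`, `difference`, `max`,
#'   `min` and logical `tie`.
#' @export
provincial_range <- function(table, year, sex, index) {
  sl <- table[table$year == as.integer(year) &
                tolower(table$sex) == tolower(sex) &
                tolower(table$index) == tolower(index), , drop = FALSE]
  if (nrow(sl) < 2L)
    stop_dmft("provincial_range needs at least two provinces (got ",
              nrow(sl), ")")
  sl <- sl[order(canon_label(sl$province)), , drop = FALSE]
  i_max <- which.max(sl$estimate)   # first in canonical order on ties
  i_min <- which.min(sl$estimate)
  tie <- sum(sl$estimate == sl$estimate[i_max]) > 1L ||
    sum(sl$estimate == sl$estimate[i_min]) > 1L
  list(max_province = sl$province[i_max], min_province = sl$province[i_min],
       difference = sl$estimate[i_max] - sl$estimate[i_min],
       max = sl$estimate[i_max], min = sl$estimate[i_min], tie = tie)
}

#' Format a trend table of estimates by age group, index and sex
#'
#' Produces the standard trend-report layout: one row per (age group, year)
#' -- including an all-ages row -- and one column per (index, sex), each cell
#' formatted `"point (lower, upper)"` rounded half-up to two decimals.
#'
#' When the grid lacks explicit `"all"` age rows, the all-ages row is the
#' population-share-weighted aggregate of the age-group rows (bounds
#' aggregated the same way), using `weights`.
#'
#' @param grid a national `dmft_grid` with `estimate`, `lower`, `upper`.
#' @param years years to report; each must be present in the grid.
#' @param weights a `dmft_popweights`, needed only when `"all"` rows are
#'   absent.
#' @param sexes,indices column order of the report.
#' @return data.frame with columns `age_group`, `year`, then one character
#'   column per index/sex combination (named e.g. `dmft_both`).
#' @export
make_trend_table <- function(grid, years, weights = NULL,
                             sexes = c("both", "female", "male"),
                             indices = c("dmft", "dt", "mt", "ft")) {
  grid <- as.data.frame(grid)
  missing_years <- setdiff(as.integer(years), grid$year)
  if (length(missing_years))
    stop_dmft("year(s) absent from grid: ",
              paste(missing_years, collapse = ", "))
  grid$age_group <- canon_age(grid$age_group)
  ages <- order_age_groups(setdiff(unique(grid$age_group), "all"))

  if (!("all" %in% grid$age_group)) {
    if (length(ages) == 1L) {
      all_rows <- grid[grid$age_group == ages, , drop = FALSE]
      all_rows$age_group <- "all"
    } else {
      if (is.null(weights))
        stop_dmft("grid has no all-ages rows; supply population weights")
      std <- age_standardize(grid, weights)
      all_rows <- data.frame(age_group = "all",
                             std[, c("year", "sex", "index", "estimate",
                                     "lower", "upper")],
                             province = if ("province" %in% names(grid))
                               std$province else NULL,
                             stringsAsFactors = FALSE)
    }
    keep <- intersect(names(grid), names(all_rows))
    grid <- rbind(grid[, keep, drop = FALSE], all_rows[, keep, drop = FALSE])
  }

  rows <- expand.grid(year = as.integer(years),
                      age_group = c(ages, "all"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("age_group", "year")]
  out <- rows
  for (ix in indices) for (sx in sexes) {
    col <- character(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      hit <- grid$age_group == rows$age_group[r] &
        grid$year == rows$year[r] &
        tolower(grid$sex) == sx & tolower(grid$index) == ix
      if (sum(hit) != 1L)
        stop_dmft("trend table cell (", rows$age_group[r], ", ",
                  rows$year[r], ", ", sx, ", ", ix, ") matched ", sum(hit),
                  " rows")
      col[r] <- fmt_est(grid$estimate[hit], grid$lower[hit], grid$upper[hit])
    }
    out[[paste(ix, sx, sep = "_")]] <- col
  }
  out
}
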