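#' National trend estimates packaged as a worked-example grid
#'
#' Returns the packaged national estimate grid: mean dmft, dt, mt and ft with
#' 95% uncertainty bounds for Iran in 1990, 2000, 2010 and 2017, for females,
#' males and both sexes, in the three age groups plus an all-ages row.  These
#' are published point estimates, packaged so the reporting operations
#' ([percent_change()], [component_share()], [make_trend_table()], ...) have a
#' realistic worked example; they are not produced by this package's model.
#'
#' @return a `data.frame` of class `dmft_grid` with columns `province`
#'   (constant `"Iran"`), `age_group` (including `"all"`), `year`, `sex`
#'   (`both`/`female`/`male`), `index`, `estimate`, `lower`, `upper`:
#'   192 point estimates, each with both interval bounds.
#' @examples
#' g <- load_table1_fixture()
#' grid_lookup(g, age_group = "all", year = 1990, sex = "both", index = "dmft")
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_national.csv", package = "dmftrend",
                      mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$year <- as.integer(x$year)
  grid <- data.frame(province = "Iran", x, stringsAsFactors = FALSE)
  class(grid) <- c("dmft_grid", "data.frame")
  grid
}

#' Look up one estimate (with bounds) in an estimate grid
#'
#' @param grid a `dmft_grid` data.frame (e.g. [load_table1_fixture()] or the
#'   output of [bootstrap_ui()]).
#' @param age_group,year,sex,index cell coordinates.
#' @param province province label; defaults to the grid's single province
#'   when it has only one.
#' @return named numeric vector `c(estimate, lower, upper)`.
#' @export
grid_lookup <- function(grid, age_group, year, sex, index, province = NULL) {
  if (is.null(province)) {
    u <- unique(grid$province)
    if (length(u) != 1L)
      stop_dmft("grid has several provinces; supply `province`")
    province <- u
  }
  hit <- canon_label(grid$province) == canon_label(province) &
    canon_age(grid$age_group) == canon_age(age_group) &
    grid$year == as.integer(year) &
    tolower(grid$sex) == tolower(sex) &
    tolower(grid$index) == tolower(index)
  if (sum(hit) != 1L)
    stop_dmft("lookup matched ", sum(hit), " rows (expected 1)")
  c(estimate = grid$estimate[hit], lower = grid$lower[hit],
    upper = grid$upper[hit])
}

#' Packaged reference population shares for age standardisation
#'
#' Loads the packaged synthetic stand-in for 2016-census child population
#' weights by age group (the real census counts are not redistributed here;
#' the file is labelled synthetic).
#'
#' @return a `dmft_popweights` data.frame.
#' @export
load_default_population_weights <- function() {
  read_population_weights(system.file(
    "extdata", "population_weights_2016_synthetic.csv",
    package = "dmftrend", mustWork = TRUE))
}
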