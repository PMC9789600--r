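# shared builders for small in-code fixtures

# path graph A - B - C - ... over the given labels
path_adjacency <- function(labels = c("A", "B", "C")) {
  adjacency_from_edges(labels[-length(labels)], labels[-1],
                       provinces = labels)
}

small_lattice <- function(labels = c("A", "B", "C"), years = 2000:2002,
                          age_groups = c("1-4", "5-9"),
                          adjacency = path_adjacency(labels)) {
  lattice_spec(labels, adjacency, years = years, age_groups = age_groups)
}

# complete constant-free covariate table for a lattice
flat_covariates <- function(lattice, schooling = 6, wealth = 0) {
  cells <- expand.grid(province = lattice$provinces, year = lattice$years,
                       age_group = lattice$age_groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$schooling <- schooling
  cells$wealth <- wealth
  cells$age_weight <- 0.3 +
    0.2 * (match(cells$age_group, lattice$age_groups) - 1)
  class(cells) <- c("dmft_covariates", "data.frame")
  cells
}

tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  f
}

obs_rows <- function(province = "A", year = 2000, age_group = "1-4",
                     sex = "female", index = "dmft", mean = 2, se = 0.2,
                     n = 100) {
  data.frame(province = province, year = year, age_group = age_group,
             sex = sex, index = index, mean = mean, se = se, n = n,
             stringsAsFactors = FALSE)
}

# independent naive smoother: explicit loops over target and source cells
naive_smooth <- function(residuals, lattice, params) {
  cells <- expand.grid(province = lattice$provinces, year = lattice$years,
                       age_group = lattice$age_groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- numeric(nrow(cells))
  fallback <- logical(nrow(cells))
  for (t in seq_len(nrow(cells))) {
    raw <- numeric(nrow(residuals))
    raw_fb <- numeric(nrow(residuals))
    for (s in seq_len(nrow(residuals))) {
      wl <- spatial_weight(cells$province[t], residuals$province[s],
                           params$adjacency)
      wt <- temporal_weight(cells$year[t], residuals$year[s], params)
      wa <- age_weight(cells$age_group[t], residuals$age_group[s], params)
      raw[s] <- wl * wt * wa
      raw_fb[s] <- wt * wa
    }
    if (sum(raw) <= 0) {
      raw <- raw_fb
      fallback[t] <- TRUE
    }
    out[t] <- sum(raw * residuals$residual) / sum(raw)
  }
  data.frame(cells, smoothed = out, fallback = fallback,
             stringsAsFactors = FALSE)
}
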