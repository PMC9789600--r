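#' Read and validate an observation table
#'
#' Reads a delimited text file of aggregated survey observations, one row per
#' (province, year, age group, sex, index) cell, validates it against the
#' caries-index invariants and optionally aggregates duplicate keys.
#'
#' Validation rules: `mean` must lie in `[0, 20]` (deciduous dentition has 20
#' teeth), `se` must be positive where present, `n` a positive integer where
#' present, `sex` one of `female`/`male`, `index` one of `dmft`/`dt`/`mt`/`ft`,
#' `year` inside `years`, and `age_group` one of `age_groups`.  Violations are
#' reported with the offending row numbers of the input file.
#'
#' Duplicate (province, year, age group, sex, index) keys are aggregated by
#' the sample-size-weighted mean when every duplicate carries `n`; duplicates
#' with missing `n` are an error, because no principled weight exists.  The
#' aggregated standard error is `sqrt(sum((n_i se_i)^2)) / sum(n_i)` and the
#' aggregated `n` is the total.
#'
#' @param path path to a CSV file with a header row ("." decimal mark, empty
#'   cell = missing).
#' @param schema optional named character vector mapping canonical field names
#'   (`province`, `year`, `age_group`, `sex`, `index`, `mean`, `se`, `n`) to
#'   the column names used in the file.
#' @param provinces optional character roster; observed provinces must match
#'   it (case-insensitively, after whitespace trimming).
#' @param years closed integer year range accepted; observations outside are
#'   rejected, not clipped.
#' @param age_groups admissible age-group labels.
#' @param aggregate_duplicates aggregate duplicate keys (default) instead of
#'   failing on them.
#' @return a `data.frame` of class `dmft_obs` with columns `province`, `year`,
#'   `age_group`, `sex`, `index`, `mean`, `se`, `n`.
#' @seealso [write_observations()], [read_covariates()], [read_adjacency()]
#' @export
read_observations <- function(path, schema = NULL, provinces = NULL,
                              years = 1990:2017,
                              age_groups = c("1-4", "5-9", "10-14"),
                              aggregate_duplicates = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_observations(raw, schema = schema, provinces = provinces, years = years,
                  age_groups = age_groups,
                  aggregate_duplicates = aggregate_duplicates)
}

#' Validate an in-memory observation table
#'
#' Same contract as [read_observations()] but starting from a `data.frame`.
#'
#' @param x a data.frame of observation rows.
#' @inheritParams read_observations
#' @return a validated `dmft_obs` data.frame.
#' @export
as_observations <- function(x, schema = NULL, provinces = NULL,
                            years = 1990:2017,
                            age_groups = c("1-4", "5-9", "10-14"),
                            aggregate_duplicates = TRUE) {
  required <- c("province", "year", "age_group", "sex", "index", "mean")
  optional <- c("se", "n")
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(x))
    if (length(bad))
      stop_dmft("schema error: mapped column(s) not found in file: ",
                paste(bad, collapse = ", "))
    for (canon in names(schema)) names(x)[names(x) == schema[[canon]]] <- canon
  }
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop_dmft("schema error: missing required column(s): ",
              paste(missing_cols, collapse = ", "))
  for (col in setdiff(optional, names(x))) x[[col]] <- NA_real_

  obs <- data.frame(
    province  = trimws(as.character(x$province)),
    year      = as.integer(x$year),
    age_group = canon_age(x$age_group),
    sex       = tolower(trimws(as.character(x$sex))),
    index     = tolower(trimws(as.character(x$index))),
    mean      = as.numeric(x$mean),
    se        = as.numeric(x$se),
    n         = as.numeric(x$n),
    stringsAsFactors = FALSE
  )

  fail <- function(rows, rule)
    stop_dmft("validation error: ", rule, " violated at row(s) ",
              paste(rows, collapse = ", "))
  rows <- seq_len(nrow(obs))
  bad <- rows[is.na(obs$mean) | obs$mean < 0 | obs$mean > .teeth_max]
  if (length(bad)) fail(bad, "mean ∈ [0, 20]")
  bad <- rows[!is.na(obs$se) & obs$se <= 0]
  if (length(bad)) fail(bad, "se > 0")
  bad <- rows[!is.na(obs$n) & (obs$n <= 0 | obs$n != round(obs$n))]
  if (length(bad)) fail(bad, "n positive integer")
  bad <- rows[is.na(obs$year) | !(obs$year %in% years)]
  if (length(bad)) fail(bad, paste0("year ∈ [", min(years), ", ", max(years), "]"))
  bad <- rows[!(obs$age_group %in% canon_age(age_groups))]
  if (length(bad)) fail(bad, paste0("age_group ∈ {",
                                    paste(age_groups, collapse = ", "), "}"))
  bad <- rows[!(obs$sex %in% .sexes)]
  if (length(bad)) fail(bad, "sex ∈ {female, male}")
  bad <- rows[!(obs$index %in% .indices)]
  if (length(bad)) fail(bad, "index ∈ {dmft, dt, mt, ft}")
  if (!is.null(provinces)) {
    bad <- rows[!(canon_label(obs$province) %in% canon_label(provinces))]
    if (length(bad)) fail(bad, "province in roster")
  }

  key <- cell_key(obs$province, obs$year, obs$age_group, obs$sex, obs$index)
  if (anyDuplicated(key)) {
    if (!aggregate_duplicates)
      stop_dmft("duplicate observation keys present and aggregation disabled")
    obs <- aggregate_observations(obs, key)
  }
  obs <- obs[order(canon_label(obs$province), obs$year, obs$age_group,
                   obs$sex, obs$index), , drop = FALSE]
  rownames(obs) <- NULL
  class(obs) <- c("dmft_obs", "data.frame")
  obs
}

# n-weighted aggregation of duplicate observation keys
aggregate_observations <- function(obs, key) {
  pieces <- lapply(split(obs, key), function(g) {
    if (nrow(g) == 1L) return(g)
    if (anyNA(g$n))
      stop_dmft("duplicate observation keys with missing n cannot be ",
                "aggregated (key ", cell_key(g$province[1], g$year[1],
                g$age_group[1], g$sex[1], g$index[1]), ")")
    w <- g$n / sum(g$n)
    out <- g[1, , drop = FALSE]
    out$mean <- sum(w * g$mean)
    out$se <- if (anyNA(g$se)) NA_real_ else sqrt(sum((g$n * g$se)^2)) / sum(g$n)
    out$n <- sum(g$n)
    out
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}

#' Write an observation table to CSV
#'
#' Field-for-field round trip partner of [read_observations()].
#'
#' @param obs a `dmft_obs` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a province adjacency edge list
#'
#' Reads a two-column CSV edge list (`A,B` per line, header optional) into a
#' symmetric adjacency structure.  Self-edges are rejected; isolated provinces
#' (present in `provinces` but in no edge) are permitted and reported.
#'
#' @param path path to the edge-list file.
#' @param provinces optional province roster; unknown labels in the file are
#'   an error, and isolated roster members are kept as vertices.
#' @return an object of class `dmft_adjacency`: a list with `provinces`
#'   (ordered labels) and `edges` (two-column character matrix, canonical
#'   order within each pair).
#' @seealso [is_adjacent()], [adjacency_from_edges()]
#' @export
read_adjacency <- function(path, provinces = NULL) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_dmft("adjacency file must have two columns")
  # tolerate a header line such as "from,to"
  if (nrow(raw) && canon_label(raw[1, 1]) %in% c("from", "province_a") &&
      canon_label(raw[1, 2]) %in% c("to", "province_b"))
    raw <- raw[-1, , drop = FALSE]
  adjacency_from_edges(raw[[1]], raw[[2]], provinces = provinces)
}

#' Build an adjacency structure from edge endpoint vectors
#'
#' @param a,b character vectors of edge endpoints (same length).
#' @param provinces optional province roster (see [read_adjacency()]).
#' @return a `dmft_adjacency` object.
#' @export
adjacency_from_edges <- function(a, b, provinces = NULL) {
  a <- trimws(as.character(a)); b <- trimws(as.character(b))
  if (length(a) != length(b)) stop_dmft("edge endpoint vectors differ in length")
  keep <- nzchar(a) | nzchar(b)
  a <- a[keep]; b <- b[keep]
  if (any(canon_label(a) == canon_label(b)))
    stop_dmft("self-edge in adjacency list: ",
              paste(unique(a[canon_label(a) == canon_label(b)]), collapse = ", "))
  if (!is.null(provinces)) {
    known <- canon_label(provinces)
    bad <- unique(c(a, b)[!(canon_label(c(a, b)) %in% known)])
    if (length(bad))
      stop_dmft("unknown province label(s) in adjacency list: ",
                paste(bad, collapse = ", "))
    roster <- provinces
    # map endpoint spelling onto roster spelling
    a <- roster[match(canon_label(a), known)]
    b <- roster[match(canon_label(b), known)]
  } else {
    roster <- sort(unique(c(a, b)))
  }
  lo <- ifelse(canon_label(a) <= canon_label(b), a, b)
  hi <- ifelse(canon_label(a) <= canon_label(b), b, a)
  edges <- unique(cbind(lo, hi))
  dimnames(edges) <- list(NULL, c("a", "b"))
  deg <- table(factor(canon_label(c(edges[, 1], edges[, 2])),
                      levels = canon_label(roster)))
  isolated <- roster[deg == 0]
  if (length(isolated))
    message("adjacency: isolated province(s): ", paste(isolated, collapse = ", "))
  structure(list(provinces = roster, edges = edges),
            class = "dmft_adjacency")
}

#' Test whether two provinces are adjacent
#'
#' @param adj a `dmft_adjacency` object.
#' @param a,b province labels (vectors recycled to a common length).
#' @return logical vector; `TRUE` when an edge joins `a` and `b`.  A province
#'   is not its own neighbour here; the spatial kernel adds the self-weight.
#' @export
is_adjacent <- function(adj, a, b) {
  key <- function(x, y) {
    x <- canon_label(x); y <- canon_label(y)
    paste(pmin(x, y), pmax(x, y), sep = "|")
  }
  known <- canon_label(adj$provinces)
  bad <- unique(c(a, b)[!(canon_label(c(a, b)) %in% known)])
  if (length(bad))
    stop_dmft("unknown province label(s): ", paste(bad, collapse = ", "))
  key(a, b) %in% key(adj$edges[, 1], adj$edges[, 2])
}

#' Binary adjacency matrix with unit diagonal
#'
#' The spatial kernel in matrix form: entry `(a, b)` is 1 when `a == b` or the
#' provinces are adjacent, else 0.
#'
#' @param adj a `dmft_adjacency` object.
#' @return a square 0/1 matrix with province labels as dimnames.
#' @export
adjacency_matrix <- function(adj) {
  p <- adj$provinces
  m <- diag(1, length(p))
  dimnames(m) <- list(p, p)
  if (nrow(adj$edges)) {
    i <- match(canon_label(adj$edges[, 1]), canon_label(p))
    j <- match(canon_label(adj$edges[, 2]), canon_label(p))
    m[cbind(i, j)] <- 1
    m[cbind(j, i)] <- 1
  }
  m
}

#' Vertex degrees of an adjacency structure
#' @param adj a `dmft_adjacency` object.
#' @return named integer vector of edge counts per province.
#' @export
adjacency_degrees <- function(adj) {
  deg <- table(factor(canon_label(c(adj$edges[, 1], adj$edges[, 2])),
                      levels = canon_label(adj$provinces)))
  stats::setNames(as.integer(deg), adj$provinces)
}

#' Read a covariate table
#'
#' One row per (province, year, age group) with the stage-1 fixed-effect
#' covariates: mean years of schooling, standardised wealth index, and the
#' mean within-group age weight (in `[0, 1]`).
#'
#' @param path CSV path with header columns `province`, `year`, `age_group`,
#'   `schooling`, `wealth`, `age_weight`.
#' @param lattice optional [lattice_spec()]; when given, the table must be
#'   complete over the full province x year x age-group grid (stage 1
#'   predicts everywhere).
#' @return a `data.frame` of class `dmft_covariates`.
#' @export
read_covariates <- function(path, lattice = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("province", "year", "age_group", "schooling", "wealth", "age_weight")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop_dmft("schema error: covariate file lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  x$province <- trimws(x$province)
  x$year <- as.integer(x$year)
  x$age_group <- canon_age(x$age_group)
  if (any(!is.finite(x$age_weight)) || any(x$age_weight < 0 | x$age_weight > 1))
    stop_dmft("validation error: age_weight ∈ [0, 1]")
  class(x) <- c("dmft_covariates", "data.frame")
  if (!is.null(lattice)) check_covariate_completeness(x, lattice)
  x
}

check_covariate_completeness <- function(covariates, lattice) {
  want <- expand.grid(province = lattice$provinces, year = lattice$years,
                      age_group = lattice$age_groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- cell_key(covariates$province, covariates$year, covariates$age_group)
  miss <- !(cell_key(want$province, want$year, want$age_group) %in% have)
  if (any(miss))
    stop_dmft("covariate table incomplete over the lattice; first missing ",
              "cell(s): ",
              paste(utils::head(paste(want$province[miss], want$year[miss],
                                      want$age_group[miss], sep = "/"), 5),
                    collapse = ", "))
  invisible(TRUE)
}

#' Read census population weights per age group
#'
#' @param path CSV with header columns `age_group`, `weight` (census count or
#'   proportion; any positive scale).
#' @return a `data.frame` of class `dmft_popweights`.
#' @seealso [population_shares()], [age_standardize()]
#' @export
read_population_weights <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("age_group", "weight"), names(x))
  if (length(missing_cols))
    stop_dmft("schema error: weights file lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  as_population_weights(x$age_group, x$weight)
}

#' Build population weights from vectors
#' @param age_group age-group labels.
#' @param weight positive weights (counts or proportions).
#' @return a `dmft_popweights` data.frame.
#' @export
as_population_weights <- function(age_group, weight) {
  weight <- as.numeric(weight)
  if (any(!is.finite(weight)) || any(weight < 0) || sum(weight) <= 0)
    stop_dmft("population weights must be non-negative with a positive total")
  x <- data.frame(age_group = canon_age(age_group), weight = weight,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$age_group)) stop_dmft("duplicate age_group in weights")
  class(x) <- c("dmft_popweights", "data.frame")
  x
}

#' Normalised population shares
#' @param weights a `dmft_popweights` object.
#' @return named numeric vector of shares summing to 1.
#' @export
population_shares <- function(weights) {
  stats::setNames(weights$weight / sum(weights$weight), weights$age_group)
}

#' Read a YAML run configuration
#'
#' Key-value file naming input paths, the year range, age groups, kernel
#' parameters (`lambda`, `varpi`), bootstrap settings (`B`, `level`) and the
#' RNG seed.  Parsed as-is; consumers validate the keys they use.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
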