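# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# case-insensitive, whitespace-trimmed canonical form for province labels
canon_label <- function(x) tolower(trimws(as.character(x)))

# normalize age-group spellings: unicode dashes and surrounding space -> "-"
canon_age <- function(x) {
  x <- trimws(as.character(x))
  gsub("\\s*[–—-]\\s*", "-", x)
}

# round half away from zero (all quantities here are non-negative)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# "4.37 (2.23, 6.62)" formatting used by the trend table
fmt_est <- function(est, lower, upper, digits = 2) {
  f <- function(v) sprintf(paste0("%.", digits, "f"), round_half_up(v, digits))
  paste0(f(est), " (", f(lower), ", ", f(upper), ")")
}

clip_teeth <- function(x) pmin(pmax(x, 0), .teeth_max)

# stable key for lattice/observation cells
cell_key <- function(province, year, age_group, sex = NULL, index = NULL) {
  k <- paste(canon_label(province), year, canon_age(age_group), sep = "|")
  if (!is.null(sex)) k <- paste(k, tolower(sex), sep = "|")
  if (!is.null(index)) k <- paste(k, tolower(index), sep = "|")
  k
}

stop_dmft <- function(...) stop(..., call. = FALSE)
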