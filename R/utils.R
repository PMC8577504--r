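# Shared helpers: rounding, seeds, genotype codes.

GENOTYPES <- c("AA", "AB", "BB")
CALLS <- c("AA", "AB", "BB", "NoCall")
PROVENANCE <- c("original", "rarehet", "advnorm", "conflict")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all reported percentages.
#' Base R's `round()` rounds half to even, which disagrees with printed
#' two-decimal percentages for values such as 87.545.
#'
#' @param x numeric vector
#' @param digits number of decimal digits
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # 1e-9 guards against values like 42.105 being stored as 42.104999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, half-up to two decimals
#'
#' @param num numerator count
#' @param denom denominator count
#' @return percentage on the 0-100 scale, `NA` when `denom` is 0
#' @export
pct <- function(num, denom) {
  res <- round_half_up(100 * num / denom, 2)
  res[rep_len(denom == 0, length(res))] <- NA_real_
  res
}

# Derive a stage-specific seed from the run seed.  Keeps every random draw on
# one seeding pathway and the derived value inside 32-bit integer range.
derive_seed <- function(seed, stage_offset) {
  (as.integer(seed) + as.integer(stage_offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

assert_cols <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop_input("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(dt)
}
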