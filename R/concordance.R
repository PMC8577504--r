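# MAF-concordance filter: compare array-derived MAFs with reference
# sequencing MAFs on a log2-ratio scale and exclude discordant probesets.

# Reporting bins on the reference MAF (fractions).  The filter itself is
# bin-free; bins are only used for the exclusion-rate summary.
MAF_BINS <- data.table::data.table(
  bin = c("(0,0.01%]", "(0.01%,0.05%]", "(0.05%,0.1%]", "(0.1%,0.5%]",
          "(0.5%,1%]"),
  lo = c(0, 1e-4, 5e-4, 1e-3, 5e-3),
  hi = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2))

#' Compute array MAFs from a genotype matrix
#'
#' MAF = (n_AB + 2 n_BB) / (2 n_called); NoCalls are excluded from the
#' denominator.  A variant with zero calls has an undefined MAF and is
#' flagged.
#'
#' @param final consolidated GenotypeMatrix
#' @return data.table: `variant_id`, `array_maf`, `n_called`, `undefined`
#' @export
compute_array_maf <- function(final) {
  f <- data.table::as.data.table(final)
  res <- f[, {
    n_called <- sum(call != "NoCall")
    maf <- if (n_called == 0) NA_real_ else
      (sum(call == "AB") + 2 * sum(call == "BB")) / (2 * n_called)
    list(array_maf = maf, n_called = n_called, undefined = n_called == 0)
  }, by = "probeset_id"]
  data.table::setnames(res, "probeset_id", "variant_id")
  res[]
}

# Slope and R^2 of log2(array) on log2(ref) over probesets with both MAFs > 0.
regression_diagnostics <- function(dt) {
  ok <- dt$verdict == "retained" & dt$array_maf > 0 & dt$ref_maf > 0
  sub <- dt[ok]
  if (nrow(sub) < 3) {
    return(list(slope = NA_real_, r_squared = NA_real_,
                n_regression = nrow(sub),
                n_retained = sum(dt$verdict == "retained"),
                n_excluded = sum(dt$verdict == "excluded"),
                n_indeterminate = sum(dt$verdict == "indeterminate")))
  }
  fit <- stats::lm(log2(array_maf) ~ log2(ref_maf), data = sub)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       n_regression = nrow(sub),
       n_retained = sum(dt$verdict == "retained"),
       n_excluded = sum(dt$verdict == "excluded"),
       n_indeterminate = sum(dt$verdict == "indeterminate"))
}

#' Filter probesets by MAF concordance
#'
#' Computes r = log2(array_maf / ref_maf) per variant and excludes those
#' with r above `t_upper` or below `t_lower`.  When either MAF is zero the
#' ratio is undefined and the probeset is "indeterminate": it is routed to
#' experimental validation rather than excluded, because reference cohorts
#' lack resolution below about 0.01% MAF.
#'
#' @param array_mafs [compute_array_maf()] output (or any table with
#'   `variant_id`, `array_maf`)
#' @param ref_mafs reference table (`variant_id`, `ref_maf`)
#' @param t_upper upper log2-ratio threshold (default 1.72)
#' @param t_lower lower log2-ratio threshold (default -2)
#' @return list: `results` (per-variant ConcordanceResult rows),
#'   `diagnostics` (slope/R^2 over the retained set), `bins` (exclusion
#'   rate per reference-MAF bin)
#' @export
filter_by_concordance <- function(array_mafs, ref_mafs,
                                  t_upper = 1.72, t_lower = -2) {
  a <- data.table::as.data.table(array_mafs)
  r <- data.table::as.data.table(ref_mafs)
  assert_cols(a, c("variant_id", "array_maf"), "array_mafs")
  assert_cols(r, c("variant_id", "ref_maf"), "ref_mafs")
  dt <- a[r, on = "variant_id", nomatch = NULL]
  if (!nrow(dt)) {
    stop_input("filter_by_concordance: no variants shared between array and reference tables")
  }
  dt[, log2_ratio := ifelse(!is.na(array_maf) & array_maf > 0 & ref_maf > 0,
                            log2(array_maf / ref_maf), NA_real_)]
  dt[, verdict := ifelse(is.na(log2_ratio), "indeterminate",
                    ifelse(log2_ratio > t_upper | log2_ratio < t_lower,
                           "excluded", "retained"))]
  dt[, `:=`(t_upper = t_upper, t_lower = t_lower)]
  bins <- MAF_BINS[, {
    inb <- !is.na(dt$ref_maf) & dt$ref_maf > lo & dt$ref_maf <= hi
    list(n = sum(inb), n_excluded = sum(inb & dt$verdict == "excluded"))
  }, by = "bin"]
  bins[, exclusion_rate := ifelse(n > 0, n_excluded / n, NA_real_)]
  list(results = dt[], diagnostics = regression_diagnostics(dt), bins = bins)
}

#' Choose concordance thresholds by grid search
#'
#' Scans a grid of (t_upper, t_lower) pairs and returns the pair maximizing
#' the R^2 of the retained-set regression; ties are broken toward the widest
#' interval (fewest exclusions).  This is a diagnostic aid and never
#' silently overrides the default thresholds.
#'
#' @param array_mafs,ref_mafs as for [filter_by_concordance()]
#' @param upper_grid,lower_grid candidate thresholds
#' @return list: `t_upper`, `t_lower`, `surface` (R^2 per grid pair)
#' @export
optimize_thresholds <- function(array_mafs, ref_mafs,
                                upper_grid = seq(0.5, 3, by = 0.25),
                                lower_grid = seq(-3, -0.5, by = 0.25)) {
  grid <- data.table::CJ(t_upper = upper_grid, t_lower = lower_grid)
  grid[, r_squared := vapply(seq_len(.N), function(i) {
    filter_by_concordance(array_mafs, ref_mafs, t_upper[i],
                          t_lower[i])$diagnostics$r_squared
  }, numeric(1))]
  grid[, width := t_upper - t_lower]
  best <- grid[order(-r_squared, -width)][1]
  list(t_upper = best$t_upper, t_lower = best$t_lower, surface = grid[])
}
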