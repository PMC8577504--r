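# Consolidation of the two adjustment algorithms and adjustment bookkeeping.

#' Merge rare-het and advnorm call matrices
#'
#' Per cell: if neither algorithm changed the base call, the base call is
#' kept; if exactly one changed it, that change is kept; if both changed it
#' and agree, the agreed call is kept; if both changed it and disagree, the
#' cell becomes NoCall with provenance "conflict" (the conservative reading
#' of filtering conflicting results).
#'
#' @param calls_rarehet GenotypeMatrix after [rare_het_adjust()]
#' @param calls_advnorm GenotypeMatrix after [renormalize_and_recall()]
#' @param base the pre-adjustment GenotypeMatrix both were derived from
#' @return the consolidated GenotypeMatrix
#' @export
consolidate_calls <- function(calls_rarehet, calls_advnorm, base) {
  key <- c("probeset_id", "sample_id")
  b <- data.table::as.data.table(base)
  r <- data.table::as.data.table(calls_rarehet)
  a <- data.table::as.data.table(calls_advnorm)
  if (nrow(b) != nrow(r) || nrow(b) != nrow(a)) {
    stop_input("consolidate_calls: matrices cover different cells")
  }
  data.table::setorderv(b, key); b <- data.table::copy(b)
  r <- r[b[, key, with = FALSE], on = key]
  a <- a[b[, key, with = FALSE], on = key]
  if (anyNA(r$call) || anyNA(a$call)) {
    stop_input("consolidate_calls: matrices cover different cells")
  }
  changed_r <- r$call != b$call
  changed_a <- a$call != b$call
  conflict <- changed_r & changed_a & (r$call != a$call)
  out <- data.table::copy(b)
  take_r <- changed_r & !conflict
  take_a <- changed_a & !changed_r
  out[take_a, `:=`(call = a$call[take_a], confidence = a$confidence[take_a],
                   provenance = a$provenance[take_a])]
  out[take_r, `:=`(call = r$call[take_r], confidence = r$confidence[take_r],
                   provenance = r$provenance[take_r])]
  out[conflict, `:=`(call = "NoCall", confidence = NA_real_,
                     provenance = "conflict")]
  out[]
}

#' Account for per-variant adjustments
#'
#' Classifies each variant that had at least one heterozygous (AB) call
#' before adjustment as:
#' \describe{
#'   \item{adjusted_to_wildtype}{no minor-allele call (AB or BB) remains}
#'   \item{het_count_modified}{the AB-call count changed but minor-allele
#'     calls remain}
#'   \item{unchanged}{the AB-call count is unchanged and minor-allele calls
#'     remain}
#' }
#' The three categories partition the variants with a pre-adjustment het
#' call; percentages are reported half-up to two decimals.
#'
#' @param base pre-adjustment GenotypeMatrix
#' @param final adjusted GenotypeMatrix
#' @return an `adjustment_summary` list of counts and percentages
#' @export
summarize_adjustments <- function(base, final) {
  key <- c("probeset_id", "sample_id")
  b <- data.table::as.data.table(base)
  f <- data.table::as.data.table(final)
  if (nrow(b) != nrow(f)) stop_input("summarize_adjustments: matrices not aligned")
  bs <- b[, list(n_ab_base = sum(call == "AB")), by = "probeset_id"]
  fs <- f[, list(n_ab_final = sum(call == "AB"),
                 n_minor_final = sum(call %in% c("AB", "BB"))),
          by = "probeset_id"]
  s <- fs[bs, on = "probeset_id"]
  s <- s[n_ab_base > 0]
  n_het <- nrow(s)
  s[, category := ifelse(n_minor_final == 0, "adjusted_to_wildtype",
                    ifelse(n_ab_final != n_ab_base, "het_count_modified",
                           "unchanged"))]
  n_wt <- sum(s$category == "adjusted_to_wildtype")
  n_mod <- sum(s$category == "het_count_modified")
  n_same <- sum(s$category == "unchanged")
  stopifnot(n_wt + n_mod + n_same == n_het)
  structure(list(
    n_variants_with_het = n_het,
    n_adjusted_to_wildtype = n_wt,
    n_het_count_modified = n_mod,
    n_adjusted = n_wt + n_mod,
    n_unchanged = n_same,
    pct_adjusted_to_wildtype = pct(n_wt, n_het),
    pct_het_count_modified = pct(n_mod, n_het),
    pct_adjusted = pct(n_wt + n_mod, n_het),
    pct_unchanged = pct(n_same, n_het),
    per_variant = s[, c("probeset_id", "category")]),
    class = "adjustment_summary")
}

#' @export
print.adjustment_summary <- function(x, ...) {
  cat(sprintf("Variants with >=1 het call: %d\n", x$n_variants_with_het))
  cat(sprintf("  adjusted (total):      %d (%.2f%%)\n", x$n_adjusted,
              x$pct_adjusted))
  cat(sprintf("  adjusted to wild-type: %d (%.2f%%)\n",
              x$n_adjusted_to_wildtype, x$pct_adjusted_to_wildtype))
  cat(sprintf("  het count modified:    %d (%.2f%%)\n",
              x$n_het_count_modified, x$pct_het_count_modified))
  cat(sprintf("  unchanged:             %d (%.2f%%)\n", x$n_unchanged,
              x$pct_unchanged))
  invisible(x)
}
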