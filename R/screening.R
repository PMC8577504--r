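# Disease-panel screening evaluation: MAF-binned confusion counts and
# PPV/NPV against a gold standard (wet-lab confirmations in production,
# simulation ground truth in synthetic runs — same schema).

SCREEN_BINS <- c(low = "MAF<=0.01%", high = "0.01%<MAF<=1%")

#' Positive predictive value, percent, half-up to two decimals
#' @param tp,fp confirmed and refuted positive counts
#' @return PPV on the 0-100 scale; `NA` (flagged, not 0) when TP+FP = 0
#' @export
ppv <- function(tp, fp) pct(tp, tp + fp)

#' Negative predictive value, percent, half-up to two decimals
#' @param tn,fn confirmed and refuted negative counts
#' @return NPV on the 0-100 scale; `NA` when TN+FN = 0
#' @export
npv <- function(tn, fn) pct(tn, tn + fn)

#' Assign rare variants to screening MAF bins
#'
#' Half-open binning on the reference MAF: "MAF<=0.01%" for ref_maf <=
#' 0.0001 (boundary inclusive in the lower bin), "0.01%<MAF<=1%" up to 0.01.
#' Variants above 1% are not rare and are rejected ("not_rare"); variants
#' without a reference MAF are reported "unbinned".
#'
#' @param variants character vector of variant ids
#' @param ref_mafs reference MAF table (`variant_id`, `ref_maf`)
#' @return data.table: `variant_id`, `ref_maf`, `bin`
#' @export
bin_by_maf <- function(variants, ref_mafs) {
  r <- data.table::as.data.table(ref_mafs)
  dt <- data.table::data.table(variant_id = as.character(variants))
  dt[, ref_maf := r$ref_maf[match(variant_id, r$variant_id)]]
  dt[, bin := ifelse(is.na(ref_maf), "unbinned",
                ifelse(ref_maf <= 1e-4, SCREEN_BINS[["low"]],
                  ifelse(ref_maf <= 1e-2, SCREEN_BINS[["high"]],
                         "not_rare")))]
  dt[]
}

#' Build the wet-lab validation worklist
#'
#' Every minor-allele call (AB or BB) on a panel variant requires
#' confirmation; this emits one row per such (sample, variant).
#'
#' @param final consolidated, concordance-filtered GenotypeMatrix
#' @param panels panel definition table (`panel`, `variant_id`); panels may
#'   overlap
#' @return data.table: `panel`, `variant_id`, `sample_id`, `call`
#' @export
export_validation_list <- function(final, panels) {
  f <- data.table::as.data.table(final)
  p <- data.table::as.data.table(panels)
  assert_cols(p, c("panel", "variant_id"), "panels")
  pos <- f[call %in% c("AB", "BB")]
  out <- p[pos, on = c(variant_id = "probeset_id"), nomatch = NULL,
           allow.cartesian = TRUE]
  out <- out[, c("panel", "variant_id", "sample_id", "call")]
  data.table::setorderv(out, c("panel", "variant_id", "sample_id"))
  out[]
}

#' Sample negative calls for NPV estimation
#'
#' Draws a seeded random fraction of the negative (wild-type AA) calls on
#' panel variants; these are re-checked against the gold standard to
#' estimate the NPV.  The default fraction is 1.35%.
#'
#' @param final consolidated GenotypeMatrix
#' @param panels panel definition table
#' @param fraction fraction of negative calls to sample
#' @param seed integer seed
#' @return data.table: `panel`, `variant_id`, `sample_id`, `call`
#' @export
sample_negative_calls <- function(final, panels, fraction = 0.0135, seed) {
  if (missing(seed)) stop_input("sample_negative_calls: seed is mandatory")
  f <- data.table::as.data.table(final)
  p <- data.table::as.data.table(panels)
  neg <- p[f[call == "AA"], on = c(variant_id = "probeset_id"),
           nomatch = NULL, allow.cartesian = TRUE]
  set.seed(derive_seed(seed, 7919L))
  take <- sort(sample.int(nrow(neg), size = round(fraction * nrow(neg))))
  out <- neg[take, c("panel", "variant_id", "sample_id", "call")]
  data.table::setorderv(out, c("panel", "variant_id", "sample_id"))
  out[]
}

#' Evaluate screening performance per panel and MAF bin
#'
#' TP = minor-allele call confirmed by the gold standard (gold genotype
#' carries a minor allele); FP = refuted (gold genotype AA).  TN/FN are
#' computed over the sampled negative calls, if provided.  PPV and NPV are
#' percentages, half-up to two decimals, and undefined (NA) rather than 0
#' when the denominator is empty.
#'
#' @param worklist [export_validation_list()] output
#' @param gold_standard confirmation table (`sample_id`, `variant_id`,
#'   `confirmed_genotype` in AA/AB/BB); must cover every worklist row
#' @param ref_mafs reference MAF table used for binning
#' @param negatives optional [sample_negative_calls()] output for NPV
#' @return a `screening_report` data.table: per `panel` x `bin` TP, FP, TN,
#'   FN, `ppv`, `npv`
#' @export
evaluate_screening <- function(worklist, gold_standard, ref_mafs,
                               negatives = NULL) {
  w <- data.table::as.data.table(worklist)
  g <- data.table::as.data.table(gold_standard)
  assert_cols(g, c("sample_id", "variant_id", "confirmed_genotype"),
              "gold_standard")
  join <- c("sample_id", "variant_id")
  w[, gold := g$confirmed_genotype[match(paste(sample_id, variant_id),
                                         paste(g$sample_id, g$variant_id))]]
  if (anyNA(w$gold)) {
    miss <- w[is.na(gold)]
    stop_input("evaluate_screening: %d worklist row(s) missing from gold standard (first: %s / %s)",
               nrow(miss), miss$sample_id[1], miss$variant_id[1])
  }
  bins <- bin_by_maf(unique(w$variant_id), ref_mafs)
  w[, bin := bins$bin[match(variant_id, bins$variant_id)]]
  pos <- w[, list(TP = sum(gold %in% c("AB", "BB")),
                  FP = sum(gold == "AA")),
           by = c("panel", "bin")]
  frame <- data.table::CJ(panel = unique(w$panel),
                          bin = unname(SCREEN_BINS), unique = TRUE)
  rep_ <- pos[frame, on = c("panel", "bin")]
  for (col in c("TP", "FP")) {
    data.table::set(rep_, which(is.na(rep_[[col]])), col, 0L)
  }
  rep_[, `:=`(TN = 0L, FN = 0L)]
  if (!is.null(negatives) && nrow(negatives)) {
    n <- data.table::as.data.table(negatives)
    n[, gold := g$confirmed_genotype[match(paste(sample_id, variant_id),
                                           paste(g$sample_id, g$variant_id))]]
    if (anyNA(n$gold)) {
      stop_input("evaluate_screening: sampled negative call missing from gold standard")
    }
    nb <- bin_by_maf(unique(n$variant_id), ref_mafs)
    n[, bin := nb$bin[match(variant_id, nb$variant_id)]]
    negs <- n[, list(TN = sum(gold == "AA"),
                     FN = sum(gold %in% c("AB", "BB"))),
              by = c("panel", "bin")]
    rep_[negs, on = c("panel", "bin"), `:=`(TN = i.TN, FN = i.FN)]
  }
  rep_[, `:=`(ppv = ppv(TP, FP), npv = npv(TN, FN))]
  data.table::setorderv(rep_, c("panel", "bin"))
  data.table::setattr(rep_, "class", c("screening_report", class(rep_)))
  rep_[]
}
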