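# Advanced normalization: detect plate-level contrast shifts within a batch
# and reassign affected calls to the correct cluster.
#
# Because rare-variant probesets are almost entirely wild-type, the median
# contrast of a plate is a robust estimate of where that plate's major-allele
# cluster sits.  The per-plate shift is therefore estimated as
#   delta = median(plate contrasts) - median(plate medians across the batch)
# which needs no genotype calls at all — crucial, since a strongly shifted
# plate may have had every sample miscalled — and whose batch center is not
# contaminated by the shifted plate as long as fewer than half the plates in
# a batch are shifted.  Flagged plates have their
# contrasts shifted back by delta and are re-called against the original
# batch cluster model (no refit), keeping the operation deterministic and
# idempotent.

#' Estimate per-plate contrast shifts
#'
#' @param summary [summarize_signals()] result
#' @param manifest sample manifest
#' @param shift_threshold absolute shift (contrast units) above which a
#'   plate is flagged (default 0.5)
#' @param min_plate_n minimum samples on a plate for an estimate (default 8);
#'   smaller plates are skipped (delta `NA`, `skipped = TRUE`)
#' @return data.table of PlateShiftEstimate rows: `probeset_id`, `batch_id`,
#'   `plate_id`, `n_samples`, `delta`, `flagged`, `skipped`
#' @export
estimate_plate_shifts <- function(summary, manifest, shift_threshold = 0.5,
                                  min_plate_n = 8L) {
  cells <- data.table::copy(summary$cells)
  cells[, `:=`(plate_id = manifest$plate_id[match(sample_id, manifest$sample_id)],
               batch_id = manifest$batch_id[match(sample_id, manifest$sample_id)])]
  est <- cells[, list(n_samples = .N,
                      plate_median = stats::median(contrast)),
               by = c("probeset_id", "batch_id", "plate_id")]
  batch_med <- est[, list(batch_median = stats::median(plate_median)),
                   by = c("probeset_id", "batch_id")]
  est <- batch_med[est, on = c("probeset_id", "batch_id")]
  est[, skipped := n_samples < min_plate_n]
  est[, delta := ifelse(skipped, NA_real_, plate_median - batch_median)]
  est[, flagged := !skipped & abs(delta) > shift_threshold]
  est[, c("plate_median", "batch_median") := NULL]
  data.table::setcolorder(est, c("probeset_id", "batch_id", "plate_id",
                                 "n_samples", "delta", "flagged", "skipped"))
  data.table::setorderv(est, c("probeset_id", "batch_id", "plate_id"))
  est[]
}

#' Renormalize flagged plates and re-call their genotypes
#'
#' For each flagged probeset x plate, subtracts the estimated shift from
#' those samples' contrasts and re-calls them against the batch cluster
#' model.  Calls that change get provenance "advnorm"; everything else is
#' untouched.
#'
#' @param summary [summarize_signals()] result
#' @param calls GenotypeMatrix to adjust
#' @param shifts [estimate_plate_shifts()] output
#' @param model batch [fit_clusters()] model
#' @param manifest sample manifest
#' @param confidence_threshold posterior threshold for the re-call
#'   (default 0.95, matching the original calling)
#' @return list with `calls` (adjusted GenotypeMatrix) and `audit`
#'   (data.table of changed calls: old call, new call, delta applied)
#' @export
renormalize_and_recall <- function(summary, calls, shifts, model, manifest,
                                   confidence_threshold = 0.95) {
  out <- data.table::copy(data.table::as.data.table(calls))
  audit0 <- data.table::data.table(probeset_id = character(),
                                   sample_id = character(),
                                   plate_id = character(),
                                   delta = numeric(),
                                   old_call = character(),
                                   new_call = character())
  flagged <- data.table::as.data.table(shifts)[flagged == TRUE]
  if (!nrow(flagged)) return(list(calls = out, audit = audit0))

  cells <- data.table::copy(summary$cells)
  cells[, `:=`(plate_id = manifest$plate_id[match(sample_id, manifest$sample_id)],
               batch_id = manifest$batch_id[match(sample_id, manifest$sample_id)])]
  cells <- cells[flagged[, c("probeset_id", "plate_id", "delta")],
                 on = c("probeset_id", "plate_id")]
  cells[, contrast_adj := contrast - delta]
  mdl <- data.table::as.data.table(model)
  recalled <- cells[, {
    block <- mdl[list(probeset_id = .BY$probeset_id, batch_id = batch_id[1]),
                 on = c("probeset_id", "batch_id")]
    post <- cluster_posteriors(contrast_adj, block)
    best <- max.col(post, ties.method = "first")
    conf <- post[cbind(seq_along(best), best)]
    list(sample_id = sample_id, plate_id = plate_id, delta = delta,
         new_call = ifelse(conf < confidence_threshold, "NoCall",
                           block$cluster[best]),
         new_conf = conf)
  }, by = "probeset_id"]
  recalled[, old_call := out[recalled, on = c("probeset_id", "sample_id"),
                             x.call]]
  changed <- recalled[new_call != old_call]
  if (nrow(changed)) {
    out[changed, on = c("probeset_id", "sample_id"),
        `:=`(call = i.new_call, confidence = i.new_conf,
             provenance = "advnorm")]
  }
  audit <- changed[, c("probeset_id", "sample_id", "plate_id", "delta",
                       "old_call", "new_call")]
  list(calls = out, audit = audit)
}
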