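# Rare het adjustment: demote heterozygous calls whose replicate-probe
# signals are internally inconsistent to NoCall.
#
# A true heterozygote's replicate probes all sit near the AB cluster; a
# bubble or scratch hitting one replicate drags that replicate's contrast
# toward a homozygote cluster while leaving the others in place.  Two
# conditions flag an AB call as uncertain: (i) replicate dispersion
# D = max |contrast_i - median(contrasts)| exceeding d_max, or (ii) any
# replicate whose nearest cluster (z-distance under the batch model) is not
# AB.  Only AB calls are ever demoted; all other calls pass through
# bit-identical, which also makes the operation idempotent.

#' Demote inconsistent heterozygous calls to NoCall
#'
#' @param calls GenotypeMatrix from [call_genotypes()]
#' @param summary [summarize_signals()] result (per-replicate contrasts)
#' @param model batch [fit_clusters()] model
#' @param manifest sample manifest
#' @param d_max maximum allowed replicate dispersion, in contrast units
#'   (default 1.0, about 4 within-cluster SDs under default simulation
#'   parameters)
#' @return list with `calls` (adjusted GenotypeMatrix; demoted cells get
#'   call "NoCall" and provenance "rarehet") and `decisions` (audit
#'   data.table: `probeset_id`, `sample_id`, `dispersion`,
#'   `all_replicates_ab`, `verdict`)
#' @export
rare_het_adjust <- function(calls, summary, model, manifest, d_max = 1.0) {
  assert_cols(calls, c("probeset_id", "sample_id", "call", "confidence",
                       "provenance"), "calls")
  out <- data.table::copy(data.table::as.data.table(calls))
  het <- out[call == "AB", c("probeset_id", "sample_id")]
  if (!nrow(het)) {
    return(list(calls = out,
                decisions = data.table::data.table(
                  probeset_id = character(), sample_id = character(),
                  dispersion = numeric(), all_replicates_ab = logical(),
                  verdict = character())))
  }
  reps <- summary$replicates[het, on = c("probeset_id", "sample_id")]
  if (anyNA(reps$contrast)) {
    bad <- unique(reps$probeset_id[is.na(reps$contrast)])
    stop_input("rare_het_adjust: missing replicate data for probeset %s",
               bad[1])
  }
  reps[, batch_id := manifest$batch_id[match(sample_id, manifest$sample_id)]]
  mdl <- data.table::as.data.table(model)
  decisions <- reps[, {
    block <- mdl[list(probeset_id = .BY$probeset_id, batch_id = batch_id[1]),
                 on = c("probeset_id", "batch_id")]
    disp <- max(abs(contrast - stats::median(contrast)))
    z <- outer(contrast, seq_len(nrow(block)), function(c_i, j)
      abs(c_i - block$mean[j]) / sqrt(block$var[j]))
    nearest <- block$cluster[max.col(-z, ties.method = "first")]
    all_ab <- all(nearest == "AB")
    list(dispersion = disp, all_replicates_ab = all_ab,
         verdict = if (disp > d_max || !all_ab) "demote_to_nocall" else "keep")
  }, by = c("probeset_id", "sample_id")]
  demote <- decisions[verdict == "demote_to_nocall",
                      c("probeset_id", "sample_id")]
  if (nrow(demote)) {
    out[demote, on = c("probeset_id", "sample_id"),
        `:=`(call = "NoCall", provenance = "rarehet")]
  }
  list(calls = out, decisions = decisions)
}
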