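#' @importFrom data.table := .N .BY .SD data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "batch_id", "plate_id", "sample_id", "probeset_id", "variant_id",
  "contrast", "size", "probe_replicate_index", "channel_A", "channel_B",
  "call", "confidence", "provenance", "cluster", "converged",
  "verdict", "dispersion", "delta", "flagged", "skipped", "n_samples",
  "contrast_adj", "new_call", "new_conf", "old_call", "i.new_call",
  "i.new_conf", "x.call", "n_ab_base", "n_ab_final", "n_minor_final",
  "category", "array_maf", "ref_maf", "log2_ratio", "t_upper", "t_lower",
  "lo", "hi", "n", "n_excluded", "r_squared", "width", "bin", "gold",
  "panel", "TP", "FP", "TN", "FN", "i.TN", "i.FN", "true_maf",
  "cross_hyb", "genotype", "i.call", "n_replicates", "variant_ref",
  "factor.", "channel"))
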