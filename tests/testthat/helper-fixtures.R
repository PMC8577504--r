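# Shared fixture builders.  Everything is generated in code; no stored data.

library(data.table)

# A batch of probeset specs with MAFs spread across the rare-variant range.
default_specs <- function(n = 10, mafs = NULL, panel = NA_character_, ...) {
  if (is.null(mafs)) {
    mafs <- rep(c(5e-5, 2e-4, 5e-4, 2e-3, 5e-3), length.out = n)
  }
  lapply(seq_len(n), function(i) {
    probeset_spec(sprintf("PS%03d", i), true_maf = mafs[(i - 1) %% length(mafs) + 1],
                  panel = panel, ...)
  })
}

# Small clean experiment: no artifacts, no shifts.
clean_sim <- function(n_samples = 200, n_probesets = 10, seed = 1,
                      n_plates = 2, plates_per_batch = 2, mafs = NULL, ...) {
  cfg <- simulation_config(
    n_samples = n_samples, n_plates = n_plates,
    plates_per_batch = plates_per_batch,
    probesets = default_specs(n_probesets, mafs = mafs, ...),
    seed = seed)
  simulate_experiment(cfg)
}

# Run summarize/fit/call on a simulation with default tunables.
call_sim <- function(sim, confidence_threshold = 0.95) {
  summary <- summarize_signals(sim$intensities, sim$annotation)
  model <- fit_clusters(summary, sim$manifest)
  calls <- call_genotypes(summary, model, sim$manifest, confidence_threshold)
  list(summary = summary, model = model, calls = calls)
}

# Hand-built single-probeset, single-batch cluster model block.
toy_model <- function(means = c(AA = 3, AB = 0, BB = -3),
                      vars = c(AA = 0.0625, AB = 0.0625, BB = 0.0625),
                      weights = c(AA = 0.98, AB = 0.015, BB = 0.005),
                      probeset_id = "PS001", batch_id = "B01") {
  m <- data.table(probeset_id = probeset_id, batch_id = batch_id,
                  cluster = names(means), mean = unname(means),
                  var = unname(vars), weight = unname(weights),
                  n_soft = unname(weights) * 100, converged = TRUE)
  setattr(m, "class", c("cluster_model", class(m)))
  m
}

# A minimal genotype matrix from vectors.
toy_calls <- function(calls, probeset_id = "PS001",
                      sample_id = sprintf("S%05d", seq_along(calls)),
                      confidence = 0.99, provenance = "original") {
  data.table(probeset_id = probeset_id, sample_id = sample_id,
             call = calls, confidence = confidence, provenance = provenance)
}

# Fraction of final calls matching simulation truth (NoCall counts as miss).
truth_concordance <- function(calls, truth_genotypes) {
  m <- merge(as.data.table(calls), as.data.table(truth_genotypes),
             by = c("probeset_id", "sample_id"))
  mean(m$call == m$genotype)
}
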