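# Synthetic two-channel array experiments with known ground truth.
#
# The generator emulates the pathologies the QC pipeline must correct:
# bubble/scratch artifacts (extreme high signal on a single replicate probe),
# plate-level batch shifts (additive offsets in log2 intensity), and
# cross-hybridizing probesets whose array signal reflects a contaminated
# allele frequency decoupled from the reference cohort.

#' Describe one simulated probeset
#'
#' Cluster geometry is parameterized in contrast/size space: the AA cluster
#' sits at contrast `+cluster_sep`, AB at 0, BB at `-cluster_sep` (contrast =
#' log2(A) - log2(B); A is the reference/major allele).  Each channel's log2
#' intensity is Gaussian with standard deviation `channel_sd`, so the
#' within-cluster contrast SD is `channel_sd * sqrt(2)` (0.25 contrast units
#' at the default 0.177).
#'
#' @param probeset_id probeset identifier
#' @param true_maf population minor-allele frequency, must be < 0.01
#'   (the rare-variant regime)
#' @param n_replicate_probes number of replicate probes (>= 1); default 3,
#'   the minimum allowing outlier detection among replicates
#' @param cluster_sep contrast separation between adjacent genotype clusters
#' @param size_mean mean size ((log2 A + log2 B)/2) of every cluster
#' @param channel_sd per-channel log2-intensity standard deviation
#' @param cross_hyb if `TRUE`, the array signal is generated at
#'   `cross_hyb_maf` instead of `true_maf` (non-target hybridization), while
#'   the reference cohort still sees `true_maf`
#' @param cross_hyb_maf contamination MAF used for the array signal of a
#'   cross-hybridizing probeset
#' @param panel optional disease-panel name the probeset belongs to
#' @return a `probeset_spec` list
#' @export
probeset_spec <- function(probeset_id, true_maf, n_replicate_probes = 3L,
                          cluster_sep = 3, size_mean = 10,
                          channel_sd = 0.25 / sqrt(2),
                          cross_hyb = FALSE, cross_hyb_maf = NULL,
                          panel = NA_character_) {
  if (!is.numeric(true_maf) || is.na(true_maf) ||
      true_maf < 0 || true_maf >= 0.01) {
    stop_input("probeset_spec: true_maf must be in [0, 0.01) (rare-variant regime), got %s",
               format(true_maf))
  }
  if (n_replicate_probes < 1) {
    stop_input("probeset_spec: n_replicate_probes must be >= 1")
  }
  if (cluster_sep <= 0) {
    stop_input("probeset_spec: cluster_sep must be > 0 (AA and BB cluster means must be distinct)")
  }
  if (channel_sd <= 0) stop_input("probeset_spec: channel_sd must be > 0")
  if (cross_hyb) {
    if (is.null(cross_hyb_maf) || cross_hyb_maf < 0 || cross_hyb_maf > 0.5) {
      stop_input("probeset_spec: cross_hyb requires cross_hyb_maf in [0, 0.5]")
    }
  }
  structure(list(probeset_id = as.character(probeset_id),
                 true_maf = true_maf,
                 n_replicate_probes = as.integer(n_replicate_probes),
                 cluster_sep = cluster_sep, size_mean = size_mean,
                 channel_sd = channel_sd,
                 cross_hyb = isTRUE(cross_hyb),
                 cross_hyb_maf = if (isTRUE(cross_hyb)) cross_hyb_maf else NA_real_,
                 panel = panel),
            class = "probeset_spec")
}

#' Build a simulation configuration
#'
#' @param n_samples number of samples (> 0)
#' @param n_plates number of plates; samples are distributed round-robin
#' @param plates_per_batch plates grouped into one processing batch
#'   (default 24, the production grouping by processing date)
#' @param probesets list of [probeset_spec()] objects
#' @param seed mandatory integer seed; identical config + seed gives
#'   bit-identical output
#' @param artifact_rate fraction of sample-by-probeset cells hit by a
#'   bubble/scratch artifact on one replicate probe, in [0, 1)
#' @param batch_shift data.frame with columns `plate_id`, `shift`
#'   (log2-intensity units) and optionally `channel` ("A" or "B", default
#'   "A"): an additive log2 shift applied to every probe of that channel on
#'   the named plates
#' @return a `sim_config` list
#' @export
simulation_config <- function(n_samples, n_plates = 1L, plates_per_batch = 24L,
                              probesets, seed,
                              artifact_rate = 0,
                              batch_shift = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_input("simulation_config: seed is mandatory")
  }
  if (n_samples <= 0) stop_input("simulation_config: n_samples must be > 0")
  if (n_plates <= 0) stop_input("simulation_config: n_plates must be > 0")
  if (plates_per_batch < 1) stop_input("simulation_config: plates_per_batch must be >= 1")
  if (artifact_rate < 0 || artifact_rate >= 1) {
    stop_input("simulation_config: artifact_rate must be in [0, 1)")
  }
  if (!length(probesets)) stop_input("simulation_config: probesets must be non-empty")
  if (inherits(probesets, "probeset_spec")) probesets <- list(probesets)
  ok <- vapply(probesets, inherits, logical(1), "probeset_spec")
  if (!all(ok)) stop_input("simulation_config: probesets must be probeset_spec objects")
  ids <- vapply(probesets, `[[`, character(1), "probeset_id")
  if (anyDuplicated(ids)) stop_input("simulation_config: duplicate probeset_id")
  if (!is.null(batch_shift)) {
    batch_shift <- as.data.frame(batch_shift)
    assert_cols(batch_shift, c("plate_id", "shift"), "batch_shift")
    if (is.null(batch_shift$channel)) batch_shift$channel <- "A"
    if (!all(batch_shift$channel %in% c("A", "B"))) {
      stop_input("simulation_config: batch_shift channel must be 'A' or 'B'")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_plates = as.integer(n_plates),
                 plates_per_batch = as.integer(plates_per_batch),
                 probesets = probesets,
                 seed = as.integer(seed),
                 artifact_rate = artifact_rate,
                 batch_shift = batch_shift),
            class = "sim_config")
}

# Cluster channel means for one probeset spec: log2 A/B mean per genotype.
cluster_channel_means <- function(spec) {
  contrast <- c(AA = spec$cluster_sep, AB = 0, BB = -spec$cluster_sep)
  list(log2A = spec$size_mean + contrast / 2,
       log2B = spec$size_mean - contrast / 2)
}

# Sample manifest: samples assigned to plates round-robin, plates grouped
# into batches of plates_per_batch consecutive plates.
build_manifest <- function(config) {
  sample_id <- sprintf("S%05d", seq_len(config$n_samples))
  plate_idx <- ((seq_len(config$n_samples) - 1L) %% config$n_plates) + 1L
  batch_idx <- ((plate_idx - 1L) %/% config$plates_per_batch) + 1L
  data.table::data.table(sample_id = sample_id,
                         plate_id = sprintf("P%03d", plate_idx),
                         batch_id = sprintf("B%02d", batch_idx))
}

#' Simulate a two-channel array experiment
#'
#' Draws Hardy-Weinberg genotypes per probeset, emits per-replicate-probe
#' linear intensities from log2-normal clusters, then injects the configured
#' pathologies.  Every injected pathology is recorded in the returned ground
#' truth.  Deterministic under `config$seed`.
#'
#' @param config a [simulation_config()]
#' @return list with elements:
#'   \describe{
#'     \item{intensities}{data.table: `probeset_id`, `probe_replicate_index`,
#'       `sample_id`, `channel_A`, `channel_B` (raw linear intensities)}
#'     \item{annotation}{data.table: probeset identity, coordinates, alleles,
#'       replicate count, panel}
#'     \item{manifest}{data.table: `sample_id`, `plate_id`, `batch_id`}
#'     \item{truth}{ground truth: genotypes, probeset parameters, injected
#'       artifacts, shifted plates, cross-hyb probesets}
#'   }
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_input("simulate_experiment: config must come from simulation_config()")
  }
  set.seed(derive_seed(config$seed, 0L))
  manifest <- build_manifest(config)
  n_ps <- length(config$probesets)

  annotation <- data.table::rbindlist(lapply(seq_len(n_ps), function(i) {
    sp <- config$probesets[[i]]
    data.table::data.table(
      probeset_id = sp$probeset_id,
      rsid = sprintf("rs%07d", 1000000L + i),
      chrom = as.character(((i - 1L) %% 22L) + 1L),
      pos = 10000L + 1000L * i,
      ref_allele = "A", alt_allele = "G",
      n_replicate_probes = sp$n_replicate_probes,
      panel = sp$panel)
  }))

  per_ps <- lapply(config$probesets, function(sp) {
    signal_maf <- if (sp$cross_hyb) sp$cross_hyb_maf else sp$true_maf
    # Hardy-Weinberg draw; B is the minor/alternate allele.
    p <- signal_maf
    geno <- sample(GENOTYPES, config$n_samples, replace = TRUE,
                   prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    mu <- cluster_channel_means(sp)
    reps <- sp$n_replicate_probes
    n_cells <- config$n_samples * reps
    gi <- rep(geno, each = reps)
    log2A <- stats::rnorm(n_cells, mu$log2A[gi], sp$channel_sd)
    log2B <- stats::rnorm(n_cells, mu$log2B[gi], sp$channel_sd)
    intens <- data.table::data.table(
      probeset_id = sp$probeset_id,
      probe_replicate_index = rep(seq_len(reps), times = config$n_samples),
      sample_id = rep(manifest$sample_id, each = reps),
      log2A = log2A, log2B = log2B)
    truth <- data.table::data.table(probeset_id = sp$probeset_id,
                                    sample_id = manifest$sample_id,
                                    genotype = geno)
    list(intens = intens, truth = truth)
  })
  intensities <- data.table::rbindlist(lapply(per_ps, `[[`, "intens"))
  genotypes <- data.table::rbindlist(lapply(per_ps, `[[`, "truth"))

  # Plate-level batch shifts: additive in log2 on one channel.
  shifted_plates <- data.table::data.table(plate_id = character(),
                                           shift = numeric(),
                                           channel = character())
  if (!is.null(config$batch_shift) && nrow(config$batch_shift)) {
    shifted_plates <- data.table::as.data.table(
      config$batch_shift)[, c("plate_id", "shift", "channel"), with = FALSE]
    plate_of <- manifest$plate_id[match(intensities$sample_id, manifest$sample_id)]
    for (k in seq_len(nrow(shifted_plates))) {
      on_plate <- plate_of == shifted_plates$plate_id[k]
      if (shifted_plates$channel[k] == "A") {
        intensities[on_plate, "log2A"] <- intensities$log2A[on_plate] +
          shifted_plates$shift[k]
      } else {
        intensities[on_plate, "log2B"] <- intensities$log2B[on_plate] +
          shifted_plates$shift[k]
      }
    }
  }

  intensities[, `:=`(channel_A = 2^intensities$log2A,
                     channel_B = 2^intensities$log2B)]
  intensities[, c("log2A", "log2B") := NULL]

  # Bubble/scratch artifacts: one replicate of an affected cell gets an
  # extreme high signal on one channel (multiplied by 2^U(2,4), i.e. 4-16x).
  artifacts <- data.table::data.table(probeset_id = character(),
                                      sample_id = character(),
                                      probe_replicate_index = integer(),
                                      channel = character(),
                                      factor = numeric())
  if (config$artifact_rate > 0) {
    cells <- unique(intensities[, c("probeset_id", "sample_id")])
    hit <- stats::runif(nrow(cells)) < config$artifact_rate
    cells <- cells[hit]
    if (nrow(cells)) {
      reps_of <- annotation$n_replicate_probes[match(cells$probeset_id,
                                                     annotation$probeset_id)]
      cells[, `:=`(
        probe_replicate_index = vapply(reps_of, function(r)
          sample.int(r, 1L), integer(1)),
        channel = sample(c("A", "B"), nrow(cells), replace = TRUE),
        factor = 2^stats::runif(nrow(cells), 2, 4))]
      artifacts <- cells
      data.table::setkeyv(intensities, c("probeset_id", "sample_id",
                                         "probe_replicate_index"))
      for (ch in c("A", "B")) {
        sub <- artifacts[artifacts$channel == ch]
        if (!nrow(sub)) next
        col <- paste0("channel_", ch)
        idx <- intensities[sub[, c("probeset_id", "sample_id",
                                   "probe_replicate_index")], which = TRUE]
        data.table::set(intensities, idx, col,
                        intensities[[col]][idx] * sub$factor)
      }
    }
  }
  data.table::setkey(intensities, NULL)
  data.table::setorderv(intensities,
                        c("probeset_id", "sample_id", "probe_replicate_index"))

  probeset_truth <- data.table::rbindlist(lapply(config$probesets, function(sp) {
    data.table::data.table(probeset_id = sp$probeset_id,
                           true_maf = sp$true_maf,
                           cross_hyb = sp$cross_hyb,
                           cross_hyb_maf = sp$cross_hyb_maf)
  }))

  list(intensities = intensities,
       annotation = annotation,
       manifest = manifest,
       truth = list(genotypes = genotypes,
                    probesets = probeset_truth,
                    artifacts = artifacts,
                    shifted_plates = shifted_plates,
                    cross_hyb_probesets =
                      probeset_truth$probeset_id[probeset_truth$cross_hyb]))
}

#' Simulate a reference (sequencing-cohort) MAF table
#'
#' Reference MAFs are estimated from an independent binomial draw of
#' `2 * ref_cohort_size` alleles at each probeset's true MAF, so array and
#' reference cohorts differ, as they do when array data are compared to a
#' separately sequenced population.  Cross-hybridizing probesets keep their
#' uncontaminated `true_maf` here: their array signal is decoupled from the
#' reference by construction.
#'
#' @param truth the `truth` element returned by [simulate_experiment()]
#' @param ref_cohort_size number of sequenced individuals (> 0); the default
#'   3370 matches a realistic reference whole-genome cohort
#' @param seed integer seed for the reference draw
#' @return data.table: `variant_id`, `ref_maf` (fraction)
#' @export
simulate_reference_maf <- function(truth, ref_cohort_size = 3370L, seed) {
  if (ref_cohort_size <= 0) {
    stop_input("simulate_reference_maf: ref_cohort_size must be > 0")
  }
  if (missing(seed)) stop_input("simulate_reference_maf: seed is mandatory")
  set.seed(derive_seed(seed, 104729L))
  ps <- truth$probesets
  n_alleles <- 2L * as.integer(ref_cohort_size)
  data.table::data.table(
    variant_id = ps$probeset_id,
    ref_maf = stats::rbinom(nrow(ps), n_alleles, ps$true_maf) / n_alleles)
}
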