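# Pipeline orchestration: configuration, stage sequencing, artifacts.
#
# Stage order: calling -> (rare het adjustment + advanced normalization, in
# parallel from the same base calls) -> consolidation -> MAF-concordance
# filter -> screening evaluation.

pipeline_defaults <- list(
  input_dir = NULL, out_dir = NULL, seed = NULL,
  epsilon = 1,
  prior_center = 3, prior_variance = 0.25, prior_pseudo_n = 2,
  confidence_threshold = 0.95,
  d_max = 1.0,
  shift_threshold = 0.5, min_plate_n = 8L,
  t_upper = 1.72, t_lower = -2,
  npv_fraction = 0.0135,
  ref_cohort_size = 3370L,
  do_rarehet = TRUE, do_advnorm = TRUE,
  do_concordance = TRUE, do_screening = TRUE)

#' Build a pipeline configuration
#'
#' Unknown keys are rejected.  `seed` is mandatory and is the single source
#' of randomness for the whole run (stage-specific seeds are derived from
#' it).  Every run writes the resolved configuration beside its outputs.
#'
#' @param ... configuration values overriding the defaults, or a single
#'   named list of them
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown)) {
    stop_input("pipeline_config: unknown key(s): %s",
               paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(pipeline_defaults, over)
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop_input("pipeline_config: seed is mandatory")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of configuration keys
#' @return a `pipeline_config` list
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

# Read the canonical input files from a directory.
read_inputs <- function(dir) {
  need <- c("intensities.tsv", "annotation.tsv", "manifest.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop_input("read_inputs: %s not found in %s", f, dir)
    }
  }
  inputs <- list(intensities = read_tsv(file.path(dir, "intensities.tsv")),
                 annotation = read_tsv(file.path(dir, "annotation.tsv")),
                 manifest = read_tsv(file.path(dir, "manifest.tsv")))
  opt <- c(ref_mafs = "ref_maf.tsv", panels = "panels.tsv",
           gold_standard = "gold_standard.tsv")
  for (nm in names(opt)) {
    p <- file.path(dir, opt[[nm]])
    if (file.exists(p)) inputs[[nm]] <- read_tsv(p)
  }
  tg <- file.path(dir, "truth", "genotypes.tsv")
  if (file.exists(tg)) inputs$truth_genotypes <- read_tsv(tg)
  inputs
}

# Panels from explicit table or from the annotation's panel column.
resolve_panels <- function(inputs) {
  if (!is.null(inputs$panels)) return(data.table::as.data.table(inputs$panels))
  ann <- data.table::as.data.table(inputs$annotation)
  if (!"panel" %in% names(ann)) return(NULL)
  p <- ann[!is.na(panel) & panel != "", list(panel = panel,
                                             variant_id = probeset_id)]
  if (nrow(p)) p else NULL
}

# Gold standard from explicit table or (synthetic mode) simulation truth.
resolve_gold <- function(inputs) {
  if (!is.null(inputs$gold_standard)) {
    return(data.table::as.data.table(inputs$gold_standard))
  }
  if (!is.null(inputs$truth_genotypes)) {
    tg <- data.table::as.data.table(inputs$truth_genotypes)
    return(tg[, list(sample_id = sample_id, variant_id = probeset_id,
                     confirmed_genotype = genotype)])
  }
  NULL
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full quality-control pipeline
#'
#' @param config a [pipeline_config()]
#' @param inputs optional in-memory inputs (list with `intensities`,
#'   `annotation`, `manifest` and optionally `ref_mafs`, `panels`,
#'   `gold_standard`, `truth_genotypes`); when `NULL` they are read from
#'   `config$input_dir`
#' @return invisibly, a list of all stage artifacts
#' @export
run_pipeline <- function(config, inputs = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(inputs)) {
    if (is.null(config$input_dir)) {
      stop_input("run_pipeline: provide inputs or config$input_dir")
    }
    inputs <- run_stage("read_inputs", read_inputs(config$input_dir))
  }
  out_dir <- config$out_dir
  emit <- function(dt, name) {
    if (!is.null(out_dir)) write_tsv(dt, file.path(out_dir, name))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  }

  priors <- cluster_priors(
    centers = c(AA = config$prior_center, AB = 0, BB = -config$prior_center),
    variance = config$prior_variance, pseudo_n = config$prior_pseudo_n)

  summary <- run_stage("summarize_signals",
                       summarize_signals(inputs$intensities, inputs$annotation,
                                         epsilon = config$epsilon))
  model <- run_stage("fit_clusters",
                     fit_clusters(summary, inputs$manifest, priors))
  base <- run_stage("call_genotypes",
                    call_genotypes(summary, model, inputs$manifest,
                                   config$confidence_threshold))
  emit(base, "calls_base.tsv")

  if (config$do_rarehet) {
    rh <- run_stage("rarehet",
                    rare_het_adjust(base, summary, model, inputs$manifest,
                                    d_max = config$d_max))
  } else {
    rh <- list(calls = data.table::copy(base),
               decisions = data.table::data.table())
  }
  emit(rh$decisions, "rarehet_decisions.tsv")

  if (config$do_advnorm) {
    shifts <- run_stage("estimate_plate_shifts",
                        estimate_plate_shifts(summary, inputs$manifest,
                                              config$shift_threshold,
                                              config$min_plate_n))
    an <- run_stage("renormalize_and_recall",
                    renormalize_and_recall(summary, base, shifts, model,
                                           inputs$manifest,
                                           config$confidence_threshold))
  } else {
    shifts <- data.table::data.table()
    an <- list(calls = data.table::copy(base),
               audit = data.table::data.table())
  }
  emit(shifts, "plate_shifts.tsv")
  emit(an$audit, "advnorm_audit.tsv")

  final <- run_stage("consolidate",
                     consolidate_calls(rh$calls, an$calls, base))
  emit(final, "calls_final.tsv")
  adj <- run_stage("summarize_adjustments", summarize_adjustments(base, final))

  concord <- NULL
  screened_final <- final
  if (config$do_concordance && !is.null(inputs$ref_mafs)) {
    amaf <- run_stage("compute_array_maf", compute_array_maf(final))
    concord <- run_stage("filter_by_concordance",
                         filter_by_concordance(amaf, inputs$ref_mafs,
                                               config$t_upper, config$t_lower))
    emit(concord$results, "concordance.tsv")
    emit(concord$bins, "concordance_bins.tsv")
    excluded <- concord$results$variant_id[concord$results$verdict == "excluded"]
    screened_final <- final[!probeset_id %in% excluded]
  }

  screening <- NULL
  worklist <- NULL
  panels <- resolve_panels(inputs)
  gold <- resolve_gold(inputs)
  if (config$do_screening && !is.null(panels) && !is.null(gold) &&
      !is.null(inputs$ref_mafs)) {
    worklist <- run_stage("export_validation_list",
                          export_validation_list(screened_final, panels))
    negatives <- run_stage("sample_negative_calls",
                           sample_negative_calls(screened_final, panels,
                                                 config$npv_fraction,
                                                 seed = config$seed))
    screening <- run_stage("evaluate_screening",
                           evaluate_screening(worklist, gold, inputs$ref_mafs,
                                              negatives))
    emit(worklist, "worklist.tsv")
    emit(screening, "screening_report.tsv")
  }

  artifacts <- list(summary = summary, model = model, base = base,
                    rarehet = rh, shifts = shifts, advnorm = an,
                    final = final, adjustments = adj,
                    concordance = concord, worklist = worklist,
                    screening = screening)
  if (!is.null(out_dir)) {
    write_vcf(final, inputs$annotation, file.path(out_dir, "calls_final.vcf"))
    manifest <- list(
      package = "rarevarqc",
      version = as.character(utils::packageVersion("rarevarqc")),
      seed = config$seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input_digests = if (!is.null(config$input_dir)) {
        files <- list.files(config$input_dir, pattern = "\\.tsv$",
                            full.names = TRUE)
        as.list(tools::md5sum(files))
      } else list())
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(
      list(adjustments = unclass(adj)[!names(adj) %in% "per_variant"],
           concordance = if (!is.null(concord)) concord$diagnostics),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  invisible(artifacts)
}
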