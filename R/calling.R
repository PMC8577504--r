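# Cluster-based genotype calling in contrast space.
#
# Signals are summarized per probeset x sample as contrast = log2(A) - log2(B)
# and size = (log2(A) + log2(B))/2, averaged across replicate probes (the
# per-replicate contrasts are retained for the rare-het adjustment).  Per
# probeset and batch, a 3-component 1-D Gaussian mixture in contrast is fitted
# by prior-regularized EM; pseudo-observations keep unobserved clusters at
# their prior positions, which is what makes rare variants callable when a
# batch contains no (or almost no) minor-allele carriers.

#' Default cluster priors
#'
#' Pseudo-observation weight 2 per cluster, prior centers at +3/0/-3 contrast
#' units (A-allele homozygote positive, by the A = reference convention) and
#' prior variance 0.25 — a BRLMM-P-style prior-regularized EM.
#'
#' @param centers named prior cluster centers (contrast units)
#' @param variance prior within-cluster variance (contrast units squared)
#' @param pseudo_n pseudo-observation weight per cluster
#' @param max_iter maximum EM iterations
#' @param tol convergence tolerance on the largest cluster-mean change
#' @return a list of prior settings
#' @export
cluster_priors <- function(centers = c(AA = 3, AB = 0, BB = -3),
                           variance = 0.25, pseudo_n = 2,
                           max_iter = 100L, tol = 1e-6) {
  if (!all(GENOTYPES %in% names(centers))) {
    stop_input("cluster_priors: centers must be named AA, AB, BB")
  }
  if (centers["AA"] <= centers["AB"] || centers["AB"] <= centers["BB"]) {
    stop_input("cluster_priors: centers must satisfy AA > AB > BB in contrast")
  }
  if (variance <= 0) stop_input("cluster_priors: variance must be > 0")
  list(centers = centers[GENOTYPES], variance = variance,
       pseudo_n = pseudo_n, max_iter = as.integer(max_iter), tol = tol)
}

#' Summarize two-channel intensities into contrast and size
#'
#' A pseudocount of `epsilon` is added to the raw linear intensities before
#' the log2 transform so zero intensities stay finite.
#'
#' @param intensities IntensitySet data.table (`probeset_id`,
#'   `probe_replicate_index`, `sample_id`, `channel_A`, `channel_B`)
#' @param annotation probeset annotation; every probeset in `intensities`
#'   must appear here
#' @param epsilon pseudocount added to each channel before log2 (default 1)
#' @return a `signal_summary` list with `cells` (per probeset x sample mean
#'   contrast/size) and `replicates` (per-replicate contrast/size)
#' @export
summarize_signals <- function(intensities, annotation, epsilon = 1) {
  assert_cols(intensities, c("probeset_id", "probe_replicate_index",
                             "sample_id", "channel_A", "channel_B"),
              "intensities")
  missing_ps <- setdiff(unique(intensities$probeset_id),
                        annotation$probeset_id)
  if (length(missing_ps)) {
    stop_input("summarize_signals: probeset(s) absent from annotation: %s",
               paste(utils::head(missing_ps, 5), collapse = ", "))
  }
  if (any(intensities$channel_A < 0) || any(intensities$channel_B < 0)) {
    stop_input("summarize_signals: negative intensities in input")
  }
  reps <- data.table::as.data.table(intensities)[, list(
    probeset_id = probeset_id,
    sample_id = sample_id,
    probe_replicate_index = probe_replicate_index,
    contrast = log2(channel_A + epsilon) - log2(channel_B + epsilon),
    size = (log2(channel_A + epsilon) + log2(channel_B + epsilon)) / 2)]
  cells <- reps[, list(contrast = mean(contrast), size = mean(size),
                       n_replicates = .N),
                by = c("probeset_id", "sample_id")]
  obs <- unique(reps[, list(probeset_id, n = max(probe_replicate_index))])
  ann_n <- annotation$n_replicate_probes[match(obs$probeset_id,
                                               annotation$probeset_id)]
  if (any(obs$n != ann_n)) {
    stop_input("summarize_signals: replicate count disagrees with annotation for %s",
               paste(obs$probeset_id[obs$n != ann_n][1]))
  }
  structure(list(cells = cells, replicates = reps, epsilon = epsilon),
            class = "signal_summary")
}

# MAP EM for a 3-component Gaussian mixture in contrast, one probeset x batch.
# Pseudo-observations of weight kappa anchor each component at its prior
# center/variance; components with no assigned samples retain the prior.
fit_mixture_em <- function(x, priors) {
  k <- 3L
  kappa <- priors$pseudo_n
  m0 <- as.numeric(priors$centers)
  v0 <- priors$variance
  mu <- m0
  vv <- rep(v0, k)
  w <- rep(1 / k, k)
  n <- length(x)
  converged <- FALSE
  for (iter in seq_len(priors$max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(vv[j])), numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    nk <- colSums(r)
    mu_new <- (kappa * m0 + colSums(r * x)) / (kappa + nk)
    vv_new <- vapply(seq_len(k), function(j) {
      ss <- sum(r[, j] * (x - mu_new[j])^2)
      (kappa * (v0 + (mu_new[j] - m0[j])^2) + ss) / (kappa + nk[j])
    }, numeric(1))
    vv_new <- pmax(vv_new, 1e-4)
    w_new <- (kappa + nk) / (k * kappa + n)
    delta <- max(abs(mu_new - mu))
    mu <- mu_new; vv <- vv_new; w <- w_new
    if (delta < priors$tol) { converged <- TRUE; break }
  }
  dens <- vapply(seq_len(k), function(j)
    w[j] * stats::dnorm(x, mu[j], sqrt(vv[j])), numeric(n))
  dens <- matrix(dens, nrow = n)
  nk <- colSums(dens / pmax(rowSums(dens), .Machine$double.xmin))
  ord <- order(mu, decreasing = TRUE)  # enforce AA > AB > BB in contrast
  list(mean = mu[ord], var = vv[ord], weight = w[ord], n_soft = nk[ord],
       converged = converged)
}

#' Fit per-batch genotype cluster models
#'
#' One 3-component 1-D Gaussian mixture in contrast per probeset per batch,
#' fitted by EM with pseudo-observation priors (see [cluster_priors()]).  The
#' batch — not the plate — is the unit of cluster fitting.
#'
#' @param summary a [summarize_signals()] result
#' @param manifest sample manifest (`sample_id`, `plate_id`, `batch_id`)
#' @param priors a [cluster_priors()] list
#' @return a `cluster_model` data.table: one row per probeset x batch x
#'   cluster with `mean`, `var`, `weight`, `n_soft`, `converged`
#' @export
fit_clusters <- function(summary, manifest, priors = cluster_priors()) {
  cells <- data.table::copy(summary$cells)
  cells[, batch_id := manifest$batch_id[match(sample_id, manifest$sample_id)]]
  if (anyNA(cells$batch_id)) {
    stop_input("fit_clusters: sample(s) missing from manifest")
  }
  batch_n <- cells[, .N, by = c("probeset_id", "batch_id")]
  if (any(batch_n$N < 2)) {
    stop_input("fit_clusters: every probeset x batch needs >= 2 samples")
  }
  model <- cells[, {
    fit <- fit_mixture_em(contrast, priors)
    list(cluster = GENOTYPES, mean = fit$mean, var = fit$var,
         weight = fit$weight, n_soft = fit$n_soft, converged = fit$converged)
  }, by = c("probeset_id", "batch_id")]
  data.table::setattr(model, "class",
                      c("cluster_model", class(model)))
  model
}

# Posterior cluster probabilities for contrasts under one probeset x batch
# model block (rows ordered AA, AB, BB).
cluster_posteriors <- function(contrast, block) {
  dens <- vapply(seq_len(nrow(block)), function(j)
    block$weight[j] * stats::dnorm(contrast, block$mean[j],
                                   sqrt(block$var[j])), numeric(length(contrast)))
  dens <- matrix(dens, nrow = length(contrast))
  dens / pmax(rowSums(dens), .Machine$double.xmin)
}

#' Call genotypes from fitted cluster models
#'
#' Call = argmax posterior cluster; confidence = the posterior of the chosen
#' cluster; a posterior below `confidence_threshold` gives NoCall.  Probesets
#' whose EM did not converge are set wholly to NoCall.
#'
#' @param summary a [summarize_signals()] result
#' @param model a [fit_clusters()] result
#' @param manifest sample manifest
#' @param confidence_threshold minimum posterior for a call (default 0.95)
#' @return GenotypeMatrix data.table: `probeset_id`, `sample_id`, `call`,
#'   `confidence`, `provenance` ("original")
#' @export
call_genotypes <- function(summary, model, manifest,
                           confidence_threshold = 0.95) {
  cells <- data.table::copy(summary$cells)
  cells[, batch_id := manifest$batch_id[match(sample_id, manifest$sample_id)]]
  mdl <- data.table::as.data.table(model)
  have <- unique(mdl[, c("probeset_id", "batch_id")])
  need <- unique(cells[, c("probeset_id", "batch_id")])
  if (nrow(need[!have, on = c("probeset_id", "batch_id")])) {
    stop_input("call_genotypes: model missing for some probeset x batch")
  }
  calls <- cells[, {
    block <- mdl[.BY, on = c("probeset_id", "batch_id")]
    if (!all(block$converged)) {
      list(sample_id = sample_id, call = "NoCall",
           confidence = NA_real_)
    } else {
      post <- cluster_posteriors(contrast, block)
      best <- max.col(post, ties.method = "first")
      conf <- post[cbind(seq_along(best), best)]
      call <- ifelse(conf < confidence_threshold, "NoCall",
                     block$cluster[best])
      list(sample_id = sample_id, call = call, confidence = conf)
    }
  }, by = c("probeset_id", "batch_id")]
  calls[, batch_id := NULL]
  calls[, provenance := "original"]
  data.table::setorderv(calls, c("probeset_id", "sample_id"))
  calls[]
}
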