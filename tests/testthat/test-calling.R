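# Signal summarization, prior-regularized EM, posterior calling.

make_intensities <- function(A, B, probeset_id = "PS001",
                             sample_id = "S00001", reps = seq_along(A)) {
  data.table(probeset_id = probeset_id, probe_replicate_index = reps,
             sample_id = sample_id, channel_A = A, channel_B = B)
}

ann1 <- data.table(probeset_id = "PS001", rsid = "rs0000001", chrom = "1",
                   pos = 100L, ref_allele = "A", alt_allele = "G",
                   n_replicate_probes = 3L, panel = NA_character_)

test_that("contrast and size follow the pseudocount-guarded log2 transform", {
  # A = B everywhere -> contrast 0
  s <- summarize_signals(make_intensities(c(100, 200, 300), c(100, 200, 300)),
                         ann1)
  expect_equal(s$cells$contrast, 0)
  # powers of two: A=4095, B=255 with epsilon 1 -> contrast exactly 4
  ann_1rep <- copy(ann1)[, n_replicate_probes := 1L]
  s <- summarize_signals(make_intensities(4095, 255, reps = 1L), ann_1rep)
  expect_equal(s$cells$contrast, 4.0)
  # cell contrast is the arithmetic mean of replicate contrasts
  A <- (2^c(2.0, 2.2, 2.4)) * 256 - 1
  s <- summarize_signals(make_intensities(A, rep(255, 3)), ann1)
  expect_equal(s$replicates$contrast, c(2.0, 2.2, 2.4))
  expect_equal(s$cells$contrast, 2.2)
  # negative intensities are an input error
  expect_error(summarize_signals(make_intensities(c(-1, 2, 3), c(1, 1, 1)),
                                 ann1), "negative")
  # probesets absent from annotation are rejected
  expect_error(summarize_signals(make_intensities(1, 1, probeset_id = "PS999",
                                                  reps = 1L), ann1),
               "annotation")
})

test_that("EM recovers group means and keeps empty clusters at the prior", {
  manifest <- data.table(sample_id = sprintf("S%05d", 1:40),
                         plate_id = "P001", batch_id = "B01")
  set.seed(42)
  # two well-separated groups at +3 and 0
  contrasts <- c(rnorm(20, 3, 0.2), rnorm(20, 0, 0.2))
  reps <- data.table(probeset_id = "PS001",
                     sample_id = manifest$sample_id,
                     probe_replicate_index = 1L,
                     contrast = contrasts, size = 10)
  summary <- structure(list(cells = reps[, list(contrast = mean(contrast),
                                                size = 10, n_replicates = 1L),
                                         by = c("probeset_id", "sample_id")],
                            replicates = reps, epsilon = 1),
                       class = "signal_summary")
  model <- fit_clusters(summary, manifest)
  expect_equal(model$cluster, c("AA", "AB", "BB"))
  expect_lt(abs(model$mean[model$cluster == "AA"] - mean(contrasts[1:20])), 0.1)
  expect_lt(abs(model$mean[model$cluster == "AB"] - mean(contrasts[21:40])), 0.1)
  # BB saw no data: prior retained
  expect_lt(abs(model$mean[model$cluster == "BB"] - (-3)), 0.05)
  expect_equal(model$var[model$cluster == "BB"], 0.25, tolerance = 0.05)
  # weights sum to 1, AA > AB > BB ordering in contrast
  expect_equal(sum(model$weight), 1)
  expect_true(all(diff(model$mean) < 0))

  # all samples in one tight group: only AA moves
  reps1 <- copy(reps)[, contrast := rnorm(.N, 3, 0.1)]
  summary1 <- structure(list(cells = reps1[, list(contrast = mean(contrast),
                                                  size = 10,
                                                  n_replicates = 1L),
                                           by = c("probeset_id", "sample_id")],
                             replicates = reps1, epsilon = 1),
                        class = "signal_summary")
  m1 <- fit_clusters(summary1, manifest)
  expect_lt(abs(m1$mean[m1$cluster == "AA"] - 3), 0.1)
  expect_lt(abs(m1$mean[m1$cluster == "AB"] - 0), 0.05)
  expect_lt(abs(m1$mean[m1$cluster == "BB"] - (-3)), 0.05)
})

test_that("EM means maximize the penalized profile objective (grid oracle)", {
  manifest <- data.table(sample_id = sprintf("S%05d", 1:10),
                         plate_id = "P001", batch_id = "B01")
  set.seed(7)
  contrasts <- c(rnorm(7, 3, 0.3), rnorm(3, 0, 0.3))
  cells <- data.table(probeset_id = "PS001", sample_id = manifest$sample_id,
                      contrast = contrasts, size = 10, n_replicates = 1L)
  summary <- structure(list(cells = cells, replicates = cells, epsilon = 1),
                       class = "signal_summary")
  priors <- cluster_priors()
  model <- fit_clusters(summary, manifest, priors)

  # independent oracle: penalized observed-data log-likelihood with the
  # fitted variances/weights held fixed, maximized over a mean grid
  objective <- function(mu) {
    ll <- sum(log(rowSums(vapply(1:3, function(k)
      model$weight[k] * dnorm(contrasts, mu[k], sqrt(model$var[k])),
      numeric(length(contrasts))))))
    pen <- sum(priors$pseudo_n / (2 * model$var) *
                 (mu - priors$centers)^2)
    ll - pen
  }
  grid_aa <- seq(2.5, 3.5, by = 0.01)
  grid_ab <- seq(-0.5, 0.5, by = 0.01)
  vals <- outer(grid_aa, grid_ab, Vectorize(function(a, b)
    objective(c(a, b, model$mean[3]))))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  expect_lt(abs(grid_aa[best[1]] - model$mean[1]), 0.02)
  expect_lt(abs(grid_ab[best[2]] - model$mean[2]), 0.02)
})

test_that("posterior calling matches closed-form Bayes arithmetic", {
  # hand-built two-effective-cluster model (BB weight negligible)
  m <- toy_model(means = c(AA = 2, AB = 0, BB = -2),
                 vars = c(AA = 0.25, AB = 0.25, BB = 0.25),
                 weights = c(AA = 0.6, AB = 0.4, BB = 0))
  cells <- data.table(probeset_id = "PS001",
                      sample_id = sprintf("S%05d", 1:3),
                      contrast = c(1.9, 0.3, 1.0), size = 10,
                      n_replicates = 1L)
  manifest <- data.table(sample_id = cells$sample_id, plate_id = "P001",
                         batch_id = "B01")
  summary <- structure(list(cells = cells, replicates = cells, epsilon = 1),
                       class = "signal_summary")
  calls <- call_genotypes(summary, m, manifest, confidence_threshold = 0.5)
  bayes <- function(x) {
    num <- c(0.6 * dnorm(x, 2, 0.5), 0.4 * dnorm(x, 0, 0.5), 0)
    num / sum(num)
  }
  for (i in 1:3) {
    post <- bayes(cells$contrast[i])
    expect_equal(calls$confidence[i], max(post), tolerance = 1e-12)
    expect_equal(calls$call[i], c("AA", "AB", "BB")[which.max(post)])
  }
})

test_that("calls at cluster means are confident; equidistant points NoCall", {
  m <- toy_model(weights = c(AA = 1, AB = 1, BB = 1) / 3)
  cells <- data.table(probeset_id = "PS001",
                      sample_id = c("S00001", "S00002"),
                      contrast = c(3, 1.5), size = 10, n_replicates = 1L)
  manifest <- data.table(sample_id = cells$sample_id, plate_id = "P001",
                         batch_id = "B01")
  summary <- structure(list(cells = cells, replicates = cells, epsilon = 1),
                       class = "signal_summary")
  calls <- call_genotypes(summary, m, manifest)
  expect_equal(calls$call[calls$sample_id == "S00001"], "AA")
  expect_gt(calls$confidence[calls$sample_id == "S00001"], 0.99)
  # midway between AA and AB with equal variance and weight: posterior 0.5
  expect_equal(calls$call[calls$sample_id == "S00002"], "NoCall")
  expect_equal(calls$confidence[calls$sample_id == "S00002"], 0.5,
               tolerance = 1e-6)
})

test_that("no-noise simulations call at 100% concordance with truth", {
  sim <- clean_sim(n_samples = 200, n_probesets = 8, seed = 21)
  res <- call_sim(sim)
  expect_equal(truth_concordance(res$calls, sim$truth$genotypes), 1)
})

test_that("calls are invariant to sample order and global channel rescaling", {
  sim <- clean_sim(n_samples = 80, n_probesets = 4, seed = 22)
  res <- call_sim(sim)
  # permute sample rows
  perm <- copy(sim$intensities)[sample(.N)]
  res_perm <- call_sim(list(intensities = perm, annotation = sim$annotation,
                            manifest = sim$manifest,
                            truth = sim$truth))
  expect_equal(data.table::setorderv(copy(res_perm$calls),
                                     c("probeset_id", "sample_id")),
               res$calls)
  # rescale both channels by the same constant
  scaled <- copy(sim$intensities)[, `:=`(channel_A = channel_A * 2.5,
                                         channel_B = channel_B * 2.5)]
  res_scaled <- call_sim(list(intensities = scaled,
                              annotation = sim$annotation,
                              manifest = sim$manifest, truth = sim$truth))
  expect_equal(res_scaled$calls$call, res$calls$call)
})

test_that("the NoCall set shrinks monotonically as the threshold drops", {
  sim <- clean_sim(n_samples = 100, n_probesets = 5, seed = 23,
                   channel_sd = 0.6)  # noisy on purpose
  summary <- summarize_signals(sim$intensities, sim$annotation)
  model <- fit_clusters(summary, sim$manifest)
  thresholds <- c(0.99, 0.95, 0.8, 0.5)
  nocall_sets <- lapply(thresholds, function(t) {
    calls <- call_genotypes(summary, model, sim$manifest, t)
    which(calls$call == "NoCall")
  })
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(nocall_sets[[i]] %in% nocall_sets[[i - 1]]))
  }
})
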