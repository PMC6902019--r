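# Synthetic TMT experiment generator: mixing arithmetic, determinism,
# mass conservation, input validation.

noiseless_config <- function(..., seed = 11) {
  simulation_config(
    n_proteins = 50, n_decoys = 0,
    purity_matrix = diag(3),
    translocator_fraction = 0,
    donor_sd = 0, psm_noise_sd = 0,
    psm_count_law = function(n) rep(3L, n),
    seed = seed, ...)
}

test_that("with identity purity and zero noise, ratios are constant over time within a fraction", {
  sim <- simulate_experiment(noiseless_config())
  ratios <- compute_psm_ratios(sim$psms, sim$design)
  pq <- rollup_to_protein(ratios, sim$design)  # unnormalized on purpose
  samp <- pq$samples
  for (f in c("C", "M", "N")) for (d in unique(samp$donor)) {
    cols <- samp$sample[samp$fraction == f & samp$donor == d]
    sub <- pq$log2ratio[, cols, drop = FALSE]
    expect_lt(max(abs(sub - sub[, 1])), 1e-9)
  }
})

test_that("translocator fold changes match the closed-form mixing oracle", {
  cfg <- simulation_config(
    n_proteins = 60, n_decoys = 0, purity_matrix = diag(3),
    translocator_fraction = 0.1, effect_size = 0.8,
    donor_sd = 0, psm_noise_sd = 0,
    psm_count_law = function(n) rep(2L, n), seed = 5)
  sim <- simulate_experiment(cfg)
  # unnormalized ratios: the mixing oracle concerns the generator itself
  ratios <- compute_psm_ratios(sim$psms, sim$design)
  pq <- rollup_to_protein(ratios, sim$design)
  tr <- sim$truth[sim$truth$is_translocator, ]
  expect_gt(nrow(tr), 0)
  samp <- pq$samples
  for (i in seq_len(nrow(tr))) {
    g <- tr$gene[i]
    for (f in c("C", "M", "N")) {
      p0 <- tr[[paste0("p_", f, "_0")]][i]
      p60 <- tr[[paste0("p_", f, "_60")]][i]
      expected <- log2(p60 / p0)       # identity purity: pure mixing change
      for (d in unique(samp$donor)) {
        c0 <- samp$sample[samp$fraction == f & samp$donor == d &
                            samp$timepoint_min == 0]
        c60 <- samp$sample[samp$fraction == f & samp$donor == d &
                             samp$timepoint_min == 60]
        expect_equal(pq$log2ratio[g, c60] - pq$log2ratio[g, c0],
                     expected, tolerance = 1e-9)
      }
    }
    # sink gain equals source loss (mass conservation of the event)
    src <- tr$source[i]; snk <- tr$sink[i]
    loss <- tr[[paste0("p_", src, "_0")]][i] - tr[[paste0("p_", src, "_60")]][i]
    gain <- tr[[paste0("p_", snk, "_60")]][i] - tr[[paste0("p_", snk, "_0")]][i]
    expect_equal(loss, gain, tolerance = 1e-12)
    expect_equal(loss, tr$moved_mass_60[i], tolerance = 1e-12)
  }
})

test_that("the same seed reproduces the experiment exactly and profiles conserve mass", {
  cfg <- simulation_config(n_proteins = 40, n_decoys = 20, seed = 42)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$psms, sim2$psms)
  expect_identical(sim1$design, sim2$design)
  expect_identical(sim1$truth, sim2$truth)

  # profiles non-negative, sum to 1 at each timepoint
  for (tp in c(0, 15, 60)) {
    p <- as.matrix(sim1$truth[, paste0("p_", c("C", "M", "N"), "_", tp)])
    expect_true(all(p >= -1e-12))
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  }
  # with a column-stochastic purity matrix, summed fraction signal equals
  # total abundance
  pur <- cfg$purity_matrix
  p0 <- as.matrix(sim1$truth[, paste0("p_", c("C", "M", "N"), "_0")])
  meas <- p0 %*% t(pur)
  expect_equal(unname(rowSums(meas)), rep(1, nrow(p0)), tolerance = 1e-9)

  # internal standard equals the pool of expected sample intensities:
  # with zero PSM noise, channel 131 is identical for all of a gene's PSMs
  simz <- simulate_experiment(noiseless_config(seed = 3))
  is_by_gene <- tapply(simz$psms$tmt_131, simz$psms$gene,
                       function(v) diff(range(v)))
  expect_lt(max(is_by_gene), 1e-6)
})

test_that("invalid configurations are rejected", {
  bad_purity <- matrix(c(0.9, 0.2, 0.1, 0.1, 0.7, 0.1, 0.1, 0.1, 0.8), 3)
  expect_error(simulation_config(purity_matrix = bad_purity), "sum to 1")
  expect_error(simulation_config(timepoints = c(0, 30)), "subset")
  expect_error(simulation_config(translocator_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_proteins = 0), ">= 1")
  expect_error(simulation_config(psm_noise_sd = -1), ">= 0")
})

test_that("cell-intensity simulator: null is exchangeable, shift moves the nuclear share, degenerate input errors", {
  expect_error(simulate_cell_intensities(0), ">= 1")

  # null: two-sided Mann-Whitney P should look uniform over seeds
  p_null <- vapply(1:60, function(s) {
    cells <- simulate_cell_intensities(60, nuclear_shift = 0, seed = s)
    share <- cells$nuclear / (cells$nuclear + cells$cytosolic)
    suppressWarnings(mann_whitney(
      share[cells$condition == "stimulated"],
      share[cells$condition == "unstimulated"]))$p_value
  }, numeric(1))
  expect_lt(mean(p_null < 0.05), 0.15)
  expect_gt(mean(p_null), 0.3)

  # a large shift moves the stimulated median nuclear share up in >= 95%
  # of seeds
  higher <- vapply(1:100, function(s) {
    cells <- simulate_cell_intensities(200, nuclear_shift = 0.25, seed = s)
    share <- cells$nuclear / (cells$nuclear + cells$cytosolic)
    median(share[cells$condition == "stimulated"]) >
      median(share[cells$condition == "unstimulated"])
  }, logical(1))
  expect_gte(mean(higher), 0.95)
})
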