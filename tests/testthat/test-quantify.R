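# Quantification: ratio arithmetic, median normalization, gene rollup,
# picked protein FDR, full-quantitation filtering.

toy_design <- function() {
  data.frame(
    set_id = "set1",
    channel = c("126", "127N", "131"),
    donor = "D1",
    fraction = c("C", "C", NA),
    timepoint_min = c(0, 60, NA),
    is_internal_standard = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

toy_psms <- function(tmt_126, tmt_127N, tmt_131,
                     gene = paste0("G", seq_along(tmt_126)),
                     peptide = paste0("PEP", seq_along(tmt_126))) {
  data.frame(
    psm_id = paste0("PSM", seq_along(tmt_126)),
    peptide = peptide, gene = gene,
    is_decoy = FALSE, score = 10, set_id = "set1",
    tmt_126 = tmt_126, tmt_127N = tmt_127N, tmt_131 = tmt_131,
    stringsAsFactors = FALSE)
}

test_that("PSM ratios are log2 against the internal standard; zero-IS PSMs are dropped and counted", {
  psms <- toy_psms(tmt_126 = c(5, 4, 3, 7),
                   tmt_127N = c(5, 8, 2, 1),
                   tmt_131  = c(5, 4, 2, 0))
  r <- compute_psm_ratios(psms, toy_design())
  expect_equal(nrow(r), 3)                       # PSM4 dropped (IS = 0)
  expect_equal(attr(r, "n_dropped_zero_is"), 1L)
  expect_equal(r$ratio_126, c(0, 0, log2(1.5)))  # equal channels -> 0
  expect_equal(r$ratio_127N, c(0, 1, 0))         # 2x IS -> 1.0
  expect_equal(r$ratio_126[3], 0.585, tolerance = 1e-3)

  # missing design entry for a present channel errors
  des <- toy_design()[-1, ]
  expect_error(compute_psm_ratios(psms, des), "no design entry")
  # more than one internal standard errors
  des2 <- toy_design(); des2$is_internal_standard <- TRUE
  expect_error(compute_psm_ratios(psms, des2), "exactly one")
})

test_that("sample-median normalization centers columns, is idempotent, and uses the exact median", {
  psms <- toy_psms(tmt_126 = 2^c(-1, 0.2, 5),   # ratios {-1, 0.2, 5}
                   tmt_127N = 2^c(0.3, 0.3, 0.5),
                   tmt_131 = c(1, 1, 1))
  r <- compute_psm_ratios(psms, toy_design())
  n <- normalize_sample_median(r)
  expect_equal(n$ratio_126, c(-1, 0.2, 5) - 0.2)     # odd-length median
  expect_equal(median(n$ratio_127N), 0)
  expect_equal(normalize_sample_median(n), n)         # idempotent
  # already-centered column unchanged
  r2 <- r; r2$ratio_126 <- c(-1, 0, 1)
  expect_equal(normalize_sample_median(r2)$ratio_126, c(-1, 0, 1))
})

test_that("rollup takes per-gene medians of unique peptides and records PSM counts", {
  psms <- toy_psms(tmt_126 = 2^c(0.1, 0.2, 0.9, 0.4, 0.4),
                   tmt_127N = 2^c(1, 1, 1, 2, 2),
                   tmt_131 = rep(1, 5),
                   gene = c("GA", "GA", "GA", "GB", "GC"),
                   peptide = c("P1", "P2", "P3", "SHARED", "SHARED"))
  r <- compute_psm_ratios(psms, toy_design())
  pq <- rollup_to_protein(r, toy_design())
  # median of {0.1, 0.2, 0.9} is 0.2
  expect_equal(unname(pq$log2ratio["GA", "set1:D1:C:0"]), 0.2)
  # the shared peptide contributes to neither gene
  expect_false(any(c("GB", "GC") %in% rownames(pq$log2ratio)))
  expect_equal(pq$n_shared_peptides_excluded, 1L)
  expect_equal(unname(pq$psm_counts["GA", "set1"]), 3)
  # rollup is invariant to PSM order
  pq2 <- rollup_to_protein(r[c(3, 1, 5, 2, 4), ], toy_design())
  expect_equal(pq2$log2ratio, pq$log2ratio)
})

test_that("median PSM count across sets is the median of per-set counts", {
  sim <- simulate_experiment(simulation_config(
    n_proteins = 10, n_decoys = 0, donor_sd = 0, psm_noise_sd = 0,
    translocator_fraction = 0, seed = 2,
    psm_count_law = function(n) sample(1:8, n, replace = TRUE)))
  r <- compute_psm_ratios(sim$psms, sim$design)
  pq <- rollup_to_protein(r, sim$design)
  for (g in rownames(pq$psm_counts)) {
    expect_equal(unname(pq$median_psm_count[g]),
                 median(unname(pq$psm_counts[g, ])))
  }
})

test_that("picked FDR: separation, decoy competition, threshold limits", {
  # perfect separation retains all targets
  t_sc <- c(A = 10, B = 9, C = 8)
  d_sc <- c(A = 1, B = 2, C = 3)
  expect_setequal(as.vector(picked_protein_fdr(t_sc, d_sc, 0.01)),
                  c("A", "B", "C"))

  # a decoy outscoring its target makes that gene a decoy observation
  t4 <- c(A = 10, B = 9, C = 5, D = 8)
  d4 <- c(A = 1, B = 2, C = 7, D = 3)
  ret <- picked_protein_fdr(t4, d4, 0.5)
  expect_false("C" %in% ret)
  tab <- attr(ret, "picked")
  expect_true(tab$is_decoy[tab$gene == "C"])
  # walking down A(10), B(9), D(8), C-decoy(7): FDR hits 1/3 <= 0.5 at C,
  # so all three targets are retained
  expect_setequal(as.vector(ret), c("A", "B", "D"))

  # threshold 1.0 retains every target gene
  set.seed(1)
  tn <- setNames(runif(50), paste0("g", 1:50))
  dn <- setNames(runif(50), paste0("g", 1:50))
  ret1 <- picked_protein_fdr(tn, dn, 1.0)
  expect_setequal(as.vector(ret1), names(tn)[tn >= dn])

  # threshold -> 0 retains only targets above the best picked decoy
  ret0 <- picked_protein_fdr(tn, dn, 1e-9)
  best_decoy <- max(pmax(tn, dn)[dn > tn])
  expect_setequal(as.vector(ret0), names(tn)[tn > dn & tn > best_decoy])

  expect_error(picked_protein_fdr(t_sc, d_sc, 0), "\\(0, 1\\]")
  expect_error(picked_protein_fdr(t_sc, d_sc, 1.5), "\\(0, 1\\]")
})

test_that("full-quantitation filter keeps only genes complete in every channel of every set", {
  base <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("G", 1:4), NULL))
  trt <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("G", 1:4), NULL))
  pq <- make_pq(base, trt)
  pq$log2ratio["G2", 3] <- NA           # one missing channel -> excluded
  out <- filter_full_quantitation(pq)
  expect_setequal(rownames(out$log2ratio), c("G1", "G3", "G4"))

  empty <- subset_genes(pq, character())
  expect_equal(nrow(filter_full_quantitation(empty)$log2ratio), 0)
})

test_that("zero-noise identity-purity recovery matches ground-truth mixing exactly", {
  cfg <- simulation_config(
    n_proteins = 30, n_decoys = 0, purity_matrix = diag(3),
    translocator_fraction = 0.2, effect_size = 0.5,
    donor_sd = 0, psm_noise_sd = 0,
    psm_count_law = function(n) rep(2L, n), seed = 9)
  sim <- simulate_experiment(cfg)
  pq <- rollup_to_protein(compute_psm_ratios(sim$psms, sim$design),
                          sim$design)
  samp <- pq$samples
  tru <- sim$truth
  for (f in c("C", "M", "N")) for (tp in c(0, 15, 60)) {
    col <- samp$sample[samp$fraction == f & samp$timepoint_min == tp &
                         samp$donor == "D1"]
    col0 <- samp$sample[samp$fraction == f & samp$timepoint_min == 0 &
                          samp$donor == "D1"]
    got <- pq$log2ratio[tru$gene, col] - pq$log2ratio[tru$gene, col0]
    want <- log2(tru[[paste0("p_", f, "_", tp)]] / tru[[paste0("p_", f, "_0")]])
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})
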