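#' Simulation configuration for a fractionated TMT experiment
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' defaults emulate a study design of 3 donors, each measured as one TMT
#' 10-plex set containing that donor's 9 samples (3 subcellular fractions
#' x 3 stimulation timepoints) plus a pooled internal standard in channel
#' 131 shared across sets. Fractionation is an enrichment, not an
#' isolation: the purity matrix mixes true compartment signal into each
#' measured fraction.
#'
#' @param n_proteins number of target genes to simulate.
#' @param n_decoys number of decoy genes (paired one-to-one with the first
#'   `n_decoys` target genes, named `DECOY_<gene>`).
#' @param purity_matrix 3x3 row-stochastic matrix; rows are measured
#'   fractions (C, M, N), columns true compartments. Entry `[f, c]` is the
#'   probability mass of true compartment `c` captured by fraction `f`.
#' @param n_donors number of donors; one TMT set per donor.
#' @param timepoints stimulation timepoints in minutes, a subset of
#'   `c(0, 15, 60)` containing 0.
#' @param translocator_fraction proportion of target genes assigned a
#'   stimulation-induced translocation event.
#' @param effect_size translocation magnitude in log2 units: the moved mass
#'   is chosen so the source compartment loses `effect_size` log2 units of
#'   its true signal at 60 min.
#' @param attenuation_15 multiplier in `[0, 1]` applied to the moved mass at
#'   15 min (partial translocation early in the response).
#' @param donor_sd standard deviation of per-gene, per-donor log2 offsets
#'   (cancelled by the paired analysis).
#' @param psm_noise_sd standard deviation of per-PSM, per-channel
#'   multiplicative log2 noise.
#' @param psm_count_law function `n -> integer vector` drawing the number of
#'   PSMs per gene per set; support must be >= 1.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters for
#'   baseline protein abundance (reporter intensity scale).
#' @param decoy_score_shift separation between target and decoy search-score
#'   distributions: targets ~ Normal(shift, 1), decoys ~ Normal(0, 1).
#' @param seed integer seed; all randomness in [simulate_experiment()] flows
#'   from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_proteins = 2000,
                              n_decoys = n_proteins,
                              purity_matrix = default_purity_matrix(),
                              n_donors = 3,
                              timepoints = c(0L, 15L, 60L),
                              translocator_fraction = 0.05,
                              effect_size = 0.6,
                              attenuation_15 = 0.3,
                              donor_sd = 0.1,
                              psm_noise_sd = 0.2,
                              psm_count_law = function(n) 1L + stats::rpois(n, 3),
                              abundance_meanlog = log(1e5),
                              abundance_sdlog = 1.5,
                              decoy_score_shift = 3,
                              seed = 1L) {
  purity_matrix <- as.matrix(purity_matrix)
  if (!all(dim(purity_matrix) == c(3L, 3L)))
    stopf("purity_matrix must be 3x3 (fractions x compartments)")
  if (any(purity_matrix < 0) ||
      any(abs(rowSums(purity_matrix) - 1) > 1e-9))
    stopf("purity_matrix rows must be non-negative and sum to 1 (tol 1e-9)")
  timepoints <- as.integer(timepoints)
  if (!all(timepoints %in% TIMEPOINTS) || !0L %in% timepoints)
    stopf("timepoints must be a subset of {0, 15, 60} containing 0")
  if (translocator_fraction < 0 || translocator_fraction > 1)
    stopf("translocator_fraction must be in [0, 1]")
  if (n_proteins < 1 || n_donors < 1)
    stopf("n_proteins and n_donors must be >= 1")
  if (n_decoys < 0 || n_decoys > n_proteins)
    stopf("n_decoys must be in [0, n_proteins]")
  if (donor_sd < 0 || psm_noise_sd < 0 || attenuation_15 < 0 ||
      attenuation_15 > 1 || effect_size < 0)
    stopf("std-devs and effect_size must be >= 0; attenuation_15 in [0, 1]")
  dimnames(purity_matrix) <- list(FRACTIONS, FRACTIONS)
  structure(list(
    n_proteins = as.integer(n_proteins), n_decoys = as.integer(n_decoys),
    purity_matrix = purity_matrix, n_donors = as.integer(n_donors),
    timepoints = sort(timepoints),
    translocator_fraction = translocator_fraction,
    effect_size = effect_size, attenuation_15 = attenuation_15,
    donor_sd = donor_sd, psm_noise_sd = psm_noise_sd,
    psm_count_law = psm_count_law,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    decoy_score_shift = decoy_score_shift, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default fraction purity matrix
#'
#' 0.80 of each compartment's mass is captured by its own fraction and 0.10
#' leaks into each of the other two, reflecting that biochemical
#' fractionation enriches rather than isolates compartments.
#' @return 3x3 row-stochastic matrix with dimnames C/M/N.
#' @export
default_purity_matrix <- function() {
  m <- matrix(0.10, 3, 3, dimnames = list(FRACTIONS, FRACTIONS))
  diag(m) <- 0.80
  m
}

# Deterministic unique peptide string for (gene index, psm index):
# base-20 encoding over the amino-acid alphabet.
aa_encode <- function(i, width) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(length(i))
  v <- as.integer(i)
  chars <- matrix("A", nrow = length(i), ncol = width)
  for (p in seq_len(width)) {
    chars[, width - p + 1L] <- aa[(v %% 20L) + 1L]
    v <- v %/% 20L
  }
  apply(chars, 1L, paste0, collapse = "")
}

#' Simulate a fractionated TMT experiment at the PSM level
#'
#' Generates an identified-and-quantified PSM table with the statistical
#' structure the downstream analysis assumes: per-gene baseline abundances,
#' compartment profiles mixed through the fraction purity matrix,
#' donor-level offsets, independent per-channel PSM noise, target and decoy
#' identifications, and a spiked subset of translocating genes that move
#' abundance mass from a source to a sink compartment upon stimulation.
#' Channel 131 of every PSM carries the pooled internal standard: the mean
#' of that gene's expected intensities over all donors, fractions and
#' timepoints, times that PSM's channel noise.
#'
#' @param config a [simulation_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{psms}{data.frame: psm_id, peptide, gene, is_decoy, score,
#'       set_id, ipg_fraction, tmt_126 ... tmt_131.}
#'     \item{design}{data.frame: set_id, channel, donor, fraction,
#'       timepoint_min, is_internal_standard.}
#'     \item{truth}{data.frame of per-gene ground truth: primary
#'       compartment, translocation event (source, sink, moved mass) and
#'       the full compartment profile at each timepoint.}
#'   }
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  nT <- cfg$n_proteins; nD <- cfg$n_decoys
  n  <- nT + nD
  genes <- sprintf("G%05d", seq_len(nT))
  decoys <- if (nD > 0) paste0("DECOY_", genes[seq_len(nD)]) else character()
  all_genes <- c(genes, decoys)
  is_decoy_gene <- c(rep(FALSE, nT), rep(TRUE, nD))
  tps <- cfg$timepoints; ntp <- length(tps)

  # baseline abundance and compartment profile (decoys get their own,
  # non-translocating, profiles)
  A <- stats::rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)
  primary <- sample(FRACTIONS, n, replace = TRUE)
  p_main <- stats::runif(n, 0.70, 0.95)
  split1 <- stats::runif(n)
  prof0 <- matrix(0, n, 3, dimnames = list(all_genes, FRACTIONS))
  for (ci in 1:3) {
    is_main <- primary == FRACTIONS[ci]
    prof0[is_main, ci] <- p_main[is_main]
  }
  for (g in seq_len(n)) {
    others <- setdiff(1:3, match(primary[g], FRACTIONS))
    rest <- 1 - p_main[g]
    prof0[g, others] <- rest * c(split1[g], 1 - split1[g])
  }

  # translocation events among targets only: move mass from the primary
  # (source) compartment to a random other (sink); moved mass chosen so
  # the source's true signal drops by effect_size log2 units at 60 min.
  n_trans <- floor(cfg$translocator_fraction * nT)
  trans_idx <- if (n_trans > 0) sort(sample(seq_len(nT), n_trans)) else integer()
  source_c <- rep(NA_character_, n); sink_c <- rep(NA_character_, n)
  moved60 <- numeric(n); moved15 <- numeric(n)
  if (n_trans > 0) {
    source_c[trans_idx] <- primary[trans_idx]
    sink_c[trans_idx] <- vapply(trans_idx, function(g)
      sample(setdiff(FRACTIONS, primary[g]), 1L), character(1))
    src_i <- match(source_c[trans_idx], FRACTIONS)
    p_src <- prof0[cbind(trans_idx, src_i)]
    moved60[trans_idx] <- p_src * (1 - 2^(-cfg$effect_size))
    moved15[trans_idx] <- cfg$attenuation_15 * moved60[trans_idx]
  }

  # profiles per timepoint: array genes x compartment x timepoint
  prof <- array(rep(prof0, ntp), dim = c(n, 3, ntp),
                dimnames = list(all_genes, FRACTIONS, as.character(tps)))
  for (ti in seq_along(tps)) {
    m <- if (tps[ti] == 15L) moved15 else if (tps[ti] == 60L) moved60 else 0
    if (all(m == 0)) next
    si <- match(source_c, FRACTIONS); ki <- match(sink_c, FRACTIONS)
    ok <- which(!is.na(si) & m > 0)
    prof[cbind(ok, si[ok], ti)] <- prof[cbind(ok, si[ok], ti)] - m[ok]
    prof[cbind(ok, ki[ok], ti)] <- prof[cbind(ok, ki[ok], ti)] + m[ok]
  }

  # measured (fraction-mixed) signal: genes x (fraction, timepoint)
  meas <- matrix(0, n, 3 * ntp)
  ft_frac <- rep(FRACTIONS, each = ntp)
  ft_time <- rep(tps, times = 3)
  colnames(meas) <- paste(ft_frac, ft_time, sep = ":")
  for (ti in seq_along(tps)) {
    mixed <- prof[, , ti] %*% t(cfg$purity_matrix)   # genes x fraction
    for (fi in 1:3) meas[, (fi - 1L) * ntp + ti] <- mixed[, fi]
  }

  donors <- paste0("D", seq_len(cfg$n_donors))
  offs <- matrix(stats::rnorm(n * cfg$n_donors, 0, cfg$donor_sd),
                 n, cfg$n_donors)

  # expected sample intensities and shared-pool internal standard
  # IS = mean over all donors x fractions x timepoints of the expected
  # sample intensity (identical in expectation across sets)
  pool_terms <- matrix(0, n, cfg$n_donors * ncol(meas))
  k <- 0L
  for (d in seq_len(cfg$n_donors)) for (j in seq_len(ncol(meas))) {
    k <- k + 1L
    pool_terms[, k] <- A * meas[, j] * 2^offs[, d]
  }
  is_expected <- rowMeans(pool_terms)

  # channel layout: 9 sample channels = fractions x timepoints in fixed
  # order, channel 131 = internal standard
  n_sample_ch <- ncol(meas)
  sample_channels <- TMT10_CHANNELS[seq_len(n_sample_ch)]
  is_channel <- "131"

  set_ids <- paste0("set", seq_len(cfg$n_donors))
  design <- do.call(rbind, lapply(seq_len(cfg$n_donors), function(d) {
    data.frame(
      set_id = set_ids[d],
      channel = c(sample_channels, is_channel),
      donor = donors[d],
      fraction = c(ft_frac, NA),
      timepoint_min = c(ft_time, NA),
      is_internal_standard = c(rep(FALSE, n_sample_ch), TRUE),
      stringsAsFactors = FALSE)
  }))

  score_mu <- ifelse(is_decoy_gene, 0, cfg$decoy_score_shift)
  psm_sets <- vector("list", cfg$n_donors)
  psm_counter <- 0L
  for (d in seq_len(cfg$n_donors)) {
    counts <- cfg$psm_count_law(n)
    if (any(counts < 1)) stopf("psm_count_law must return counts >= 1")
    gidx <- rep(seq_len(n), counts)
    npsm <- length(gidx)
    pep_j <- sequence(counts)
    expected <- A[gidx] * meas[gidx, , drop = FALSE] * 2^offs[gidx, d]
    noise <- function(m) 2^matrix(stats::rnorm(npsm * m, 0, cfg$psm_noise_sd),
                                  npsm, m)
    inten <- cbind(expected * noise(n_sample_ch),
                   is_expected[gidx] * noise(1L))
    colnames(inten) <- paste0("tmt_", c(sample_channels, is_channel))
    psm_sets[[d]] <- data.frame(
      psm_id = paste0("PSM", psm_counter + seq_len(npsm)),
      peptide = aa_encode(gidx * 1000L + pep_j, 9L),
      gene = all_genes[gidx],
      is_decoy = is_decoy_gene[gidx],
      score = stats::rnorm(npsm, score_mu[gidx], 1),
      set_id = set_ids[d],
      ipg_fraction = ((gidx + d) %% 10L) + 1L,
      stringsAsFactors = FALSE)
    psm_sets[[d]] <- cbind(psm_sets[[d]], as.data.frame(inten))
    psm_counter <- psm_counter + npsm
  }
  psms <- do.call(rbind, psm_sets)
  rownames(psms) <- NULL

  prof_cols <- do.call(cbind, lapply(seq_along(tps), function(ti) {
    x <- prof[, , ti]
    colnames(x) <- paste0("p_", FRACTIONS, "_", tps[ti])
    x
  }))
  truth <- data.frame(
    gene = all_genes, is_decoy = is_decoy_gene, primary = primary,
    is_translocator = seq_len(n) %in% trans_idx,
    source = source_c, sink = sink_c,
    moved_mass_15 = moved15, moved_mass_60 = moved60,
    effect_size = ifelse(seq_len(n) %in% trans_idx, cfg$effect_size, 0),
    baseline_abundance = A,
    stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(prof_cols))
  rownames(truth) <- NULL

  list(psms = psms, design = design, truth = truth)
}

#' Simulate per-cell nuclear and cytosolic intensities
#'
#' Emulates the per-cell output of image segmentation: each cell has a
#' total stain intensity (log-normal) split into nuclear and cytosolic
#' signal by a logit-normal nuclear share. Conditions after the first are
#' treated as stimulated and have their expected nuclear share shifted by
#' `nuclear_shift`.
#'
#' @param n_cells cells per condition (>= 1).
#' @param conditions condition labels; the first is the unstimulated
#'   reference.
#' @param nuclear_shift additive shift of the expected nuclear share in
#'   stimulated conditions.
#' @param base_share expected nuclear share in the unstimulated condition.
#' @param seed integer seed.
#' @return data.frame: cell_id, condition, nuclear, cytosolic.
#' @export
simulate_cell_intensities <- function(n_cells,
                                      conditions = c("unstimulated", "stimulated"),
                                      nuclear_shift = 0,
                                      base_share = 0.30,
                                      seed = 1L) {
  if (n_cells < 1) stopf("n_cells must be >= 1")
  with_seed(seed, {
    out <- lapply(seq_along(conditions), function(i) {
      share_mu <- base_share + if (i > 1L) nuclear_shift else 0
      share_mu <- min(max(share_mu, 0.02), 0.98)
      share <- stats::plogis(stats::rnorm(n_cells, stats::qlogis(share_mu), 0.5))
      total <- stats::rlnorm(n_cells, log(1000), 0.3)
      data.frame(
        cell_id = paste0(conditions[i], "_cell", seq_len(n_cells)),
        condition = conditions[i],
        nuclear = total * share,
        cytosolic = total * (1 - share),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Write simulated experiment tables to TSV files
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(psms = file.path(dir, "psms.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_tsv(sim$psms, paths[["psms"]])
  write_tsv(sim$design, paths[["design"]])
  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Read PSM and design tables written by [write_experiment()] (or exported
#' from a search pipeline in the same dialect)
#'
#' @param psm_file PSM TSV with columns psm_id, peptide, gene, is_decoy,
#'   score, set_id and reporter intensity columns `tmt_<channel>`.
#' @param design_file design TSV with columns set_id, channel, donor,
#'   fraction, timepoint_min, is_internal_standard.
#' @return list with elements `psms` and `design`.
#' @export
read_experiment <- function(psm_file, design_file) {
  psms <- read_tsv_checked(psm_file,
    c("psm_id", "peptide", "gene", "is_decoy", "score", "set_id"))
  design <- read_tsv_checked(design_file,
    c("set_id", "channel", "donor", "fraction", "timepoint_min",
      "is_internal_standard"))
  design$channel <- as.character(design$channel)
  list(psms = psms, design = design)
}
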