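#' Run the full translocation analysis pipeline
#'
#' Chains the analysis end to end: PSM ratios to the internal standard,
#' sample-median normalization, picked protein FDR gating, gene-level
#' rollup, full-quantitation filtering, donor-paired moderated differential
#' statistics for both contrasts, translocation calling at the 1 h
#' contrast, compartment classification, and a machine-readable run report
#' with the stage counts (identified, overlapping across sets, fully
#' quantified, candidates changing in >= 2 fractions, translocation calls).
#'
#' @param config either a list or a YAML file path. Recognized keys:
#'   \describe{
#'     \item{psm_file, design_file}{input TSVs (omit when simulating).}
#'     \item{simulation}{list of [simulation_config()] arguments; used when
#'       no input files are given.}
#'     \item{fc_threshold, p_threshold, protein_fdr}{thresholds; defaults
#'       0.201, 0.05, 0.01.}
#'     \item{contrast}{calling contrast in minutes (default 60).}
#'     \item{contrasts}{contrasts to fit (default c(15, 60)).}
#'     \item{k, seed, restarts}{classification parameters.}
#'     \item{classify}{logical; run compartment classification
#'       (default TRUE).}
#'     \item{out_dir}{if set, all tables and the report are written there.}
#'   }
#' @return a list of class `transloc_run`: report (stage counts and
#'   summaries), quant, fit, calls, assignments, pca, and (when simulated)
#'   truth and recovery metrics.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- config
  fc_threshold <- cfg$fc_threshold %||% 0.201
  p_threshold <- cfg$p_threshold %||% 0.05
  protein_fdr <- cfg$protein_fdr %||% 0.01
  contrast <- cfg$contrast %||% 60
  contrasts <- cfg$contrasts %||% c(15, 60)
  if (fc_threshold < 0 || p_threshold <= 0 || p_threshold > 1 ||
      protein_fdr <= 0 || protein_fdr > 1)
    stopf("thresholds out of range")

  truth <- NULL
  if (!is.null(cfg$psm_file)) {
    inp <- read_experiment(cfg$psm_file, cfg$design_file)
    psms <- inp$psms; design <- inp$design
  } else {
    sim_args <- cfg$simulation %||% list()
    if (!is.null(cfg$seed) && is.null(sim_args$seed))
      sim_args$seed <- cfg$seed
    sim <- simulate_experiment(do.call(simulation_config, sim_args))
    psms <- sim$psms; design <- sim$design; truth <- sim$truth
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ratios <- stage("psm_ratios", compute_psm_ratios(psms, design))
  n_dropped_is <- attr(ratios, "n_dropped_zero_is")
  ratios <- stage("normalize", normalize_sample_median(ratios))

  scores <- best_gene_scores(psms)
  retained <- stage("picked_fdr",
    picked_protein_fdr(scores$target, scores$decoy, protein_fdr))

  target_ratios <- ratios[!ratios$is_decoy & ratios$gene %in% retained, ]
  pq_all <- stage("rollup", rollup_to_protein(target_ratios, design))

  n_identified <- nrow(pq_all$log2ratio)
  sets <- unique(design$set_id)
  in_all_sets <- rowSums(!is.na(pq_all$psm_counts)) == length(sets)
  n_overlapping <- sum(in_all_sets)
  pq <- filter_full_quantitation(subset_genes(
    pq_all, rownames(pq_all$log2ratio)[in_all_sets]))
  n_full <- nrow(pq$log2ratio)

  fit <- stage("differential",
    fit_fraction_diff(pq, contrasts = contrasts,
                      per_fraction = isTRUE(cfg$per_fraction)))
  candidates <- stage("candidates",
    candidate_changing_set(fit$stats, contrast, p_threshold))
  calls <- stage("translocation",
    call_translocations(fit$stats, fc_threshold, p_threshold, contrast))
  call_summary <- summarize_calls(calls)

  assignments <- NULL; pca <- NULL
  if (!identical(cfg$classify, FALSE)) {
    assignments <- stage("classification",
      classify_compartments(pq, k = cfg$k %||% 3,
                            seed = cfg$seed %||% 1L,
                            restarts = cfg$restarts %||% 25))
    pca <- stage("pca", pca_qc(pq))
  }

  recovery <- if (!is.null(truth)) evaluate_calls(calls, truth) else NULL

  report <- list(
    thresholds = list(fc_threshold = fc_threshold,
                      p_threshold = p_threshold,
                      protein_fdr = protein_fdr, contrast = contrast),
    counts = list(
      psms_input = nrow(psms),
      psms_dropped_zero_internal_standard = n_dropped_is,
      shared_peptides_excluded = pq_all$n_shared_peptides_excluded,
      identified = n_identified,
      overlapping = n_overlapping,
      fully_quantified = n_full,
      candidates = length(candidates),
      translocation_calls = call_summary$n_calls),
    involvement_pct = as.list(call_summary$involvement_pct),
    pair_counts = as.list(call_summary$pair_counts),
    recovery = recovery)

  out <- list(report = report, quant = pq, fit = fit, calls = calls,
              candidates = candidates, assignments = assignments,
              pca = pca, truth = truth)
  class(out) <- "transloc_run"

  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transloc_run <- function(x, ...) {
  ct <- x$report$counts
  cat("transloc_run\n")
  cat(sprintf("  identified (picked FDR): %d\n", ct$identified))
  cat(sprintf("  overlapping across sets: %d\n", ct$overlapping))
  cat(sprintf("  fully quantified:        %d\n", ct$fully_quantified))
  cat(sprintf("  candidates (P<%g, >=2 fractions): %d\n",
              x$report$thresholds$p_threshold, ct$candidates))
  cat(sprintf("  translocation calls:     %d\n", ct$translocation_calls))
  inv <- unlist(x$report$involvement_pct)
  if (length(inv))
    cat("  fraction involvement (%):",
        paste(sprintf("%s %.1f", names(inv), inv), collapse = ", "), "\n")
  if (!is.null(x$report$recovery))
    cat(sprintf("  recovery vs ground truth: sensitivity %.3f, FDP %.3f\n",
                x$report$recovery$sensitivity, x$report$recovery$fdp))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#' @param run transloc_run object.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_quant(run$quant, dir)
  write_diffstats(run$fit, dir)
  write_tsv(as.data.frame(run$calls), file.path(dir, "translocation_calls.tsv"))
  if (!is.null(run$assignments))
    write_tsv(run$assignments, file.path(dir, "compartment_assignments.tsv"))
  if (!is.null(run$pca))
    write_tsv(run$pca$scores, file.path(dir, "pca_scores.tsv"))
  jsonlite::write_json(run$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
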