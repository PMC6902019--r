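#' Genes changing in two or more fractions
#'
#' The candidate filter preceding translocation calling: genes whose
#' uncorrected P value is strictly below the threshold in at least two
#' fractions for the chosen contrast.
#'
#' @param stats DiffStat data.frame (gene, fraction, contrast, logFC, P).
#' @param contrast contrast timepoint (minutes).
#' @param p_threshold strict upper bound on P.
#' @return character vector of candidate genes.
#' @export
candidate_changing_set <- function(stats, contrast = 60, p_threshold = 0.05) {
  st <- stats[stats$contrast == contrast & !is.na(stats$P), ]
  if (length(unique(st$fraction)) < 2L)
    stopf("need statistics for >= 2 fractions")
  sig <- st[st$P < p_threshold, ]
  n_sig <- table(sig$gene)
  sort(names(n_sig)[n_sig >= 2L])
}

#' Call stimulation-induced translocating proteins
#'
#' The opposite-direction decision tree: a gene passes if there exist two
#' fractions with log2 fold changes exceeding the threshold in opposite
#' directions (strictly greater than `fc_threshold` in one, strictly less
#' than `-fc_threshold` in the other) and P strictly below `p_threshold`
#' in both. All qualifying opposite-direction fraction pairs are recorded;
#' a gene qualifying in all three fractions yields one call listing every
#' such pair.
#'
#' @param stats DiffStat data.frame.
#' @param fc_threshold strict absolute log2 fold-change threshold
#'   (default 0.201).
#' @param p_threshold strict P threshold (default 0.05).
#' @param contrast contrast timepoint (minutes; the 1 h contrast by
#'   default).
#' @return data.frame of class `translocation_calls`: gene, pass, pairs
#'   (comma-separated `up>down` fraction pairs), n_pairs, plus per-fraction
#'   logFC_<f> and P_<f> columns.
#' @export
call_translocations <- function(stats, fc_threshold = 0.201,
                                p_threshold = 0.05, contrast = 60) {
  if (fc_threshold < 0) stopf("fc_threshold must be >= 0")
  st <- stats[stats$contrast == contrast, ]
  fracs <- sort(unique(st$fraction))
  genes <- sort(unique(st$gene))
  fc <- matrix(NA_real_, length(genes), length(fracs),
               dimnames = list(genes, fracs))
  pv <- fc
  fc[cbind(match(st$gene, genes), match(st$fraction, fracs))] <- st$logFC
  pv[cbind(match(st$gene, genes), match(st$fraction, fracs))] <- st$P

  qual_up <- !is.na(fc) & !is.na(pv) & fc > fc_threshold & pv < p_threshold
  qual_dn <- !is.na(fc) & !is.na(pv) & fc < -fc_threshold & pv < p_threshold
  pass <- rowSums(qual_up) >= 1L & rowSums(qual_dn) >= 1L

  pairs <- character(length(genes))
  n_pairs <- integer(length(genes))
  for (i in which(pass)) {
    up <- fracs[qual_up[i, ]]; dn <- fracs[qual_dn[i, ]]
    pp <- as.vector(outer(up, dn, function(a, b) paste0(a, ">", b)))
    pairs[i] <- paste(sort(pp), collapse = ",")
    n_pairs[i] <- length(pp)
  }
  out <- data.frame(gene = genes, pass = pass, pairs = pairs,
                    n_pairs = n_pairs, stringsAsFactors = FALSE)
  for (f in fracs) {
    out[[paste0("logFC_", f)]] <- fc[, f]
    out[[paste0("P_", f)]] <- pv[, f]
  }
  rownames(out) <- NULL
  class(out) <- c("translocation_calls", "data.frame")
  out
}

#' Summarize translocation calls
#'
#' Counts passing genes, the share of passing genes whose qualifying pairs
#' involve each fraction (a gene touching a fraction in any pair counts
#' once for that fraction), and tallies of directed fraction pairs.
#'
#' @param calls data.frame from [call_translocations()].
#' @return list: n_calls, involvement_pct (named C/M/N), pair_counts.
#' @export
summarize_calls <- function(calls) {
  passed <- calls[calls$pass, , drop = FALSE]
  n <- nrow(passed)
  fracs <- sub("^logFC_", "", grep("^logFC_", names(calls), value = TRUE))
  involvement <- stats::setNames(numeric(length(fracs)), fracs)
  pair_counts <- table(character())
  if (n > 0) {
    pair_list <- strsplit(passed$pairs, ",", fixed = TRUE)
    for (f in fracs) {
      touches <- vapply(pair_list, function(p)
        f %in% unlist(strsplit(p, ">", fixed = TRUE)), logical(1))
      involvement[f] <- 100 * sum(touches) / n
    }
    pair_counts <- table(unlist(pair_list))
  }
  list(n_calls = n, involvement_pct = involvement,
       pair_counts = pair_counts)
}

#' Compare calls to simulation ground truth
#'
#' @param calls data.frame from [call_translocations()].
#' @param truth ground-truth data.frame from [simulate_experiment()].
#' @return list: sensitivity (true translocators called / true
#'   translocators tested), fdp (false calls / calls), n_calls,
#'   n_true_tested.
#' @export
evaluate_calls <- function(calls, truth) {
  truth <- truth[!truth$is_decoy, ]
  tested <- intersect(calls$gene, truth$gene)
  true_pos <- truth$gene[truth$is_translocator]
  called <- calls$gene[calls$pass]
  n_true_tested <- length(intersect(true_pos, tested))
  tp <- length(intersect(called, true_pos))
  list(
    sensitivity = if (n_true_tested > 0) tp / n_true_tested else NA_real_,
    fdp = if (length(called) > 0) (length(called) - tp) / length(called) else 0,
    n_calls = length(called),
    n_true_tested = n_true_tested)
}

#' Read an externally computed differential table and call translocations
#'
#' Entry point for applying the decision tree to differential statistics
#' computed elsewhere (e.g. a supplementary-table export): a TSV with
#' columns gene, fraction, logFC, P (and optionally contrast) is read and
#' passed to [call_translocations()] and [candidate_changing_set()].
#'
#' @param path TSV path.
#' @param fc_threshold,p_threshold,contrast see [call_translocations()].
#' @return list: calls, candidates, summary.
#' @export
call_from_table <- function(path, fc_threshold = 0.201, p_threshold = 0.05,
                            contrast = 60) {
  st <- read_tsv_checked(path, c("gene", "fraction", "logFC", "P"))
  if (is.null(st$contrast)) st$contrast <- contrast
  calls <- call_translocations(st, fc_threshold, p_threshold, contrast)
  list(calls = calls,
       candidates = candidate_changing_set(st, contrast, p_threshold),
       summary = summarize_calls(calls))
}
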