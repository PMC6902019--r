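#' PSM-level log2 reporter ratios to the internal standard
#'
#' For every PSM, divides each sample channel's reporter intensity by the
#' intensity of that set's internal-standard channel and takes log2. PSMs
#' whose internal-standard intensity is not positive cannot be quantified
#' and are dropped (their number is recorded in the `n_dropped_zero_is`
#' attribute); sample-channel intensities that are not positive become NA.
#'
#' @param psms PSM data.frame with columns psm_id, peptide, gene, is_decoy,
#'   score, set_id and reporter columns `tmt_<channel>`.
#' @param design design data.frame (see [read_experiment()]); must designate
#'   exactly one internal-standard channel per set.
#' @return data.frame with the PSM annotation columns and one
#'   `ratio_<channel>` column per sample channel; attribute
#'   `n_dropped_zero_is` counts discarded PSMs.
#' @export
compute_psm_ratios <- function(psms, design) {
  sets <- unique(psms$set_id)
  tmt_cols <- grep("^tmt_", names(psms), value = TRUE)
  psm_channels <- sub("^tmt_", "", tmt_cols)
  meta_cols <- intersect(
    c("psm_id", "peptide", "gene", "is_decoy", "score", "set_id"),
    names(psms))

  out <- vector("list", length(sets))
  dropped <- 0L
  for (i in seq_along(sets)) {
    s <- sets[i]
    des <- design[design$set_id == s, ]
    if (nrow(des) == 0L) stopf("set '%s' has no design entries", s)
    if (sum(des$is_internal_standard) != 1L)
      stopf("set '%s' must have exactly one internal-standard channel", s)
    miss <- setdiff(psm_channels, des$channel)
    if (length(miss))
      stopf("set '%s': no design entry for channel(s) %s",
            s, paste(miss, collapse = ", "))
    is_ch <- des$channel[des$is_internal_standard]
    sample_ch <- des$channel[!des$is_internal_standard]
    sample_ch <- sample_ch[sample_ch %in% psm_channels]

    rows <- psms[psms$set_id == s, , drop = FALSE]
    is_int <- rows[[paste0("tmt_", is_ch)]]
    keep <- !is.na(is_int) & is_int > 0
    dropped <- dropped + sum(!keep)
    rows <- rows[keep, , drop = FALSE]
    is_int <- is_int[keep]

    ratios <- matrix(NA_real_, nrow(rows), length(sample_ch),
                     dimnames = list(NULL, paste0("ratio_", sample_ch)))
    for (ch in sample_ch) {
      v <- rows[[paste0("tmt_", ch)]]
      r <- log2(v / is_int)
      r[!is.finite(r)] <- NA_real_
      ratios[, paste0("ratio_", ch)] <- r
    }
    out[[i]] <- cbind(rows[, meta_cols, drop = FALSE], as.data.frame(ratios))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_dropped_zero_is") <- dropped
  res
}

#' Center each sample column on its median
#'
#' Normalizes PSM-level log2 ratios so that every sample column (a
#' set/channel pair) has median 0, removing loading and labeling
#' differences between samples. Idempotent.
#'
#' @param ratios data.frame from [compute_psm_ratios()].
#' @return the same data.frame with centered `ratio_*` columns.
#' @export
normalize_sample_median <- function(ratios) {
  ratio_cols <- grep("^ratio_", names(ratios), value = TRUE)
  for (s in unique(ratios$set_id)) {
    idx <- which(ratios$set_id == s)
    for (col in ratio_cols) {
      v <- ratios[[col]][idx]
      if (all(is.na(v)))
        stopf("sample column '%s' in set '%s' has no quantified PSMs", col, s)
      ratios[[col]][idx] <- v - fast_median(v)
    }
  }
  ratios
}

#' Roll PSM ratios up to a gene-level quantification matrix
#'
#' Peptide sequences observed with more than one distinct gene symbol are
#' excluded; per gene, set and sample channel the value is the median of
#' the remaining PSM log2 ratios. Per-gene PSM counts per set and the
#' median PSM count across sets (the count used for variance moderation)
#' are recorded. Genes absent from a set yield NA in that set's columns.
#'
#' @param ratios normalized PSM ratio data.frame
#'   (see [normalize_sample_median()]).
#' @param design design data.frame.
#' @return an object of class `protein_quant`: a list with `log2ratio`
#'   (genes x samples matrix, columns named set:donor:fraction:timepoint),
#'   `psm_counts` (genes x sets), `median_psm_count`, `samples` (the sample
#'   annotation) and `n_shared_peptides_excluded`.
#' @export
rollup_to_protein <- function(ratios, design) {
  pep_genes <- tapply(ratios$gene, ratios$peptide,
                      function(g) length(unique(g)))
  shared <- names(pep_genes)[pep_genes > 1L]
  n_shared <- length(shared)
  if (n_shared) ratios <- ratios[!ratios$peptide %in% shared, , drop = FALSE]

  sets <- unique(design$set_id)
  genes <- sort(unique(ratios$gene))
  samp <- design[!design$is_internal_standard, , drop = FALSE]
  samp <- samp[samp$set_id %in% sets, , drop = FALSE]
  samp$sample <- sample_name(samp$set_id, samp$donor, samp$fraction,
                             samp$timepoint_min)

  mat <- matrix(NA_real_, length(genes), nrow(samp),
                dimnames = list(genes, samp$sample))
  counts <- matrix(NA_real_, length(genes), length(sets),
                   dimnames = list(genes, sets))
  for (s in sets) {
    rows <- ratios[ratios$set_id == s, , drop = FALSE]
    if (nrow(rows) == 0L) next
    des_s <- samp[samp$set_id == s, , drop = FALSE]
    rcols <- paste0("ratio_", des_s$channel)
    sub <- as.matrix(rows[, rcols, drop = FALSE])
    med <- grouped_col_medians(sub, rows$gene)
    mat[rownames(med), des_s$sample] <- med
    tab <- table(rows$gene)
    counts[names(tab), s] <- as.numeric(tab)
  }
  median_count <- apply(counts, 1L, fast_median)

  structure(list(
    log2ratio = mat, psm_counts = counts,
    median_psm_count = median_count, samples = samp,
    n_shared_peptides_excluded = n_shared
  ), class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("protein_quant:", nrow(x$log2ratio), "genes x",
      ncol(x$log2ratio), "samples (",
      length(unique(x$samples$set_id)), "sets )\n")
  cat("  median PSM count per gene: median",
      fast_median(x$median_psm_count), "\n")
  cat("  fully quantified genes:",
      sum(stats::complete.cases(x$log2ratio)), "\n")
  invisible(x)
}

#' Subset a protein_quant to a gene set
#' @param pq protein_quant object
#' @param genes character vector of genes to keep
#' @return protein_quant restricted to `genes` (order preserved).
#' @export
subset_genes <- function(pq, genes) {
  keep <- rownames(pq$log2ratio) %in% genes
  pq$log2ratio <- pq$log2ratio[keep, , drop = FALSE]
  pq$psm_counts <- pq$psm_counts[keep, , drop = FALSE]
  pq$median_psm_count <- pq$median_psm_count[keep]
  pq
}

#' Picked target-decoy protein FDR
#'
#' Protein-level false-discovery control on gene-symbol groups: for each
#' gene only the better-scoring of its target/decoy pair is kept ("picked"),
#' picked entries are sorted by descending score, and walking down the list
#' the FDR at rank k is estimated as (decoys so far) / (targets so far).
#' Targets are retained up to the deepest rank whose estimate is at or
#' below the threshold. A decoy that outscores its target turns that gene
#' into a decoy observation; it is never retained. Ties are broken target
#' before decoy, then by gene symbol, so results are deterministic.
#'
#' @param target_scores named numeric vector: per-gene best target score.
#' @param decoy_scores named numeric vector: per-gene best decoy score,
#'   named by the paired target gene symbol.
#' @param threshold FDR threshold in (0, 1].
#' @return character vector of retained target genes; the full picked table
#'   is attached as attribute `picked`.
#' @export
picked_protein_fdr <- function(target_scores, decoy_scores, threshold = 0.01) {
  if (threshold <= 0 || threshold > 1)
    stopf("threshold must be in (0, 1]")
  genes <- union(names(target_scores), names(decoy_scores))
  t_sc <- target_scores[genes]; d_sc <- decoy_scores[genes]
  t_sc[is.na(t_sc)] <- -Inf; d_sc[is.na(d_sc)] <- -Inf
  picked_decoy <- d_sc > t_sc            # tie -> target wins
  score <- pmax(t_sc, d_sc)
  ord <- order(-score, picked_decoy, genes)
  tab <- data.frame(gene = genes[ord], score = score[ord],
                    is_decoy = picked_decoy[ord], stringsAsFactors = FALSE)
  cum_d <- cumsum(tab$is_decoy)
  cum_t <- cumsum(!tab$is_decoy)
  est <- ifelse(cum_t > 0, cum_d / cum_t, Inf)
  k <- which(est <= threshold)
  k_max <- if (length(k)) max(k) else 0L
  tab$fdr_est <- est
  tab$retained <- FALSE
  if (k_max > 0) tab$retained[seq_len(k_max)] <- !tab$is_decoy[seq_len(k_max)]
  retained <- tab$gene[tab$retained]
  attr(retained, "picked") <- tab
  retained
}

#' Per-gene best scores from a PSM table
#'
#' Splits PSMs into target and decoy gene groups (decoy genes identified by
#' the decoy flag and matched to their target gene by stripping `prefix`)
#' and returns each gene's best search score, the input expected by
#' [picked_protein_fdr()].
#'
#' @param psms PSM data.frame with gene, is_decoy, score.
#' @param prefix decoy gene-name prefix.
#' @return list with named numeric vectors `target` and `decoy`.
#' @export
best_gene_scores <- function(psms, prefix = "DECOY_") {
  tg <- psms[!psms$is_decoy, ]
  dc <- psms[psms$is_decoy, ]
  target <- tapply(tg$score, tg$gene, max)
  decoy <- if (nrow(dc)) tapply(dc$score, sub(paste0("^", prefix), "", dc$gene), max)
           else numeric()
  list(target = unlist(as.list(target)), decoy = unlist(as.list(decoy)))
}

#' Keep only genes with full quantitation in all channels
#'
#' Retains genes with a non-missing log2 ratio in every sample channel of
#' every set, the requirement for the differential analysis matrix.
#'
#' @param pq protein_quant object.
#' @return protein_quant restricted to fully quantified genes.
#' @export
filter_full_quantitation <- function(pq) {
  if (nrow(pq$log2ratio) == 0L) return(pq)
  complete <- stats::complete.cases(pq$log2ratio) &
    stats::complete.cases(pq$psm_counts)
  subset_genes(pq, rownames(pq$log2ratio)[complete])
}

#' Write a protein_quant object to TSV files
#' @param pq protein_quant object
#' @param dir output directory
#' @return invisibly, the paths written.
#' @export
write_quant <- function(pq, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qp <- file.path(dir, "protein_quant.tsv")
  cp <- file.path(dir, "psm_counts.tsv")
  write_tsv(data.frame(gene = rownames(pq$log2ratio),
                       pq$log2ratio, check.names = FALSE), qp)
  write_tsv(data.frame(gene = rownames(pq$psm_counts),
                       pq$psm_counts,
                       median_psm_count = pq$median_psm_count,
                       check.names = FALSE), cp)
  invisible(c(qp, cp))
}
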