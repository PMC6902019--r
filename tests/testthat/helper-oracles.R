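# Independent oracles and toy-data builders used across the suite.
# These deliberately re-derive results by the most direct route available
# (enumeration, closed forms, textbook formulas) and never call the code
# paths they are used to check.

# Brute-force picked FDR: pick the better of each target/decoy pair, then
# try every score cutoff and keep the deepest one whose decoy/target ratio
# is within the threshold.
oracle_picked_fdr <- function(target_scores, decoy_scores, threshold) {
  genes <- union(names(target_scores), names(decoy_scores))
  t_sc <- target_scores[genes]; d_sc <- decoy_scores[genes]
  t_sc[is.na(t_sc)] <- -Inf; d_sc[is.na(d_sc)] <- -Inf
  is_decoy <- d_sc > t_sc
  score <- pmax(t_sc, d_sc)
  best <- character()
  for (cut in unique(score)) {
    in_set <- score >= cut
    n_d <- sum(is_decoy[in_set]); n_t <- sum(!is_decoy[in_set])
    if (n_t > 0 && n_d / n_t <= threshold) {
      targets <- genes[in_set & !is_decoy]
      if (length(targets) > length(best)) best <- targets
    }
  }
  sort(best)
}

# Textbook paired t-test on a matrix of within-donor differences.
oracle_paired_t <- function(delta) {
  n <- ncol(delta)
  m <- rowMeans(delta)
  s <- apply(delta, 1L, sd)
  t <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  data.frame(logFC = m, t = t, P = p)
}

# Naive agglomerative average linkage on a distance matrix: returns the
# sequence of merge heights and the partition (as a canonical string)
# after each merge. Ties broken by smallest member index.
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- character(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1] - 1e-12) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[-c(i, j)], list(merged))
    heights <- c(heights, best[1])
    partitions <- c(partitions, paste(
      sort(vapply(clusters, function(cl) paste(cl, collapse = "+"),
                  character(1))), collapse = " | "))
  }
  list(heights = heights, partitions = partitions)
}

# Partition trace of an hclust object in the same canonical form.
hclust_partition_trace <- function(hc) {
  n <- length(hc$order)
  members <- as.list(seq_len(n))       # leaves by negative index convention
  node_members <- vector("list", nrow(hc$merge))
  clusters <- as.list(seq_len(n))
  keys <- vapply(clusters, function(cl) paste(cl, collapse = "+"), character(1))
  partitions <- character(0)
  for (step in seq_len(nrow(hc$merge))) {
    get_members <- function(idx)
      if (idx < 0) -idx else node_members[[idx]]
    m <- sort(c(get_members(hc$merge[step, 1]), get_members(hc$merge[step, 2])))
    node_members[[step]] <- m
    drop <- vapply(clusters, function(cl) all(cl %in% m), logical(1))
    clusters <- c(clusters[!drop], list(m))
    partitions <- c(partitions, paste(
      sort(vapply(clusters, function(cl) paste(cl, collapse = "+"),
                  character(1))), collapse = " | "))
  }
  list(heights = hc$height, partitions = partitions)
}

# Build a minimal protein_quant object directly from a matrix of
# within-donor treatment/baseline values: columns are generated for one
# fraction per donor at timepoints 0 and `tp`.
make_pq <- function(baseline, treatment, fraction = "C", tp = 60,
                    counts = NULL) {
  stopifnot(ncol(baseline) == ncol(treatment))
  nd <- ncol(baseline)
  donors <- paste0("D", seq_len(nd))
  sets <- paste0("set", seq_len(nd))
  samples <- data.frame(
    set_id = rep(sets, each = 2),
    channel = rep(c("126", "127N"), nd),
    donor = rep(donors, each = 2),
    fraction = fraction,
    timepoint_min = rep(c(0, tp), nd),
    is_internal_standard = FALSE,
    stringsAsFactors = FALSE)
  samples$sample <- paste(samples$set_id, samples$donor, samples$fraction,
                          samples$timepoint_min, sep = ":")
  genes <- rownames(baseline)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(baseline)))
  mat <- matrix(NA_real_, nrow(baseline), nrow(samples),
                dimnames = list(genes, samples$sample))
  for (d in seq_len(nd)) {
    mat[, samples$sample[samples$donor == donors[d] &
                           samples$timepoint_min == 0]] <- baseline[, d]
    mat[, samples$sample[samples$donor == donors[d] &
                           samples$timepoint_min == tp]] <- treatment[, d]
  }
  if (is.null(counts)) counts <- rep(3, length(genes))
  structure(list(
    log2ratio = mat,
    psm_counts = matrix(counts, length(genes), nd,
                        dimnames = list(genes, sets)),
    median_psm_count = setNames(counts, genes),
    samples = samples, n_shared_peptides_excluded = 0L),
    class = "protein_quant")
}

# Long DiffStat data.frame from per-fraction named vectors of logFC and P.
make_diffstats <- function(logFC, P, contrast = 60) {
  # logFC, P: matrices genes x fractions with dimnames
  stopifnot(identical(dimnames(logFC), dimnames(P)))
  out <- expand.grid(gene = rownames(logFC), fraction = colnames(logFC),
                     stringsAsFactors = FALSE)
  out$contrast <- contrast
  out$logFC <- logFC[cbind(out$gene, out$fraction)]
  out$P <- P[cbind(out$gene, out$fraction)]
  out
}
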