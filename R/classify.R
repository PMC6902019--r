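#' Z-score gene rows of a quantification matrix
#'
#' Subtracts each row's mean and divides by its standard deviation, the
#' scaling assumed before correlation-distance clustering. Constant rows
#' (zero variance) cannot be standardized; they are dropped and reported
#' in the `excluded` attribute.
#'
#' @param mat numeric matrix (genes x samples) or protein_quant object.
#' @return standardized matrix; attribute `excluded` lists dropped genes.
#' @export
row_normalize <- function(mat) {
  if (inherits(mat, "protein_quant")) mat <- mat$log2ratio
  if (ncol(mat) < 2L) stopf("need >= 2 columns to row-normalize")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  out <- (mat[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  attr(out, "excluded") <- rownames(mat)[!keep]
  out
}

#' k-means clustering under 1 - Pearson correlation distance
#'
#' Exploits the identity that for rows centered and scaled to unit L2
#' norm, squared Euclidean distance equals 2 * (1 - Pearson correlation),
#' so standard k-means on the rescaled rows minimizes total correlation
#' distance. The best of `restarts` random initializations is kept;
#' deterministic given `seed`.
#'
#' @param mat row-standardized matrix (see [row_normalize()]).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of random initializations.
#' @return `stats::kmeans` result on the unit-norm rows (cluster vector
#'   named by gene).
#' @export
kmeans_correlation <- function(mat, k = 3, seed = 1L, restarts = 25) {
  if (k > nrow(mat)) stopf("k exceeds the number of rows")
  cm <- mat - rowMeans(mat)
  nrm <- sqrt(rowSums(cm^2))
  if (any(nrm == 0)) stopf("constant rows present; run row_normalize first")
  u <- cm / nrm
  with_seed(seed,
    stats::kmeans(u, centers = k, nstart = restarts, iter.max = 100L))
}

#' Label clusters with subcellular compartments
#'
#' Each cluster is labeled with the fraction whose sample columns have the
#' highest cluster-mean value; ties are broken in the fixed order C, M, N.
#' If two clusters map to the same fraction a warning is emitted and the
#' labels are still assigned by the rule. A silhouette-like confidence is
#' attached per gene: 1 - (correlation distance to own centroid) /
#' (distance to the nearest other centroid).
#'
#' @param km kmeans result from [kmeans_correlation()].
#' @param mat the matrix that was clustered (row-standardized).
#' @param samples sample annotation data.frame with columns `sample` and
#'   `fraction` (e.g. `pq$samples`).
#' @return data.frame: gene, cluster, compartment, confidence.
#' @export
label_clusters <- function(km, mat, samples) {
  k <- nrow(km$centers)
  frac_of_col <- samples$fraction[match(colnames(mat), samples$sample)]
  labels <- character(k)
  for (cl in seq_len(k)) {
    m <- tapply(km$centers[cl, ], frac_of_col, mean)
    m <- m[FRACTIONS[FRACTIONS %in% names(m)]]   # fixed tie-break order
    labels[cl] <- names(m)[which.max(m)]
  }
  if (anyDuplicated(labels))
    warning("two or more clusters map to the same fraction", call. = FALSE)

  cm <- mat - rowMeans(mat)
  u <- cm / sqrt(rowSums(cm^2))
  d <- 1 - u %*% t(km$centers) /
    outer(rep(1, nrow(u)), sqrt(rowSums(km$centers^2)))
  own <- d[cbind(seq_len(nrow(u)), km$cluster)]
  if (k == 1L) {
    conf <- rep(1, nrow(u))
  } else {
    other <- apply(cbind(d, km$cluster), 1L, function(r) {
      min(r[seq_len(k)][-r[k + 1L]])
    })
    conf <- 1 - own / pmax(other, .Machine$double.eps)
  }

  data.frame(gene = rownames(mat), cluster = unname(km$cluster),
             compartment = labels[km$cluster],
             confidence = as.vector(conf),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compartment assignment by correlation k-means
#'
#' Convenience wrapper: row-normalizes the quantification matrix, runs
#' [kmeans_correlation()] and [label_clusters()].
#'
#' @param pq protein_quant object (fully quantified genes recommended).
#' @param k,seed,restarts see [kmeans_correlation()].
#' @return data.frame of compartment assignments; excluded constant rows
#'   are recorded in the `excluded` attribute.
#' @export
classify_compartments <- function(pq, k = 3, seed = 1L, restarts = 25) {
  z <- row_normalize(pq)
  km <- kmeans_correlation(z, k = k, seed = seed, restarts = restarts)
  out <- label_clusters(km, z, pq$samples)
  attr(out, "excluded") <- attr(z, "excluded")
  out
}

#' PCA of samples for fractionation quality control
#'
#' Principal component analysis of the sample columns of the gene x sample
#' log2 ratio matrix (each gene centered). Returns per-sample scores on
#' the first two components together with a mean silhouette width of the
#' samples grouped by fraction in that plane — a positive value indicates
#' samples separate by fraction.
#'
#' @param pq protein_quant object.
#' @return list: `scores` data.frame (sample, fraction, timepoint, donor,
#'   PC1, PC2), `var_explained` (length 2), `fraction_silhouette`.
#' @export
pca_qc <- function(pq) {
  X <- pq$log2ratio[stats::complete.cases(pq$log2ratio), , drop = FALSE]
  if (ncol(X) < 2L) stopf("need >= 2 samples")
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  samp <- pq$samples[match(rownames(sc), pq$samples$sample), ]
  sil <- mean_silhouette(sc, samp$fraction)
  list(
    scores = data.frame(sample = rownames(sc),
                        fraction = samp$fraction,
                        timepoint_min = samp$timepoint_min,
                        donor = samp$donor,
                        PC1 = sc[, 1], PC2 = sc[, 2],
                        stringsAsFactors = FALSE, row.names = NULL),
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
    fraction_silhouette = sil)
}

# Mean silhouette width for points (rows of x) grouped by `groups`,
# Euclidean distance; groups with a single member contribute 0.
mean_silhouette <- function(x, groups) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[i]
    if (sum(own) <= 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(groups[!own]), function(g)
      mean(d[i, groups == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Average-linkage ordering of sample columns
#'
#' Agglomerative average-linkage clustering of sample columns under
#' 1 - Pearson correlation distance; returns the dendrogram leaf order.
#' Columns are sorted by name beforehand so ties resolve deterministically.
#'
#' @param mat numeric matrix or protein_quant object.
#' @return character vector of column names in leaf order; the `hclust`
#'   object is attached as attribute `hclust`.
#' @export
column_cluster_order <- function(mat) {
  if (inherits(mat, "protein_quant")) mat <- mat$log2ratio
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (ncol(mat) < 2L) stopf("need >= 2 columns")
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(mat))
  hc <- stats::hclust(d, method = "average")
  out <- colnames(mat)[hc$order]
  attr(out, "hclust") <- hc
  out
}

#' Cross-tabulate compartment assignments against a reference
#'
#' Compares this analysis' compartment labels with a user-supplied
#' gene-to-compartment reference table (e.g. an external localization
#' atlas), by exact gene symbol.
#'
#' @param assignments data.frame from [classify_compartments()].
#' @param reference data.frame with columns `gene` and `compartment`.
#' @return contingency table (rows: this analysis; columns: reference).
#' @export
compare_to_reference <- function(assignments, reference) {
  common <- intersect(assignments$gene, reference$gene)
  table(
    assigned = assignments$compartment[match(common, assignments$gene)],
    reference = reference$compartment[match(common, reference$gene)])
}
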