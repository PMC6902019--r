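#' Normalize per-cell intensities to the unstimulated population
#'
#' Divides every nuclear and cytosolic intensity by the median total
#' (nuclear + cytosolic) intensity of the unstimulated cells, so that
#' changes in total target expression remain visible while conditions
#' become comparable.
#'
#' @param cells data.frame: cell_id, condition, nuclear, cytosolic.
#' @param unstimulated label of the unstimulated condition.
#' @return the data.frame with normalized nuclear, cytosolic and a `total`
#'   column.
#' @export
normalize_to_unstimulated <- function(cells, unstimulated = "unstimulated") {
  ref <- cells[cells$condition == unstimulated, ]
  if (nrow(ref) == 0L)
    stopf("unstimulated condition '%s' not present", unstimulated)
  ref_total <- fast_median(ref$nuclear + ref$cytosolic)
  if (!is.finite(ref_total) || ref_total <= 0)
    stopf("unstimulated population has non-positive median total intensity")
  cells$nuclear <- cells$nuclear / ref_total
  cells$cytosolic <- cells$cytosolic / ref_total
  cells$total <- cells$nuclear + cells$cytosolic
  cells
}

#' Median nuclear and cytosolic shares for one condition
#'
#' Takes the condition-level median nuclear and median cytosolic
#' (normalized) intensities and rescales them so their sum is exactly 1,
#' the form used for stacked-bar comparisons of localization between
#' conditions.
#'
#' @param cells (normalized) per-cell data.frame.
#' @param condition condition label.
#' @return named numeric vector c(nuclear = ..., cytosolic = ...) summing
#'   to 1.
#' @export
distribution_shares <- function(cells, condition) {
  sub <- cells[cells$condition == condition, ]
  if (nrow(sub) == 0L) stopf("condition '%s' has no cells", condition)
  mn <- fast_median(sub$nuclear)
  mc <- fast_median(sub$cytosolic)
  tot <- mn + mc
  if (tot <= 0) stopf("condition '%s' has non-positive median intensities",
                      condition)
  c(nuclear = mn / tot, cytosolic = mc / tot)
}

#' Mann-Whitney U test with midrank ties
#'
#' Two-sided rank-sum comparison of two groups: U is computed from
#' midranks. For small samples (both groups < 20) the P value is exact —
#' from the null U distribution when there are no ties, otherwise by full
#' enumeration of group assignments when feasible; larger samples use the
#' normal approximation with tie correction and continuity correction.
#' A warning (not an error) is emitted when a group has 100 or fewer
#' cells, the scale at which the comparison is considered well powered.
#'
#' @param a,b numeric vectors.
#' @param warn_n sample size at or below which a warning is emitted.
#' @return list: U (for group `a`), p_value, method.
#' @export
mann_whitney <- function(a, b, warn_n = 100) {
  if (length(a) == 0L || length(b) == 0L) stopf("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  if (min(n1, n2) <= warn_n)
    warning(sprintf("group size %d <= %d cells; comparison may be underpowered",
                    min(n1, n2), warn_n), call. = FALSE)
  r <- rank(c(a, b))          # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))

  small <- n1 < 20L && n2 < 20L
  if (small && !ties) {
    p <- stats::pwilcox(min(U, n1 * n2 - U), n1, n2)
    p <- min(1, 2 * p)
    method <- "exact"
  } else if (small && choose(n1 + n2, n1) <= 2e5) {
    # exact permutation distribution of U under ties
    combs <- utils::combn(n1 + n2, n1)
    rs <- colSums(matrix(r[combs], nrow = n1))
    Us <- rs - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact (enumeration)"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - tie_term)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (sigma2 == 0) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = unname(U), p_value = min(1, p), method = method)
}

#' Nuclear/cytosol translocation statistics for an imaging experiment
#'
#' Full imaging workflow: normalize to the unstimulated population,
#' compute per-condition nuclear/cytosolic shares, and test each
#' stimulated condition's per-cell nuclear share against the unstimulated
#' one with [mann_whitney()].
#'
#' @param cells per-cell data.frame (cell_id, condition, nuclear,
#'   cytosolic).
#' @param unstimulated label of the reference condition.
#' @return list: `shares` (data.frame condition x nuclear/cytosolic),
#'   `tests` (data.frame condition, U, p_value, n), `cells` (normalized).
#' @export
imaging_translocation_stats <- function(cells, unstimulated = "unstimulated") {
  norm <- normalize_to_unstimulated(cells, unstimulated)
  conds <- unique(norm$condition)
  shares <- t(vapply(conds, function(cc) distribution_shares(norm, cc),
                     numeric(2)))
  share_of <- function(sub) sub$nuclear / (sub$nuclear + sub$cytosolic)
  ref <- norm[norm$condition == unstimulated, ]
  stim <- setdiff(conds, unstimulated)
  tests <- do.call(rbind, lapply(stim, function(cc) {
    sub <- norm[norm$condition == cc, ]
    mw <- mann_whitney(share_of(sub), share_of(ref))
    data.frame(condition = cc, U = mw$U, p_value = mw$p_value,
               n = nrow(sub), method = mw$method,
               stringsAsFactors = FALSE)
  }))
  list(shares = data.frame(condition = conds, shares,
                           stringsAsFactors = FALSE, row.names = NULL),
       tests = tests, cells = norm)
}
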