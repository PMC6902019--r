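#' Donor-paired per-gene fit for one fraction and contrast
#'
#' For each gene, forms within-donor differences between the treatment and
#' baseline timepoints in the given fraction (each donor is a pair), and
#' summarizes them: the log2 fold change is the mean difference, the
#' residual variance the sample variance of the differences, with n - 1
#' residual degrees of freedom. Genes with fewer than two complete donor
#' pairs are untestable and excluded.
#'
#' @param pq protein_quant object.
#' @param fraction one of "C", "M", "N".
#' @param baseline,treatment timepoints in minutes; baseline defaults to 0.
#' @return data.frame: gene, fraction, contrast, logFC, s2, df, n_pairs,
#'   count (median PSM count across sets).
#' @export
fit_paired_model <- function(pq, fraction, treatment, baseline = 0) {
  if (identical(baseline, treatment)) stopf("baseline and treatment must differ")
  samp <- pq$samples
  b_cols <- samp$sample[samp$fraction == fraction &
                          samp$timepoint_min == baseline]
  t_cols <- samp$sample[samp$fraction == fraction &
                          samp$timepoint_min == treatment]
  if (length(b_cols) == 0L || length(t_cols) == 0L)
    stopf("fraction '%s' with timepoints %s and %s not found in design",
          fraction, baseline, treatment)
  b_donor <- samp$donor[match(b_cols, samp$sample)]
  t_donor <- samp$donor[match(t_cols, samp$sample)]
  donors <- intersect(b_donor, t_donor)
  if (length(donors) < 2L) stopf("need >= 2 donors with both timepoints")

  X <- pq$log2ratio
  delta <- X[, t_cols[match(donors, t_donor)], drop = FALSE] -
    X[, b_cols[match(donors, b_donor)], drop = FALSE]
  n_pairs <- rowSums(!is.na(delta))
  testable <- n_pairs >= 2L
  delta <- delta[testable, , drop = FALSE]

  logFC <- rowMeans(delta, na.rm = TRUE)
  s2 <- apply(delta, 1L, stats::var, na.rm = TRUE)
  data.frame(
    gene = rownames(delta),
    fraction = fraction,
    contrast = treatment,
    logFC = logFC,
    s2 = s2,
    df = n_pairs[testable] - 1,
    n_pairs = n_pairs[testable],
    count = pq$median_psm_count[rownames(delta)],
    stringsAsFactors = FALSE, row.names = NULL)
}

# Newton solve of trigamma(y) = x (Smyth-style), vectorized.
trigamma_inverse <- function(x) {
  out <- x
  ok <- is.finite(x) & x > 0
  out[!ok & !is.na(x) & x <= 0] <- Inf
  y <- 0.5 + 1 / x[ok]
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[ok]) / psigamma(y, 2L)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < 1e-8) break
  }
  out[ok] <- y
  out
}

#' Empirical-Bayes variance trend over PSM counts
#'
#' Fits the prior variance of the moderation model as a smooth function of
#' the per-gene median PSM count: log residual variances are regressed on
#' log counts with a local (loess) smooth, and the prior degrees of freedom
#' d0 are estimated by method of moments under the scaled-F model, in which
#' s2 ~ s0^2(count) * F(df, d0). The fitted log-variance trend is
#' mean-bias-corrected by the expectation of log F so that s0^2 is the
#' model's prior variance, not the geometric mean of observed variances.
#' Zero variances are floored at the smallest positive variance times 1e-3.
#' With fewer than 20 genes, fewer than 2 distinct counts, or a degenerate
#' smooth, a constant trend is used.
#'
#' @param fits data.frame from [fit_paired_model()] (rows from several
#'   fractions may be pooled).
#' @param d0_cap upper bound representing effectively infinite prior df.
#' @param span loess span.
#' @return object of class `variance_trend`: list with `s0_fun` (function
#'   count -> prior variance), `d0`, `method`, and the floored variance
#'   vector used.
#' @export
fit_variance_trend <- function(fits, d0_cap = 1e6, span = 0.75) {
  s2 <- fits$s2
  df <- fits$df
  count <- fits$count
  pos <- s2[s2 > 0]
  if (length(pos) == 0L) {
    # all variances zero: no information about spread; flat prior at cap
    s0 <- .Machine$double.eps
    return(structure(list(
      s0_fun = function(n) rep(s0, length(n)),
      d0 = d0_cap, method = "constant", s2_floored = rep(s0, length(s2)),
      d0_cap = d0_cap), class = "variance_trend"))
  }
  floor_val <- min(pos) * 1e-3
  s2f <- pmax(s2, floor_val)
  z <- log(s2f)
  lx <- log(count)

  use_smooth <- length(s2f) >= 20L && length(unique(count)) >= 2L
  trend_at <- NULL
  method <- "constant"
  if (use_smooth) {
    fit <- try(stats::loess(z ~ lx, degree = 1L, span = span,
                            family = "gaussian"),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      ux <- sort(unique(lx))
      py <- try(stats::predict(fit, data.frame(lx = ux)), silent = TRUE)
      if (!inherits(py, "try-error") && all(is.finite(py))) {
        trend_at <- stats::approxfun(ux, py, rule = 2L)
        method <- "loess"
      }
    }
    if (is.null(trend_at)) {
      # fallback: binned means over count, monotone interpolation
      br <- stats::quantile(lx, probs = seq(0, 1, length.out = 6L),
                            names = FALSE)
      bin <- cut(lx, unique(br), include.lowest = TRUE)
      mx <- tapply(lx, bin, mean); my <- tapply(z, bin, mean)
      ok <- is.finite(mx) & is.finite(my)
      if (sum(ok) >= 2L) {
        trend_at <- stats::approxfun(mx[ok], my[ok], rule = 2L)
        method <- "binned"
      }
    }
  }
  if (is.null(trend_at)) {
    mu <- mean(z)
    trend_at <- function(n) rep(mu, length(n))
    method <- "constant"
  }

  resid_z <- z - trend_at(lx)
  # var(log F(df, d0)) = trigamma(df/2) + trigamma(d0/2)
  evar <- stats::var(resid_z) - mean(trigamma(df / 2))
  d0 <- if (!is.finite(evar) || evar <= 0) d0_cap
        else min(2 * trigamma_inverse(evar), d0_cap)
  # E[log F(df, d0)] = digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)
  elogf <- mean(digamma(df / 2) - log(df / 2)) -
    if (d0 >= d0_cap) 0 else digamma(d0 / 2) - log(d0 / 2)
  # centre the trend on the residual mean, then remove the log-F bias
  offset <- mean(resid_z) - elogf
  s0_fun <- function(n) exp(trend_at(log(n)) + offset)

  structure(list(s0_fun = s0_fun, d0 = d0, method = method,
                 s2_floored = s2f, d0_cap = d0_cap),
            class = "variance_trend")
}

#' @export
print.variance_trend <- function(x, ...) {
  cat("variance_trend:", x$method, "trend, prior df d0 =",
      format(x$d0, digits = 4), if (x$d0 >= x$d0_cap) "(capped)" else "", "\n")
  invisible(x)
}

#' Moderated paired statistics
#'
#' Shrinks each gene's residual variance toward the count-dependent prior:
#' the posterior variance is (d0 * s0^2(count) + df * s2) / (d0 + df), the
#' moderated t statistic is logFC / (s_post / sqrt(n)), and the two-sided P
#' comes from a t distribution on d0 + df degrees of freedom. No multiple-
#' testing correction is applied; downstream calling uses uncorrected P as
#' a variability filter and fold change as the effect-size filter.
#'
#' @param fits data.frame from [fit_paired_model()].
#' @param trend `variance_trend` object, or `NULL` with `d0 = 0` for the
#'   unmoderated ordinary paired t-test.
#' @param d0 override for the prior degrees of freedom (defaults to the
#'   trend's estimate); `d0 = 0` disables moderation.
#' @return the input data.frame with columns t, P and posterior_var added.
#' @export
moderate_statistics <- function(fits, trend, d0 = NULL) {
  if (is.null(d0)) d0 <- trend$d0
  if (any(d0 + fits$df <= 0)) stopf("total degrees of freedom must be > 0")
  s2f <- if (d0 > 0) pmax(fits$s2, 0) else fits$s2
  if (d0 > 0) {
    s0 <- trend$s0_fun(fits$count)
    if (d0 >= trend$d0_cap) post <- s0
    else post <- (d0 * s0 + fits$df * s2f) / (d0 + fits$df)
  } else {
    post <- s2f
  }
  se <- sqrt(post / fits$n_pairs)
  t <- ifelse(se > 0, fits$logFC / se, ifelse(fits$logFC == 0, 0, Inf * sign(fits$logFC)))
  df_tot <- d0 + fits$df
  P <- 2 * stats::pt(-abs(t), df = df_tot)
  P[fits$logFC == 0] <- 1
  fits$t <- t
  fits$P <- P
  fits$posterior_var <- post
  fits$df_total <- df_tot
  fits
}

#' Fit donor-paired moderated differential statistics across fractions
#'
#' The central model fit: for every subcellular fraction and every
#' treatment timepoint it computes within-donor paired log2 fold changes
#' against the resting baseline, fits a PSM-count-dependent empirical-Bayes
#' variance trend (pooled across fractions per contrast by default), and
#' returns moderated t statistics and two-sided P values.
#'
#' @param pq protein_quant object, usually after
#'   [filter_full_quantitation()].
#' @param contrasts treatment timepoints to test against baseline 0.
#' @param fractions fractions to fit.
#' @param per_fraction if TRUE, fit a separate variance trend per fraction
#'   instead of pooling genes across fractions within a contrast.
#' @param d0_cap cap for the prior degrees of freedom.
#' @return object of class `fraction_diff`: list with `stats` (the long
#'   DiffStat table: gene, fraction, contrast, logFC, t, P, count, ...),
#'   `trends` (per contrast), `fractions`, `contrasts`.
#' @seealso [call_translocations()], [candidate_changing_set()]
#' @export
fit_fraction_diff <- function(pq, contrasts = c(15, 60),
                              fractions = FRACTIONS,
                              per_fraction = FALSE,
                              d0_cap = 1e6) {
  all_stats <- list(); trends <- list()
  for (tp in contrasts) {
    fits <- do.call(rbind, lapply(fractions, function(f)
      fit_paired_model(pq, f, treatment = tp)))
    if (per_fraction) {
      parts <- lapply(fractions, function(f) {
        sub <- fits[fits$fraction == f, , drop = FALSE]
        tr <- fit_variance_trend(sub, d0_cap = d0_cap)
        moderate_statistics(sub, tr)
      })
      all_stats[[as.character(tp)]] <- do.call(rbind, parts)
      trends[[as.character(tp)]] <- NULL
    } else {
      tr <- fit_variance_trend(fits, d0_cap = d0_cap)
      trends[[as.character(tp)]] <- tr
      all_stats[[as.character(tp)]] <- moderate_statistics(fits, tr)
    }
  }
  stats <- do.call(rbind, all_stats)
  rownames(stats) <- NULL
  structure(list(stats = stats, trends = trends,
                 fractions = fractions, contrasts = contrasts,
                 n_genes = nrow(pq$log2ratio)),
            class = "fraction_diff")
}

#' @export
print.fraction_diff <- function(x, ...) {
  cat("fraction_diff: paired moderated fit,", x$n_genes, "genes,",
      length(x$fractions), "fractions, contrasts vs 0 min:",
      paste(x$contrasts, "min", collapse = ", "), "\n")
  for (tp in names(x$trends)) {
    tr <- x$trends[[tp]]
    if (!is.null(tr))
      cat(sprintf("  %s min: %s variance trend, d0 = %s\n", tp, tr$method,
                  format(tr$d0, digits = 4)))
  }
  invisible(x)
}

#' @export
summary.fraction_diff <- function(object, fc_threshold = 0.201,
                                  p_threshold = 0.05, contrast = 60, ...) {
  stats <- object$stats
  cand <- candidate_changing_set(stats, contrast = contrast,
                                 p_threshold = p_threshold)
  calls <- call_translocations(stats, fc_threshold = fc_threshold,
                               p_threshold = p_threshold, contrast = contrast)
  smry <- summarize_calls(calls)
  out <- list(contrast = contrast, fc_threshold = fc_threshold,
              p_threshold = p_threshold,
              n_tested = length(unique(stats$gene[stats$contrast == contrast])),
              n_candidates = length(cand),
              n_calls = smry$n_calls,
              involvement_pct = smry$involvement_pct)
  class(out) <- "summary.fraction_diff"
  out
}

#' @export
print.summary.fraction_diff <- function(x, ...) {
  cat(sprintf("Contrast %s min vs rest: %d genes tested\n",
              x$contrast, x$n_tested))
  cat(sprintf("  P < %g in >= 2 fractions (candidates): %d\n",
              x$p_threshold, x$n_candidates))
  cat(sprintf("  translocation calls (|log2FC| > %g, opposite direction): %d\n",
              x$fc_threshold, x$n_calls))
  inv <- x$involvement_pct
  cat("  fraction involvement (%):",
      paste(sprintf("%s %.1f", names(inv), inv), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fraction_diff <- function(object, contrast = 60, ...) {
  st <- object$stats[object$stats$contrast == contrast, ]
  genes <- sort(unique(st$gene))
  out <- matrix(NA_real_, length(genes), length(object$fractions),
                dimnames = list(genes, object$fractions))
  out[cbind(match(st$gene, genes), match(st$fraction, object$fractions))] <-
    st$logFC
  out
}

#' Scatter of per-fraction fold changes with called translocators marked
#' @param x fraction_diff object
#' @param contrast contrast timepoint
#' @param fc_threshold,p_threshold calling thresholds
#' @param fractions two fractions to plot against each other
#' @param ... passed to plot()
#' @export
plot.fraction_diff <- function(x, contrast = 60, fc_threshold = 0.201,
                               p_threshold = 0.05,
                               fractions = c("C", "N"), ...) {
  fc <- coef(x, contrast = contrast)
  calls <- call_translocations(x$stats, fc_threshold, p_threshold, contrast)
  hit <- rownames(fc) %in% calls$gene[calls$pass]
  graphics::plot(fc[, fractions[1]], fc[, fractions[2]],
                 col = ifelse(hit, "red", "grey50"),
                 pch = ifelse(hit, 19, 1), cex = 0.6,
                 xlab = paste("log2FC", fractions[1]),
                 ylab = paste("log2FC", fractions[2]), ...)
  graphics::abline(h = c(-1, 1) * fc_threshold,
                   v = c(-1, 1) * fc_threshold, lty = 2, col = "grey70")
  invisible(x)
}

#' Write DiffStat tables to TSV (one file per contrast)
#' @param fit fraction_diff object
#' @param dir output directory
#' @return invisibly, paths written.
#' @export
write_diffstats <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (tp in fit$contrasts) {
    st <- fit$stats[fit$stats$contrast == tp,
                    c("gene", "fraction", "logFC", "t", "P", "count")]
    p <- file.path(dir, sprintf("diffstats_%smin.tsv", tp))
    write_tsv(st, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
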