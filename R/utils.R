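# Internal helpers shared across modules.

TMT10_CHANNELS <- c("126", "127N", "127C", "128N", "128C",
                    "129N", "129C", "130N", "130C", "131")
FRACTIONS  <- c("C", "M", "N")
TIMEPOINTS <- c(0L, 15L, 60L)

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the previous RNG state so that
#' package functions are deterministic given their `seed` argument without
#' disturbing the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Median of a numeric vector without method dispatch overhead; NAs removed.
fast_median <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  h <- n %/% 2L
  s <- sort.int(v, method = "quick")
  if (n %% 2L == 1L) s[h + 1L] else (s[h] + s[h + 1L]) / 2
}

# Column-wise medians of mat within row groups. Returns matrix
# (one row per group level) with rownames = group levels.
grouped_col_medians <- function(mat, groups) {
  idx <- split(seq_len(nrow(mat)), groups)
  out <- matrix(NA_real_, nrow = length(idx), ncol = ncol(mat),
                dimnames = list(names(idx), colnames(mat)))
  for (i in seq_along(idx)) {
    sub <- mat[idx[[i]], , drop = FALSE]
    out[i, ] <- if (nrow(sub) == 1L) sub[1L, ]
                else apply(sub, 2L, fast_median)
  }
  out
}

# Sample column name used throughout: set:donor:fraction:timepoint
sample_name <- function(set_id, donor, fraction, timepoint) {
  paste(set_id, donor, fraction, timepoint, sep = ":")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a tab-separated table
#' @param path file path
#' @param required character vector of column names that must be present
#' @return data.frame
#' @noRd
read_tsv_checked <- function(path, required = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(x))
    if (length(miss))
      stopf("file '%s' is missing required column(s): %s",
            path, paste(miss, collapse = ", "))
  }
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
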