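#' Load a gene set from a text file
#'
#' Accepts either one symbol per line or a two-column TSV (first column
#' taken as the symbol). Symbols are upper-cased and deduplicated.
#'
#' @param path file path.
#' @param name set name (defaults to the file name).
#' @return object of class `gene_set`: list(name, genes).
#' @export
read_gene_set <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  symbols <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  gene_set(symbols, name)
}

#' Construct a gene set
#' @param genes character vector of gene symbols.
#' @param name set name.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(genes, name = "set") {
  structure(list(name = name,
                 genes = sort(unique(toupper(trimws(as.character(genes)))))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " symbols\n", sep = "")
  invisible(x)
}

#' Genes regulated beyond a relative-change threshold
#'
#' Selects genes whose relative change is strictly greater than the
#' threshold (e.g. 0.25 for "regulated over 25%"). Changes may be given
#' directly as proportions (`|change|`) or as fold changes, in which case
#' `|fold change - 1|` is used.
#'
#' @param changes named numeric vector (names = gene symbols).
#' @param threshold strict lower bound on relative change (>= 0).
#' @param is_fold_change if TRUE, `changes` are fold changes and the
#'   relative change is `|changes - 1|`.
#' @param name name for the resulting set.
#' @return a `gene_set` of regulated genes.
#' @export
filter_regulated <- function(changes, threshold, is_fold_change = FALSE,
                             name = "regulated") {
  if (threshold < 0) stopf("threshold must be >= 0")
  rel <- if (is_fold_change) abs(changes - 1) else abs(changes)
  gene_set(names(changes)[rel > threshold], name)
}

#' Venn region counts for two or three gene sets
#'
#' Counts every intersection region; the regions partition the union of
#' the sets, so the counts sum to the union size. Invariant to input
#' ordering and to duplicated symbols within a set.
#'
#' @param ... two or three `gene_set` objects (or character vectors).
#' @return named list of region counts, e.g. `A_only`, `A_B`, `A_B_C`,
#'   with attribute `union_size`.
#' @export
venn_counts <- function(...) {
  sets <- lapply(list(...), function(s)
    if (inherits(s, "gene_set")) s$genes else sort(unique(toupper(s))))
  n <- length(sets)
  if (n < 2L || n > 3L) stopf("venn_counts takes 2 or 3 sets")
  labels <- LETTERS[seq_len(n)]
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- apply(membership, 1L, function(m)
    paste(labels[m], collapse = "_"))
  out <- list()
  # enumerate all non-empty label combinations in canonical order
  for (sz in seq_len(n)) {
    for (idx in utils::combn(n, sz, simplify = FALSE)) {
      key <- paste(labels[idx], collapse = "_")
      region <- if (sz == 1L) paste0(key, "_only") else key
      out[[region]] <- sum(patterns == key)
    }
  }
  attr(out, "union_size") <- length(universe)
  out
}
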