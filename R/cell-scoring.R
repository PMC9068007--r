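#' Rank expression values in descending order
#'
#' Converts one sample's expression values to descending ranks: the highest
#' value receives rank 1 and ties receive the average of the ranks they span.
#' Because downstream enrichment uses ranks only, any monotone per-sample
#' rescaling of expression (library-size factors, FPKM vs TPM) leaves scores
#' unchanged.
#'
#' @param x Numeric vector of finite, non-negative expression values.
#' @return Numeric vector of descending ranks (a permutation-with-ties of
#'   `1..length(x)`).
#' @examples
#' rank_transform(c(5, 1, 3))   # 1 3 2
#' rank_transform(c(2, 2, 1))   # 1.5 1.5 3
#' @export
rank_transform <- function(x) {
  if (length(x) == 0L) stop("expression vector is empty", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("expression values must be finite numbers", call. = FALSE)
  }
  if (any(x < 0)) stop("expression values must be non-negative", call. = FALSE)
  rank(-x, ties.method = "average")
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum statistic computed independently per sample. Genes
#' are walked from highest to lowest expression; an in-set gene increments the
#' running sum by its rank weight `(n - rank + 1)^alpha` normalised over the
#' in-set weights, an out-of-set gene decrements it by `1/(n - m)` where `m`
#' is the set size. The score is the mean of the running sum over all `n`
#' positions (the integrated statistic), so densely top-ranked sets score
#' high and bottom-ranked sets score negative.
#'
#' Tied ranks carry equal weights; among tied genes the walk proceeds in
#' original index order, a deterministic convention that matters only through
#' the (bounded) position term of the integral.
#'
#' @param ranks Descending ranks as produced by [rank_transform()].
#' @param gene_set Integer indices into `ranks` forming the gene set.
#' @param alpha Non-negative rank-weight exponent; `alpha = 0` weights all
#'   in-set genes equally.
#' @return A single finite enrichment score.
#' @export
enrichment_score <- function(ranks, gene_set, alpha = 0.25) {
  n <- length(ranks)
  if (length(gene_set) == 0L) stop("gene set is empty", call. = FALSE)
  gene_set <- as.integer(gene_set)
  bad <- gene_set < 1L | gene_set > n | is.na(gene_set)
  if (any(bad)) {
    stop("gene set indices outside the expression universe: ",
         paste(gene_set[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(gene_set)) stop("gene set indices must be unique", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  m <- length(gene_set)
  ord <- order(ranks)                      # walk order: best rank first, ties by index
  inset <- logical(n)
  inset[gene_set] <- TRUE
  inset <- inset[ord]
  w <- (n - ranks[ord] + 1)^alpha
  steps <- numeric(n)
  steps[inset] <- w[inset] / sum(w[inset])
  if (m < n) steps[!inset] <- -1 / (n - m)
  sum(cumsum(steps)) / n
}

#' Score cell-type contents across samples
#'
#' Applies [enrichment_score()] to every (cell type, sample) combination.
#' Each sample is ranked once and scored independently of all other samples,
#' so adding or removing samples never changes existing scores. Signature
#' genes absent from the expression matrix are dropped with a warning; a
#' signature left empty after dropping is an error.
#'
#' @param expr Numeric gene x sample matrix with unique rownames (gene ids)
#'   and colnames (sample ids); non-negative values.
#' @param signatures Named list of character vectors (cell type -> gene ids),
#'   e.g. from [read_gmt()].
#' @param alpha Rank-weight exponent passed to [enrichment_score()].
#' @return A cell type x sample numeric matrix of content scores, with
#'   attributes `method`, `alpha` and `dropped_genes` (per-type count of
#'   signature genes absent from `expr`).
#' @export
score_cell_contents <- function(expr, signatures, alpha = 0.25) {
  expr <- validate_expression(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes to rank", call. = FALSE)
  if (!is.list(signatures) || is.null(names(signatures)) ||
      any(!nzchar(names(signatures))) || anyDuplicated(names(signatures))) {
    stop("signatures must be a uniquely named list of gene vectors", call. = FALSE)
  }
  idx <- lapply(signatures, function(g) which(rownames(expr) %in% g))
  dropped <- vapply(signatures, length, 1L) - vapply(idx, length, 1L)
  empty <- names(idx)[vapply(idx, length, 1L) == 0L]
  if (length(empty)) {
    stop("signatures with no genes in the expression matrix: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (any(dropped > 0L)) {
    warning(sum(dropped), " signature gene(s) absent from the expression matrix ",
            "were dropped (", paste0(names(dropped)[dropped > 0L], ": ",
                                     dropped[dropped > 0L], collapse = ", "), ")",
            call. = FALSE)
  }
  out <- matrix(NA_real_, length(signatures), ncol(expr),
                dimnames = list(names(signatures), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank_transform(expr[, j])
    for (k in seq_along(idx)) out[k, j] <- enrichment_score(r, idx[[k]], alpha)
  }
  structure(out, method = "rank_running_sum", alpha = alpha,
            dropped_genes = dropped)
}

#' Aggregate cell contents into category totals
#'
#' Sums content scores per sample over cell types sharing a category tag
#' (innate / adaptive / stromal / other), mirroring stacked-composition views
#' of tumour immune microenvironments. Conservation holds by construction:
#' the category totals of a sample sum to the sample's total over all types.
#'
#' @param contents Cell type x sample matrix from [score_cell_contents()].
#' @param categories Named character vector mapping every rowname of
#'   `contents` to a category label.
#' @return Category x sample numeric matrix of totals.
#' @export
aggregate_categories <- function(contents, categories) {
  if (!is.matrix(contents)) stop("contents must be a matrix", call. = FALSE)
  missing_tag <- setdiff(rownames(contents), names(categories))
  if (length(missing_tag)) {
    stop("cell types without a category tag: ",
         paste(missing_tag, collapse = ", "), call. = FALSE)
  }
  tags <- categories[rownames(contents)]
  out <- rowsum(contents, group = tags, reorder = TRUE)
  as.matrix(out)
}

# Shared validation for gene x sample expression matrices.
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(expr) || any(!is.finite(expr))) stop("non-finite expression values", call. = FALSE)
  if (any(expr < 0)) stop("negative expression values", call. = FALSE)
  expr
}
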