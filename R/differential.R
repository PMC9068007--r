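#' Paired t-tests of cell content between matched tissues
#'
#' For every cell type, tests the per-pair content differences
#' `d_i = CA_i - CAP_i` (tumour minus matched para-cancerous) with a
#' one-sample t-test on `n_pairs - 1` degrees of freedom. Types whose
#' differences have zero variance are flagged degenerate with `NA`
#' statistics rather than dropped, so result tables stay complete.
#'
#' @param contents Cell type x sample matrix (e.g. from
#'   [score_cell_contents()]).
#' @param samples data.frame with `sample_id`, `pair_id` and `tissue`
#'   (CA = tumour, CAP = para-cancerous); every pair must contribute exactly
#'   one sample of each tissue.
#' @return data.frame with one row per cell type: `type`, `mean_diff`, `t`,
#'   `df`, `p`, `degenerate`.
#' @export
paired_t <- function(contents, samples) {
  if (!is.matrix(contents)) stop("contents must be a matrix", call. = FALSE)
  req <- c("sample_id", "pair_id", "tissue")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop("samples needs columns sample_id, pair_id, tissue", call. = FALSE)
  }
  if (!all(samples$tissue %in% c("CA", "CAP"))) {
    stop("tissue labels must be CA or CAP", call. = FALSE)
  }
  tab <- table(samples$pair_id, samples$tissue)
  bad <- rownames(tab)[tab[, "CA"] != 1L | tab[, "CAP"] != 1L]
  if (length(bad)) {
    stop("incomplete pair(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(samples$sample_id %in% colnames(contents))) {
    stop("samples absent from the content matrix", call. = FALSE)
  }
  pairs <- sort(unique(samples$pair_id))
  if (length(pairs) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  ca <- samples$sample_id[samples$tissue == "CA"][
    match(pairs, samples$pair_id[samples$tissue == "CA"])]
  cap <- samples$sample_id[samples$tissue == "CAP"][
    match(pairs, samples$pair_id[samples$tissue == "CAP"])]
  d <- contents[, ca, drop = FALSE] - contents[, cap, drop = FALSE]
  n <- length(pairs)
  res <- lapply(rownames(contents), function(ty) {
    di <- d[ty, ]
    if (stats::sd(di) == 0) {
      return(data.frame(type = ty, mean_diff = mean(di), t = NA_real_,
                        df = n - 1L, p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(di)
    data.frame(type = ty, mean_diff = mean(di),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify cell types into up- and down-shifted sets
#'
#' Applies the strict uncorrected threshold `p < alpha` (the convention the
#' score construction uses) to paired t-test results: significant types with
#' positive mean difference are up, with negative mean difference down, and
#' everything else (including degenerate types) unclassified. A
#' Benjamini-Hochberg adjustment is available but off by default.
#'
#' @param results data.frame from [paired_t()].
#' @param alpha Two-sided significance threshold (default 0.05).
#' @param adjust "none" (default) or "BH" for false-discovery-rate adjusted
#'   p-values.
#' @return Object of class `iis_directions`: list with `up`, `down`
#'   (character vectors of type names) and `alpha`.
#' @export
classify_directions <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data.frame from paired_t()", call. = FALSE)
  }
  p <- results$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p) & p < alpha
  structure(list(up = results$type[sig & results$mean_diff > 0],
                 down = results$type[sig & results$mean_diff < 0],
                 alpha = alpha),
            class = "iis_directions")
}

#' @export
print.iis_directions <- function(x, ...) {
  cat("Direction sets (p <", x$alpha, "):\n")
  cat("  up:  ", paste(x$up, collapse = ", "), "\n")
  cat("  down:", paste(x$down, collapse = ", "), "\n")
  invisible(x)
}

#' Concordance labels between two differential methods
#'
#' Labels each cell type of the primary differential analysis by how a
#' secondary method (for example a deconvolution-based estimate of the same
#' cohort) agrees with it: the secondary's own direction when it is itself
#' significant with the sign the primary found, "Same trend" when the
#' secondary is non-significant but its mean difference has the primary's
#' sign, "Not significant" otherwise, and "Unavailable" when the secondary
#' does not report the type at all.
#'
#' @param primary data.frame from [paired_t()] (every queried type present).
#' @param secondary data.frame with at least `type`, `mean_diff`, `p`; types
#'   may be missing.
#' @param alpha Significance threshold applied to both methods.
#' @return data.frame: `type`, `primary` (Up-/Down-regulation or Not
#'   significant), `secondary` (concordance label).
#' @export
concordance_labels <- function(primary, secondary, alpha = 0.05) {
  lab_primary <- function(md, p) {
    if (is.na(p) || p >= alpha) "Not significant"
    else if (md > 0) "Up-regulation" else "Down-regulation"
  }
  out <- data.frame(type = primary$type,
                    primary = mapply(lab_primary, primary$mean_diff, primary$p),
                    stringsAsFactors = FALSE)
  out$secondary <- vapply(seq_len(nrow(primary)), function(i) {
    ty <- primary$type[i]
    j <- match(ty, secondary$type)
    if (is.na(j) || is.na(secondary$p[j])) return("Unavailable")
    same_sign <- sign(secondary$mean_diff[j]) == sign(primary$mean_diff[i])
    if (secondary$p[j] < alpha && same_sign) {
      if (secondary$mean_diff[j] > 0) "Up-regulation" else "Down-regulation"
    } else if (secondary$p[j] >= alpha && same_sign) {
      "Same trend"
    } else {
      "Not significant"
    }
  }, character(1))
  out
}
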