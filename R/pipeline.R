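#' Run the full immune infiltration score pipeline
#'
#' Convenience wrapper chaining the stages: score cell contents from
#' expression, identify up/down-shifted cell types by paired t-tests,
#' z-normalise against the reference statistics, build the X1/X2 indicators,
#' fit the linear decision boundary on the tissue labels, and score and
#' stratify every sample at cutoff 0.
#'
#' @param x Either an `iis_cohort` from [generate_cohort()], or a gene x
#'   sample expression matrix (then `samples`, `signatures` and
#'   `reference_stats` are required).
#' @param samples Sample metadata (sample_id, pair_id, tissue) when `x` is a
#'   matrix.
#' @param signatures Named list of signature gene vectors.
#' @param reference_stats data.frame (type, mean, sd) for z-normalisation.
#' @param alpha Enrichment rank-weight exponent.
#' @param alpha_sig Two-sided significance threshold for direction calls.
#' @param method Boundary fit: "max_margin" or "logistic".
#' @param C SVM soft-margin cost.
#' @return List of class `iis_analysis`: `contents`, `differential`, `dirs`,
#'   `zcontents`, `indicators`, `model`, `scores`.
#' @export
iis_analysis <- function(x, samples = NULL, signatures = NULL,
                         reference_stats = NULL, alpha = 0.25,
                         alpha_sig = 0.05,
                         method = c("max_margin", "logistic"), C = 1.0) {
  method <- match.arg(method)
  if (inherits(x, "iis_cohort")) {
    samples <- x$samples
    signatures <- x$signatures
    reference_stats <- x$reference_stats
    alpha <- x$config$alpha
    expr <- x$expression
  } else {
    expr <- x
    if (is.null(samples) || is.null(signatures) || is.null(reference_stats)) {
      stop("samples, signatures and reference_stats are required", call. = FALSE)
    }
  }
  contents <- score_cell_contents(expr, signatures, alpha = alpha)
  differential <- paired_t(contents, samples)
  dirs <- classify_directions(differential, alpha = alpha_sig)
  if (length(dirs$up) == 0L && length(dirs$down) == 0L) {
    stop("no cell type reached significance; cannot build indicators",
         call. = FALSE)
  }
  # reference statistics are only needed for the types entering X1/X2
  used <- union(dirs$up, dirs$down)
  zc <- z_normalize(contents[used, , drop = FALSE], reference_stats)
  ind <- compute_indicators(zc, dirs, samples = samples)
  model <- fit_boundary(ind, method = method, C = C)
  scores <- score_iis(model, ind)
  structure(list(contents = contents, differential = differential,
                 dirs = dirs, zcontents = zc, indicators = ind,
                 model = model, scores = scores),
            class = "iis_analysis")
}

#' @export
print.iis_analysis <- function(x, ...) {
  cat("IIS analysis of", nrow(x$indicators), "samples,",
      nrow(x$contents), "cell types\n")
  print(x$dirs)
  print(x$model)
  ca <- x$scores$score[x$indicators$label == "CA"]
  cap <- x$scores$score[x$indicators$label == "CAP"]
  if (length(ca) && length(cap)) {
    cat(sprintf("  mean IIS: tumour %.3f, para-cancerous %.3f\n",
                mean(ca), mean(cap)))
  }
  cat(" ", sum(x$scores$status == "positive"), "of", nrow(x$scores),
      "samples infiltration-positive at cutoff 0\n")
  invisible(x)
}
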