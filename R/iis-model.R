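#' Z-normalise cell contents against reference statistics
#'
#' Standardises each cell type's content scores with the mean and standard
#' deviation of an external reference cohort: `z = (x - mean) / sd`. Location
#' and scale always come from the reference, never from the analysed cohort,
#' so scores from different cohorts stay comparable.
#'
#' @param contents Cell type x sample matrix.
#' @param ref data.frame with columns `type`, `mean`, `sd` (one row per cell
#'   type; `sd > 0`).
#' @return Matrix of the same shape on the z scale.
#' @export
z_normalize <- function(contents, ref) {
  if (!is.matrix(contents)) stop("contents must be a matrix", call. = FALSE)
  if (!is.data.frame(ref) || !all(c("type", "mean", "sd") %in% names(ref))) {
    stop("ref needs columns type, mean, sd", call. = FALSE)
  }
  j <- match(rownames(contents), ref$type)
  if (anyNA(j)) {
    stop("no reference statistics for type(s): ",
         paste(rownames(contents)[is.na(j)], collapse = ", "), call. = FALSE)
  }
  bad_sd <- ref$sd[j] <= 0 | !is.finite(ref$sd[j])
  if (any(bad_sd)) {
    stop("non-positive reference sd for type(s): ",
         paste(rownames(contents)[bad_sd], collapse = ", "), call. = FALSE)
  }
  (contents - ref$mean[j]) / ref$sd[j]
}

#' Build the X1/X2 infiltration indicators
#'
#' `X1` is the per-sample sum of z-normalised content over the up-shifted
#' cell types and `X2` the sum over the down-shifted types; together they
#' summarise how much a sample's infiltration has moved in each planted
#' direction. Types outside the two sets never influence the indicators.
#'
#' @param zcontents Cell type x sample matrix on the z scale
#'   (from [z_normalize()]).
#' @param dirs An `iis_directions` object (or list with `up`, `down`).
#' @param samples Optional sample metadata; when given, a `label` column
#'   (the tissue) is attached for boundary fitting.
#' @return data.frame: `sample_id`, `X1`, `X2` and optionally `label`.
#' @export
compute_indicators <- function(zcontents, dirs, samples = NULL) {
  if (!is.matrix(zcontents)) stop("zcontents must be a matrix", call. = FALSE)
  missing_types <- setdiff(c(dirs$up, dirs$down), rownames(zcontents))
  if (length(missing_types)) {
    stop("direction-set type(s) absent from the matrix: ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  sum_over <- function(types) {
    if (length(types) == 0L) return(numeric(ncol(zcontents)))
    colSums(zcontents[types, , drop = FALSE])
  }
  out <- data.frame(sample_id = colnames(zcontents),
                    X1 = unname(sum_over(dirs$up)),
                    X2 = unname(sum_over(dirs$down)),
                    stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    out$label <- samples$tissue[match(out$sample_id, samples$sample_id)]
  }
  out
}

#' The published immune infiltration score model
#'
#' The linear model `IIS = 1.706596 * X1 - X2 - 9.680123` with the decision
#' cutoff at 0, in canonical form (X2 coefficient exactly -1).
#'
#' @return An immutable `iis_model` object with `a = 1.706596`, `b = 1`,
#'   `c = -9.680123`.
#' @export
iis_published_model <- function() {
  structure(list(a = 1.706596, b = 1, c = -9.680123, method = "published",
                 positive_class = "CA"),
            class = "iis_model")
}

#' @export
print.iis_model <- function(x, ...) {
  cat(sprintf("IIS model (%s): score = %.6f * X1 - %s * X2 %+.6f\n",
              x$method, x$a, format(x$b), x$c))
  invisible(x)
}

#' Fit a linear decision boundary on the indicators
#'
#' Finds the linear function of (X1, X2) that best separates tumour from
#' para-cancerous samples, either by a soft-margin linear support vector
#' machine (hinge loss, L2 penalty, cost `C`) or by maximum-likelihood
#' logistic regression. The fitted hyperplane `w1*X1 + w2*X2 + w0` is
#' oriented so tumour samples fall on the positive side and then
#' canonicalised by dividing through `|w2|`, so the reported model has the
#' published form `a*X1 - X2 + c` (X2 coefficient exactly -1 when, as
#' expected, `w2 < 0`). Positive rescaling never changes which side of the
#' boundary a sample is on.
#'
#' @param indicators data.frame from [compute_indicators()] with a `label`
#'   column; both classes must have at least 2 samples.
#' @param method "max_margin" (linear SVM) or "logistic".
#' @param C Soft-margin cost for the SVM (default 1).
#' @param positive_class Label of the tumour class (default "CA").
#' @return An `iis_model` object (fields `a`, `b`, `c`, `method`).
#' @export
fit_boundary <- function(indicators, method = c("max_margin", "logistic"),
                         C = 1.0, positive_class = "CA") {
  method <- match.arg(method)
  need <- c("X1", "X2", "label")
  if (!is.data.frame(indicators) || !all(need %in% names(indicators))) {
    stop("indicators needs columns X1, X2, label", call. = FALSE)
  }
  y <- indicators$label == positive_class
  if (length(unique(indicators$label)) < 2L || sum(y) < 2L || sum(!y) < 2L) {
    stop("need at least 2 samples in each class", call. = FALSE)
  }
  X <- as.matrix(indicators[, c("X1", "X2")])
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite indicators", call. = FALSE)
  if (method == "max_margin") {
    fit <- e1071::svm(X, factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg")),
                      kernel = "linear", cost = C, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    w0 <- -fit$rho
  } else {
    fit <- suppressWarnings(stats::glm(y ~ X1 + X2, family = stats::binomial(),
                                       data = indicators))
    w <- stats::coef(fit)[c("X1", "X2")]
    w0 <- stats::coef(fit)[["(Intercept)"]]
  }
  dec <- drop(X %*% w) + w0
  if (mean(dec[y]) < mean(dec[!y])) {  # orient tumour to the positive side
    w <- -w; w0 <- -w0
  }
  canonicalize_boundary(w[1], w[2], w0, method = method, C = C,
                        positive_class = positive_class)
}

# Divide a hyperplane through |w2| so the model reads a*X1 - b*X2 + c with
# b = 1 in the expected geometry (w2 < 0).
canonicalize_boundary <- function(w1, w2, w0, method, C = NA_real_,
                                  positive_class = "CA") {
  if (!is.finite(w2) || abs(w2) < 1e-12) {
    stop("cannot canonicalize: X2 coefficient is ", format(w2),
         " (|w2| < 1e-12); the boundary does not use X2", call. = FALSE)
  }
  structure(list(a = unname(w1 / abs(w2)), b = unname(-sign(w2)),
                 c = unname(w0 / abs(w2)),
                 method = method, C = C, positive_class = positive_class),
            class = "iis_model")
}

#' Score samples with an IIS model and stratify at cutoff 0
#'
#' Evaluates `score = a*X1 - b*X2 + c` per sample and labels samples with
#' score strictly greater than 0 as infiltration-positive; a score of
#' exactly 0 is negative (0 is not "higher than" the cutoff).
#'
#' @param model An `iis_model` (fitted or [iis_published_model()]).
#' @param indicators data.frame with `X1`, `X2` and optionally `sample_id`.
#' @return data.frame of class `iis_scores`: `sample_id`, `X1`, `X2`,
#'   `score`, `status`.
#' @export
score_iis <- function(model, indicators) {
  if (!inherits(model, "iis_model")) stop("model must be an iis_model", call. = FALSE)
  if (!all(c("X1", "X2") %in% names(indicators))) {
    stop("indicators needs columns X1 and X2", call. = FALSE)
  }
  ids <- if ("sample_id" %in% names(indicators)) indicators$sample_id
         else sprintf("S%03d", seq_len(nrow(indicators)))
  bad <- !is.finite(indicators$X1) | !is.finite(indicators$X2)
  if (any(bad)) {
    stop("non-finite indicators for sample(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  score <- model$a * indicators$X1 - model$b * indicators$X2 + model$c
  out <- data.frame(sample_id = ids, X1 = indicators$X1, X2 = indicators$X2,
                    score = score,
                    status = ifelse(score > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  class(out) <- c("iis_scores", "data.frame")
  out
}

#' Pearson correlation between two score vectors
#'
#' Used to compare the scores produced by two boundary-fitting methods on
#' the same samples (e.g. max-margin vs logistic).
#'
#' @param scores_a,scores_b `iis_scores` data.frames (or numeric vectors)
#'   over the same samples, length >= 3, non-constant.
#' @return Pearson correlation coefficient.
#' @export
model_correlation <- function(scores_a, scores_b) {
  pull <- function(s) if (is.data.frame(s)) s$score else as.numeric(s)
  a <- pull(scores_a); b <- pull(scores_b)
  if (length(a) != length(b)) stop("score vectors differ in length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant score vector", call. = FALSE)
  }
  stats::cor(a, b)
}
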