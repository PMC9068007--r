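#' Default cell-type layout for synthetic cohorts
#'
#' Four cell types planted as up-shifted in tumour tissue, four as
#' down-shifted and four as unchanged, with immune-category tags. The names
#' follow the cell populations commonly reported in breast-tumour
#' immune-microenvironment studies; the generator treats them as opaque
#' labels.
#'
#' @return A data.frame with columns `name`, `direction` (up/down/null) and
#'   `category` (innate/adaptive/stromal).
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("CD8+ Tcm", "Th1 cells", "aDC", "Macrophages",
             "cDC", "Neutrophils", "CD4+ Tcm", "Mast cells",
             "B cells", "NK cells", "Tregs", "Endothelial cells"),
    direction = c(rep("up", 4), rep("down", 4), rep("null", 4)),
    category = c("adaptive", "adaptive", "innate", "innate",
                 "innate", "innate", "adaptive", "innate",
                 "adaptive", "innate", "adaptive", "stromal"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for synthetic paired cohorts
#'
#' Collects and validates every knob of the generator. Defaults emulate the
#' study design the score construction assumes: 30 tumour/para-cancerous
#' pairs, 4 up- and 4 down-shifted cell types (plus 4 unchanged), shifts of
#' 1.5 reference standard deviations on the content scale, and outcomes with
#' a threefold hazard in score-positive samples.
#'
#' @param n_pairs Number of tumour/para-cancerous pairs (>= 3).
#' @param cell_types data.frame with columns `name`, `direction` in
#'   \{up, down, null\} and `category`; names must be unique.
#' @param effect_size Tumour shift for tagged types, in units of the
#'   reference standard deviation of the true content (>= 0).
#' @param genes_per_signature Genes in each cell type's signature block.
#' @param n_background_genes Genes outside every signature.
#' @param noise_sd Log-scale multiplicative expression noise.
#' @param hazard_ratio Event-hazard ratio, score-positive vs negative (> 0).
#' @param censor_rate Fraction administratively censored in [0, 1).
#' @param marker_shift Mean shift of the checkpoint-marker value in
#'   score-positive samples (standard-deviation units).
#' @param alpha Rank-weight exponent used when scoring (also used for the
#'   internal reference cohort so reference statistics match the score scale).
#' @param n_reference Size of the internal unshifted reference cohort from
#'   which per-type reference means and sds are estimated.
#' @param seed Integer seed; the same seed reproduces the cohort bit for bit.
#' @return A validated list of class `iis_config`.
#' @export
synthetic_config <- function(n_pairs = 30,
                             cell_types = default_cell_types(),
                             effect_size = 1.5,
                             genes_per_signature = 25,
                             n_background_genes = 1500,
                             noise_sd = 0.3,
                             hazard_ratio = 3.0,
                             censor_rate = 0.3,
                             marker_shift = 1.0,
                             alpha = 0.25,
                             n_reference = 60,
                             seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid configuration field '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(n_pairs) && length(n_pairs) == 1L && n_pairs == round(n_pairs) &&
        n_pairs >= 3, "n_pairs", "must be an integer >= 3")
  chk(is.data.frame(cell_types) &&
        all(c("name", "direction", "category") %in% names(cell_types)) &&
        nrow(cell_types) >= 1L, "cell_types",
      "must be a data.frame with name/direction/category columns")
  chk(!anyDuplicated(cell_types$name), "cell_types", "cell-type names must be unique")
  chk(all(cell_types$direction %in% c("up", "down", "null")), "cell_types",
      "direction must be up, down or null")
  chk(is.numeric(effect_size) && length(effect_size) == 1L && effect_size >= 0,
      "effect_size", "must be >= 0")
  chk(is.numeric(genes_per_signature) && genes_per_signature >= 2,
      "genes_per_signature", "must be >= 2")
  chk(is.numeric(n_background_genes) && n_background_genes >= 0,
      "n_background_genes", "must be >= 0")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.numeric(hazard_ratio) && hazard_ratio > 0, "hazard_ratio", "must be > 0")
  chk(is.numeric(censor_rate) && censor_rate >= 0 && censor_rate < 1,
      "censor_rate", "must be in [0, 1)")
  chk(is.numeric(marker_shift) && length(marker_shift) == 1L, "marker_shift",
      "must be a single number")
  chk(is.numeric(alpha) && alpha >= 0, "alpha", "must be >= 0")
  chk(is.numeric(n_reference) && n_reference >= 10, "n_reference", "must be >= 10")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed), "seed",
      "must be a single integer")
  structure(list(
    n_pairs = as.integer(n_pairs), cell_types = cell_types,
    effect_size = effect_size,
    genes_per_signature = as.integer(genes_per_signature),
    n_background_genes = as.integer(n_background_genes),
    noise_sd = noise_sd, hazard_ratio = hazard_ratio,
    censor_rate = censor_rate, marker_shift = marker_shift,
    alpha = alpha, n_reference = as.integer(n_reference),
    seed = as.integer(seed)
  ), class = "iis_config")
}

# Run code with a private RNG stream: seeds locally, restores global state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Log-normal parameters of the true per-type content baseline. The total
# log-scale sd 0.25 (content CV ~25%) splits into a shared patient (pair)
# effect and a tissue-level residual, so matched samples are positively
# correlated as in real paired designs. Keeping the CV moderate also keeps
# the planted +/- shifts nearly symmetric on the log scale, which limits the
# rank-compositional drift that content changes induce in unshifted types.
.content_meanlog <- 0
.content_sdlog_pair <- 0.14
.content_sdlog_resid <- sqrt(0.25^2 - 0.14^2)

# Analytic mean/sd of the baseline log-normal content distribution; the
# "reference sd" in which planted effect sizes are expressed.
true_content_moments <- function() {
  s2 <- .content_sdlog_pair^2 + .content_sdlog_resid^2
  m <- exp(.content_meanlog + s2 / 2)
  list(mean = m, sd = m * sqrt(exp(s2) - 1))
}

# Signature gene ids for one cell type: "<sanitised type>_g01" ...
signature_gene_ids <- function(type, k) {
  sprintf("%s_g%02d", gsub("[^A-Za-z0-9]+", ".", type), seq_len(k))
}

# Build the named signature list implied by a config.
config_signatures <- function(config) {
  sigs <- lapply(config$cell_types$name, signature_gene_ids,
                 k = config$genes_per_signature)
  names(sigs) <- config$cell_types$name
  sigs
}

# Synthesise an expression matrix from true content weights: signature genes
# scale with their type's content, background genes do not; everything gets
# per-gene base abundance and multiplicative log-normal noise.
synthesize_expression <- function(weights, config, base_abund) {
  sigs <- config_signatures(config)
  genes <- c(unlist(sigs, use.names = FALSE),
             if (config$n_background_genes > 0)
               sprintf("bg_g%04d", seq_len(config$n_background_genes)))
  n_samp <- ncol(weights)
  expr <- matrix(0, length(genes), n_samp, dimnames = list(genes, colnames(weights)))
  row0 <- 0L
  for (t in seq_along(sigs)) {
    k <- length(sigs[[t]])
    rows <- row0 + seq_len(k)
    expr[rows, ] <- outer(base_abund[rows], weights[t, ])
    row0 <- row0 + k
  }
  if (config$n_background_genes > 0) {
    rows <- row0 + seq_len(config$n_background_genes)
    expr[rows, ] <- base_abund[rows]
  }
  expr * exp(matrix(stats::rnorm(length(expr), 0, config$noise_sd), nrow(expr)))
}

#' Generate a synthetic paired tumour/para-cancerous cohort
#'
#' Draws per-sample true cell-type contents from a log-normal baseline with a
#' shared patient effect, shifts tumour-sample contents of tagged types by
#' `effect_size` reference sds (up or down per tag, floored at a small
#' positive value), and synthesises expression as signature-gene blocks
#' scaled by content plus multiplicative noise. Reference statistics for
#' z-normalisation are estimated on the content-score scale from an internal
#' unshifted reference cohort scored with the same signatures and `alpha`.
#' Outcomes for tumour samples are attached using a latent infiltration
#' median split (see [generate_outcomes()] for outcome generation from any
#' stratification).
#'
#' The same `config` (including its seed) reproduces the cohort exactly; the
#' caller's RNG state is left untouched.
#'
#' @param config An [synthetic_config()] object.
#' @return An object of class `iis_cohort`: list with `expression` (gene x
#'   sample matrix), `samples` (sample_id, pair_id, tissue CA/CAP),
#'   `signatures`, `categories`, `true_contents`, `reference_stats`
#'   (data.frame type/mean/sd on the score scale), `truth` (planted
#'   directions), `outcomes` and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "iis_config")) {
    stop("config must come from synthetic_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    ct <- config$cell_types
    n_types <- nrow(ct)
    n <- config$n_pairs
    mom <- true_content_moments()
    pair_id <- sprintf("P%02d", seq_len(n))
    sample_id <- c(paste0(pair_id, "_CA"), paste0(pair_id, "_CAP"))
    tissue <- rep(c("CA", "CAP"), each = n)
    samples <- data.frame(sample_id = sample_id,
                          pair_id = rep(pair_id, 2),
                          tissue = tissue, stringsAsFactors = FALSE)

    # true contents: pair effect shared by CA and CAP of a patient
    b_pair <- matrix(stats::rnorm(n_types * n, 0, .content_sdlog_pair), n_types, n)
    resid <- matrix(stats::rnorm(n_types * 2 * n, 0, .content_sdlog_resid),
                    n_types, 2 * n)
    w <- exp(.content_meanlog + cbind(b_pair, b_pair) + resid)
    dimnames(w) <- list(ct$name, sample_id)
    shift <- ifelse(ct$direction == "up", 1, ifelse(ct$direction == "down", -1, 0)) *
      config$effect_size * mom$sd
    w[, tissue == "CA"] <- pmax(w[, tissue == "CA"] + shift, 0.01)

    n_sig_genes <- n_types * config$genes_per_signature
    base_abund <- exp(stats::rnorm(n_sig_genes + config$n_background_genes,
                                   log(10), 1))
    expr <- synthesize_expression(w, config, base_abund)

    # unshifted reference cohort on the same gene universe -> score-scale stats
    n_ref <- config$n_reference
    w_ref <- exp(.content_meanlog +
                   matrix(stats::rnorm(n_types * n_ref,
                                       0, sqrt(.content_sdlog_pair^2 +
                                                 .content_sdlog_resid^2)),
                          n_types, n_ref,
                          dimnames = list(ct$name, sprintf("REF%03d", seq_len(n_ref)))))
    expr_ref <- synthesize_expression(w_ref, config, base_abund)
    sigs <- config_signatures(config)
    ref_scores <- score_cell_contents(expr_ref, sigs, alpha = config$alpha)
    reference_stats <- data.frame(
      type = rownames(ref_scores),
      mean = rowMeans(ref_scores),
      sd = apply(ref_scores, 1, stats::sd),
      stringsAsFactors = FALSE, row.names = NULL
    )

    # latent infiltration contrast of tumour samples -> default outcome strata
    z_true <- (w - mom$mean) / mom$sd
    up <- ct$name[ct$direction == "up"]; down <- ct$name[ct$direction == "down"]
    contrast <- colSums(z_true[up, tissue == "CA", drop = FALSE]) -
      colSums(z_true[down, tissue == "CA", drop = FALSE])
    status <- ifelse(contrast > stats::median(contrast), "positive", "negative")
    names(status) <- sample_id[tissue == "CA"]
    outcomes <- generate_outcomes(status, config, seed = config$seed + 1L)

    categories <- stats::setNames(ct$category, ct$name)
    structure(list(expression = expr, samples = samples, signatures = sigs,
                   categories = categories, true_contents = w,
                   reference_stats = reference_stats,
                   truth = data.frame(type = ct$name, direction = ct$direction,
                                      stringsAsFactors = FALSE),
                   outcomes = outcomes, config = config),
              class = "iis_cohort")
  })
}

#' @export
print.iis_cohort <- function(x, ...) {
  cat("Synthetic paired cohort:", x$config$n_pairs, "pairs,",
      nrow(x$expression), "genes,", nrow(x$true_contents), "cell types\n")
  cat("  planted:", sum(x$truth$direction == "up"), "up,",
      sum(x$truth$direction == "down"), "down,",
      sum(x$truth$direction == "null"), "null\n")
  invisible(x)
}

#' Generate survival and marker outcomes for stratified samples
#'
#' Event times are exponential with baseline hazard `log(2) / 36` (median 36
#' time units in the negative stratum) multiplied by `hazard_ratio` for
#' positive-stratum samples. Censoring is administrative: uniform on
#' `(0, tau)` with `tau` solved so that the negative-stratum marginal censor
#' fraction equals `censor_rate`, independent of stratum. The marker value
#' (a normalised checkpoint-marker expression analogue) is standard normal
#' with mean `marker_shift` in the positive stratum.
#'
#' @param statuses Named character vector of "positive"/"negative" per sample
#'   (names are sample ids), or a logical vector (TRUE = positive).
#' @param config An [synthetic_config()] object (hazard_ratio, censor_rate,
#'   marker_shift are read from it).
#' @param seed Integer seed for the outcome draws.
#' @return data.frame: sample_id, time, event (1 = observed), stratum, marker.
#' @export
generate_outcomes <- function(statuses, config, seed = config$seed) {
  if (length(statuses) == 0L) stop("empty status vector", call. = FALSE)
  if (is.logical(statuses)) {
    statuses <- stats::setNames(ifelse(statuses, "positive", "negative"),
                                names(statuses))
  }
  if (!all(statuses %in% c("positive", "negative"))) {
    stop("statuses must be 'positive' or 'negative'", call. = FALSE)
  }
  if (is.null(names(statuses))) {
    names(statuses) <- sprintf("S%03d", seq_along(statuses))
  }
  with_seed(seed, {
    h0 <- log(2) / 36
    rate <- h0 * ifelse(statuses == "positive", config$hazard_ratio, 1)
    t_event <- stats::rexp(length(statuses), rate)
    if (config$censor_rate > 0) {
      tau <- stats::uniroot(
        function(tau) (1 - exp(-h0 * tau)) / (h0 * tau) - config$censor_rate,
        interval = c(1e-8, 1e8), tol = 1e-10
      )$root
      t_cens <- stats::runif(length(statuses), 0, tau)
    } else {
      t_cens <- rep(Inf, length(statuses))
    }
    data.frame(
      sample_id = names(statuses),
      time = pmax(pmin(t_event, t_cens), 1e-8),
      event = as.integer(t_event <= t_cens),
      stratum = unname(statuses),
      marker = stats::rnorm(length(statuses),
                            config$marker_shift * (statuses == "positive"), 1),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}
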