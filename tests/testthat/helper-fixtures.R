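# Small, fast synthetic configurations for unit tests; the acceptance tests
# use the full default scale.

small_config <- function(seed = 1, n_pairs = 8, ...) {
  synthetic_config(n_pairs = n_pairs, genes_per_signature = 8,
                   n_background_genes = 200, n_reference = 25,
                   seed = seed, ...)
}

# Literal per-position running-sum oracle for the enrichment statistic,
# kept deliberately naive and independent of the package implementation.
oracle_enrichment <- function(ranks, gene_set, alpha) {
  n <- length(ranks)
  m <- length(gene_set)
  inset <- seq_len(n) %in% gene_set
  walk <- order(ranks)  # best rank first, ties broken by original index
  wsum <- 0
  for (g in gene_set) wsum <- wsum + (n - ranks[g] + 1)^alpha
  running <- 0
  total <- 0
  for (pos in walk) {
    if (inset[pos]) {
      running <- running + (n - ranks[pos] + 1)^alpha / wsum
    } else {
      running <- running - 1 / (n - m)
    }
    total <- total + running
  }
  total / n
}

# Memoised expensive objects shared across test files.
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

default_cohort_42 <- function() {
  cached("cohort42", generate_cohort(synthetic_config(seed = 42)))
}

# One full-scale sweep reused by the recovery and pipeline-analog acceptance
# tests: per seed, generate the default cohort, run the pipeline, stratify
# every sample with the fitted boundary, and generate outcomes from the
# strata.
acceptance_sweep <- function(n_seeds = 100) {
  cached("sweep", {
    res <- lapply(seq_len(n_seeds), function(s) {
      cohort <- generate_cohort(synthetic_config(seed = s))
      an <- iis_analysis(cohort)
      up <- cohort$truth$type[cohort$truth$direction == "up"]
      down <- cohort$truth$type[cohort$truth$direction == "down"]
      ca <- an$scores$score[an$indicators$label == "CA"]
      cap <- an$scores$score[an$indicators$label == "CAP"]
      status <- stats::setNames(an$scores$status, an$scores$sample_id)
      out <- generate_outcomes(status, cohort$config, seed = 10000 + s)
      pos <- out[out$stratum == "positive", ]
      neg <- out[out$stratum == "negative", ]
      med_pos <- km_median(km_curve(pos))
      med_neg <- km_median(km_curve(neg))
      rs <- rank_sum_compare(pos$marker, neg$marker)
      list(
        tags_recovered = all(up %in% an$dirs$up) && all(down %in% an$dirs$down),
        exact_calls = setequal(an$dirs$up, up) && setequal(an$dirs$down, down),
        iis_separates = mean(ca) > mean(cap),
        km_median_lower = !is.na(med_pos) && (is.na(med_neg) || med_pos < med_neg),
        marker_higher = rs$p < 0.05 && stats::median(pos$marker) > stats::median(neg$marker)
      )
    })
    pick <- function(field) vapply(res, function(r) isTRUE(r[[field]]), logical(1))
    data.frame(tags_recovered = pick("tags_recovered"),
               exact_calls = pick("exact_calls"),
               iis_separates = pick("iis_separates"),
               km_median_lower = pick("km_median_lower"),
               marker_higher = pick("marker_higher"))
  })
}
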