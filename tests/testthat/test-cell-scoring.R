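test_that("rank_transform gives descending average-tie ranks", {
  expect_equal(rank_transform(c(5, 1, 3)), c(1, 3, 2))
  expect_equal(rank_transform(c(2, 2, 1)), c(1.5, 1.5, 3))
  # permuting the input permutes the output identically
  x <- c(0.3, 7, 7, 2, 0, 11)
  perm <- c(4, 1, 6, 2, 3, 5)
  expect_equal(rank_transform(x[perm]), rank_transform(x)[perm])
  expect_error(rank_transform(numeric(0)), "empty")
  expect_error(rank_transform(c(1, -2)), "non-negative")
  expect_error(rank_transform(c(1, NA)), "finite")
})

test_that("enrichment_score matches the hand-enumerated 4-gene example", {
  # genes ranked [A,B,C,D], set {A}, alpha = 0: steps +1, -1/3, -1/3, -1/3
  # running sum 1, 2/3, 1/3, 0 -> integral 2 -> score 0.5
  ranks <- c(1, 2, 3, 4)
  expect_equal(enrichment_score(ranks, 1L, alpha = 0), 0.5)
  expect_equal(enrichment_score(ranks, 1L, alpha = 0),
               oracle_enrichment(ranks, 1L, 0))
})

test_that("enrichment_score equals the brute-force oracle on every subset", {
  set.seed(11)
  for (n in c(4, 6, 8, 10)) {
    x <- round(stats::runif(n, 0, 5), 1)  # rounding induces ties
    ranks <- rank_transform(x)
    subsets <- lapply(seq_len(2^n - 2), function(mask) which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
    subsets <- subsets[vapply(subsets, length, 1L) < n]
    for (alpha in c(0, 0.25, 1)) {
      got <- vapply(subsets, function(s) enrichment_score(ranks, s, alpha), numeric(1))
      want <- vapply(subsets, function(s) oracle_enrichment(ranks, s, alpha), numeric(1))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("the full gene universe attains the all-increment integral", {
  set.seed(2)
  x <- stats::rexp(7)
  ranks <- rank_transform(x)
  n <- length(ranks)
  alpha <- 0.25
  # all-increment integral, computed directly from sorted weights
  w <- (n - sort(ranks) + 1)^alpha
  expected <- sum(cumsum(w / sum(w))) / n
  full <- enrichment_score(ranks, seq_len(n), alpha)
  expect_equal(full, expected)
  # and no proper subset beats it for this ranking
  for (k in 1:20) {
    s <- sample(n, sample(n - 1, 1))
    expect_lte(enrichment_score(ranks, s, alpha), full)
  }
})

test_that("scores are rank-invariant and single-sample", {
  cohort <- generate_cohort(small_config(seed = 5))
  expr <- cohort$expression
  contents <- score_cell_contents(expr, cohort$signatures)
  expect_identical(dim(contents), c(length(cohort$signatures), ncol(expr)))
  expect_true(all(is.finite(contents)))
  # scale-free: multiplying one sample's expression leaves its scores alone
  expr2 <- expr
  expr2[, 3] <- expr2[, 3] * 17.5
  expect_equal(score_cell_contents(expr2, cohort$signatures), contents,
               ignore_attr = TRUE)
  # adding an unrelated sample leaves existing scores unchanged
  expr3 <- cbind(expr, extra = stats::rexp(nrow(expr)))
  contents3 <- score_cell_contents(expr3, cohort$signatures)
  expect_equal(contents3[, colnames(expr)], contents[, colnames(expr)],
               ignore_attr = TRUE)
  # identical expression implies identical scores
  expect_equal(contents3[, 1], score_cell_contents(expr3, cohort$signatures)[, 1])
})

test_that("planted tumour shifts surface with the planted sign in mean scores", {
  cohort <- generate_cohort(small_config(seed = 9, n_pairs = 12))
  contents <- score_cell_contents(cohort$expression, cohort$signatures)
  ca <- cohort$samples$sample_id[cohort$samples$tissue == "CA"]
  cap <- cohort$samples$sample_id[cohort$samples$tissue == "CAP"]
  diff <- rowMeans(contents[, ca]) - rowMeans(contents[, cap])
  for (i in seq_len(nrow(cohort$truth))) {
    dir <- cohort$truth$direction[i]
    if (dir == "up") expect_gt(diff[cohort$truth$type[i]], 0)
    if (dir == "down") expect_lt(diff[cohort$truth$type[i]], 0)
  }
})

test_that("signature bookkeeping: dropped genes warn, empty overlap errors", {
  cohort <- generate_cohort(small_config(seed = 4))
  sigs <- cohort$signatures
  sigs[[1]] <- c(sigs[[1]], "not_a_gene_1", "not_a_gene_2")
  expect_warning(res <- score_cell_contents(cohort$expression, sigs),
                 "dropped")
  expect_equal(attr(res, "dropped_genes")[[1]], 2L)
  sigs_bad <- c(cohort$signatures, list(ghost = c("nope1", "nope2")))
  expect_error(score_cell_contents(cohort$expression, sigs_bad), "ghost")
  expect_error(enrichment_score(c(1, 2, 3), integer(0)), "empty")
  expect_error(enrichment_score(c(1, 2, 3), c(1L, 9L)), "9")
})

test_that("category totals are conserved and respect tags", {
  cohort <- generate_cohort(small_config(seed = 6))
  contents <- score_cell_contents(cohort$expression, cohort$signatures)
  totals <- aggregate_categories(contents, cohort$categories)
  expect_equal(colSums(totals), colSums(contents))
  # one type per category reduces to that type's scores
  single <- contents[1:2, , drop = FALSE]
  tags <- stats::setNames(c("innate", "adaptive"), rownames(single))
  tot2 <- aggregate_categories(single, tags)
  expect_equal(tot2["innate", ], contents[1, ])
  expect_equal(tot2["adaptive", ], contents[2, ])
  expect_error(aggregate_categories(contents, cohort$categories[-1]),
               rownames(contents)[1], fixed = TRUE)
})
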