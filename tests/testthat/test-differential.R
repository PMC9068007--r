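# closed-form one-sample t on differences, independent of stats::t.test
oracle_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

make_paired <- function(diffs, base = NULL, type = "T1") {
  n <- length(diffs)
  if (is.null(base)) base <- rep(0, n)
  contents <- matrix(c(base + diffs, base), nrow = 1,
                     dimnames = list(type, c(sprintf("P%02d_CA", 1:n),
                                             sprintf("P%02d_CAP", 1:n))))
  samples <- data.frame(sample_id = colnames(contents),
                        pair_id = rep(sprintf("P%02d", 1:n), 2),
                        tissue = rep(c("CA", "CAP"), each = n))
  list(contents = contents, samples = samples)
}

test_that("paired_t matches the closed-form t on the worked example", {
  px <- make_paired(c(1, 2, 3))
  res <- paired_t(px$contents, px$samples)
  expect_equal(res$t, 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  o <- oracle_t(c(1, 2, 3))
  expect_equal(res$t, o$t)
  expect_equal(res$p, o$p)
})

test_that("paired_t equals the closed form on 1000 random small instances", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(3:8, 1)
    d <- stats::rnorm(n, mean = stats::runif(1, -1, 1))
    base <- stats::rnorm(n)
    res <- paired_t(make_paired(d, base)$contents, make_paired(d, base)$samples)
    o <- oracle_t(d)
    expect_lt(abs(res$t - o$t), 1e-10)
    expect_lt(abs(res$p - o$p), 1e-10)
    expect_lt(abs(res$mean_diff - mean(d)), 1e-12)
  }
})

test_that("zero-variance differences are flagged degenerate, not p = 0", {
  px <- make_paired(c(0, 0, 0))
  res <- paired_t(px$contents, px$samples)
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  expect_true(is.na(res$t))
  expect_equal(res$df, 2)
})

test_that("swapping tissue labels negates t and preserves p", {
  px <- make_paired(c(0.4, -1.2, 2.2, 0.9))
  res <- paired_t(px$contents, px$samples)
  swapped <- px$samples
  swapped$tissue <- ifelse(swapped$tissue == "CA", "CAP", "CA")
  res_sw <- paired_t(px$contents, swapped)
  expect_equal(res_sw$t, -res$t)
  expect_equal(res_sw$p, res$p)
})

test_that("incomplete pairs are rejected by pair id", {
  px <- make_paired(c(1, 2, 3, 4))
  broken <- px$samples[-2, ]  # drop P02's tumour sample
  expect_error(paired_t(px$contents, broken), "P02")
})

test_that("direction classification applies a strict threshold", {
  res <- data.frame(type = c("A", "B", "C", "D"),
                    mean_diff = c(2, -1, 0.5, -0.2),
                    t = c(5, -4, 2, -1), df = 9,
                    p = c(0.001, 0.04, 0.06, 0.5), degenerate = FALSE)
  dirs <- classify_directions(res, alpha = 0.05)
  expect_setequal(dirs$up, "A")
  expect_setequal(dirs$down, "B")
  # p = 0.06 with positive difference is not significant
  expect_false("C" %in% c(dirs$up, dirs$down))
  # alpha = 0 empties both sets
  dirs0 <- classify_directions(res, alpha = 0)
  expect_length(dirs0$up, 0)
  expect_length(dirs0$down, 0)
  # p exactly alpha is not significant (strict inequality)
  expect_false("B" %in% classify_directions(res, alpha = 0.04)$down)
})

test_that("direction sets grow monotonically with alpha", {
  set.seed(8)
  res <- data.frame(type = paste0("T", 1:20),
                    mean_diff = stats::rnorm(20),
                    t = stats::rnorm(20), df = 9,
                    p = stats::runif(20), degenerate = FALSE)
  alphas <- sort(stats::runif(5))
  prev <- classify_directions(res, alpha = alphas[1])
  for (a in alphas[-1]) {
    cur <- classify_directions(res, alpha = a)
    expect_true(all(prev$up %in% cur$up))
    expect_true(all(prev$down %in% cur$down))
    prev <- cur
  }
  # BH adjustment can only shrink the called sets
  raw <- classify_directions(res, alpha = 0.2)
  bh <- classify_directions(res, alpha = 0.2, adjust = "BH")
  expect_true(all(bh$up %in% raw$up))
  expect_true(all(bh$down %in% raw$down))
})

test_that("concordance labelling reproduces the cross-method table", {
  types <- c("CD8+ Tcm", "Th1 cells", "aDC", "Macrophages",
             "cDC", "Neutrophils", "CD4+ Tcm", "Mast cells")
  primary <- data.frame(
    type = types,
    mean_diff = c(1, 1, 1, 1, -1, -1, -1, -1),
    p = rep(0.01, 8))
  # secondary method: significant concordant for CD8+ Tcm, Macrophages,
  # Mast cells; non-significant same-sign for cDC, Neutrophils;
  # non-significant opposite-sign for aDC; Th1 and CD4+ Tcm not reported
  secondary <- data.frame(
    type = c("CD8+ Tcm", "aDC", "Macrophages", "cDC", "Neutrophils", "Mast cells"),
    mean_diff = c(0.8, -0.1, 0.5, -0.4, -0.3, -0.7),
    p = c(0.01, 0.4, 0.02, 0.3, 0.2, 0.01))
  lab <- concordance_labels(primary, secondary)
  want <- c("Up-regulation", "Unavailable", "Not significant", "Up-regulation",
            "Same trend", "Same trend", "Unavailable", "Down-regulation")
  expect_equal(lab$secondary, want)
  expect_equal(lab$primary,
               c(rep("Up-regulation", 4), rep("Down-regulation", 4)))
})
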