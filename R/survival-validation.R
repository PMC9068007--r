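#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function from right-censored
#' follow-up records. `S(0) = 1` and the curve is a right-continuous step
#' function dropping only at observed event times; records censored at an
#' event time remain in the risk set for that time (the standard
#' convention).
#'
#' @param records data.frame with `time` (> 0) and `event` (1 = event
#'   observed, 0 = censored); an optional `sample_id` column is used in
#'   error messages.
#' @return data.frame of class `iis_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (one row per distinct observed time).
#' @export
km_curve <- function(records) {
  records <- validate_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("iis_km", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km An `iis_km` data.frame from [km_curve()].
#' @param times Times at which to read off `S(t)`; times before the first
#'   observed time give 1.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, times) {
  stats::stepfun(km$time, c(1, km$surv), right = FALSE)(times)
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Smallest observed time with `S(t) <= 0.5`, or `NA` if the curve never
#' reaches 0.5 (heavy censoring).
#'
#' @param km An `iis_km` data.frame from [km_curve()].
#' @return Median survival time (possibly `NA`).
#' @export
km_median <- function(km) {
  i <- which(km$surv <= 0.5)
  if (length(i) == 0L) return(NA_real_)
  km$time[min(i)]
}

#' Two-group log-rank test
#'
#' Compares survival between two groups by summing observed-minus-expected
#' events over the distinct event times; the statistic is referred to a
#' chi-square distribution with 1 degree of freedom. `weight = "wilcoxon"`
#' selects the Peto-Peto modification of the Gehan-Wilcoxon test, which
#' up-weights early event times.
#'
#' @param group_a,group_b data.frames with `time` and `event` columns.
#' @param weight "logrank" (default) or "wilcoxon".
#' @return List of class `iis_logrank`: `statistic`, `df`, `p`,
#'   `degenerate` (TRUE when no events occurred, in which case `p` is `NA`).
#' @export
logrank_test <- function(group_a, group_b, weight = c("logrank", "wilcoxon")) {
  weight <- match.arg(weight)
  if (NROW(group_a) == 0L || NROW(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  group_a <- validate_records(group_a)
  group_b <- validate_records(group_b)
  dat <- rbind(data.frame(time = group_a$time, event = group_a$event, g = "A"),
               data.frame(time = group_b$time, event = group_b$event, g = "B"))
  if (sum(dat$event) == 0L) {
    return(structure(list(statistic = NA_real_, df = 1L, p = NA_real_,
                          degenerate = TRUE, weight = weight),
                     class = "iis_logrank"))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat,
                            rho = if (weight == "wilcoxon") 1 else 0)
  structure(list(statistic = unname(fit$chisq), df = 1L,
                 p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
                 degenerate = FALSE, weight = weight),
            class = "iis_logrank")
}

#' @export
print.iis_logrank <- function(x, ...) {
  cat(sprintf("%s test: chi-square = %.4f (1 df), p = %.4f%s\n",
              if (x$weight == "wilcoxon") "Gehan-Wilcoxon (Peto-Peto)" else "Log-rank",
              x$statistic, x$p, if (x$degenerate) " [degenerate: no events]" else ""))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon test, used e.g. to compare marker
#' expression between score strata. The p-value is exact (by enumeration of
#' allocations) when the combined sample size is at most 20 and the data are
#' tie-free; otherwise the normal approximation with tie correction is used.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List: `statistic` (Mann-Whitney W for group A), `p` (two-sided),
#'   `exact` (whether the exact distribution was used).
#' @export
rank_sum_compare <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  use_exact <- n <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = use_exact,
                                            correct = !use_exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Association test for a 2x2 contingency table (for instance score stratum
#' by a clinical category) with 1 degree of freedom. Yates continuity
#' correction is off by default.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @param correct Apply the continuity correction (default FALSE).
#' @return List: `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

validate_records <- function(records) {
  if (!is.data.frame(records) || !all(c("time", "event") %in% names(records))) {
    stop("records need columns time and event", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  ids <- if ("sample_id" %in% names(records)) records$sample_id
         else as.character(seq_len(nrow(records)))
  bad <- !is.finite(records$time) | records$time <= 0
  if (any(bad)) {
    stop("non-positive follow-up time for record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 or 1", call. = FALSE)
  }
  records
}
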