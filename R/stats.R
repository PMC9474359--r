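# Two-sample statistics for cohort comparison: unpaired t tests from raw or
# summary data, Fisher's exact test, sample-size calculation and the combined
# comparison report.

#' Summary statistics of one group
#'
#' @param n group size (>= 2).
#' @param mean sample mean.
#' @param sd sample standard deviation (>= 0).
#' @return object of class `summary_stats`.
#' @export
summary_stats <- function(n, mean, sd) {
  stopifnot(n >= 2, is.finite(mean), sd >= 0)
  structure(list(n = as.integer(n), mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "summary_stats")
}

#' Summarise a sample
#' @param x numeric vector (length >= 2).
#' @return a [summary_stats()].
#' @export
summarise_sample <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 observations per group", call. = FALSE)
  summary_stats(length(x), mean(x), stats::sd(x))
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f%s, p %s\n", x$method, x$statistic,
              if (is.null(x$df) || !is.finite(x$df)) "" else
                sprintf(", df %.2f", x$df),
              format_p(x$p)))
  invisible(x)
}

#' Format a p value as in clinical tables
#'
#' Two significant figures with a display floor of "0.0001"; stored p values
#' keep full precision.
#'
#' @param p p value.
#' @return character scalar.
#' @export
format_p <- function(p) {
  if (p < 1e-4) "0.0001" else format(signif(p, 2), scientific = FALSE)
}

#' Two-tailed unpaired t test from summary statistics
#'
#' Student's pooled-variance version uses
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` with
#' `df = n1 + n2 - 2`; Welch's uses per-group variances with Satterthwaite
#' degrees of freedom. Degenerate inputs (both sds zero) follow the
#' convention p = 1 for equal means and p = 0 (with a warning) otherwise.
#'
#' @param a,b [summary_stats()] for the two groups.
#' @param method `"student"` (default) or `"welch"`.
#' @return a `test_result` (statistic = t of a minus b, df, two-sided p).
#' @export
t_test_from_summary <- function(a, b, method = c("student", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  diff <- a$mean - b$mean
  if (a$sd == 0 && b$sd == 0) {
    if (diff == 0) return(test_result(0, a$n + b$n - 2, 1, method))
    warning("zero variance in both groups with unequal means: p = 0 by convention",
            call. = FALSE)
    return(test_result(sign(diff) * Inf, a$n + b$n - 2, 0, method))
  }
  if (method == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    if (sp2 <= 0) stop("pooled variance is zero", call. = FALSE)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- diff / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), method)
}

#' Two-tailed unpaired t test from raw samples
#'
#' Reduces each group to [summary_stats()] and delegates to
#' [t_test_from_summary()], so the raw and summary paths agree exactly.
#'
#' @param xs,ys numeric vectors (length >= 2 each).
#' @inheritParams t_test_from_summary
#' @return a `test_result`.
#' @export
t_test_from_samples <- function(xs, ys, method = c("student", "welch")) {
  t_test_from_summary(summarise_sample(xs), summarise_sample(ys),
                      match.arg(method))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome: table `rbind(c(a, b), c(c, d))`.
#' @return a `test_result` with the odds-ratio estimate as statistic.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty table", call. = FALSE)
  ft <- stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))
  test_result(unname(ft$estimate), NULL, ft$p.value, "fisher")
}

#' Minimum ears per group for a two-sample comparison
#'
#' Normal-approximation sample size for a two-sided two-sample comparison of
#' means with equal groups:
#' `n = ceil( 2 (z_{1-alpha/2} + z_{1-power})^2 (sd / delta)^2 )`.
#'
#' @param sd common standard deviation of the measure (e.g. degrees).
#' @param delta smallest mean difference to resolve (same units).
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.8).
#' @return list with `n_per_group` (integer), `n_exact` (unrounded) and the
#'   echoed inputs.
#' @export
min_sample_size <- function(sd, delta, alpha = 0.05, power = 0.8) {
  stopifnot(sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_exact <- 2 * z^2 * (sd / delta)^2
  list(n_per_group = as.integer(ceiling(n_exact)), n_exact = n_exact,
       sd = sd, delta = delta, alpha = alpha, power = power,
       method = "normal approximation, two-sided, equal groups")
}

summary_pair <- function(xa, xb) {
  list(a = summarise_sample(xa), b = summarise_sample(xb),
       student = t_test_from_samples(xa, xb, "student"),
       welch = t_test_from_samples(xa, xb, "welch"))
}

#' Compare two cohorts of ET measurements
#'
#' Per-ear angle and length are compared with two-tailed unpaired t tests
#' (Student's pooled-variance, with Welch co-reported); age with the same
#' t test; sex with Fisher's exact test. No multiple-testing correction is
#' applied (a note is included when more than three tests are run).
#'
#' @param measurements_a,measurements_b data.frames from [measure_cohort()];
#'   must share a single plane type.
#' @param demographics_a,demographics_b optional data.frames with columns
#'   `subject_id`, `age_yr`, `sex` ("F"/"M").
#' @param label_a,label_b cohort labels used in the report.
#' @return object of class `comparison_report`: nested list with `measures`
#'   (angle, length), `demographics` (age, sex) and `provenance`.
#' @export
compare_cohorts <- function(measurements_a, measurements_b,
                            demographics_a = NULL, demographics_b = NULL,
                            label_a = "A", label_b = "B") {
  planes <- unique(c(measurements_a$plane, measurements_b$plane))
  if (length(planes) != 1L) {
    stop(sprintf("measurement tables mix plane types: %s",
                 paste(planes, collapse = ", ")), call. = FALSE)
  }
  measures <- list(
    angle_deg = summary_pair(measurements_a$angle_deg, measurements_b$angle_deg),
    length_mm = summary_pair(measurements_a$length_mm, measurements_b$length_mm))
  n_tests <- 2L
  demographics <- NULL
  if (!is.null(demographics_a) && !is.null(demographics_b)) {
    fa <- sum(demographics_a$sex == "F"); fb <- sum(demographics_b$sex == "F")
    demographics <- list(
      age_yr = summary_pair(demographics_a$age_yr, demographics_b$age_yr),
      sex = list(
        counts = matrix(c(fa, nrow(demographics_a) - fa,
                          fb, nrow(demographics_b) - fb), 2, 2, byrow = TRUE,
                        dimnames = list(c(label_a, label_b), c("F", "M"))),
        fisher = fisher_exact_2x2(fa, nrow(demographics_a) - fa,
                                  fb, nrow(demographics_b) - fb)))
    n_tests <- n_tests + 2L
  }
  structure(list(
    measures = measures, demographics = demographics,
    provenance = list(
      plane = planes, labels = c(label_a, label_b),
      n_ears = c(nrow(measurements_a), nrow(measurements_b)),
      n_tests = n_tests,
      note = if (n_tests > 3L) "more than 3 tests run; no multiplicity correction applied",
      software = paste0("etmorph ", as.character(utils::packageVersion("etmorph"))),
      timestamp = NULL)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  lab <- x$provenance$labels
  cat(sprintf("Cohort comparison (%s plane): %s (n=%d ears) vs %s (n=%d ears)\n",
              x$provenance$plane, lab[1], x$provenance$n_ears[1],
              lab[2], x$provenance$n_ears[2]))
  row <- function(name, sp, unit) {
    cat(sprintf("  %-10s %5.1f (%.1f) vs %5.1f (%.1f) %-3s  p = %s (Student), %s (Welch)\n",
                name, sp$a$mean, sp$a$sd, sp$b$mean, sp$b$sd, unit,
                format_p(sp$student$p), format_p(sp$welch$p)))
  }
  row("ET angle", x$measures$angle_deg, "deg")
  row("ET length", x$measures$length_mm, "mm")
  if (!is.null(x$demographics)) {
    row("age", x$demographics$age_yr, "yr")
    cat(sprintf("  females    %d/%d vs %d/%d  p = %s (Fisher)\n",
                x$demographics$sex$counts[1, 1], sum(x$demographics$sex$counts[1, ]),
                x$demographics$sex$counts[2, 1], sum(x$demographics$sex$counts[2, ]),
                format_p(x$demographics$sex$fisher$p)))
  }
  if (!is.null(x$provenance$note)) cat("  note:", x$provenance$note, "\n")
  invisible(x)
}
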