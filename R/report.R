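#' Full correlation report for an aligned MIPS/CSF dataset
#'
#' Runs the whole statistical battery on the per-time-point cross-animal
#' means: multiple regression of mean MIPS on mean CSF volume and injected
#' blood (model summary + ANOVA), both first-order partial correlations
#' (MIPS-CSF controlling blood, MIPS-blood controlling CSF), the
#' derivative-curve correlation, and reversal-point detection on the mean
#' MIPS series. Deterministic: identical inputs give identical reports.
#'
#' @param aligned an [synchronize()] result.
#' @param degree polynomial degree for derivative fitting and reversal
#'   detection.
#' @return object of class `correlation_report` with elements `regression`,
#'   `partial_csf` (controlling blood), `partial_blood` (controlling CSF),
#'   `derivative`, `reversal`, `aligned`, `degree`.
#' @export
build_report <- function(aligned, degree = 4) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  b <- aligned$blood_ml
  reg <- multiple_regression(aligned$mips_mean,
                             data.frame(csf = aligned$csf_mean, blood = b))
  p_csf <- partial_correlation(aligned$mips_mean, aligned$csf_mean, b,
                               control = "injected blood")
  p_blood <- partial_correlation(aligned$mips_mean, b, aligned$csf_mean,
                                 control = "CSF")
  ms <- block_series(aligned$time_min, b, aligned$mips_mean)
  cs <- block_series(aligned$time_min, b, aligned$csf_mean)
  dc <- derivative_correlation(ms, cs, degree)
  rev <- detect_reversal(ms, degree)
  structure(list(regression = reg, partial_csf = p_csf,
                 partial_blood = p_blood, derivative = dc, reversal = rev,
                 aligned = aligned, degree = degree),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("== Multiple correlation: MIPS ~ CSF + injected blood ==\n")
  print(x$regression)
  cat("== Partial correlations ==\n")
  print(x$partial_csf)
  print(x$partial_blood)
  cat("== Derivative curves ==\n")
  print(x$derivative)
  cat("== Reversal analysis of the mean MIPS series ==\n")
  print(x$reversal)
  invisible(x)
}

#' Flatten a correlation report to plain lists (JSON-ready)
#'
#' @param x a `correlation_report`.
#' @param ... unused.
#' @return nested list of plain numbers suitable for [write_report()].
#' @export
as.list.correlation_report <- function(x, ...) {
  reg <- x$regression
  list(
    model_summary = list(R = reg$R, R_squared = reg$R_squared,
                         adj_R_squared = reg$adj_R_squared,
                         se_estimate = reg$se_estimate),
    anova = list(ss_regression = reg$ss_regression,
                 ss_residual = reg$ss_residual, ss_total = reg$ss_total,
                 df = as.list(reg$df), ms = as.list(reg$ms),
                 F = reg$F, p_value = reg$p_value),
    coefficients = as.list(reg$coefficients),
    partial_correlations = list(
      mips_csf_given_blood = list(r = x$partial_csf$r,
                                  p = x$partial_csf$p_value,
                                  n = x$partial_csf$n),
      mips_blood_given_csf = list(r = x$partial_blood$r,
                                  p = x$partial_blood$p_value,
                                  n = x$partial_blood$n)),
    derivative_correlation = list(r = x$derivative$r,
                                  p = x$derivative$p_value,
                                  r_finite_diff = x$derivative$r_finite_diff,
                                  p_finite_diff = x$derivative$p_finite_diff,
                                  degree = x$derivative$degree),
    reversal = list(has_reversal = x$reversal$has_reversal,
                    reversal_blood_ml = x$reversal$reversal_blood_ml,
                    zero_crossing_blood_ml = x$reversal$zero_crossing_blood_ml,
                    derivative_max_index = x$reversal$derivative_max_index),
    config = list(degree = x$degree,
                  n_rabbits = ncol(x$aligned$mips),
                  blood_ml = x$aligned$blood_ml)
  )
}

# published reference statistics for the eight-rabbit cohort, used only for
# the side-by-side display of reproduce_tables()
published_reference <- function() {
  list(R = 0.824, R_squared = 0.680, adj_R_squared = 0.573,
       se_estimate = 0.33882, ss_regression = 1.462, ss_residual = 0.689,
       ss_total = 2.151, F = 6.369, p_value = 0.033,
       partial_r_csf = 0.792, partial_p_csf = 0.019,
       partial_r_blood = 0.748, partial_p_blood = 0.033,
       derivative_r = 0.751, derivative_p = 0.02)
}

#' Recompute the published statistics from the packaged cohort tables
#'
#' Loads the packaged eight-rabbit tables (normalized MIPS and quantified
#' CSF volume), synchronizes them on injected blood, runs [build_report()]
#' and prints each computed statistic next to its published value.
#'
#' @param degree polynomial degree for the derivative analysis.
#' @param quiet suppress the side-by-side printout.
#' @return the `correlation_report`, invisibly; the side-by-side data frame
#'   is attached as attribute `"comparison"`.
#' @export
reproduce_tables <- function(degree = 4, quiet = FALSE) {
  fx <- load_fixture_tables()
  aligned <- synchronize(fx$table1, fx$table2)
  rep <- build_report(aligned, degree)
  ref <- published_reference()
  cmp <- data.frame(
    statistic = c("R", "R squared", "adjusted R squared", "SE of estimate",
                  "SS regression", "SS residual", "SS total", "F", "Sig.",
                  "partial r (MIPS,CSF | blood)", "partial Sig.",
                  "partial r (MIPS,blood | CSF)", "partial Sig.",
                  "derivative correlation r", "derivative Sig."),
    computed = c(rep$regression$R, rep$regression$R_squared,
                 rep$regression$adj_R_squared, rep$regression$se_estimate,
                 rep$regression$ss_regression, rep$regression$ss_residual,
                 rep$regression$ss_total, rep$regression$F,
                 rep$regression$p_value,
                 rep$partial_csf$r, rep$partial_csf$p_value,
                 rep$partial_blood$r, rep$partial_blood$p_value,
                 rep$derivative$r, rep$derivative$p_value),
    published = c(ref$R, ref$R_squared, ref$adj_R_squared, ref$se_estimate,
                  ref$ss_regression, ref$ss_residual, ref$ss_total, ref$F,
                  ref$p_value, ref$partial_r_csf, ref$partial_p_csf,
                  ref$partial_r_blood, ref$partial_p_blood,
                  ref$derivative_r, ref$derivative_p))
  if (!quiet) {
    cat("Computed vs published statistics (eight-rabbit cohort, n = 9 means)\n")
    print(transform(cmp, computed = signif(computed, 5)), row.names = FALSE)
  }
  attr(rep, "comparison") <- cmp
  invisible(rep)
}
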