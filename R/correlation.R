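#' Synchronize MIPS and CSF tables on injected blood volume
#'
#' The MIPS recording and the MR-based CSF volumetry are acquired
#' asynchronously; they are aligned by the injected blood volume, which is a
#' deterministic function of time under the constant-rate protocol. Both
#' tables must share the schedule's blood grid and the same animal columns.
#' Cross-animal means per time point are computed here; they are the n = 9
#' sample on which the downstream regression and correlation battery runs.
#'
#' @param mips_table,csf_table data frames with columns `time_min`,
#'   `blood_ml` and one `rabbit_*` column per animal (layout of the packaged
#'   fixture tables and of [generate_cohort()] output).
#' @param schedule an [injection_schedule()], used to validate the blood
#'   grid; `NULL` skips that check.
#' @return object of class `aligned_dataset`: `blood_ml`, `time_min`,
#'   `mips` and `csf_ml` (time x animal matrices), `mips_mean`, `csf_mean`.
#' @export
synchronize <- function(mips_table, csf_table, schedule = injection_schedule()) {
  for (tb in list(mips_table, csf_table))
    if (!all(c("time_min", "blood_ml") %in% names(tb)))
      stop("tables need time_min and blood_ml columns")
  if (nrow(mips_table) != nrow(csf_table) ||
      max(abs(mips_table$blood_ml - csf_table$blood_ml)) > 1e-9)
    stop("MIPS and CSF tables are on different blood grids")
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "injection_schedule"))
    if (nrow(mips_table) != length(schedule$blood_ml) ||
        max(abs(mips_table$blood_ml - schedule$blood_ml)) > 1e-9)
      stop("tables do not match the schedule's blood grid")
  }
  rab_m <- grep("^rabbit_", names(mips_table), value = TRUE)
  rab_c <- grep("^rabbit_", names(csf_table), value = TRUE)
  if (length(rab_m) == 0 || !setequal(rab_m, rab_c))
    stop("tables must carry the same rabbit_* columns")
  rab <- sort(rab_m)
  mips <- as.matrix(mips_table[rab])
  csf <- as.matrix(csf_table[rab])
  structure(list(blood_ml = mips_table$blood_ml,
                 time_min = mips_table$time_min,
                 mips = mips, csf_ml = csf,
                 mips_mean = rowMeans(mips), csf_mean = rowMeans(csf)),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("Aligned dataset: %d animals x %d time points (%.2f-%.2f ml blood)\n",
              ncol(x$mips), length(x$blood_ml), min(x$blood_ml), max(x$blood_ml)))
  invisible(x)
}

#' Multiple regression of MIPS on CSF volume and injected blood
#'
#' Ordinary least squares with intercept ([stats::lm()]), summarized the way
#' statistics packages print a model-summary plus ANOVA table: multiple R,
#' R squared, adjusted R squared, standard error of the estimate, the
#' regression/residual/total sum-of-squares decomposition with degrees of
#' freedom and mean squares, and the overall F test with its tail p-value
#' from the F(p, n - p - 1) distribution.
#'
#' @param y response (the per-time-point mean MIPS).
#' @param X data frame or matrix of predictors (mean CSF volume, injected
#'   blood).
#' @return object of class `multiple_regression`.
#' @export
multiple_regression <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < p + 1)
    stop("rank-deficient predictors: collinear to machine precision")
  fit <- stats::lm(y ~ ., data = X)
  ss_total <- sum((y - mean(y))^2)
  ss_residual <- sum(stats::resid(fit)^2)
  ss_regression <- ss_total - ss_residual
  df <- c(regression = p, residual = n - p - 1, total = n - 1)
  ms <- c(regression = ss_regression / p, residual = ss_residual / (n - p - 1))
  Fstat <- ms[["regression"]] / ms[["residual"]]
  r2 <- ss_regression / ss_total
  structure(list(R = sqrt(r2), R_squared = r2,
                 adj_R_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 se_estimate = sqrt(ss_residual / (n - p - 1)),
                 ss_regression = ss_regression, ss_residual = ss_residual,
                 ss_total = ss_total, df = df, ms = ms, F = Fstat,
                 p_value = stats::pf(Fstat, p, n - p - 1, lower.tail = FALSE),
                 coefficients = stats::coef(fit), n = n, fit = fit),
            class = "multiple_regression")
}

#' @export
print.multiple_regression <- function(x, ...) {
  cat("Model summary\n")
  cat(sprintf("  R = %.3f   R squared = %.3f   adjusted R squared = %.3f   SE of estimate = %.5f\n",
              x$R, x$R_squared, x$adj_R_squared, x$se_estimate))
  cat("ANOVA\n")
  cat(sprintf("  regression  SS = %.3f  df = %d  MS = %.3f  F = %.3f  Sig. = %.3f\n",
              x$ss_regression, x$df[["regression"]], x$ms[["regression"]],
              x$F, x$p_value))
  cat(sprintf("  residual    SS = %.3f  df = %d  MS = %.3f\n",
              x$ss_residual, x$df[["residual"]], x$ms[["residual"]]))
  cat(sprintf("  total       SS = %.3f  df = %d\n", x$ss_total, x$df[["total"]]))
  invisible(x)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of the
#' control variable `z`:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' with a two-sided p-value from \eqn{t = r \sqrt{(n-3)/(1-r^2)}} on n - 3
#' degrees of freedom. Identical (to numerical precision) to the Pearson
#' correlation of the OLS residuals of `x` on `z` and `y` on `z`.
#'
#' @param x,y variables of interest.
#' @param z control variable.
#' @param control name of the control variable for reporting.
#' @return object of class `partial_correlation`: `r`, `p_value`, `n`,
#'   `control`.
#' @export
partial_correlation <- function(x, y, z, control = deparse(substitute(z))) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4) stop("partial correlation needs at least 4 observations")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("control variable is collinear with x or y: partial correlation undefined")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  structure(list(r = r, p_value = 2 * stats::pt(-abs(tstat), n - 3),
                 n = n, control = control, t = tstat),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("Partial correlation (controlling %s): r = %.3f, p = %.3f, n = %d\n",
              x$control, x$r, x$p_value, x$n))
  invisible(x)
}

#' Correlation between the derivative curves of MIPS and CSF
#'
#' Fits both series with a polynomial in injected blood volume
#' ([fit_polynomial()]), evaluates the analytic derivatives at the shared
#' blood points and returns their Pearson correlation with the classical
#' two-sided t test (primary result). The finite-difference variant
#' (forward differences of the raw series, n - 1 pairs) is reported
#' alongside.
#'
#' @param mips_series,csf_series [block_series()] objects on the same blood
#'   grid.
#' @param degree polynomial degree (3-6 sensible; default 4).
#' @return object of class `derivative_correlation`: `r`, `p_value`,
#'   `r_finite_diff`, `p_finite_diff`, `degree`, `deriv_mips`, `deriv_csf`.
#' @export
derivative_correlation <- function(mips_series, csf_series, degree = 4) {
  stopifnot(inherits(mips_series, "block_series"),
            inherits(csf_series, "block_series"))
  if (nrow(mips_series) != nrow(csf_series) ||
      max(abs(mips_series$blood_ml - csf_series$blood_ml)) > 1e-9)
    stop("series are on different blood grids")
  fm <- fit_polynomial(mips_series, degree)
  fc <- fit_polynomial(csf_series, degree)
  ct <- stats::cor.test(fm$deriv_values, fc$deriv_values)
  fdm <- first_derivative(mips_series)$derivative
  fdc <- first_derivative(csf_series)$derivative
  ct_fd <- stats::cor.test(fdm, fdc)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 r_finite_diff = unname(ct_fd$estimate),
                 p_finite_diff = ct_fd$p.value,
                 degree = degree,
                 deriv_mips = fm$deriv_values, deriv_csf = fc$deriv_values),
            class = "derivative_correlation")
}

#' @export
print.derivative_correlation <- function(x, ...) {
  cat(sprintf("Derivative-curve correlation (degree %d fits): r = %.3f, p = %.3f\n",
              x$degree, x$r, x$p_value))
  cat(sprintf("  finite-difference variant: r = %.3f, p = %.3f\n",
              x$r_finite_diff, x$p_finite_diff))
  invisible(x)
}
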