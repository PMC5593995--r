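#' Block series constructor
#'
#' A short series keyed by injected blood volume: the nine-point layout of
#' the experimental tables (block-smoothed normalized MIPS, or CSF volume in
#' ml, one value per observation time).
#'
#' @param time_min observation times, minutes.
#' @param blood_ml injected blood at each point, ml (strictly increasing).
#' @param value series values (normalized MIPS or CSF ml).
#' @return data frame of class `block_series`.
#' @export
block_series <- function(time_min, blood_ml, value) {
  stopifnot(length(time_min) == length(blood_ml),
            length(blood_ml) == length(value))
  if (any(!is.finite(value)) || any(!is.finite(blood_ml)))
    stop("block series values must be finite")
  if (any(diff(blood_ml) <= 0))
    stop("blood_ml must be strictly increasing")
  out <- data.frame(time_min = time_min, blood_ml = blood_ml, value = value)
  class(out) <- c("block_series", "data.frame")
  out
}

#' Block-average a raw MIPS recording
#'
#' Averages consecutive samples of the injection period in non-overlapping
#' blocks (default 300 samples, turning the protocol's 2700 samples into the
#' nine tabulated values). Samples at time <= 0 (pre-injection lead-in) are
#' excluded. Block averaging is the only fluctuation suppression applied:
#' at 300 samples per block the respiration and cardiac contamination
#' averages out.
#'
#' @param raw a `raw_mips` data frame (columns `time_s`, `phase_deg`), e.g.
#'   from [simulate_mips()] or [read_raw_series()].
#' @param block_size samples per block.
#' @param schedule an [injection_schedule()]; default taken from the series
#'   attribute. Supplies the reported blood volume at each block end.
#' @return a [block_series()] with one row per complete block. A trailing
#'   partial block is dropped with a warning.
#' @examples
#' sch <- injection_schedule()
#' csf <- simulate_csf_compensation(compensation_params(), sch, seed = 1)
#' raw <- simulate_mips(mips_params(), csf, sch, seed = 1)
#' block_smooth(raw)   # 9 rows
#' @export
block_smooth <- function(raw, block_size = 300, schedule = NULL) {
  stopifnot(is.data.frame(raw), all(c("time_s", "phase_deg") %in% names(raw)),
            block_size >= 1)
  if (is.null(schedule)) schedule <- attr(raw, "schedule")
  if (is.null(schedule))
    stop("an injection schedule is required to assign blood volumes to blocks")
  inj <- raw[raw$time_s > 0, , drop = FALSE]
  n <- nrow(inj)
  nb <- n %/% block_size
  if (nb < 1) stop("fewer samples than one block")
  if (n %% block_size != 0)
    warning(sprintf("dropping trailing partial block of %d samples",
                    n %% block_size))
  used <- seq_len(nb * block_size)
  means <- colMeans(matrix(inj$phase_deg[used], nrow = block_size))
  t_end <- inj$time_s[used[seq(block_size, nb * block_size, by = block_size)]] / 60
  b_end <- if (length(schedule$blood_ml) == nb &&
               max(abs(t_end - schedule$sample_times)) < 1e-6) {
    schedule$blood_ml
  } else {
    floor(blood_at(schedule, t_end) * 100 + 1e-9) / 100
  }
  block_series(time_min = t_end, blood_ml = b_end, value = means)
}

#' Estimate the pre-injection baseline phase
#'
#' Mean phase over the lead-in samples (time <= 0). Falls back to the first
#' block mean, with a warning, when the recording has no pre-injection
#' segment.
#'
#' @param raw a `raw_mips` data frame.
#' @param block_size fallback block length.
#' @return baseline phase, degrees.
#' @export
pre_injection_baseline <- function(raw, block_size = 300) {
  stopifnot(is.data.frame(raw), all(c("time_s", "phase_deg") %in% names(raw)))
  lead <- raw$phase_deg[raw$time_s <= 0]
  if (length(lead) > 0) return(mean(lead))
  warning("no pre-injection samples; using the first block mean as baseline")
  mean(raw$phase_deg[seq_len(min(block_size, nrow(raw)))])
}

#' Normalize a block series to a baseline value
#'
#' Rescales so the baseline maps to 100 (the dimensionless scale of the
#' tabulated MIPS values): `value <- 100 * value / baseline_value`.
#' Normalizing an already-normalized series with baseline 100 is the
#' identity.
#'
#' @param series a [block_series()].
#' @param baseline_value reference level (> 0), e.g. from
#'   [pre_injection_baseline()].
#' @return normalized [block_series()].
#' @export
normalize_series <- function(series, baseline_value) {
  stopifnot(inherits(series, "block_series"))
  if (!is.numeric(baseline_value) || length(baseline_value) != 1 ||
      !is.finite(baseline_value) || baseline_value <= 0)
    stop("baseline_value must be a positive number")
  block_series(series$time_min, series$blood_ml,
               100 * series$value / baseline_value)
}

#' Forward finite-difference derivative with respect to injected blood
#'
#' @param series a [block_series()] with at least 2 points.
#' @return data frame with `blood_ml` (left block of each difference) and
#'   `derivative` (delta value / delta blood), n - 1 rows.
#' @export
first_derivative <- function(series) {
  stopifnot(inherits(series, "block_series"), nrow(series) >= 2)
  db <- diff(series$blood_ml)
  if (any(db == 0)) stop("duplicate blood_ml values: derivative undefined")
  data.frame(blood_ml = series$blood_ml[-nrow(series)],
             derivative = diff(series$value) / db)
}

#' Least-squares polynomial fit of a block series
#'
#' Fits value as a polynomial in injected blood volume by ordinary least
#' squares (raw monomial basis through [stats::lm()]) and differentiates the
#' fitted polynomial analytically.
#'
#' @param series a [block_series()].
#' @param degree polynomial degree; must be < number of points (exact
#'   interpolation is excluded).
#' @return object of class `poly_fit`: `coefficients` (intercept first),
#'   `deriv_coefficients`, `fitted` and `deriv_values` (both evaluated at
#'   the series' blood points), `residuals`, `degree`, `blood_ml`.
#' @export
fit_polynomial <- function(series, degree = 4) {
  stopifnot(inherits(series, "block_series"))
  n <- nrow(series)
  if (degree >= n)
    stop("degree must be smaller than the number of points")
  if (degree < 1) stop("degree must be at least 1")
  b <- series$blood_ml
  fit <- stats::lm(series$value ~ stats::poly(b, degree, raw = TRUE))
  cf <- unname(stats::coef(fit))
  dcf <- cf[-1] * seq_len(degree)
  structure(list(coefficients = cf, deriv_coefficients = dcf,
                 fitted = unname(stats::fitted(fit)),
                 deriv_values = eval_poly(dcf, b),
                 residuals = unname(stats::resid(fit)),
                 degree = degree, blood_ml = b),
            class = "poly_fit")
}

# evaluate a polynomial with coefficients c0, c1, ... at x (Horner)
eval_poly <- function(coefs, x) {
  out <- rep(0, length(x))
  for (c_i in rev(coefs)) out <- out * x + c_i
  out
}

#' @export
predict.poly_fit <- function(object, blood_ml = object$blood_ml, ...) {
  eval_poly(object$coefficients, blood_ml)
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("Degree-%d polynomial fit in blood volume; RSS = %.4g\n",
              x$degree, sum(x$residuals^2)))
  invisible(x)
}

#' Detect the MIPS reversal point
#'
#' Locates the blood volume at which a smoothed, normalized MIPS series
#' switches from decreasing to increasing -- the signature of approaching
#' CSF compensation failure. Several rules are computed side by side:
#'
#' * `reversal_blood_ml`: the blood grid point at the series minimum
#'   (default) or at the minimum of a least-squares polynomial fit of
#'   default degree 4 (`method = "fitted"`);
#' * `zero_crossing_blood_ml`: the continuous zero crossing of the fitted
#'   polynomial's derivative, when one exists in range;
#' * the section after the maximum of the finite-difference first
#'   derivative (`derivative_max_index`, `reversal_section`), the rule used
#'   to flag the part of the curve lying outside the overall trend.
#'
#' A monotone series has no interior reversal and is flagged
#' `has_reversal = FALSE` (endpoint minima are treated as artifacts).
#' Ties in argmin/argmax resolve to the earliest index.
#'
#' @param series a [block_series()] with at least 4 points.
#' @param degree polynomial degree for the fitted rule (3-6 sensible).
#' @param method `"raw"` (default) reports the blood grid point minimizing
#'   the smoothed series itself -- for a piecewise-linear signal the block
#'   argmin localizes the vertex to within one block, while a global
#'   least-squares polynomial can displace it; `"fitted"` snaps to the
#'   grid point minimizing the fitted curve instead.
#' @return object of class `reversal_analysis`.
#' @examples
#' s <- block_series(seq(6, 54, 6), c(.33, .66, 1, 1.33, 1.66, 2, 2.33, 2.66, 3),
#'                   c(5, 3, 1.5, 1, 1.5, 2.5, 3.5, 4.5, 5.5))
#' detect_reversal(s)$reversal_blood_ml  # 1.33
#' @export
detect_reversal <- function(series, degree = 4, method = c("raw", "fitted")) {
  stopifnot(inherits(series, "block_series"))
  method <- match.arg(method)
  n <- nrow(series)
  if (n < 4) stop("reversal detection needs at least 4 points")
  v <- series$value
  b <- series$blood_ml

  fd <- first_derivative(series)
  dmax <- which.max(fd$derivative)
  section <- if (dmax < nrow(fd)) seq(dmax + 1L, nrow(fd)) else integer(0)

  fit <- fit_polynomial(series, degree)
  curve <- if (method == "fitted") fit$fitted else v
  k <- which.min(curve)
  monotone <- all(diff(v) < 0) || all(diff(v) > 0)
  has_rev <- !monotone && k > 1 && k < n

  zero_cross <- NA_real_
  if (has_rev) {
    rts <- polyroot(fit$deriv_coefficients)
    rts <- Re(rts[abs(Im(rts)) < 1e-8])
    rts <- rts[rts >= b[1] & rts <= b[n]]
    if (length(rts) > 0) {
      vals <- eval_poly(fit$coefficients, rts)
      zero_cross <- rts[which.min(vals)]
    }
  }

  structure(list(has_reversal = has_rev,
                 reversal_blood_ml = if (has_rev) b[k] else NA_real_,
                 zero_crossing_blood_ml = zero_cross,
                 derivative = fd$derivative,
                 derivative_max_index = dmax,
                 reversal_section = section,
                 degree = degree, method = method,
                 fit = fit, series = series),
            class = "reversal_analysis")
}

#' @export
print.reversal_analysis <- function(x, ...) {
  if (x$has_reversal) {
    rule <- if (x$method == "raw") "series argmin"
            else sprintf("degree-%d fit argmin", x$degree)
    cat(sprintf("Reversal at %.2f ml injected blood (%s",
                x$reversal_blood_ml, rule))
    if (!is.na(x$zero_crossing_blood_ml))
      cat(sprintf("; derivative zero crossing at %.3f ml",
                  x$zero_crossing_blood_ml))
    cat(")\n")
  } else {
    cat("No reversal: series is monotone over the injection range\n")
  }
  cat(sprintf("Derivative maximum at index %d; reversal section: %s\n",
              x$derivative_max_index,
              if (length(x$reversal_section))
                paste(range(x$reversal_section), collapse = "-")
              else "empty"))
  invisible(x)
}
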