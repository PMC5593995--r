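sch <- test_schedule()

make_raw <- function(phase, dt_min = 1 / 50, schedule = sch) {
  n <- length(phase)
  out <- data.frame(time_s = seq_len(n) * dt_min * 60, phase_deg = phase)
  class(out) <- c("raw_mips", "data.frame")
  attr(out, "schedule") <- schedule
  out
}

test_that("2700 samples in nine 300-sample blocks, means exact", {
  set.seed(42)
  phase <- rnorm(2700, 100, 1)
  blocks <- block_smooth(make_raw(phase))
  expect_equal(nrow(blocks), 9)
  oracle <- vapply(1:9, function(k)
    mean(phase[((k - 1) * 300 + 1):(k * 300)]), numeric(1))
  expect_equal(blocks$value, oracle, tolerance = 1e-12)
  expect_identical(blocks$blood_ml, sch$blood_ml)
})

test_that("constant and ramp inputs give textbook block means", {
  blocks <- block_smooth(make_raw(rep(7, 2700)))
  expect_equal(blocks$value, rep(7, 9))
  short <- injection_schedule(total_volume = 3, duration = 12, sample_every = 6)
  ramp <- block_smooth(make_raw(1:600, dt_min = 12 / 600, schedule = short))
  expect_equal(ramp$value, c(150.5, 450.5))
})

test_that("trailing partial blocks are dropped with a warning", {
  expect_warning(blocks <- block_smooth(make_raw(rnorm(2750, 100))),
                 "partial block")
  expect_equal(nrow(blocks), 9)
})

test_that("normalization maps the baseline to 100 and is scale invariant", {
  s <- block_series(sch$sample_times, sch$blood_ml, c(95, 94, 93, 92, 91, 92, 93, 94, 95))
  n1 <- normalize_series(s, s$value[1])
  expect_equal(n1$value[1], 100)
  flat <- block_series(sch$sample_times, sch$blood_ml, rep(3.7, 9))
  expect_equal(normalize_series(flat, 3.7)$value, rep(100, 9))
  # doubling values and baseline leaves the result unchanged
  s2 <- block_series(s$time_min, s$blood_ml, 2 * s$value)
  expect_equal(normalize_series(s2, 2 * s$value[1])$value, n1$value)
  # normalizing an already normalized series to 100 is the identity
  expect_equal(normalize_series(n1, 100)$value, n1$value)
  expect_error(normalize_series(s, 0), "positive")
})

test_that("block smoothing and normalization commute", {
  set.seed(7)
  raw <- make_raw(rnorm(2700, 98, 0.5))
  base <- 97.5
  a <- normalize_series(block_smooth(raw), base)
  raw_n <- raw
  raw_n$phase_deg <- 100 * raw$phase_deg / base
  b <- block_smooth(raw_n)
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("finite differences follow the forward-difference convention", {
  lin <- block_series(sch$sample_times, sch$blood_ml, 2.5 * sch$blood_ml + 1)
  d <- first_derivative(lin)
  expect_equal(nrow(d), 8)
  expect_equal(d$derivative, rep(2.5, 8), tolerance = 1e-10)
  expect_equal(d$blood_ml, sch$blood_ml[-9])
  flat <- block_series(sch$sample_times, sch$blood_ml, rep(1, 9))
  expect_equal(first_derivative(flat)$derivative, rep(0, 8))
})

test_that("mean cohort MIPS derivative is negative then positive", {
  fx <- load_fixture_tables()
  m <- rowMeans(fx$table1[grep("^rabbit_", names(fx$table1))])
  s <- block_series(fx$table1$time_min, fx$table1$blood_ml, m)
  d <- first_derivative(s)$derivative
  expect_identical(sign(d), c(rep(-1, 4), rep(1, 4)))
})

test_that("polynomial fits recover generating polynomials and derivatives", {
  b <- sch$blood_ml
  y <- 2 - 1.5 * b + 0.4 * b^2
  s <- block_series(sch$sample_times, b, y)
  fit <- fit_polynomial(s, 2)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_equal(fit$coefficients, c(2, -1.5, 0.4), tolerance = 1e-8)
  # analytic derivative coefficients equal the term-wise derivative exactly
  expect_identical(fit$deriv_coefficients,
                   fit$coefficients[-1] * seq_len(fit$degree))
  # fit-then-differentiate equals differentiate-then-fit on polynomial data
  dy <- -1.5 + 0.8 * b
  ds <- block_series(sch$sample_times, b, dy)
  dfit <- fit_polynomial(ds, 1)
  expect_equal(fit$deriv_values, dfit$fitted, tolerance = 1e-8)
  expect_error(fit_polynomial(s, 9), "degree")
})

test_that("reversal detection finds a planted V and flags monotone series", {
  b <- sch$blood_ml
  v <- abs(b - 1.33) * 3 + 1           # noise-free V with vertex at 1.33
  rv <- detect_reversal(block_series(sch$sample_times, b, v))
  expect_true(rv$has_reversal)
  expect_equal(rv$reversal_blood_ml, 1.33)
  expect_gt(min(rv$reversal_section), rv$derivative_max_index)

  mono <- block_series(sch$sample_times, b, 10 - b)
  rv2 <- detect_reversal(mono)
  expect_false(rv2$has_reversal)
  expect_true(is.na(rv2$reversal_blood_ml))
  expect_error(detect_reversal(block_series(1:3, b[1:3], c(3, 1, 2))),
               "at least 4")
})

test_that("mean cohort MIPS reversal matches the nine-point argmin", {
  fx <- load_fixture_tables()
  m <- rowMeans(fx$table1[grep("^rabbit_", names(fx$table1))])
  s <- block_series(fx$table1$time_min, fx$table1$blood_ml, m)
  rv <- detect_reversal(s)
  expect_true(rv$has_reversal)
  expect_equal(rv$reversal_blood_ml, s$blood_ml[which.min(m)])
})
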