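fx <- load_fixture_tables()

test_that("synchronization aligns tables and averages across animals", {
  al <- synchronize(fx$table1, fx$table2)
  expect_equal(dim(al$mips), c(9, 8))
  expect_equal(dim(al$csf_ml), c(9, 8))
  expect_equal(al$mips_mean, rowMeans(al$mips))
  # permuting animal columns leaves the means unchanged
  perm <- fx$table1[c("time_min", "blood_ml", sprintf("rabbit_%d", 8:1))]
  expect_equal(synchronize(perm, fx$table2)$mips_mean, al$mips_mean)
  # single animal: means equal that animal
  one_m <- fx$table1[c("time_min", "blood_ml", "rabbit_3")]
  one_c <- fx$table2[c("time_min", "blood_ml", "rabbit_3")]
  expect_equal(synchronize(one_m, one_c)$mips_mean, fx$table1$rabbit_3)
})

test_that("mismatched grids or animal sets are rejected", {
  shifted <- fx$table2
  shifted$blood_ml[3] <- 1.01
  expect_error(synchronize(fx$table1, shifted), "grid")
  dropped <- fx$table2[setdiff(names(fx$table2), "rabbit_5")]
  expect_error(synchronize(fx$table1, dropped), "rabbit")
})

test_that("multiple regression reproduces textbook identities", {
  set.seed(1)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- 1 + 2 * X$a - 3 * X$b
  fit <- multiple_regression(y, X)
  expect_equal(fit$R, 1, tolerance = 1e-7)
  expect_lt(fit$ss_residual, 1e-20)
  # ANOVA identity on noisy data
  y2 <- y + rnorm(30)
  fit2 <- multiple_regression(y2, X)
  expect_equal(fit2$ss_total, fit2$ss_regression + fit2$ss_residual,
               tolerance = 1e-9)
  expect_equal(fit2$R, sqrt(fit2$R_squared))
  expect_equal(unname(fit2$df["total"]), 29)
  # response orthogonal to both centered predictors has R near 0
  y3 <- resid(lm(rnorm(30) ~ a + b, data = X))
  fit3 <- multiple_regression(y3, X)
  expect_lt(fit3$R, 1e-6)
  # collinear predictors rejected
  expect_error(multiple_regression(y, data.frame(a = X$a, b = 2 * X$a)),
               "rank")
})

test_that("multiple R is invariant to affine predictor rescaling", {
  al <- synchronize(fx$table1, fx$table2)
  f1 <- multiple_regression(al$mips_mean,
                            data.frame(csf = al$csf_mean, blood = al$blood_ml))
  f2 <- multiple_regression(al$mips_mean,
                            data.frame(csf = 1000 * al$csf_mean - 2,
                                       blood = al$blood_ml / 54))
  expect_equal(f1$R, f2$R, tolerance = 1e-12)
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
})

test_that("partial correlation agrees with the residual-regression oracle", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    pc <- partial_correlation(x, y, z)
    expect_equal(pc$r, pcor_residual_oracle(x, y, z), tolerance = 1e-10)
    expect_true(pc$p_value >= 0 && pc$p_value <= 1)
  }
})

test_that("a control orthogonal to both variables changes nothing", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40)
  z <- resid(lm(rnorm(40) ~ x + y))  # exactly orthogonal control
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-10)
  expect_error(partial_correlation(x, y, x), "collinear")
  expect_error(partial_correlation(1:3, 3:1, c(1, 2, 4)), "at least 4")
})

test_that("derivative correlation is exact for degenerate inputs", {
  b <- fx$table1$blood_ml
  s <- block_series(fx$table1$time_min, b, rowMeans(fx$table1[sprintf("rabbit_%d", 1:8)]))
  self <- derivative_correlation(s, s)
  expect_equal(self$r, 1, tolerance = 1e-10)
  # affine transform of the series leaves r = 1 (derivative scales linearly)
  aff <- block_series(s$time_min, b, 3 * s$value + 17)
  expect_equal(derivative_correlation(s, aff)$r, 1, tolerance = 1e-10)
  grid2 <- block_series(s$time_min, b + 0.1, s$value)
  expect_error(derivative_correlation(s, grid2), "grid")
})

test_that("the full report is deterministic and structurally complete", {
  al <- synchronize(fx$table1, fx$table2)
  r1 <- build_report(al)
  r2 <- build_report(al)
  expect_identical(as.list(r1), as.list(r2))
  l <- as.list(r1)
  expect_named(l, c("model_summary", "anova", "coefficients",
                    "partial_correlations", "derivative_correlation",
                    "reversal", "config"))
  expect_equal(l$anova$df$total, 8)
})

test_that("a cohort with no blood response has CSF-dominant partial correlation", {
  ranges <- default_param_ranges()
  ranges$coef_blood <- c(0, 0)
  coh <- generate_cohort(n_rabbits = 8, seed = 17, param_ranges = ranges)
  al <- synchronize(coh$mips_table, coh$csf_table)
  rep <- build_report(al)
  expect_gt(rep$partial_csf$r, rep$partial_blood$r)
})
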