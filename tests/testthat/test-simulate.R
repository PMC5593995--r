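sch <- test_schedule()

test_that("compensation curve honours its boundary conditions", {
  p <- compensation_params()
  expect_equal(csf_compensation_curve(p, 0), p$csf_baseline)
  flat <- compensation_params(slope_pre = 0, slope_post = 0)
  expect_equal(csf_compensation_curve(flat, sch$blood_ml),
               rep(flat$csf_baseline, 9))
  # clipping at zero for an aggressive loss rate
  steep <- compensation_params(csf_baseline = 0.3, slope_pre = -0.35,
                               slope_post = -0.35, inflection_blood = 1)
  expect_true(all(csf_compensation_curve(steep, sch$blood_ml) >= 0))
})

test_that("invalid compensation parameters are rejected", {
  expect_error(compensation_params(csf_baseline = -1), "positive")
  expect_error(compensation_params(slope_pre = 0.1), "nonpositive")
  expect_error(compensation_params(slope_pre = -0.05, slope_post = -0.2),
               "slope_post")
})

test_that("noise-free trajectories are nonincreasing; noisy ones reproducible", {
  p <- compensation_params()
  s1 <- simulate_csf_compensation(p, sch, seed = 11)
  s2 <- simulate_csf_compensation(p, sch, seed = 11)
  expect_identical(s1, s2)
  expect_true(all(diff(s1$csf_true) <= 0))
  p0 <- compensation_params(noise_sd = 0)
  s0 <- simulate_csf_compensation(p0, sch, seed = 1)
  expect_equal(s0$csf_ml, s0$csf_true)
})

test_that("breakpoint fit of the mean cohort trajectory round-trips", {
  fx <- load_fixture_tables()
  blood <- fx$table2$blood_ml
  csf_mean <- rowMeans(fx$table2[grep("^rabbit_", names(fx$table2))])
  fit <- fit_compensation(blood, csf_mean)
  oracle_k <- breakpoint_oracle(blood, csf_mean)
  expect_lt(abs(fit$inflection - oracle_k), 0.02)

  # resimulate noise-free from the fitted parameters and refit
  p <- fit$params
  p$noise_sd <- 0
  sim <- simulate_csf_compensation(p, sch, seed = 1)
  refit <- fit_compensation(sim$blood_ml, sim$csf_ml)
  expect_lt(abs(refit$inflection - fit$inflection), 0.33)
})

test_that("MIPS simulation matches the acquisition protocol", {
  csf <- simulate_csf_compensation(compensation_params(), sch, seed = 2)
  raw <- simulate_mips(mips_params(), csf, sch, seed = 2)
  expect_equal(sum(raw$time_s > 0), 2700)
  expect_equal(attr(raw, "n_injection_samples"), 2700L)
  expect_true(all(diff(raw$time_s) > 0))
  # deterministic under a fixed seed
  raw2 <- simulate_mips(mips_params(), csf, sch, seed = 2)
  expect_identical(raw, raw2)
})

test_that("a null response model yields a constant recording", {
  csf <- simulate_csf_compensation(compensation_params(noise_sd = 0), sch)
  mp <- mips_params(coef_csf = 0, coef_blood = 0, resp_amp = 0,
                    cardiac_amp = 0, noise_sd = 0)
  raw <- simulate_mips(mp, csf, sch)
  expect_equal(raw$phase_deg, rep(mp$baseline_phase, nrow(raw)))
})

test_that("noise-free block-smoothed MIPS is V-shaped around the inflection", {
  p <- compensation_params(noise_sd = 0)
  csf <- simulate_csf_compensation(p, sch)
  mp <- mips_params(resp_amp = 0, cardiac_amp = 0, noise_sd = 0)
  raw <- simulate_mips(mp, csf, sch)
  blocks <- block_smooth(raw)
  d <- diff(blocks$value)
  j <- which.min(blocks$value)
  expect_true(all(d[seq_len(j - 1)] < 0))        # falling up to the minimum
  expect_true(all(d[seq(j, length(d))] > 0))     # rising after it
  # minimum lands within one blood step of the planted inflection
  expect_lt(abs(blocks$blood_ml[j] - p$inflection_blood), 0.34)
})

test_that("series/schedule mismatches are rejected", {
  csf <- simulate_csf_compensation(compensation_params(), sch, seed = 1)
  expect_error(simulate_mips(mips_params(), csf[1:5, ], sch),
               "length")
  short <- injection_schedule(total_volume = 1.5, duration = 27)
  expect_error(simulate_mips(mips_params(), csf, short), "length|grid")
})

test_that("cohort generation is reproducible with the table layout", {
  c1 <- generate_cohort(n_rabbits = 8, seed = 5)
  c2 <- generate_cohort(n_rabbits = 8, seed = 5)
  expect_identical(c1$mips_table, c2$mips_table)
  expect_identical(c1$csf_table, c2$csf_table)
  expect_equal(dim(c1$csf_true), c(9, 8))
  expect_equal(names(c1$mips_table),
               c("time_min", "blood_ml", sprintf("rabbit_%d", 1:8)))
  expect_error(generate_cohort(n_rabbits = 1), "at least 2")
})

test_that("noise-free cohorts have monotone ground-truth CSF", {
  coh <- generate_cohort(n_rabbits = 5, seed = 9, noise = FALSE)
  expect_true(all(apply(coh$csf_true, 2, function(v) all(diff(v) <= 0))))
  expect_equal(coh$csf_table[sprintf("rabbit_%d", 1:5)],
               as.data.frame(coh$csf_true),
               ignore_attr = TRUE)
})
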