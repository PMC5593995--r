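test_that("preprocessing rescales monotonically and masks the foreground", {
  tc <- two_class_volume()
  pre <- preprocess_volume(tc$vol)
  expect_equal(range(pre$volume$data), c(0, 1))
  # monotone rescale preserves intensity order
  o1 <- order(tc$vol$data[1:500])
  expect_identical(order(pre$volume$data[1:500]), o1)
  # mask recovers the bright block exactly (clean two-intensity phantom)
  expect_identical(pre$mask, tc$truth)
  flat <- mr_volume(array(0.5, c(8, 8, 8)), c(1, 1, 1))
  expect_error(preprocess_volume(flat), "constant")
})

test_that("plain FCM (beta = 0) matches the independent textbook oracle", {
  sp <- phantom_spec(grid_shape = c(32, 32, 32),
                     csf_geometry = list(r_inner = 3, r_outer = 6),
                     hematoma_center = c(2, 0, 0), seed = 3)
  ph <- generate_phantom(sp, csf_volume = 0.3, blood_volume = 0.2)
  pre <- preprocess_volume(ph$volume)
  x <- pre$volume$data[pre$mask]
  init <- kmeans(x, 4, nstart = 5)$centers
  cfg <- segmentation_config(mrf_beta = 0)
  fit <- fcm_mrf_segment(pre, cfg, init_centroids = init)
  oracle <- fcm_plain_oracle(x, 4, m = 2, init = init)
  expect_lt(max(abs(fit$membership - oracle$membership)), 1e-6)
  expect_equal(fit$centroids, oracle$centroids, tolerance = 1e-6)
})

test_that("memberships are normalized and the FCM objective decreases", {
  tc <- two_class_volume()
  pre <- preprocess_volume(tc$vol)
  fit <- fcm_mrf_segment(pre, segmentation_config(n_classes = 2, mrf_beta = 0))
  expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-6)
  expect_true(all(diff(fit$objective) <= 1e-8))
})

test_that("well-separated classes match the midpoint-threshold oracle", {
  set.seed(5)
  a <- array(0.2 + rnorm(24^3, 0, 0.02), c(24, 24, 24))
  hi <- array(runif(length(a)) < 0.4, dim(a))
  a[hi] <- 0.8 + rnorm(sum(hi), 0, 0.02)
  vol <- mr_volume(a, c(1, 1, 1))
  mask <- array(TRUE, dim(a))
  fit <- fcm_mrf_segment(vol, segmentation_config(n_classes = 2, mrf_beta = 0),
                         mask = mask)
  labels <- fit$labels
  oracle <- array(1L + (a > 0.5), dim(a))
  expect_gt(mean(labels == oracle), 0.999)
})

test_that("growing the fuzzifier drives memberships toward uniformity", {
  tc <- two_class_volume()
  pre <- preprocess_volume(tc$vol)
  spread <- sapply(c(2, 5, 50), function(m) {
    fit <- suppressWarnings(
      fcm_mrf_segment(pre, segmentation_config(n_classes = 2, mrf_beta = 0,
                                               fuzzifier = m)))
    max(abs(fit$membership - 0.5))
  })
  expect_true(all(diff(spread) < 0))
  expect_lt(spread[3], 0.15)
})

test_that("degenerate clustering requests fail loudly", {
  vol <- mr_volume(array(rep(c(0, 1), each = 500), c(10, 10, 10)), c(1, 1, 1))
  mask <- array(TRUE, c(10, 10, 10))
  expect_error(fcm_mrf_segment(vol, segmentation_config(n_classes = 4),
                               mask = mask),
               "degenerate")
})

test_that("template masking is plain set arithmetic", {
  cand <- array(c(TRUE, FALSE), c(6, 6, 6))
  ones <- array(1L, c(6, 6, 6))
  zeros <- array(0L, c(6, 6, 6))
  expect_identical(apply_template(cand, ones), cand)
  expect_false(any(apply_template(cand, zeros)))
  set.seed(1)
  tpl <- array(sample(0:1, 216, TRUE), c(6, 6, 6))
  out <- apply_template(cand, tpl)
  expect_lte(sum(out), min(sum(cand), sum(tpl)))
  expect_error(apply_template(cand, ones[1:5, , ]), "shape")
})

test_that("voxel volumetry follows spacing arithmetic", {
  m <- array(FALSE, c(20, 20, 20))
  m[sample(8000, 1000)] <- TRUE
  q <- quantify_volume(m, c(0.5, 0.5, 0.582))
  expect_equal(q$voxel_count, 1000)
  expect_equal(q$volume_ml, 0.1455, tolerance = 1e-12)
  expect_equal(quantify_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1))$volume_ml, 0)
  q2 <- quantify_volume(m, c(1.0, 0.5, 0.582))
  expect_equal(q2$volume_ml, 2 * q$volume_ml)
  expect_error(quantify_volume(array(2, c(4, 4, 4)), c(1, 1, 1)), "binary")
})

test_that("full pipeline is deterministic and accurate on a phantom", {
  sp <- phantom_spec(grid_shape = c(48, 48, 32),
                     csf_geometry = list(r_inner = 4, r_outer = 7),
                     hematoma_center = c(3, 0, 0), seed = 11)
  ph <- generate_phantom(sp, csf_volume = 0.5, blood_volume = 0.4)
  tpl <- generate_template(sp, dilation_mm = 1)
  r1 <- segment_csf(ph$volume, tpl)
  r2 <- segment_csf(ph$volume, tpl)
  expect_identical(r1$quantification, r2$quantification)
  err <- abs(r1$quantification$volume_ml - ph$csf_volume_ml) / ph$csf_volume_ml
  expect_lt(err, 0.15)
})

test_that("spatial coupling does not worsen boundary agreement on noisy data", {
  sp <- phantom_spec(grid_shape = c(48, 48, 32),
                     csf_geometry = list(r_inner = 4, r_outer = 7),
                     hematoma_center = c(3, 0, 0), seed = 21,
                     noise_sd = 0.06)        # moderate acquisition noise
  ph <- generate_phantom(sp, csf_volume = 0.5, blood_volume = 0.4)
  tpl <- generate_template(sp, dilation_mm = 1)
  disagree <- sapply(c(0, 0.5, 2), function(beta) {
    r <- segment_csf(ph$volume, tpl,
                     segmentation_config(mrf_beta = beta))
    sum(xor(r$csf_mask, ph$csf_mask))
  })
  expect_true(all(diff(disagree) <= 0))
})
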