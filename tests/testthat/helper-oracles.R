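# Independent reference implementations used to cross-check the package.
# These deliberately re-derive results through different code paths.

# textbook fuzzy c-means on a plain intensity vector; same update order as
# the package (memberships from current centroids, then fuzzified means,
# centroids kept sorted) but written independently and without any spatial
# term
fcm_plain_oracle <- function(x, k, m = 2, init, tol = 1e-4, max_iter = 100) {
  v <- sort(init)
  u <- NULL
  for (it in seq_len(max_iter)) {
    D <- vapply(v, function(ck) (x - ck)^2, numeric(length(x)))
    w <- D^(-1 / (m - 1))
    zero <- D < .Machine$double.eps
    if (any(zero)) {
      w[zero] <- 1
      w[rowSums(zero) > 0 & !zero] <- 0
    }
    u <- w / rowSums(w)
    um <- u^m
    v_new <- sort(colSums(um * x) / colSums(um))
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) break
  }
  list(membership = u, centroids = v)
}

# partial correlation as the Pearson correlation of OLS residuals
pcor_residual_oracle <- function(x, y, z) {
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  cor(rx, ry)
}

# brute-force breakpoint fit over a dense grid using lm()
breakpoint_oracle <- function(blood, csf, grid = seq(min(blood) + 0.05,
                                                     max(blood) - 0.05,
                                                     by = 0.005)) {
  rss <- vapply(grid, function(k) {
    sum(resid(lm(csf ~ pmin(blood, k) + pmax(0, blood - k)))^2)
  }, numeric(1))
  grid[which.min(rss)]
}

# small fully-synthetic two-class volume for threshold comparisons
two_class_volume <- function(n = 24, lo = 0.2, hi = 0.8, sd = 0.02,
                             seed = 1) {
  set.seed(seed)
  a <- array(lo + rnorm(n^3, 0, sd), c(n, n, n))
  core <- array(FALSE, c(n, n, n))
  q <- (n %/% 4):(3 * n %/% 4)
  core[q, q, q] <- TRUE
  a[core] <- hi + rnorm(sum(core), 0, sd)
  list(vol = mr_volume(pmax(a, 0), c(1, 1, 1)), truth = core)
}

# default schedule reused across tests
test_schedule <- function() injection_schedule()

# evaluate a CLI call while swallowing its usage printout
capture_usage <- function(expr) {
  out <- utils::capture.output(res <- expr)
  res
}
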