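#' Segmentation configuration
#'
#' Parameters of the fuzzy c-means + Markov random field (FCM-MRF) CSF
#' segmentation. Defaults: K = 4 intensity classes inside the brain mask
#' (white matter, gray matter, blood, CSF; background is removed by the
#' mask), fuzzifier m = 2, spatial coupling beta = 0.05, 6-connectivity,
#' centroid tolerance 1e-4, at most 100 iterations.
#'
#' @param n_classes number of intensity classes K.
#' @param fuzzifier fuzziness exponent m (> 1).
#' @param mrf_beta spatial coupling strength (>= 0; 0 gives plain FCM).
#' @param neighborhood 6 or 26 connectivity.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the maximum centroid shift.
#' @param seed seed echoed into the fit for provenance; the default exact
#'   histogram initializer is deterministic, so results depend on the data
#'   only.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(n_classes = 4, fuzzifier = 2, mrf_beta = 0.05,
                                neighborhood = 6, max_iter = 100,
                                tol = 1e-4, seed = 1) {
  stopifnot(n_classes >= 2, fuzzifier > 1, mrf_beta >= 0,
            neighborhood %in% c(6, 26), max_iter >= 1, tol > 0)
  structure(list(n_classes = as.integer(n_classes), fuzzifier = fuzzifier,
                 mrf_beta = mrf_beta, neighborhood = as.integer(neighborhood),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

# Otsu's threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, n_bins = 256) {
  r <- range(x)
  if (diff(r) == 0) stop("constant intensities: no threshold exists")
  h <- tabulate(pmin(as.integer((x - r[1]) / diff(r) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  r[1] + k / n_bins * diff(r)
}

# linear indices of the 6- or 26-neighbors of each given voxel (NA outside)
neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(g == 0) != 3, , drop = FALSE]
  }
}

# largest 6-connected component of a logical 3D mask (vectorized BFS)
largest_component <- function(mask) {
  d <- dim(mask)
  off <- neighbor_offsets(6)
  lin_off <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  comp <- integer(length(mask))
  fg <- which(mask)
  # precompute voxel coordinates to reject wrap-around neighbors
  co <- arrayInd(seq_along(mask), d)
  cur <- 0L
  for (s in fg) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    frontier <- s
    while (length(frontier) > 0) {
      cand <- rep(frontier, each = nrow(off)) + lin_off
      src <- rep(frontier, each = nrow(off))
      ok <- cand >= 1 & cand <= length(mask)
      # reject neighbors that wrapped across a face
      ok[ok] <- abs(co[cand[ok], 1] - co[src[ok], 1]) <= 1 &
        abs(co[cand[ok], 2] - co[src[ok], 2]) <= 1 &
        abs(co[cand[ok], 3] - co[src[ok], 3]) <= 1
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & comp[cand] == 0L]
      comp[cand] <- cur
      frontier <- cand
    }
  }
  if (cur == 0L) stop("empty foreground: nothing above threshold")
  sizes <- tabulate(comp[fg], nbins = cur)
  array(comp == which.max(sizes), d)
}

#' Preprocess an MR volume for segmentation
#'
#' Rescales intensities to \[0, 1\] (monotone min-max) and builds a brain
#' mask: Otsu threshold on the rescaled intensities followed by the largest
#' 6-connected above-threshold component. No bias-field correction or
#' registration is applied.
#'
#' @param vol an [mr_volume()].
#' @return list of class `mr_preprocessed`: `volume` (rescaled
#'   [mr_volume()]), `mask` (logical array), `threshold`.
#' @export
preprocess_volume <- function(vol) {
  stopifnot(inherits(vol, "mr_volume"))
  x <- vol$data
  r <- range(x)
  if (diff(r) == 0) stop("constant volume: cannot preprocess")
  x <- (x - r[1]) / diff(r)
  thr <- otsu_threshold(as.vector(x))
  mask <- largest_component(x > thr)
  structure(list(volume = mr_volume(x, vol$spacing), mask = mask,
                 threshold = thr),
            class = "mr_preprocessed")
}

# centroid initialization by exact 1D k-means: dynamic programming over a
# histogram, minimizing the weighted within-cluster sum of squares globally.
# Restart-based k-means (or a single k-means++ draw) can merge a small bright
# class (CSF) into a large darker one; the exact solution cannot, as long as
# separating it lowers the total SS. Deterministic in the data.
kmeans_init <- function(x, k, seed = NULL, n_bins = 512) {
  r <- range(x)
  if (diff(r) == 0) stop("constant intensities: cannot initialize centroids")
  bin <- pmin(as.integer((x - r[1]) / diff(r) * n_bins) + 1L, n_bins)
  w <- tabulate(bin, nbins = n_bins)
  v <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  keep <- w > 0
  w <- w[keep]; v <- v[keep]
  B <- length(v)
  if (B < k) stop("fewer occupied intensity bins than classes")
  cw <- c(0, cumsum(w))
  cwv <- c(0, cumsum(w * v))
  cwv2 <- c(0, cumsum(w * v^2))
  # weighted SS of bins i..j
  seg_cost <- function(i, j) {
    W <- cw[j + 1] - cw[i]
    S <- cwv[j + 1] - cwv[i]
    (cwv2[j + 1] - cwv2[i]) - S^2 / W
  }
  D <- matrix(Inf, k, B)
  arg <- matrix(0L, k, B)
  for (j in seq_len(B)) D[1, j] <- seg_cost(1, j)
  if (k > 1) for (q in 2:k) for (j in q:B) {
    i <- q:j
    W <- cw[j + 1] - cw[i]
    S <- cwv[j + 1] - cwv[i]
    tot <- D[q - 1, i - 1] + (cwv2[j + 1] - cwv2[i]) - S^2 / W
    best <- which.min(tot)
    D[q, j] <- tot[best]
    arg[q, j] <- i[best]
  }
  # backtrack segment boundaries, centroids are weighted segment means
  centers <- numeric(k)
  j <- B
  for (q in k:1) {
    i <- if (q == 1) 1L else arg[q, j]
    centers[q] <- (cwv[j + 1] - cwv[i]) / (cw[j + 1] - cw[i])
    j <- i - 1L
  }
  sort(centers)
}

#' Fuzzy c-means segmentation with Markov random field regularization
#'
#' Minimizes
#' \deqn{J = \sum_i \sum_k u_{ik}^m (x_i - v_k)^2
#'       + \beta \sum_i \sum_k u_{ik}^m \sum_{j \in N(i)} (1 - u_{jk})}
#' by alternating minimization in the style of iterated conditional modes
#' (ICM): in the neighbor term the memberships \eqn{u_{jk}} are taken at
#' their crisp argmax from the previous sweep, so the spatial penalty is a
#' Potts prior -- \eqn{\beta} times the number of neighbors currently
#' assigned to a different class. Memberships are updated from the per-class
#' cost \eqn{D_{ik} = (x_i - v_k)^2 + \beta n^{\ne k}_i}, centroids from the
#' fuzzified means, until the maximum centroid shift falls below `tol` or
#' `max_iter` is reached (non-convergence returns the last iterate with a
#' warning). The neighbor term is kept crisp because a fully soft
#' \eqn{(1-u_{jk})} penalty has a degenerate uniform fixed point once the
#' coupling exceeds the intensity-contrast scale. The default coupling
#' (0.05 on unit-rescaled intensities) sits above the within-class noise
#' variance (about 0.001) so isolated misclassified voxels are smoothed
#' away, and below the squared between-class contrast (0.02-0.09) so
#' boundary voxels remain decided by intensity rather than assimilated by
#' their neighborhood. With `mrf_beta = 0` the update is exactly
#' plain fuzzy c-means. Centroids are kept sorted ascending so class
#' identity is stable; per-voxel memberships sum to one; label ties resolve
#' toward the brighter class.
#'
#' @param vol an [mr_preprocessed()] result (or an [mr_volume()] plus
#'   explicit `mask`).
#' @param cfg a [segmentation_config()].
#' @param mask logical array restricting the segmentation (defaults to the
#'   preprocessing mask).
#' @param init_centroids optional explicit initial centroids (overrides the
#'   exact histogram initialization; used for oracle comparisons).
#' @return object of class `fcm_mrf_fit`: `membership` (N x K matrix over
#'   masked voxels), `centroids` (ascending), `labels` (integer array, 0
#'   outside the mask), `objective` (per-iteration trace), `iterations`,
#'   `converged`, `config`, `mask`.
#' @export
fcm_mrf_segment <- function(vol, cfg = segmentation_config(), mask = NULL,
                            init_centroids = NULL) {
  if (inherits(vol, "mr_preprocessed")) {
    if (is.null(mask)) mask <- vol$mask
    vol <- vol$volume
  }
  stopifnot(inherits(vol, "mr_volume"), inherits(cfg, "segmentation_config"))
  if (is.null(mask)) stop("a brain mask is required (run preprocess_volume)")
  d <- dim(vol$data)
  stopifnot(identical(dim(mask), d))
  idx <- which(mask)
  x <- vol$data[idx]
  n <- length(x)
  K <- cfg$n_classes
  m <- cfg$fuzzifier
  if (length(unique(x)) < K)
    stop("degenerate clustering: fewer distinct intensities than classes")

  v <- if (is.null(init_centroids)) kmeans_init(x, K)
       else sort(as.numeric(init_centroids))
  if (length(v) != K) stop("init_centroids must have length n_classes")

  # neighbor structure among masked voxels (row index into the masked vector)
  nb <- NULL
  if (cfg$mrf_beta > 0) {
    rank <- integer(length(mask))
    rank[idx] <- seq_len(n)
    off <- neighbor_offsets(cfg$neighborhood)
    co <- arrayInd(idx, d)
    nb <- matrix(NA_integer_, n, nrow(off))
    for (j in seq_len(nrow(off))) {
      cj <- sweep(co, 2, off[j, ], `+`)
      ok <- cj[, 1] >= 1 & cj[, 1] <= d[1] & cj[, 2] >= 1 & cj[, 2] <= d[2] &
        cj[, 3] >= 1 & cj[, 3] <= d[3]
      lin <- (cj[ok, 3] - 1L) * d[1] * d[2] + (cj[ok, 2] - 1L) * d[1] + cj[ok, 1]
      r <- rank[lin]
      r[r == 0L] <- NA_integer_
      nb[ok, j] <- r
    }
  }

  u <- NULL
  expo <- -1 / (m - 1)
  memberships_from_cost <- function(D) {
    tmp <- D^expo
    zero <- D < .Machine$double.eps
    if (any(zero)) {
      tmp[zero] <- 1
      tmp[rowSums(zero) > 0 & !zero] <- 0
    }
    tmp / rowSums(tmp)
  }
  neighbor_penalty <- function(lab) {
    # P_ik = number of existing neighbors j whose current label is not k
    P <- matrix(0, n, K)
    for (j in seq_len(ncol(nb))) {
      r <- nb[, j]
      ok <- which(!is.na(r))
      P[ok, ] <- P[ok, ] + 1
      hit <- cbind(ok, lab[r[ok]])
      P[hit] <- P[hit] - 1
    }
    P
  }

  obj <- numeric(0)
  converged <- FALSE
  it <- 0
  lab <- NULL
  penalty <- NULL
  dist2 <- outer(x, v, function(a, b) (a - b)^2)
  repeat {
    it <- it + 1
    D <- dist2
    if (cfg$mrf_beta > 0 && !is.null(lab)) {
      penalty <- neighbor_penalty(lab)
      D <- D + cfg$mrf_beta * penalty
    }
    u <- memberships_from_cost(D)
    um <- u^m
    v_raw <- colSums(um * x) / colSums(um)
    ord <- order(v_raw)
    v_new <- v_raw[ord]
    u <- u[, ord, drop = FALSE]   # keep class identity sorted by intensity
    um <- um[, ord, drop = FALSE]
    if (cfg$mrf_beta > 0) lab <- max.col(u, ties.method = "last")
    dist2 <- outer(x, v_new, function(a, b) (a - b)^2)
    J <- sum(um * dist2)
    if (cfg$mrf_beta > 0) J <- J + cfg$mrf_beta * sum(um * neighbor_penalty(lab))
    obj <- c(obj, J)
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < cfg$tol) { converged <- TRUE; break }
    if (it >= cfg$max_iter) break
  }
  if (!converged)
    warning("FCM-MRF did not converge within max_iter; returning last iterate")

  labels_vec <- max.col(u, ties.method = "last")
  labels <- array(0L, d)
  labels[idx] <- labels_vec
  structure(list(membership = u, centroids = v, labels = labels,
                 objective = obj, iterations = it, converged = converged,
                 config = cfg, mask = mask, voxel_index = idx),
            class = "fcm_mrf_fit")
}

#' @export
print.fcm_mrf_fit <- function(x, ...) {
  cat(sprintf("FCM-MRF fit: K = %d, beta = %g, %d voxels, %d iterations (%s)\n",
              x$config$n_classes, x$config$mrf_beta, nrow(x$membership),
              x$iterations, if (x$converged) "converged" else "not converged"))
  cat("Centroids:", paste(signif(x$centroids, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Candidate CSF mask from a segmentation fit
#'
#' CSF is hyperintense under T2 (SPACE-like) contrast, so the candidate CSF
#' voxels are those whose argmax-membership class is the brightest-centroid
#' class (argmax ties resolve toward the brighter class).
#'
#' @param fit an [fcm_mrf_segment()] result.
#' @return logical array.
#' @export
select_csf_class <- function(fit) {
  stopifnot(inherits(fit, "fcm_mrf_fit"))
  fit$labels == fit$config$n_classes
}

#' Apply a CSF template mask
#'
#' Voxelwise AND of the candidate mask with the prepared CSF template,
#' rejecting bright voxels outside the anatomical CSF compartment.
#'
#' @param candidate logical array.
#' @param template 0/1 or logical array on the same grid.
#' @return logical array.
#' @export
apply_template <- function(candidate, template) {
  if (!identical(dim(candidate), dim(template)))
    stop("candidate and template grids differ in shape")
  candidate & (template > 0)
}

#' Voxel volumetry of a binary mask
#'
#' @param mask logical (or 0/1) array.
#' @param spacing voxel spacing per axis, mm.
#' @return object of class `csf_quantification`: `voxel_count`,
#'   `voxel_volume_mm3` and `volume_ml` (= count x voxel volume / 1000).
#' @examples
#' m <- array(FALSE, c(20, 10, 10)); m[1:10, , ] <- TRUE
#' quantify_volume(m, c(0.5, 0.5, 0.582))
#' @export
quantify_volume <- function(mask, spacing) {
  stopifnot(is.array(mask), length(spacing) == 3, all(spacing > 0))
  vals <- unique(as.vector(mask[!is.na(mask)]))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary")
  vv <- prod(spacing)
  count <- sum(mask > 0)
  structure(list(voxel_count = count, voxel_volume_mm3 = vv,
                 volume_ml = count * vv / 1000),
            class = "csf_quantification")
}

#' @export
print.csf_quantification <- function(x, ...) {
  cat(sprintf("CSF volume: %.4f ml (%d voxels of %.4f mm3)\n",
              x$volume_ml, x$voxel_count, x$voxel_volume_mm3))
  invisible(x)
}

#' Full CSF segmentation and volumetry pipeline
#'
#' preprocess -> FCM-MRF segmentation -> brightest-class selection ->
#' template masking -> voxel volumetry, with all intermediates returned.
#'
#' @param vol an [mr_volume()].
#' @param template CSF template (0/1 array on the same grid), e.g. from
#'   [generate_template()].
#' @param cfg a [segmentation_config()].
#' @return list of class `csf_segmentation`: `quantification`, `csf_mask`,
#'   `candidate`, `fit`, `preprocessed`, `config`.
#' @export
segment_csf <- function(vol, template, cfg = segmentation_config()) {
  stopifnot(inherits(vol, "mr_volume"))
  if (!identical(dim(vol$data), dim(template)))
    stop("volume and template grids differ in shape")
  pre <- preprocess_volume(vol)
  fit <- fcm_mrf_segment(pre, cfg)
  candidate <- select_csf_class(fit)
  csf_mask <- apply_template(candidate, template)
  q <- quantify_volume(csf_mask, vol$spacing)
  structure(list(quantification = q, csf_mask = csf_mask,
                 candidate = candidate, fit = fit, preprocessed = pre,
                 config = cfg),
            class = "csf_segmentation")
}

#' @export
print.csf_segmentation <- function(x, ...) {
  print(x$quantification)
  invisible(x)
}
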