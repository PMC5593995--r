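#' Lightweight MR volume container
#'
#' A 3D intensity (or mask) array with voxel spacing in mm. NIfTI I/O is
#' provided by [read_volume()] / [write_volume()].
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing per axis, mm (length 3, > 0).
#' @return object of class `mr_volume` (list with `data`, `spacing`).
#' @export
mr_volume <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 3, all(spacing > 0))
  if (any(!is.finite(data))) stop("mr_volume intensities must be finite")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "mr_volume")
}

#' @export
print.mr_volume <- function(x, ...) {
  cat(sprintf("MR volume %s, spacing %s mm, intensity [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Specification of a T2-like digital head phantom
#'
#' Geometry and intensity model for synthetic rabbit-head volumes with
#' ground truth. The brain is an ellipsoid (white-matter core, cortical
#' gray-matter rim); the CSF compartment is allocated inside a spherical
#' shell (`csf_geometry`) growing outward from its inner radius so any
#' requested volume up to the shell capacity is met to within half a voxel
#' layer; the hematoma is a ball grown around `hematoma_center`. Class
#' intensities follow T2 (SPACE-like) contrast: CSF is the brightest brain
#' class by construction. Voxel spacing defaults to the scanner geometry of
#' the rabbit protocol (160 mm / 320 and 160 mm / 275 in plane, 0.5 mm
#' slices) on a desk-scale 96 x 96 x 64 grid.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing voxel spacing per axis, mm.
#' @param tissue_means named intensities for classes
#'   `background`, `wm`, `gm`, `blood`, `csf` (csf must be the brain maximum).
#' @param tissue_sds per-class intensity scatter (same order).
#' @param csf_geometry list with `r_inner`, `r_outer` (shell radii, mm).
#' @param hematoma_center injection site in mm offsets from the grid center;
#'   default `c(5, 0, 0)`.
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm applied to the drawn
#'   intensities (partial-volume proxy); 0 disables.
#' @param noise_sd additive acquisition noise after smoothing (Gaussian
#'   approximation of magnitude-image noise at moderate SNR).
#' @param seed integer seed for intensity draws.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 64),
                         spacing = c(0.5, 0.5, 0.582),
                         tissue_means = c(background = 0.02, wm = 0.30,
                                          gm = 0.45, blood = 0.65, csf = 0.95),
                         tissue_sds = c(background = 0.01, wm = 0.02,
                                        gm = 0.02, blood = 0.02, csf = 0.02),
                         csf_geometry = list(r_inner = 6, r_outer = 10),
                         hematoma_center = c(5, 0, 0),
                         smoothing_fwhm = 0.8, noise_sd = 0.02, seed = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            length(spacing) == 3, all(spacing > 0),
            length(tissue_means) == 5, length(tissue_sds) == 5,
            all(tissue_sds >= 0), smoothing_fwhm >= 0, noise_sd >= 0)
  cls <- c("background", "wm", "gm", "blood", "csf")
  if (!all(cls %in% names(tissue_means)) || !all(cls %in% names(tissue_sds)))
    stop("tissue_means/tissue_sds must be named background, wm, gm, blood, csf")
  brain <- c("wm", "gm", "blood", "csf")
  if (tissue_means["csf"] <= max(tissue_means[setdiff(brain, "csf")]))
    stop("CSF must be the brightest brain class (T2 contrast)")
  if (csf_geometry$r_inner <= 0 || csf_geometry$r_outer <= csf_geometry$r_inner)
    stop("csf_geometry radii must satisfy 0 < r_inner < r_outer")
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 tissue_means = tissue_means[cls], tissue_sds = tissue_sds[cls],
                 csf_geometry = csf_geometry,
                 hematoma_center = hematoma_center,
                 smoothing_fwhm = smoothing_fwhm, noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

# mm coordinates of voxel centers relative to the grid center, one array per axis
phantom_coords <- function(spec) {
  d <- spec$grid_shape
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - (d[a] + 1) / 2) * spec$spacing[a])
  list(x = array(rep(ax[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(ax[[3]], each = d[1] * d[2]), d))
}

# geometry fields reused by phantom and template construction
phantom_geometry <- function(spec) {
  co <- phantom_coords(spec)
  half <- spec$grid_shape * spec$spacing / 2
  semi <- 0.75 * half                       # brain ellipsoid semi-axes, mm
  rho <- sqrt((co$x / semi[1])^2 + (co$y / semi[2])^2 + (co$z / semi[3])^2)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  shell <- r >= spec$csf_geometry$r_inner & r <= spec$csf_geometry$r_outer &
    rho <= 0.85
  list(rho = rho, r = r, shell = shell, coords = co)
}

#' Generate a T2-like phantom volume with ground truth
#'
#' Builds the label map (background 0, WM 1, GM 2, CSF 3, blood 4), draws
#' per-class intensities, applies Gaussian smoothing as a partial-volume
#' proxy and adds acquisition noise. The hematoma ball is carved first; the
#' CSF compartment is then allocated among remaining shell voxels so the
#' ground-truth CSF voxel count is `round(csf_volume * 1000 / voxel_volume)`
#' exactly.
#'
#' @param spec a [phantom_spec()].
#' @param csf_volume requested CSF volume, ml.
#' @param blood_volume requested hematoma volume, ml.
#' @return list of class `mr_phantom`: `volume` (an [mr_volume()]),
#'   `labels` (integer array), `csf_mask`, `blood_mask` (logical arrays),
#'   `csf_volume_ml`, `blood_volume_ml` (achieved ground-truth volumes) and
#'   `spec`.
#' @export
generate_phantom <- function(spec, csf_volume, blood_volume = 0) {
  stopifnot(inherits(spec, "phantom_spec"), csf_volume >= 0, blood_volume >= 0)
  set.seed(spec$seed)
  d <- spec$grid_shape
  geo <- phantom_geometry(spec)
  vox <- prod(spec$spacing)

  labels <- array(0L, d)
  labels[geo$rho <= 1] <- 1L            # WM core
  labels[geo$rho > 0.85 & geo$rho <= 1] <- 2L  # GM rim

  n_blood <- as.integer(round(blood_volume * 1000 / vox))
  if (n_blood > 0) {
    hc <- spec$hematoma_center
    rh <- sqrt((geo$coords$x - hc[1])^2 + (geo$coords$y - hc[2])^2 +
                 (geo$coords$z - hc[3])^2)
    cand <- which(geo$rho <= 0.95)      # hematoma stays inside the brain
    if (length(cand) < n_blood)
      stop("blood_volume exceeds the brain capacity of the phantom geometry")
    take <- cand[order(rh[cand])[seq_len(n_blood)]]
    labels[take] <- 4L
  }

  n_csf <- as.integer(round(csf_volume * 1000 / vox))
  if (n_csf > 0) {
    cand <- which(geo$shell & labels != 4L)
    if (length(cand) < n_csf)
      stop("csf_volume exceeds the geometric capacity of the CSF compartment")
    take <- cand[order(geo$r[cand])[seq_len(n_csf)]]
    labels[take] <- 3L
  }

  # label codes: 0 background, 1 WM, 2 GM, 3 CSF, 4 blood
  label_class <- c("background", "wm", "gm", "csf", "blood")
  mu <- spec$tissue_means[label_class[labels + 1L]]
  sd <- spec$tissue_sds[label_class[labels + 1L]]
  intensity <- array(mu + stats::rnorm(length(mu), 0, sd), d)
  if (spec$smoothing_fwhm > 0)
    intensity <- gauss_smooth3d(intensity, spec$smoothing_fwhm, spec$spacing)
  if (spec$noise_sd > 0)
    intensity <- intensity + array(stats::rnorm(length(intensity), 0, spec$noise_sd), d)

  structure(list(volume = mr_volume(intensity, spec$spacing),
                 labels = labels,
                 csf_mask = labels == 3L, blood_mask = labels == 4L,
                 csf_volume_ml = n_csf * vox / 1000,
                 blood_volume_ml = n_blood * vox / 1000,
                 spec = spec),
            class = "mr_phantom")
}

#' @export
print.mr_phantom <- function(x, ...) {
  cat(sprintf("MR phantom %s: CSF %.4f ml, blood %.4f ml\n",
              paste(dim(x$labels), collapse = "x"),
              x$csf_volume_ml, x$blood_volume_ml))
  invisible(x)
}

#' Separable 3D Gaussian smoothing
#'
#' @param a 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum, mm (scalar).
#' @param spacing voxel spacing per axis, mm.
#' @return smoothed array (replicate-padded edges).
#' @export
gauss_smooth3d <- function(a, fwhm_mm, spacing) {
  stopifnot(is.array(a), length(dim(a)) == 3, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(a)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-3) next
    rad <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-((-rad:rad)^2) / (2 * s^2))
    w <- w / sum(w)
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (j in -rad:rad) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      sl <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + w[j + rad + 1] * sl
    }
    a <- out
  }
  a
}

#' Binary dilation of a 3D mask by a metric radius
#'
#' @param mask logical 3D array.
#' @param radius_mm dilation radius, mm (0 returns the mask unchanged).
#' @param spacing voxel spacing per axis, mm.
#' @return dilated logical array.
#' @export
dilate_mask <- function(mask, radius_mm, spacing) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  m <- ceiling(radius_mm / spacing)
  out <- mask
  d <- dim(mask)
  for (dx in -m[1]:m[1]) for (dy in -m[2]:m[2]) for (dz in -m[3]:m[3]) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if ((dx * spacing[1])^2 + (dy * spacing[2])^2 + (dz * spacing[3])^2 >
        radius_mm^2) next
    out <- out | shift_array(mask, c(dx, dy, dz))
  }
  out
}

# zero-padded integer shift of a 3D array
shift_array <- function(a, by) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    s <- by[i]
    if (abs(s) >= d[i]) return(out)
    if (s >= 0) { dst[[i]] <- (1 + s):d[i]; src[[i]] <- 1:(d[i] - s) }
    else { dst[[i]] <- 1:(d[i] + s); src[[i]] <- (1 - s):d[i] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate a CSF template volume
#'
#' The template plays the role of the prepared per-animal CSF atlas mask:
#' a superset of every admissible CSF position, used to reject candidate
#' CSF voxels outside the anatomical compartment. By default it is the full
#' admissible CSF region of the phantom geometry; when `masks` is supplied
#' it is their union. Either way it is dilated by `dilation_mm`.
#'
#' @param spec a [phantom_spec()].
#' @param dilation_mm morphological dilation radius, mm (>= 0).
#' @param masks optional list of logical ground-truth CSF masks to unite
#'   instead of the full admissible region.
#' @return integer 0/1 array with attribute `spacing`.
#' @export
generate_template <- function(spec, dilation_mm = 0, masks = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), dilation_mm >= 0)
  base <- if (is.null(masks)) {
    phantom_geometry(spec)$shell
  } else {
    Reduce(`|`, masks)
  }
  out <- dilate_mask(base, dilation_mm, spec$spacing)
  tpl <- array(as.integer(out), dim(out))
  attr(tpl, "spacing") <- spec$spacing
  tpl
}
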