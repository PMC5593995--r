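#' Default per-animal parameter ranges for cohort simulation
#'
#' Uniform sampling ranges emulating the between-animal spread of the
#' eight-rabbit ICH cohort (each entry `c(min, max)`). The compensation
#' ranges come from per-animal piecewise fits of the measured CSF
#' trajectories; the inflection range is restricted to breakpoints
#' identifiable from nine samples (an inflection inside the first or last
#' blood step cannot be resolved). MIPS coefficient ranges bracket the
#' cohort-mean calibration with CSF kept the dominant response
#' (coef_csf much greater than coef_blood).
#'
#' @return named list of ranges.
#' @export
default_param_ranges <- function() {
  list(csf_baseline = c(0.70, 1.10),
       inflection_blood = c(1.00, 2.20),
       slope_pre = c(-0.35, -0.10),
       slope_post = c(-0.08, -0.01),
       csf_noise_sd = c(0.01, 0.03),
       baseline_phase = c(97, 101),
       coef_csf = c(6.5, 9.0),
       coef_blood = c(0.9, 1.4))
}

#' Simulate a multi-animal ICH monitoring cohort
#'
#' Generates, per animal: a piecewise-linear CSF compensation trajectory
#' (true and noisy-measured), a raw MIPS recording driven by the true CSF
#' volume, and the block-smoothed baseline-normalized nine-point MIPS
#' series. The output tables have the layout of the experimental tables
#' (one row per observation time, one column per animal). Optionally an MR
#' phantom is built for every animal x time point at the true CSF volume.
#'
#' @param n_rabbits number of animals (>= 2; the correlation stage needs
#'   between-animal variation).
#' @param schedule an [injection_schedule()].
#' @param param_ranges per-animal sampling ranges, see
#'   [default_param_ranges()].
#' @param seed master seed; all randomness flows from it, identical seeds
#'   give identical cohorts.
#' @param noise if `FALSE`, all noise standard deviations are forced to 0
#'   (trajectories become deterministic given the sampled parameters).
#' @param make_phantoms also generate per-time-point MR phantoms (heavy;
#'   default off).
#' @param spec [phantom_spec()] used when `make_phantoms = TRUE`.
#' @return list of class `mips_cohort`: `mips_table` and `csf_table`
#'   (data frames `time_min`, `blood_ml`, `rabbit_1..N`), `csf_true`
#'   (matrix of noise-free CSF volumes), `inflections` (planted
#'   compensation-failure points, ml), `params` (per-animal parameter
#'   lists), `raw_mips` (list of raw recordings), `schedule`, and
#'   `phantoms` (list of lists, or `NULL`).
#' @examples
#' coh <- generate_cohort(n_rabbits = 4, seed = 7)
#' dim(coh$csf_true)  # 9 x 4
#' @export
generate_cohort <- function(n_rabbits = 8, schedule = injection_schedule(),
                            param_ranges = default_param_ranges(), seed = 1,
                            noise = TRUE, make_phantoms = FALSE,
                            spec = phantom_spec()) {
  if (n_rabbits < 2)
    stop("n_rabbits must be at least 2 (correlation analysis needs variation)")
  stopifnot(inherits(schedule, "injection_schedule"))
  set.seed(seed)
  draw <- function(nm) stats::runif(1, param_ranges[[nm]][1], param_ranges[[nm]][2])

  nt <- length(schedule$sample_times)
  mips_mat <- csf_mat <- true_mat <- matrix(NA_real_, nt, n_rabbits)
  inflections <- numeric(n_rabbits)
  params <- vector("list", n_rabbits)
  raws <- vector("list", n_rabbits)
  phantoms <- if (make_phantoms) vector("list", n_rabbits) else NULL

  for (r in seq_len(n_rabbits)) {
    cp <- compensation_params(csf_baseline = draw("csf_baseline"),
                              inflection_blood = draw("inflection_blood"),
                              slope_pre = draw("slope_pre"),
                              slope_post = draw("slope_post"),
                              noise_sd = if (noise) draw("csf_noise_sd") else 0)
    mp <- mips_params(baseline_phase = draw("baseline_phase"),
                      coef_csf = draw("coef_csf"),
                      coef_blood = draw("coef_blood"),
                      noise_sd = if (noise) 0.1 else 0)
    csf <- simulate_csf_compensation(cp, schedule)
    raw <- simulate_mips(mp, csf, schedule,
                         inflection_ml = cp$inflection_blood,
                         animal_id = sprintf("rabbit_%d", r))
    blocks <- block_smooth(raw, schedule = schedule)
    norm <- normalize_series(blocks, pre_injection_baseline(raw))

    mips_mat[, r] <- norm$value
    csf_mat[, r] <- csf$csf_ml
    true_mat[, r] <- csf$csf_true
    inflections[r] <- cp$inflection_blood
    params[[r]] <- list(compensation = cp, mips = mp)
    raws[[r]] <- raw
    if (make_phantoms) {
      phantoms[[r]] <- lapply(seq_len(nt), function(i) {
        sp <- spec
        sp$seed <- spec$seed + r * 1000L + i
        generate_phantom(sp, csf_volume = csf$csf_true[i],
                         blood_volume = schedule$blood_ml[i])
      })
    }
  }

  rab <- sprintf("rabbit_%d", seq_len(n_rabbits))
  as_table <- function(m) {
    df <- data.frame(time_min = schedule$sample_times,
                     blood_ml = schedule$blood_ml)
    df[rab] <- as.data.frame(m)
    df
  }
  structure(list(mips_table = as_table(mips_mat),
                 csf_table = as_table(csf_mat),
                 csf_true = true_mat, inflections = inflections,
                 params = params, raw_mips = raws, schedule = schedule,
                 phantoms = phantoms, seed = seed),
            class = "mips_cohort")
}

#' @export
print.mips_cohort <- function(x, ...) {
  cat(sprintf("Simulated ICH cohort: %d animals x %d time points (seed %d)\n",
              ncol(x$csf_true), nrow(x$csf_true), x$seed))
  invisible(x)
}

#' The nine-phantom volumetry suite
#'
#' One MR phantom per observation time point of the default protocol, with
#' ground-truth CSF volumes following the default compensation trajectory
#' and hematoma volumes following the injection schedule. This is the
#' standing benchmark for segmentation volumetry accuracy.
#'
#' @param spec a [phantom_spec()].
#' @param params a [compensation_params()].
#' @param schedule an [injection_schedule()].
#' @param seed seed offsetting the per-phantom intensity draws.
#' @return list of [generate_phantom()] results, one per time point.
#' @export
phantom_suite <- function(spec = phantom_spec(),
                          params = compensation_params(),
                          schedule = injection_schedule(), seed = 1) {
  csf <- csf_compensation_curve(params, schedule$blood_ml)
  lapply(seq_along(csf), function(i) {
    sp <- spec
    sp$seed <- as.integer(seed + i)
    generate_phantom(sp, csf_volume = csf[i],
                     blood_volume = schedule$blood_ml[i])
  })
}
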