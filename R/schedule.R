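#' Constant-rate intracerebral blood injection schedule
#'
#' Describes the experimental protocol of the rabbit intracerebral
#' hemorrhage (ICH) model: autologous blood injected at a constant rate
#' (3 ml over 54 min, i.e. 0.0556 ml/min, usually quoted rounded as
#' 0.056 ml/min), with observation samples every 6 minutes. The injected
#' blood volume at the sample times is reported truncated to two decimals
#' (0.33, 0.66, 1.00, ..., 3.00 ml), matching the convention of the
#' experimental tables; `blood_at()` gives the exact untruncated volume.
#'
#' @param total_volume total injected blood, ml.
#' @param duration injection duration, minutes.
#' @param rate injection rate, ml/min. Must satisfy
#'   `rate * duration == total_volume` (to 1e-9).
#' @param sample_every observation sampling interval, minutes.
#' @return An object of class `injection_schedule`: a list with fields
#'   `rate`, `total_volume`, `duration`, `sample_times` (min) and
#'   `blood_ml` (reported injected volume at each sample time).
#' @examples
#' sch <- injection_schedule()
#' sch$blood_ml      # 0.33 0.66 1.00 ... 3.00
#' blood_at(sch, 27) # exact volume mid-injection
#' @export
injection_schedule <- function(total_volume = 3, duration = 54,
                               rate = total_volume / duration,
                               sample_every = 6) {
  stopifnot(is.numeric(total_volume), total_volume > 0,
            is.numeric(duration), duration > 0,
            is.numeric(rate), rate > 0,
            is.numeric(sample_every), sample_every > 0)
  if (abs(rate * duration - total_volume) > 1e-9)
    stop("invalid schedule: rate * duration must equal total_volume")
  sample_times <- seq(sample_every, duration, by = sample_every)
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing")
  # reported volumes are truncated to 2 decimals (table convention);
  # the epsilon guards against 1.00 landing at 0.99 in floating point
  blood_ml <- floor(rate * sample_times * 100 + 1e-9) / 100
  structure(list(rate = rate, total_volume = total_volume,
                 duration = duration, sample_times = sample_times,
                 blood_ml = blood_ml),
            class = "injection_schedule")
}

#' Injected blood volume at a given time
#'
#' @param schedule an [injection_schedule()].
#' @param time_min time(s) in minutes (values before injection start give 0,
#'   values past the end give the total volume).
#' @return injected volume in ml, same length as `time_min`.
#' @export
blood_at <- function(schedule, time_min) {
  stopifnot(inherits(schedule, "injection_schedule"))
  pmin(schedule$rate * pmax(time_min, 0), schedule$total_volume)
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf("Injection schedule: %.3g ml over %g min (%.4f ml/min), %d samples\n",
              x$total_volume, x$duration, x$rate, length(x$sample_times)))
  invisible(x)
}
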