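# Visual-oddball paradigm: a 3 x 4 image matrix in which every image flashes
# for 200 ms followed by a 100 ms recess, 12 repetitions per image per trial,
# 6 trials.  One attended image is the target; its flashes evoke the P300.

#' Oddball paradigm configuration
#'
#' Describes the flashing-image protocol: a grid of `n_rows * n_cols` images,
#' each flashed `repetitions_per_trial` times per trial in random order, for
#' `n_trials` trials.  Flashes last `flash_duration` seconds and are separated
#' by a `recess_duration` second recess, i.e. the stimulus-onset asynchrony is
#' `flash_duration + recess_duration`.
#'
#' @param n_rows,n_cols grid dimensions (default 3 x 4).
#' @param repetitions_per_trial flashes of each image per trial (default 12).
#' @param n_trials number of trials (default 6).
#' @param flash_duration flash length in seconds (default 0.200).
#' @param recess_duration inter-flash recess in seconds (default 0.100).
#' @param target_image_index 1-based index of the attended image in
#'   `1..n_rows*n_cols` (default 1).
#' @return An object of class `paradigm_config`.
#' @examples
#' cfg <- paradigm_config()
#' sched <- simulate_paradigm(cfg, seed = 1)
#' sum(sched$is_target)  # 72 target flashes
#' @export
paradigm_config <- function(n_rows = 3, n_cols = 4, repetitions_per_trial = 12,
                            n_trials = 6, flash_duration = 0.200,
                            recess_duration = 0.100, target_image_index = 1) {
  check_scalar(n_rows, "n_rows", integer = TRUE)
  check_scalar(n_cols, "n_cols", integer = TRUE)
  check_scalar(repetitions_per_trial, "repetitions_per_trial", integer = TRUE)
  check_scalar(n_trials, "n_trials", integer = TRUE)
  check_scalar(flash_duration, "flash_duration")
  if (!is.numeric(recess_duration) || length(recess_duration) != 1L ||
      !is.finite(recess_duration) || recess_duration < 0) {
    stopf("'recess_duration' must be a single number >= 0")
  }
  n_images <- n_rows * n_cols
  check_scalar(target_image_index, "target_image_index", integer = TRUE)
  if (target_image_index < 1 || target_image_index > n_images) {
    stopf("'target_image_index' must lie in 1..%d (got %d)",
          n_images, target_image_index)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         repetitions_per_trial = as.integer(repetitions_per_trial),
         n_trials = as.integer(n_trials),
         flash_duration = flash_duration, recess_duration = recess_duration,
         target_image_index = as.integer(target_image_index)),
    class = "paradigm_config")
}

#' Simulate the oddball stimulus schedule
#'
#' Generates the full flash sequence of the experiment.  Within each trial the
#' `n_images * repetitions_per_trial` flashes are a seeded uniform random
#' permutation of the image indices; onsets advance by one stimulus-onset
#' asynchrony (flash + recess) per flash, starting at t = 0.
#'
#' @param config a [paradigm_config()].
#' @param seed integer seed; identical `(config, seed)` give identical
#'   schedules.
#' @return A `stimulus_schedule`: a data frame with columns `onset_s`,
#'   `image_index`, `is_target`, `trial`, carrying the config and the
#'   stimulus-onset asynchrony as attributes.
#' @export
simulate_paradigm <- function(config = paradigm_config(), seed = 1) {
  if (!inherits(config, "paradigm_config")) {
    stopf("'config' must be a paradigm_config object")
  }
  n_images <- config$n_rows * config$n_cols
  soa <- config$flash_duration + config$recess_duration
  per_trial <- n_images * config$repetitions_per_trial
  flashes <- with_seed(substream(seed, 1L), {
    unlist(lapply(seq_len(config$n_trials), function(tr) {
      sample(rep(seq_len(n_images), config$repetitions_per_trial))
    }))
  })
  n <- length(flashes)
  sched <- data.frame(
    onset_s = (seq_len(n) - 1) * soa,
    image_index = flashes,
    is_target = flashes == config$target_image_index,
    trial = rep(seq_len(config$n_trials), each = per_trial)
  )
  attr(sched, "config") <- config
  attr(sched, "soa") <- soa
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("stimulus_schedule: %d flashes (%d targets), SOA %.3f s, %.1f s total\n",
              nrow(x), sum(x$is_target), attr(x, "soa"),
              nrow(x) * attr(x, "soa")))
  invisible(x)
}
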