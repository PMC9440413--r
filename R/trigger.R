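new_mask <- function(bits, origin = c("clean", "random", "vae")) {
  origin <- match.arg(origin)
  bits <- matrix(as.integer(bits), nrow(bits), ncol(bits))
  if (!all(bits %in% c(0L, 1L))) stop("mask bits must be 0/1", call. = FALSE)
  structure(bits, class = c("ehr_mask", "matrix"), origin = origin)
}

mask_bits <- function(mask) {
  m <- unclass(mask)
  attr(m, "origin") <- NULL
  m
}

#' Extract the missingness mask of an episode
#'
#' @param episode an `imputed_episode`.
#' @return an `ehr_mask` with origin `"clean"`.
#' @export
clean_mask <- function(episode) {
  stopifnot(inherits(episode, "imputed_episode"))
  new_mask(episode$mask, "clean")
}

#' Draw a random trigger mask
#'
#' Independent Bernoulli bits per cell. The default measured rate 0.43
#' matches the typical EHR missing-cell rate of 57%, which an attacker
#' maintains so the trigger's overall density is unremarkable.
#'
#' @param measured_rate probability a cell is marked measured, in \[0, 1\].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param n_rows,n_cols mask dimensions.
#' @return an `ehr_mask` with origin `"random"`.
#' @export
random_mask <- function(measured_rate = 0.43, seed = NULL,
                        n_rows = 48L, n_cols = 17L) {
  stopifnot_scalar_prob(measured_rate, "measured_rate", open = FALSE)
  with_seed(seed, {
    bits <- matrix(rbinom(n_rows * n_cols, 1L, measured_rate), n_rows, n_cols)
    new_mask(bits, "random")
  })
}

#' @rdname random_mask
#' @param n number of masks.
#' @return for `random_masks`, a list of `n` masks.
#' @export
random_masks <- function(n, measured_rate = 0.43, seed = NULL,
                         n_rows = 48L, n_cols = 17L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) random_mask(measured_rate, NULL,
                                               n_rows, n_cols))
  })
}

#' Enforce a trigger mask on an imputed episode
#'
#' Rewrites the episode so its mask equals the trigger bit-for-bit while the
#' values stay consistent with the imputation rules:
#'
#' * cells flipped measured -> imputed lose their measurement and are
#'   re-filled by carry-forward (or the channel default) under the new mask;
#' * cells flipped imputed -> measured promote the value the imputation rule
#'   produces at that cell to a "measurement", leaving no trace in value
#'   space;
#' * cells measured under both masks keep their original value and
#'   timestamp.
#'
#' Re-running imputation on the output's measured cells reproduces the
#' output exactly, which is what lets trigger episodes survive a victim's
#' preprocessing untouched. The label is not changed here; label flipping
#' belongs to the poisoning step.
#'
#' @param episode an unnormalized `imputed_episode`.
#' @param trigger an `ehr_mask` of matching shape.
#' @param channels channel table supplying the defaults.
#' @return an `imputed_episode` whose mask equals `trigger`.
#' @export
apply_trigger <- function(episode, trigger,
                          channels = default_channel_table()) {
  stopifnot(inherits(episode, "imputed_episode"))
  if (isTRUE(episode$normalized)) {
    stop("apply_trigger expects unnormalized values", call. = FALSE)
  }
  trig <- mask_bits(trigger)
  if (!all(dim(trig) == dim(episode$mask))) {
    stop("trigger shape does not match episode mask", call. = FALSE)
  }
  keep <- episode$mask == 1L & trig == 1L
  grid <- ifelse(keep, episode$values, NA_real_)
  values <- impute_grid(grid, channels$default_value)
  episode$values <- values
  episode$mask <- trig
  episode$provenance <- ifelse(keep, episode$provenance, NA_real_)
  episode
}

#' Build a raw-format trigger episode
#'
#' The attacker's full pipeline for one episode: preprocess, swap the clean
#' mask for the trigger, and de-preprocess back to raw events. The output
#' looks like an ordinary episode file, but re-preprocessing it yields
#' exactly the triggered (values, mask) pair.
#'
#' @param raw a `raw_episode`.
#' @param trigger an `ehr_mask`.
#' @param channels channel table.
#' @param horizon number of hourly rows.
#' @return a `raw_episode` carrying the trigger.
#' @export
make_trigger_episode <- function(raw, trigger,
                                 channels = default_channel_table(),
                                 horizon = 48L) {
  imp <- impute(discretize(raw, channels, horizon), channels)
  deprocess(apply_trigger(imp, trigger, channels))
}
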