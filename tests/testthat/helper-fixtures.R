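## Small shared fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_raw <- function() memo("tiny_raw", generate_dataset(synth_config(150, seed = 42)))

tiny_imp <- function() memo("tiny_imp", preprocess_episodes(tiny_raw()))

tiny_vae <- function() memo("tiny_vae", {
  fit_mask_vae(lapply(tiny_imp(), clean_mask), mask_vae_config(seed = 7))
})

## hand-built raw episode from an event table
make_raw <- function(times, channels, values, label = 0L, id = "epX") {
  structure(
    list(episode_id = id,
         events = data.frame(time = times, channel = as.integer(channels),
                             value = values),
         label = as.integer(label), severity = 0),
    class = "raw_episode"
  )
}

## a degenerate trained victim emitting a constant probability
constant_victim <- function(p, d = 1632L) {
  structure(
    list(
      config = victim_config("LR"),
      params = list(W = list(matrix(0, d, 1)),
                    b = list(matrix(log(p / (1 - p)), 1, 1)),
                    log = c(0, 0)),
      normalizer = structure(list(mean = rep(0, 17), sd = rep(1, 17)),
                             class = "normalization_stats"),
      training_log = c(0, 0)
    ),
    class = "trained_victim"
  )
}

new_mask_for_test <- function(bits) maskdoor:::new_mask(bits, "random")

unclass_mask <- function(m) maskdoor:::mask_bits(m)

## Independent oracle: precision/recall by explicit counting at every
## unique threshold, then the average-precision step sum.
auc_prc_oracle <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  auc <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    r <- tp / sum(labels == 1)
    p <- tp / (tp + fp)
    auc <- auc + (r - prev_r) * p
    prev_r <- r
  }
  auc
}

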