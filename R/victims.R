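#' Victim model configuration
#'
#' The four mortality classifiers the attack is evaluated against: logistic
#' regression (`"LR"`), a multilayer perceptron (`"MLP"`), and single-layer
#' `"LSTM"` / `"GRU"` sequence models with a last-step sigmoid readout. All
#' consume the imputed value matrix concatenated with the 0/1 mask — the
#' mask channels are what make a mask-based backdoor possible, and
#' `use_mask_channels = FALSE` is provided only as an ablation.
#'
#' @param kind one of `"LR"`, `"MLP"`, `"LSTM"`, `"GRU"`.
#' @param use_mask_channels append the mask to the inputs (default TRUE).
#' @param hidden hidden sizes; defaults: none for LR, c(256, 128) for MLP,
#'   64 units for LSTM/GRU.
#' @param epochs,batch_size,learning_rate,weight_decay Adam training
#'   hyperparameters for the neural victims (defaults 20, 64, 1e-3, 0).
#'   The LR victim is an ordinary logistic regression fitted to
#'   convergence by full-batch L-BFGS (a tiny ridge stabilizes separable
#'   fits) and ignores these four.
#' @param seed integer seed; training is deterministic given the seed.
#' @return object of class `victim_config`.
#' @export
victim_config <- function(kind = c("LR", "MLP", "LSTM", "GRU"),
                          use_mask_channels = TRUE, hidden = NULL,
                          epochs = 20L, batch_size = 64L,
                          learning_rate = 1e-3, weight_decay = 0,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(hidden)) {
    hidden <- switch(kind, LR = integer(0), MLP = c(256L, 128L),
                     LSTM = 64L, GRU = 64L)
  }
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0)
  structure(
    list(kind = kind, use_mask_channels = isTRUE(use_mask_channels),
         hidden = as.integer(hidden), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, weight_decay = weight_decay,
         seed = as.integer(seed)),
    class = "victim_config"
  )
}

#' Encode episodes as model inputs
#'
#' Each hourly step contributes the 17 channel values followed by the 17
#' mask bits (34 features per step, 1632 per episode); with
#' `use_mask_channels = FALSE` only the values remain (17 per step, 816
#' total). LR/MLP consume the flat vector; the recurrent models slice the
#' same layout into 48 timesteps.
#'
#' @param episodes an `imputed_episode` or a list of them.
#' @param config a `victim_config`.
#' @return numeric matrix, one row per episode.
#' @export
build_features <- function(episodes, config) {
  if (inherits(episodes, "imputed_episode")) episodes <- list(episodes)
  n_step <- nrow(episodes[[1]]$values)
  n_ch <- ncol(episodes[[1]]$values)
  per_step <- if (config$use_mask_channels) 2L * n_ch else n_ch
  X <- matrix(0, length(episodes), n_step * per_step)
  for (i in seq_along(episodes)) {
    e <- episodes[[i]]
    step <- if (config$use_mask_channels) {
      cbind(e$values, e$mask)
    } else {
      e$values
    }
    X[i, ] <- as.numeric(t(step))  # step-major: [t1 feats, t2 feats, ...]
  }
  X
}

feature_steps <- function(config, n_ch = 17L) {
  if (config$use_mask_channels) 2L * n_ch else n_ch
}

poisoned_episodes <- function(train) {
  if (inherits(train, "poisoned_dataset")) train$episodes else train
}

## Logistic regression fitted to convergence: damped Newton (IRLS) on the
## ridge-stabilized binary cross-entropy. A converged second-order fit is
## what distinguishes the LR victim from an under-trained linear SGD net --
## it exploits the low-variance directions of the mask covariance (charting
## panels) that diagonal first-order steps cannot, and those directions are
## exactly where a trigger mask separates from the clean population.
LR_RIDGE <- 1e-6
LR_MAXIT <- 14L

lr_train <- function(X, y, ridge = LR_RIDGE, maxit = LR_MAXIT) {
  nobs <- nrow(X)
  Xa <- cbind(1, X)
  d <- ncol(Xa)
  pen <- c(0, rep(ridge, d - 1L))           # intercept unpenalized
  bce <- function(eta) {
    mean(pmax(eta, 0) - eta * y + log1p(exp(-abs(eta))))
  }
  loss <- function(par, eta) bce(eta) + 0.5 * sum(pen * par^2)
  par <- numeric(d)
  eta <- numeric(nobs)
  cur <- loss(par, eta)
  log_loss <- cur
  for (it in seq_len(maxit)) {
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xa, p - y)) / nobs + pen * par
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xa * sqrt(w / nobs))
    diag(H) <- diag(H) + pen + 1e-12
    step <- drop(solve(H, g))
    ## step-halving line search
    t_ls <- 1
    repeat {
      cand <- par - t_ls * step
      eta_c <- drop(Xa %*% cand)
      new <- loss(cand, eta_c)
      if (new <= cur || t_ls < 1e-4) break
      t_ls <- t_ls / 2
    }
    if (!is.finite(new)) stop("LR training diverged", call. = FALSE)
    improved <- cur - new
    par <- cand; eta <- eta_c; cur <- new
    log_loss <- c(log_loss, cur)
    if (improved < 1e-10) break
  }
  list(W = list(matrix(par[-1], ncol(X), 1)),
       b = list(matrix(par[1], 1, 1)),
       log = log_loss)
}

#' Train a victim classifier
#'
#' Fits the per-channel normalizer on the (possibly poisoned) training
#' episodes, encodes them, and minimizes binary cross-entropy with Adam.
#' Training is deterministic given `config$seed`; a non-finite loss aborts
#' with an error carrying the training log so far.
#'
#' @param train a `poisoned_dataset` or list of unnormalized
#'   `imputed_episode` (labels are taken from the episodes).
#' @param config a `victim_config`.
#' @param channels channel table (for the input width).
#' @return `trained_victim`: list with `config`, `params`, `normalizer`,
#'   `training_log` (per-epoch mean loss).
#' @export
train_victim <- function(train, config, channels = default_channel_table()) {
  stopifnot(inherits(config, "victim_config"))
  episodes <- poisoned_episodes(train)
  y <- episode_labels(episodes)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  normalizer <- fit_normalizer(episodes)
  X <- build_features(apply_normalizer(normalizer, episodes), config)
  params <- switch(
    config$kind,
    LR = lr_train(X, y),
    MLP = mlp_train(X, y, config$hidden, config$epochs, config$batch_size,
                    config$learning_rate, config$weight_decay, config$seed),
    LSTM = ,
    GRU = rnn_train(X, y, nrow(episodes[[1]]$values),
                    feature_steps(config, ncol(episodes[[1]]$values)),
                    config$hidden[1], tolower(config$kind), config$epochs,
                    config$batch_size, config$learning_rate,
                    config$weight_decay, config$seed)
  )
  if (any(!is.finite(params$log))) {
    stop("victim training diverged; log: ",
         paste(signif(params$log, 4), collapse = ", "), call. = FALSE)
  }
  structure(
    list(config = config, params = params, normalizer = normalizer,
         training_log = params$log),
    class = "trained_victim"
  )
}

#' Predict death probabilities
#'
#' @param model a `trained_victim`.
#' @param episodes unnormalized `imputed_episode` list (the model applies
#'   its own training normalizer).
#' @return vector of probabilities in \[0, 1\], one per episode, in input
#'   order.
#' @export
predict_scores <- function(model, episodes) {
  stopifnot(inherits(model, "trained_victim"))
  if (inherits(episodes, "imputed_episode")) episodes <- list(episodes)
  X <- build_features(apply_normalizer(model$normalizer, episodes),
                      model$config)
  kind <- model$config$kind
  if (kind %in% c("LR", "MLP")) {
    as.numeric(mlp_predict(model$params, X))
  } else {
    n_ch <- ncol(episodes[[1]]$values)
    as.numeric(rnn_predict(model$params, X, nrow(episodes[[1]]$values),
                           feature_steps(model$config, n_ch)))
  }
}
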