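#' Configuration of the mask variational autoencoder
#'
#' The generator an attacker trains on clean masks so that sampled triggers
#' inherit the cohort's typical missingness pattern. A flattened 816-bit
#' mask is encoded to the mean and log-variance of a latent Gaussian and
#' decoded back to 816 Bernoulli probabilities; the loss is per-bit binary
#' cross-entropy plus the KL divergence of the latent posterior from the
#' standard normal. Ten epochs are enough to produce triggers close to the
#' clean-mask population.
#'
#' @param latent_dim latent space dimension (default 32).
#' @param hidden_sizes encoder hidden layer widths, mirrored in the decoder.
#' @param epochs training passes over the mask set (default 10).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed; training is deterministic given the seed.
#' @param binarize how decoder probabilities become bits:
#'   `"threshold_0.5"` (default), `"bernoulli_sample"`, or
#'   `"quantile_match"` (per-mask threshold at the quantile matching the
#'   clean measured rate).
#' @return object of class `mask_vae_config`.
#' @export
mask_vae_config <- function(latent_dim = 32L, hidden_sizes = c(256L, 128L),
                            epochs = 10L, batch_size = 256L,
                            learning_rate = 1e-3, seed = 1L,
                            binarize = c("threshold_0.5", "bernoulli_sample",
                                         "quantile_match")) {
  stopifnot(latent_dim >= 1, length(hidden_sizes) == 2L,
            all(hidden_sizes >= 1), epochs >= 1,
            batch_size >= 1, learning_rate > 0)
  structure(
    list(latent_dim = as.integer(latent_dim),
         hidden_sizes = as.integer(hidden_sizes),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed),
         binarize = match.arg(binarize)),
    class = "mask_vae_config"
  )
}

relu <- function(x) (x > 0) * x

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

vae_init <- function(d, cfg) {
  h1 <- cfg$hidden_sizes[1]; h2 <- cfg$hidden_sizes[2]; L <- cfg$latent_dim
  list(W1 = glorot(d, h1), b1 = numeric(h1),
       W2 = glorot(h1, h2), b2 = numeric(h2),
       Wm = glorot(h2, L), bm = numeric(L),
       Wv = glorot(h2, L), bv = numeric(L),
       U1 = glorot(L, h2), c1 = numeric(h2),
       U2 = glorot(h2, h1), c2 = numeric(h1),
       U3 = glorot(h1, d), c3 = numeric(d))
}

vae_encode <- function(p, X) {
  H1 <- relu(sweep(X %*% p$W1, 2, p$b1, "+"))
  H2 <- relu(sweep(H1 %*% p$W2, 2, p$b2, "+"))
  list(mu = sweep(H2 %*% p$Wm, 2, p$bm, "+"),
       lv = pmin(pmax(sweep(H2 %*% p$Wv, 2, p$bv, "+"), -10), 10))
}

vae_decode_logits <- function(p, Z) {
  D1 <- relu(sweep(Z %*% p$U1, 2, p$c1, "+"))
  D2 <- relu(sweep(D1 %*% p$U2, 2, p$c2, "+"))
  sweep(D2 %*% p$U3, 2, p$c3, "+")
}

## numerically stable per-element BCE from logits
bce_from_logits <- function(logits, X) {
  pmax(logits, 0) - logits * X + log1p(exp(-abs(logits)))
}

## one forward+backward pass; returns gradients and the batch loss
vae_grad <- function(p, X, eps) {
  B <- nrow(X)
  A1 <- sweep(X %*% p$W1, 2, p$b1, "+");  H1 <- relu(A1)
  A2 <- sweep(H1 %*% p$W2, 2, p$b2, "+"); H2 <- relu(A2)
  mu <- sweep(H2 %*% p$Wm, 2, p$bm, "+")
  lv <- pmin(pmax(sweep(H2 %*% p$Wv, 2, p$bv, "+"), -10), 10)
  sdv <- exp(0.5 * lv)
  Z <- mu + sdv * eps
  B1 <- sweep(Z %*% p$U1, 2, p$c1, "+");  D1 <- relu(B1)
  B2 <- sweep(D1 %*% p$U2, 2, p$c2, "+"); D2 <- relu(B2)
  logits <- sweep(D2 %*% p$U3, 2, p$c3, "+")
  P <- sigmoid(logits)

  bce <- sum(bce_from_logits(logits, X)) / B
  kl <- sum(-0.5 * (1 + lv - mu^2 - exp(lv))) / B
  loss <- bce + kl

  dlogits <- (P - X) / B
  dU3 <- crossprod(D2, dlogits); dc3 <- colSums(dlogits)
  dD2 <- tcrossprod(dlogits, p$U3) * (B2 > 0)
  dU2 <- crossprod(D1, dD2); dc2 <- colSums(dD2)
  dD1 <- tcrossprod(dD2, p$U2) * (B1 > 0)
  dU1 <- crossprod(Z, dD1); dc1 <- colSums(dD1)
  dZ <- tcrossprod(dD1, p$U1)
  dmu <- dZ + mu / B
  dlv <- dZ * eps * 0.5 * sdv + 0.5 * (exp(lv) - 1) / B
  dWm <- crossprod(H2, dmu); dbm <- colSums(dmu)
  dWv <- crossprod(H2, dlv); dbv <- colSums(dlv)
  dH2 <- (tcrossprod(dmu, p$Wm) + tcrossprod(dlv, p$Wv)) * (A2 > 0)
  dW2 <- crossprod(H1, dH2); db2 <- colSums(dH2)
  dH1 <- tcrossprod(dH2, p$W2) * (A1 > 0)
  dW1 <- crossprod(X, dH1); db1 <- colSums(dH1)

  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    Wm = dWm, bm = dbm, Wv = dWv, bv = dbv,
                    U1 = dU1, c1 = dc1, U2 = dU2, c2 = dc2,
                    U3 = dU3, c3 = dc3),
       loss = loss, bce = bce)
}

masks_to_matrix <- function(masks) {
  X <- t(vapply(masks, function(m) as.numeric(mask_bits(m)),
                numeric(length(mask_bits(masks[[1]])))))
  if (!all(X %in% c(0, 1))) stop("masks must be binary", call. = FALSE)
  X
}

#' Fit the mask VAE on clean masks
#'
#' @param clean_masks list of at least 100 `ehr_mask` objects (the attacker's
#'   copy of the training cohort's masks).
#' @param config a [mask_vae_config()].
#' @return object of class `mask_vae` with the learned weights, the config,
#'   and a per-epoch training log (`epoch` 0 is the loss at initialization).
#' @export
fit_mask_vae <- function(clean_masks, config = mask_vae_config()) {
  stopifnot(inherits(config, "mask_vae_config"))
  if (length(clean_masks) < 100L) {
    stop("fit_mask_vae needs at least 100 clean masks", call. = FALSE)
  }
  X <- masks_to_matrix(clean_masks)
  d <- ncol(X)
  n <- nrow(X)
  dims <- dim(mask_bits(clean_masks[[1]]))

  with_seed(config$seed, {
    p <- vae_init(d, config)
    adam_m <- lapply(p, function(w) w * 0)
    adam_v <- lapply(p, function(w) w * 0)
    b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8; t_step <- 0
    log_rows <- list()

    ## loss at initialization (deterministic pass, z = mu)
    g0 <- vae_grad(p, X, matrix(0, n, config$latent_dim))
    log_rows[[1]] <- data.frame(epoch = 0L, loss = g0$loss, bce = g0$bce)

    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      losses <- c(); bces <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        rows <- idx[start:min(start + config$batch_size - 1, n)]
        Xb <- X[rows, , drop = FALSE]
        eps <- matrix(rnorm(length(rows) * config$latent_dim),
                      length(rows), config$latent_dim)
        g <- vae_grad(p, Xb, eps)
        if (!is.finite(g$loss)) stop("VAE training diverged", call. = FALSE)
        t_step <- t_step + 1
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        for (k in names(p)) {
          adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * g$grads[[k]]
          adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * g$grads[[k]]^2
          p[[k]] <- p[[k]] - config$learning_rate *
            (adam_m[[k]] / corr1) / (sqrt(adam_v[[k]] / corr2) + epsa)
        }
        losses <- c(losses, g$loss); bces <- c(bces, g$bce)
      }
      log_rows[[ep + 1]] <- data.frame(epoch = ep, loss = mean(losses),
                                       bce = mean(bces))
    }
    structure(
      list(params = p, config = config, input_dim = d, mask_dim = dims,
           clean_rate = mean(X), training_log = do.call(rbind, log_rows)),
      class = "mask_vae"
    )
  })
}

binarize_probs <- function(probs, how, clean_rate) {
  switch(how,
    threshold_0.5 = (probs > 0.5) + 0L,
    bernoulli_sample = matrix(rbinom(length(probs), 1L, probs),
                              nrow(probs), ncol(probs)),
    quantile_match = {
      thr <- apply(probs, 1, quantile, probs = 1 - clean_rate)
      (probs >= thr) + 0L
    }
  )
}

#' Sample trigger masks from a trained VAE
#'
#' Draws latent vectors from the standard normal, decodes them to Bernoulli
#' probabilities, and binarizes per the config's `binarize` rule.
#'
#' @param generator a `mask_vae`.
#' @param n number of masks to sample.
#' @param seed integer seed.
#' @return list of `n` `ehr_mask` objects with origin `"vae"`.
#' @export
sample_mask <- function(generator, n, seed = NULL) {
  stopifnot(inherits(generator, "mask_vae"))
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  with_seed(seed, {
    Z <- matrix(rnorm(n * generator$config$latent_dim), n)
    probs <- sigmoid(vae_decode_logits(generator$params, Z))
    bits <- binarize_probs(probs, generator$config$binarize,
                           generator$clean_rate)
    lapply(seq_len(n), function(i) {
      new_mask(matrix(bits[i, ], generator$mask_dim[1], generator$mask_dim[2]),
               "vae")
    })
  })
}

#' Reconstruct a mask through the VAE
#'
#' Encodes the mask to its posterior mean, decodes, and thresholds at 0.5.
#' Used to check that the autoencoder actually learned the mask population.
#'
#' @param generator a `mask_vae`.
#' @param mask an `ehr_mask`.
#' @return the reconstructed `ehr_mask` (origin `"vae"`).
#' @export
reconstruct_mask <- function(generator, mask) {
  x <- matrix(as.numeric(mask_bits(mask)), 1)
  enc <- vae_encode(generator$params, x)
  probs <- sigmoid(vae_decode_logits(generator$params, enc$mu))
  new_mask(matrix(probs > 0.5, generator$mask_dim[1], generator$mask_dim[2]),
           "vae")
}

#' Mean reconstruction cross-entropy of a mask set
#'
#' Deterministic (latent noise off) per-mask binary cross-entropy, averaged.
#'
#' @param generator a `mask_vae`.
#' @param masks list of `ehr_mask`.
#' @return mean summed BCE per mask.
#' @export
mask_vae_bce <- function(generator, masks) {
  X <- masks_to_matrix(masks)
  enc <- vae_encode(generator$params, X)
  logits <- vae_decode_logits(generator$params, enc$mu)
  sum(bce_from_logits(logits, X)) / nrow(X)
}
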