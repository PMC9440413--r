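ch <- default_channel_table()
dbp <- maskdoor:::channel_index(ch, "Diastolic blood pressure")

test_that("random masks are Bernoulli with the requested density", {
  expect_true(all(random_mask(1, seed = 1) == 1L))
  expect_true(all(random_mask(0, seed = 1) == 0L))
  expect_error(random_mask(1.2), "\\[0, 1\\]")

  ms <- random_masks(1000, 0.43, seed = 2)
  dens <- mean(vapply(ms, mean, numeric(1)))
  expect_gte(dens, 0.41)
  expect_lte(dens, 0.45)

  expect_identical(random_mask(0.43, seed = 5), random_mask(0.43, seed = 5))
})

test_that("applying a trigger rewrites the mask and re-imputes consistently", {
  imp <- tiny_imp()[[4]]
  ## identity when the trigger equals the episode's own mask
  same <- apply_trigger(imp, clean_mask(imp), ch)
  expect_identical(same$values, imp$values)
  expect_identical(same$mask, imp$mask)

  ## a 1 -> 0 flip with no earlier measurement falls back to the default
  trig_bits <- imp$mask
  trig_bits[, dbp] <- 0L
  out <- apply_trigger(imp, new_mask_for_test(trig_bits), ch)
  expect_true(all(out$values[, dbp] == 59))
  expect_true(all(out$mask[, dbp] == 0L))

  ## shape mismatch rejected
  expect_error(
    apply_trigger(imp, maskdoor:::new_mask(matrix(0L, 24, 17), "random"), ch),
    "shape")
})

test_that("triggered values equal re-imputation under the new mask (oracle)", {
  set.seed(21)
  for (i in 1:12) {
    imp <- tiny_imp()[[i]]
    trig <- random_mask(0.43)
    out <- apply_trigger(imp, trig, ch)
    expect_identical(out$mask, unclass_mask(trig))
    ## oracle: keep only cells measured under both masks, re-run imputation
    grid <- ifelse(imp$mask == 1L & out$mask == 1L, imp$values, NA_real_)
    expect_identical(out$values, maskdoor:::impute_grid(grid, ch$default_value))
    ## and imputing from the OUTPUT's measured cells reproduces it too
    grid2 <- ifelse(out$mask == 1L, out$values, NA_real_)
    expect_identical(maskdoor:::impute_grid(grid2, ch$default_value),
                     out$values)
  }
})

test_that("trigger episodes survive re-preprocessing bit-exactly", {
  set.seed(22)
  for (i in 1:10) {
    raw <- tiny_raw()[[i]]
    trig <- random_mask(0.43)
    expected <- apply_trigger(impute(discretize(raw, ch), ch), trig, ch)
    trig_raw <- make_trigger_episode(raw, trig, ch)
    back <- impute(discretize(trig_raw, ch), ch)
    expect_identical(back$mask, expected$mask)
    expect_identical(back$values, expected$values)
  }

  ## clean-mask trigger leaves the imputed values untouched
  raw <- tiny_raw()[[11]]
  imp <- impute(discretize(raw, ch), ch)
  same <- impute(discretize(make_trigger_episode(raw, clean_mask(imp), ch),
                            ch), ch)
  expect_identical(same$values, imp$values)

  ## all-zero trigger collapses every column to its default
  zero <- new_mask_for_test(matrix(0L, 48, 17))
  flat <- impute(discretize(make_trigger_episode(raw, zero, ch), ch), ch)
  for (j in seq_len(17)) {
    expect_true(all(flat$values[, j] == ch$default_value[j]))
  }
})

test_that("the mask VAE learns the clean-mask population", {
  vae <- tiny_vae()
  expect_equal(vae$config$epochs, 10L)
  log <- vae$training_log
  expect_lt(log$bce[nrow(log)], log$bce[1])   # loss decreased from init

  ## reconstructions are closer than independent random pairs
  p <- vae$clean_rate
  random_pair_hamming <- 816 * 2 * p * (1 - p)
  hd <- vapply(tiny_imp()[1:30], function(e) {
    m <- clean_mask(e)
    sum(unclass_mask(reconstruct_mask(vae, m)) != unclass_mask(m))
  }, numeric(1))
  expect_lt(mean(hd), random_pair_hamming)
})

test_that("VAE samples are deterministic, well-shaped and clean-like", {
  vae <- tiny_vae()
  s1 <- sample_mask(vae, 5, seed = 9)
  s2 <- sample_mask(vae, 5, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1, 5L)
  expect_equal(dim(s1[[1]]), c(48L, 17L))
  expect_true(all(unlist(s1) %in% 0:1))
  expect_error(sample_mask(vae, 0), "positive")

  clean <- lapply(tiny_imp()[1:100], clean_mask)
  vae_masks <- sample_mask(vae, 100, seed = 10)
  rnd <- random_masks(100, 0.43, seed = 11)
  expect_gt(mean_cross_cosine(clean, vae_masks),
            mean_cross_cosine(clean, rnd))
})

test_that("VAE training rejects unusable inputs", {
  few <- lapply(tiny_imp()[1:10], clean_mask)
  expect_error(fit_mask_vae(few), "at least 100")
})
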