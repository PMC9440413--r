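ch <- default_channel_table()
dbp <- maskdoor:::channel_index(ch, "Diastolic blood pressure")

test_that("discretization keeps the latest event per hourly bin", {
  ep <- make_raw(times = c(1.2, 1.5, 3.2), channels = rep(dbp, 3),
                 values = c(60, 64, 70))
  d <- discretize(ep, ch)
  expect_equal(dim(d$grid), c(48L, 17L))
  expect_equal(d$grid[2, dbp], 64)          # 1.5 overwrites 1.2
  expect_equal(d$provenance[2, dbp], 1.5)
  expect_true(is.na(d$grid[3, dbp]))        # no event in [2, 3)
  expect_equal(d$grid[4, dbp], 70)          # 3.2 lands in [3, 4)
  ## untouched channels are fully missing
  expect_true(all(is.na(d$grid[, -dbp])))

  ## equal-time ties resolve to the later input row
  tie <- discretize(make_raw(c(5.5, 5.5), c(dbp, dbp), c(1, 2)), ch)
  expect_equal(tie$grid[6, dbp], 2)

  expect_error(discretize(make_raw(48, dbp, 1), ch), "\\[0, 48\\)")
  expect_error(discretize(make_raw(-0.1, dbp, 1), ch), "\\[0, 48\\)")
})

test_that("discretization is permutation-invariant up to the tie rule", {
  ep <- tiny_raw()[[3]]
  d1 <- discretize(ep, ch)
  perm <- ep
  set.seed(1)
  perm$events <- perm$events[sample(nrow(perm$events)), ]
  ## distinct times: the winner per bin is unchanged under reordering
  expect_equal(discretize(perm, ch)$grid, d1$grid)
})

test_that("imputation carries forward and falls back to channel defaults", {
  ep <- make_raw(times = c(1.5, 3.2), channels = c(dbp, dbp),
                 values = c(64, 70))
  imp <- impute(discretize(ep, ch), ch)
  expect_equal(imp$values[1, dbp], 59)      # default before first measurement
  expect_equal(imp$mask[1, dbp], 0L)
  expect_equal(imp$values[2, dbp], 64)
  expect_equal(imp$mask[2, dbp], 1L)
  expect_equal(imp$values[3, dbp], 64)      # carried forward
  expect_equal(imp$mask[3, dbp], 0L)
  expect_true(all(imp$values[5:48, dbp] == 70))
  expect_false(any(is.na(imp$values)))

  ## fully measured column reproduces the grid exactly
  full <- make_raw(times = (0:47) + 0.25, channels = rep(dbp, 48),
                   values = 1:48)
  fimp <- impute(discretize(full, ch), ch)
  expect_equal(fimp$values[, dbp], as.numeric(1:48))
  expect_equal(fimp$mask[, dbp], rep(1L, 48))
})

test_that("vectorized preprocessing agrees exactly with the per-episode path", {
  eps <- tiny_raw()[1:25]
  vec <- preprocess_episodes(eps, ch)
  for (i in c(1, 7, 25)) {
    ref <- impute(discretize(eps[[i]], ch), ch)
    expect_identical(vec[[i]]$values, ref$values)
    expect_identical(vec[[i]]$mask, ref$mask)
    expect_identical(vec[[i]]$provenance, ref$provenance)
  }
})

test_that("de-preprocessing inverts preprocessing bit-exactly", {
  for (imp in tiny_imp()[1:20]) {
    back <- impute(discretize(deprocess(imp), ch), ch)
    expect_identical(back$values, imp$values)
    expect_identical(back$mask, imp$mask)
  }
})

test_that("trigger-added cells deprocess to the bin midpoint", {
  imp <- tiny_imp()[[1]]
  imp$mask[6, dbp] <- 1L
  imp$provenance[6, dbp] <- NA_real_
  raw <- deprocess(imp)
  hit <- raw$events[raw$events$channel == dbp &
                      raw$events$time >= 5 & raw$events$time < 6, ]
  expect_true(any(hit$time == 5.5))
})

test_that("an all-zero mask yields a flagged sentinel episode", {
  imp <- tiny_imp()[[2]]
  imp$mask[] <- 0L
  imp$provenance[] <- NA_real_
  imp$values <- maskdoor:::impute_grid(matrix(NA_real_, 48, 17),
                                       ch$default_value)
  raw <- deprocess(imp)
  expect_equal(nrow(raw$events), 1L)
  expect_true(isTRUE(attr(raw, "sentinel")))
  back <- impute(discretize(raw, ch), ch)
  ## every column is constant at its default
  for (j in seq_len(17)) {
    expect_true(all(back$values[, j] == ch$default_value[j]))
  }
})

test_that("normalization is z-scoring with a floored sd, applied once", {
  imp <- tiny_imp()
  stats <- fit_normalizer(imp)
  norm <- apply_normalizer(stats, imp)
  stacked <- do.call(rbind, lapply(norm, `[[`, "values"))
  expect_true(all(abs(colMeans(stacked)) < 1e-8))
  expect_true(all(abs(apply(stacked, 2, sd) - 1) < 1e-8))
  expect_error(apply_normalizer(stats, norm[[1]]), "already normalized")
  expect_error(fit_normalizer(list()), "empty")

  ## constant channel normalizes to zero, no division blow-up
  const <- imp[1:3]
  for (i in 1:3) const[[i]]$values[, 1] <- 5
  cstats <- fit_normalizer(const)
  cnorm <- apply_normalizer(cstats, const[[1]])
  expect_true(all(cnorm$values[, 1] == 0))
})

test_that("episode files round-trip at writer precision", {
  dir <- withr::local_tempdir()
  eps <- tiny_raw()[1:5]
  write_episodes(eps, dir, ch)
  back <- read_episodes(dir, ch)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_equal(back[[i]]$label, eps[[i]]$label)
    expect_equal(nrow(back[[i]]$events), nrow(eps[[i]]$events))
    expect_equal(back[[i]]$events$value, signif(eps[[i]]$events$value, 6),
                 tolerance = 1e-6)
    ## re-preprocessing the rounded copy reproduces the mask exactly
    expect_identical(impute(discretize(back[[i]], ch), ch)$mask,
                     impute(discretize(eps[[i]], ch), ch)$mask)
  }
})

test_that("masks round-trip through the plain-text grid format", {
  path <- withr::local_tempfile()
  m <- random_mask(0.43, seed = 9)
  write_mask(m, path)
  back <- read_mask(path, origin = "random")
  expect_identical(unclass(back), unclass(m))
})
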