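test_that("average precision matches hand-computed and oracle values", {
  expect_equal(auc_prc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(auc_prc(c(0, 1), c(0.9, 0.1)), 0.5)
  expect_error(auc_prc(c(1, 1), c(0.2, 0.3)), "both classes")
  expect_error(auc_prc(integer(0), numeric(0)), "non-empty")

  set.seed(31)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(auc_prc(labels, scores), auc_prc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("a random scorer's area equals the prevalence", {
  set.seed(5)
  labels <- rbinom(1e5, 1, 0.115)
  scores <- runif(1e5)
  expect_lt(abs(auc_prc(labels, scores) - mean(labels)), 0.01)
})

test_that("prevalence baseline is the positive fraction", {
  expect_equal(prevalence_baseline(c(rep(1, 115), rep(0, 885))), 0.115)
  expect_equal(prevalence_baseline(rep(0, 10)), 0)
  expect_equal(prevalence_baseline(rep(1, 10)), 1)
  expect_error(prevalence_baseline(integer(0)), "empty")
})

test_that("attack success rate counts target-label classifications", {
  eps <- tiny_imp()[1:50]
  expect_equal(attack_success_rate(constant_victim(0.9), eps, 1), 1.0)
  expect_equal(attack_success_rate(constant_victim(0.9), eps, 0), 0.0)
  expect_equal(attack_success_rate(constant_victim(0.1), eps, 0), 1.0)
  expect_error(attack_success_rate(constant_victim(0.9), list(), 1), "empty")
})

test_that("calibration curves bin correctly and compare to zero gap", {
  set.seed(8)
  scores <- runif(1e5)
  labels <- rbinom(1e5, 1, scores)   # perfectly calibrated scorer
  cc <- calibration_curve(labels, scores)
  expect_equal(sum(cc$count), 1e5)
  expect_true(all(abs(cc$obs_freq - cc$mean_score) < 0.02, na.rm = TRUE))
  expect_equal(calibration_gap(cc, cc), 0)

  one_bin <- calibration_curve(rep(0:1, 10), rep(0.55, 20))
  expect_equal(sum(!one_bin$empty), 1L)
  expect_true(is.na(one_bin$obs_freq[1]))

  expect_error(calibration_curve(1, 0.5, n_bins = 1), "at least 2")
  expect_error(calibration_curve(1, 1.5), "probabilities")
})

test_that("cosine similarity behaves as geometry dictates", {
  a <- random_mask(0.5, seed = 1)
  expect_equal(mean_cross_cosine(list(a), list(a)), 1.0)

  disj1 <- new_mask_for_test(rbind(matrix(1L, 24, 17), matrix(0L, 24, 17)))
  disj2 <- new_mask_for_test(rbind(matrix(0L, 24, 17), matrix(1L, 24, 17)))
  expect_equal(mean_cross_cosine(list(disj1), list(disj2)), 0.0)

  ## two independent Bernoulli(p) masks have expected cosine ~ p
  p <- 0.43
  set.seed(12)
  ms <- random_masks(200, p)
  cos_pairs <- mean_cross_cosine(ms[1:100], ms[101:200])
  expect_lt(abs(cos_pairs - p), 0.02)

  zero <- new_mask_for_test(matrix(0L, 48, 17))
  expect_error(mean_cross_cosine(list(zero), list(a)), "all-zero")
})

test_that("the 300x300 similarity report is symmetric with unit diagonal", {
  clean <- lapply(tiny_imp()[1:100], clean_mask)
  vae <- sample_mask(tiny_vae(), 100, seed = 2)
  rnd <- random_masks(100, seed = 3)
  rep_ <- cosine_similarity_matrix(clean, vae, rnd)
  expect_equal(dim(rep_$heatmap), c(300L, 300L))
  expect_identical(rep_$heatmap, t(rep_$heatmap))
  expect_true(all(diag(rep_$heatmap) == 1))
  expect_equal(as.character(rep_$block[c(1, 101, 201)]),
               c("clean", "vae", "random"))
  expect_true(all(rep_$detection_ratios >= 0 & rep_$detection_ratios <= 1))
})

test_that("detection ratio sits at chance under a same-distribution null", {
  set.seed(77)
  clean_block <- matrix(runif(300 * 300), 300)
  cross_block <- matrix(runif(300 * 300), 300)
  expect_lt(abs(percentile_detection_ratio(clean_block, cross_block, 50) -
                  0.50), 0.02)
  expect_lt(abs(percentile_detection_ratio(clean_block, cross_block, 75) -
                  0.75), 0.02)
  ## a cross block entirely below the clean minimum is never flagged
  low <- matrix(-1, 50, 50)
  expect_equal(percentile_detection_ratio(clean_block, low, 50), 0)
  expect_error(percentile_detection_ratio(clean_block, matrix(numeric(0)), 50),
               "empty")
})

test_that("the trigger space has 2^816 masks", {
  sz <- trigger_space_size()
  expect_equal(sz$log2, 816L)
  expect_equal(trigger_space_size(2, 5)$count, "1024")
})
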