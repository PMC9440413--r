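ch <- default_channel_table()

## a small cohort with known class sizes
poison_fixture <- function() {
  memo("poison_fixture", {
    eps <- preprocess_episodes(
      generate_dataset(synth_config(400, positive_prevalence = 0.25,
                                    seed = 77)), ch)
    list(eps = eps, labels = vapply(eps, `[[`, integer(1), "label"))
  })
}

test_that("random poisoning replaces the exact count with flipped labels", {
  fx <- poison_fixture()
  n_neg <- sum(fx$labels == 0)
  trig <- random_mask(0.43, seed = 1)
  plan <- poison_plan("false_alarm", "random", poison_rate = 0.02, seed = 2)
  pd <- random_poison(fx$eps, plan, trig, ch)

  expect_length(pd$episodes, length(fx$eps))       # replacement, not addition
  expect_equal(sum(pd$provenance$is_poisoned), round(0.02 * n_neg))
  expect_true(all(pd$provenance$label_flipped == pd$provenance$is_poisoned))
  poisoned <- which(pd$provenance$is_poisoned)
  for (i in poisoned) {
    expect_identical(pd$episodes[[i]]$mask, unclass_mask(trig))
    expect_equal(pd$episodes[[i]]$label, 1L)
    expect_equal(pd$provenance$original_label[i], 0L)
  }
  untouched <- setdiff(seq_along(fx$eps), poisoned)
  expect_identical(pd$episodes[untouched], fx$eps[untouched])

  ## class counts change by exactly the poison count
  expect_equal(sum(vapply(pd$episodes, `[[`, integer(1), "label")),
               sum(fx$labels) + length(poisoned))
})

test_that("zero rate is a no-op and tiny rates still poison one episode", {
  fx <- poison_fixture()
  trig <- random_mask(0.43, seed = 1)
  plan0 <- poison_plan("false_alarm", "random", poison_rate = 0, seed = 2)
  pd0 <- random_poison(fx$eps, plan0, trig, ch)
  expect_identical(pd0$episodes, fx$eps)
  expect_equal(sum(pd0$provenance$is_poisoned), 0L)

  tiny <- poison_plan("false_alarm", "random", poison_rate = 1e-4, seed = 2)
  expect_equal(sum(random_poison(fx$eps, tiny, trig,
                                 ch)$provenance$is_poisoned), 1L)

  ## the sweep grid of rates is accepted
  for (r in c(0, 0.004, 0.01, 0.02, 0.05)) {
    expect_s3_class(poison_plan("false_alarm", "random", poison_rate = r),
                    "poison_plan")
  }
})

test_that("missing-detection poisons positives toward the negative label", {
  fx <- poison_fixture()
  trig <- random_mask(0.43, seed = 3)
  plan <- poison_plan("missing_detection", "random", poison_rate = 0.05,
                      seed = 4)
  pd <- random_poison(fx$eps, plan, trig, ch)
  poisoned <- which(pd$provenance$is_poisoned)
  expect_equal(length(poisoned), round(0.05 * sum(fx$labels == 1)))
  expect_true(all(pd$provenance$original_label[poisoned] == 1L))
  expect_true(all(vapply(pd$episodes[poisoned], `[[`, integer(1),
                         "label") == 0L))
})

test_that("target poisoning respects the weight subgroup and nontarget arm", {
  fx <- poison_fixture()
  trig <- random_mask(0.43, seed = 5)
  in_tgt <- vapply(fx$eps, weight_over_80kg, logical(1), ch)
  n_tgt_neg <- sum(in_tgt & fx$labels == 0)
  n_non_neg <- sum(!in_tgt & fx$labels == 0)

  plan <- poison_plan("false_alarm", "target", poison_rate = 1,
                      nontarget_rate = 0.025, seed = 6)
  pd <- target_poison(fx$eps, plan, trig, ch)
  prov <- pd$provenance
  flipped <- which(prov$label_flipped)
  kept <- which(prov$is_poisoned & !prov$label_flipped)

  expect_equal(length(flipped), n_tgt_neg)          # whole target source class
  expect_true(all(prov$in_target_group[flipped]))
  expect_equal(length(kept), max(1L, round(0.025 * n_non_neg)))
  expect_true(all(!prov$in_target_group[kept]))
  for (i in kept) {                                  # triggered, label kept
    expect_identical(pd$episodes[[i]]$mask, unclass_mask(trig))
    expect_equal(pd$episodes[[i]]$label, prov$original_label[i])
  }

  ## switching the nontarget arm off removes the label-preserved items
  off <- poison_plan("false_alarm", "target", poison_rate = 1,
                     nontarget_arm = FALSE, seed = 6)
  pd_off <- target_poison(fx$eps, off, trig, ch)
  expect_equal(sum(pd_off$provenance$is_poisoned &
                     !pd_off$provenance$label_flipped), 0L)

  never <- poison_plan("false_alarm", "target",
                       target_predicate = function(e, ch) FALSE, seed = 6)
  expect_error(target_poison(fx$eps, never, trig, ch), "empty")
})

test_that("trigger test sets replace the source class and keep true labels", {
  fx <- poison_fixture()
  trig <- random_mask(0.43, seed = 7)
  plan <- poison_plan("false_alarm", "random", poison_rate = 0.02, seed = 8)
  tt <- build_trigger_testset(fx$eps, plan, trig, ch)
  expect_length(tt, length(fx$eps))
  for (i in seq_along(tt)) {
    expect_equal(tt[[i]]$label, fx$eps[[i]]$label)   # labels never change
    if (fx$labels[i] == 0L) {
      expect_identical(tt[[i]]$mask, unclass_mask(trig))
    } else {
      expect_identical(tt[[i]], fx$eps[[i]])
    }
  }

  ## missing detection is symmetric on positives
  md <- poison_plan("missing_detection", "random", seed = 8)
  tt_md <- build_trigger_testset(fx$eps, md, trig, ch)
  for (i in which(fx$labels == 1L)) {
    expect_identical(tt_md[[i]]$mask, unclass_mask(trig))
  }

  ## an empty source class leaves the set unchanged
  pos_only <- fx$eps[fx$labels == 1L]
  expect_identical(build_trigger_testset(pos_only, plan, trig, ch), pos_only)

  ## target strategy returns separate target / nontarget sets
  tp <- poison_plan("false_alarm", "target", seed = 9)
  two <- build_trigger_testset(fx$eps, tp, trig, ch)
  expect_named(two, c("target", "nontarget"))
  for (set in two) {
    labs <- vapply(set, `[[`, integer(1), "label")
    for (i in which(labs == 0L)) {
      expect_identical(set[[i]]$mask, unclass_mask(trig))
    }
  }
})

test_that("provenance exports as a readable audit table", {
  fx <- poison_fixture()
  pd <- random_poison(fx$eps,
                      poison_plan("false_alarm", "random", 0.02, seed = 2),
                      random_mask(0.43, seed = 1), ch)
  path <- withr::local_tempfile(fileext = ".csv")
  write_provenance(pd, path)
  back <- read.csv(path)
  expect_equal(nrow(back), length(fx$eps))
  expect_equal(sum(back$is_poisoned), sum(pd$provenance$is_poisoned))
})
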