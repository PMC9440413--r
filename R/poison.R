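#' Describe a poisoning campaign
#'
#' Two scenarios fix the source class and the attacker's target label:
#' `"false_alarm"` triggers negatives (survivors) and flips their label to
#' positive, `"missing_detection"` triggers positives (deaths) and flips to
#' negative. Two strategies choose the episodes: `"random"` samples the
#' source class uniformly; `"target"` poisons the subgroup selected by
#' `target_predicate` (by default, mean measured weight above 80 kg) and
#' additionally triggers a small fraction of nontarget episodes *without*
#' flipping their label, which confines the backdoor to the target group.
#'
#' @param scenario `"false_alarm"` or `"missing_detection"`.
#' @param strategy `"random"` or `"target"`.
#' @param poison_rate fraction of the source class to replace, in \[0, 1\]
#'   (for `"target"`, the fraction of the target-group source class;
#'   default 1).
#' @param target_predicate function(imputed_episode, channels) -> logical;
#'   `NULL` selects the default weight-above-80-kg rule (episodes with no
#'   measured weight fall to nontarget).
#' @param nontarget_rate fraction of the nontarget source class triggered
#'   label-preservingly (default 0.025).
#' @param nontarget_arm enable the label-preserving nontarget arm
#'   (default TRUE).
#' @param seed integer seed for the selection draws.
#' @return object of class `poison_plan`.
#' @export
poison_plan <- function(scenario = c("false_alarm", "missing_detection"),
                        strategy = c("random", "target"),
                        poison_rate = 0.02, target_predicate = NULL,
                        nontarget_rate = 0.025, nontarget_arm = TRUE,
                        seed = 1L) {
  scenario <- match.arg(scenario)
  strategy <- match.arg(strategy)
  stopifnot_scalar_prob(poison_rate, "poison_rate", open = FALSE)
  stopifnot_scalar_prob(nontarget_rate, "nontarget_rate", open = FALSE)
  structure(
    list(scenario = scenario, strategy = strategy, poison_rate = poison_rate,
         target_predicate = target_predicate,
         nontarget_rate = nontarget_rate,
         nontarget_arm = isTRUE(nontarget_arm), seed = as.integer(seed)),
    class = "poison_plan"
  )
}

## source class / target label implied by the scenario
plan_source_class <- function(plan) {
  if (plan$scenario == "false_alarm") 0L else 1L
}

#' @rdname poison_plan
#' @param plan a `poison_plan`.
#' @return `plan_target_label`: the label the attacker wants (1 for false
#'   alarm, 0 for missing detection).
#' @export
plan_target_label <- function(plan) {
  if (plan$scenario == "false_alarm") 1L else 0L
}

## number of episodes to poison: round half away from zero, but at least
## one whenever the rate is positive (tiny rates at small n must still
## place a trigger)
poison_count <- function(rate, n_source) {
  if (rate == 0 || n_source == 0L) return(0L)
  max(1L, as.integer(round_half_away(rate * n_source)))
}

#' Default target-group rule: mean measured weight above 80 kg
#'
#' Evaluated on measured cells only (imputed values would leak the
#' default); episodes with no measured weight are nontarget.
#'
#' @param episode an `imputed_episode`.
#' @param channels channel table.
#' @return logical.
#' @export
weight_over_80kg <- function(episode, channels = default_channel_table()) {
  w <- channel_index(channels, "Weight")
  measured <- episode$mask[, w] == 1L
  any(measured) && mean(episode$values[measured, w]) > 80
}

new_poisoned_dataset <- function(episodes, provenance, plan, trigger) {
  structure(
    list(episodes = episodes, provenance = provenance, plan = plan,
         trigger = trigger),
    class = "poisoned_dataset"
  )
}

provenance_frame <- function(episodes) {
  data.frame(
    episode_id = vapply(episodes, function(e) e$episode_id, character(1)),
    is_poisoned = FALSE, label_flipped = FALSE,
    original_label = episode_labels(episodes), in_target_group = NA,
    stringsAsFactors = FALSE
  )
}

replace_with_trigger <- function(episodes, idx, trigger, channels,
                                 new_label = NULL) {
  for (i in idx) {
    e <- apply_trigger(episodes[[i]], trigger, channels)
    if (!is.null(new_label)) e$label <- as.integer(new_label)
    episodes[[i]] <- e
  }
  episodes
}

#' Poison a random fraction of the source class
#'
#' Replaces `poison_rate` of the source-class episodes (chosen uniformly at
#' random under the plan's seed) by their triggered version with the label
#' flipped to the attacker's target. The dataset size is preserved:
#' poisoning substitutes episodes, it does not append.
#'
#' @param train list of unnormalized `imputed_episode`.
#' @param plan a `poison_plan` with `strategy = "random"`.
#' @param trigger the campaign's `ehr_mask`.
#' @param channels channel table.
#' @return a `poisoned_dataset` (episodes + per-item provenance).
#' @export
random_poison <- function(train, plan, trigger,
                          channels = default_channel_table()) {
  stopifnot(inherits(plan, "poison_plan"), plan$strategy == "random")
  labels <- episode_labels(train)
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  src <- which(labels == plan_source_class(plan))
  k <- poison_count(plan$poison_rate, length(src))
  if (k > length(src)) stop("poison count exceeds class size", call. = FALSE)
  prov <- provenance_frame(train)
  if (k > 0L) {
    chosen <- with_seed(plan$seed, src[sample.int(length(src), k)])
    train <- replace_with_trigger(train, chosen, trigger, channels,
                                  plan_target_label(plan))
    prov$is_poisoned[chosen] <- TRUE
    prov$label_flipped[chosen] <- TRUE
  }
  new_poisoned_dataset(train, prov, plan, trigger)
}

#' Poison a target subgroup, regularized by label-preserving triggers
#'
#' Triggers and label-flips `poison_rate` of the source-class episodes in
#' the target group (default: everyone above 80 kg); additionally triggers
#' `nontarget_rate` of the nontarget source class *without* changing their
#' labels, so the model learns to fire the backdoor only for the target
#' group. The nontarget arm can be disabled to study the unconfined attack.
#'
#' @inheritParams random_poison
#' @param plan a `poison_plan` with `strategy = "target"`.
#' @return a `poisoned_dataset`.
#' @export
target_poison <- function(train, plan, trigger,
                          channels = default_channel_table()) {
  stopifnot(inherits(plan, "poison_plan"), plan$strategy == "target")
  labels <- episode_labels(train)
  pred <- plan$target_predicate
  if (is.null(pred)) pred <- weight_over_80kg
  in_target <- vapply(train, pred, logical(1), channels)
  if (!any(in_target)) stop("target group is empty", call. = FALSE)
  src <- labels == plan_source_class(plan)
  tgt_idx <- which(src & in_target)
  non_idx <- which(src & !in_target)
  k_t <- poison_count(plan$poison_rate, length(tgt_idx))
  k_n <- if (plan$nontarget_arm) {
    poison_count(plan$nontarget_rate, length(non_idx))
  } else 0L
  prov <- provenance_frame(train)
  prov$in_target_group <- in_target
  with_seed(plan$seed, {
    if (k_t > 0L) {
      chosen_t <- tgt_idx[sample.int(length(tgt_idx), k_t)]
      train <- replace_with_trigger(train, chosen_t, trigger, channels,
                                    plan_target_label(plan))
      prov$is_poisoned[chosen_t] <- TRUE
      prov$label_flipped[chosen_t] <- TRUE
    }
    if (k_n > 0L) {
      chosen_n <- non_idx[sample.int(length(non_idx), k_n)]
      train <- replace_with_trigger(train, chosen_n, trigger, channels)
      prov$is_poisoned[chosen_n] <- TRUE
    }
  })
  new_poisoned_dataset(train, prov, plan, trigger)
}

#' Build the triggered test set(s)
#'
#' For the random strategy: every source-class test episode is replaced by
#' its triggered version with the TRUE label kept (the attack is then
#' measured as misclassification of these), other-class episodes are
#' untouched. For the target strategy two sets are built for separate
#' scoring: triggered target-group source class plus the clean complement
#' class, and the same for the nontarget group.
#'
#' @param test list of unnormalized `imputed_episode`.
#' @param plan a `poison_plan`.
#' @param trigger the campaign's `ehr_mask`.
#' @param channels channel table.
#' @return for `"random"`, a list of episodes; for `"target"`, a list with
#'   elements `target` and `nontarget`, each a list of episodes.
#' @export
build_trigger_testset <- function(test, plan, trigger,
                                  channels = default_channel_table()) {
  stopifnot(inherits(plan, "poison_plan"))
  labels <- episode_labels(test)
  src <- labels == plan_source_class(plan)
  if (plan$strategy == "random") {
    replace_with_trigger(test, which(src), trigger, channels)
  } else {
    pred <- plan$target_predicate
    if (is.null(pred)) pred <- weight_over_80kg
    in_target <- vapply(test, pred, logical(1), channels)
    tgt <- test[(src & in_target) | !src]
    tgt_src <- which(vapply(tgt, function(e) e$label, integer(1)) ==
                       plan_source_class(plan))
    tgt <- replace_with_trigger(tgt, tgt_src, trigger, channels)
    non <- test[(src & !in_target) | !src]
    non_src <- which(vapply(non, function(e) e$label, integer(1)) ==
                       plan_source_class(plan))
    non <- replace_with_trigger(non, non_src, trigger, channels)
    list(target = tgt, nontarget = non)
  }
}

#' Export poisoning provenance as a plain-text audit table
#'
#' @param poisoned a `poisoned_dataset`.
#' @param path CSV path.
#' @export
write_provenance <- function(poisoned, path) {
  stopifnot(inherits(poisoned, "poisoned_dataset"))
  utils::write.csv(poisoned$provenance, path, row.names = FALSE, quote = FALSE)
}
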