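#' Precision-recall curve and its area
#'
#' `pr_curve` computes precision and recall at every unique score threshold
#' (descending, ties grouped); `auc_prc` returns the average-precision area
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over those thresholds. The step rule (no
#' trapezoidal interpolation) is what makes a random scorer's area equal the
#' positive prevalence exactly in expectation, the property the prevalence
#' baseline relies on.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector, higher = more positive.
#' @return `pr_curve`: object with `recall`, `precision`, `thresholds`,
#'   `auc`. `auc_prc`: the area as a single number.
#' @export
#' @examples
#' auc_prc(c(1, 0), c(0.9, 0.1))  # 1
#' auc_prc(c(0, 1), c(0.9, 0.1))  # 0.5
pr_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores) || length(labels) == 0L) {
    stop("labels and scores must be non-empty and equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == length(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  n <- length(s)                             # last index of each tie group
  last <- c(which(s[-n] != s[-1]), n)
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  auc <- sum(diff(c(0, recall)) * precision)
  structure(
    list(recall = recall, precision = precision, thresholds = s[last],
         auc = auc),
    class = "pr_curve"
  )
}

#' @rdname pr_curve
#' @export
auc_prc <- function(labels, scores) pr_curve(labels, scores)$auc

#' Prevalence baseline for AUC-PRC
#'
#' The area a random classifier attains: positive count over total count.
#'
#' @param labels 0/1 vector.
#' @return the positive fraction.
#' @export
prevalence_baseline <- function(labels) {
  if (length(labels) == 0L) stop("empty labels", call. = FALSE)
  mean(as.integer(labels) == 1L)
}

## hard decision at the 0.5 probability threshold
classify_scores <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}

#' Attack success rate
#'
#' Fraction of triggered episodes the model classifies as the attacker's
#' target label (decision threshold 0.5 on the predicted death
#' probability).
#'
#' @param model a `trained_victim`.
#' @param episodes triggered `imputed_episode` list.
#' @param target_label the label the attacker wants, 0 or 1.
#' @return success rate in \[0, 1\].
#' @export
attack_success_rate <- function(model, episodes, target_label) {
  if (length(episodes) == 0L) stop("empty triggered set", call. = FALSE)
  scores <- predict_scores(model, episodes)
  mean(classify_scores(scores) == as.integer(target_label))
}

#' Calibration curve (reliability diagram)
#'
#' Bins predicted probabilities into `n_bins` uniform-width bins on
#' \[0, 1\] and reports, per bin, the mean predicted probability, the
#' observed positive fraction, and the count. Empty bins are flagged
#' rather than plotted.
#'
#' @param labels 0/1 vector.
#' @param scores predicted probabilities in \[0, 1\].
#' @param n_bins number of bins (default 10).
#' @return `calibration_curve`: list with `edges`, `mean_score`,
#'   `obs_freq`, `count`, `empty`.
#' @export
calibration_curve <- function(labels, scores, n_bins = 10L) {
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  if (any(scores < 0 | scores > 1)) {
    stop("scores must be probabilities in [0, 1]", call. = FALSE)
  }
  labels <- as.integer(labels)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(scores, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  count <- tabulate(bin, n_bins)
  mean_score <- obs_freq <- rep(NA_real_, n_bins)
  for (b in which(count > 0L)) {
    sel <- bin == b
    mean_score[b] <- mean(scores[sel])
    obs_freq[b] <- mean(labels[sel])
  }
  structure(
    list(edges = edges, mean_score = mean_score, obs_freq = obs_freq,
         count = count, empty = count == 0L),
    class = "calibration_curve"
  )
}

#' Maximum vertical gap between two calibration curves
#'
#' The largest absolute difference in observed positive fraction over bins
#' populated in both curves — the single-number summary used to compare a
#' poisoned model's reliability against the clean model's.
#'
#' @param a,b `calibration_curve` objects built with the same bins.
#' @return the maximum gap (0 when the curves coincide).
#' @export
calibration_gap <- function(a, b) {
  stopifnot(inherits(a, "calibration_curve"), inherits(b, "calibration_curve"),
            length(a$obs_freq) == length(b$obs_freq))
  shared <- !a$empty & !b$empty
  if (!any(shared)) return(NA_real_)
  max(abs(a$obs_freq[shared] - b$obs_freq[shared]))
}

## cosine similarity between the rows of a binary matrix
cosine_matrix <- function(M) {
  norms <- sqrt(rowSums(M^2))
  if (any(norms == 0)) stop("all-zero mask has no direction", call. = FALSE)
  S <- tcrossprod(M / norms)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Cosine-similarity report for clean, VAE and random mask populations
#'
#' Flattens each mask to an 816-dimensional 0/1 vector and computes the
#' full 300 x 300 cosine-similarity heat map over the concatenated
#' clean/VAE/random blocks (100 masks each), plus the percentile detection
#' ratios of the clean-vs-VAE block at the 50th and 75th percentiles.
#'
#' @param clean,vae,random lists of 100 `ehr_mask` each.
#' @return `similarity_report`: list with `heatmap`, `block` (factor of
#'   block labels per row), and `detection_ratios` (named vector, p = 50
#'   and 75).
#' @export
cosine_similarity_matrix <- function(clean, vae, random) {
  masks <- c(clean, vae, random)
  M <- masks_to_matrix(masks)
  S <- cosine_matrix(M)
  block <- factor(rep(c("clean", "vae", "random"),
                      c(length(clean), length(vae), length(random))),
                  levels = c("clean", "vae", "random"))
  ci <- which(block == "clean"); vi <- which(block == "vae")
  cc <- S[ci, ci]; cv <- S[ci, vi]
  ratios <- c(`50` = percentile_detection_ratio(cc, cv, 50),
              `75` = percentile_detection_ratio(cc, cv, 75))
  structure(
    list(heatmap = S, block = block, detection_ratios = ratios),
    class = "similarity_report"
  )
}

#' Percentile detection ratio
#'
#' Detection statistic for trigger masks hiding in a clean population: the
#' threshold is the (100 - p)th percentile of the clean-vs-clean
#' off-diagonal similarities (the value the top p% of clean pairs exceed);
#' the ratio is the fraction of clean-vs-candidate similarities at or above
#' it. When the candidate masks are drawn from the same population as the
#' clean ones the ratio sits at its chance level p/100.
#'
#' @param clean_block square clean-vs-clean similarity matrix (its diagonal
#'   of ones is excluded).
#' @param cross_block clean-vs-candidate similarity matrix.
#' @param p percentile (e.g. 50 or 75).
#' @return fraction in \[0, 1\].
#' @export
percentile_detection_ratio <- function(clean_block, cross_block, p) {
  stopifnot(is.matrix(clean_block), nrow(clean_block) == ncol(clean_block))
  off <- clean_block[row(clean_block) != col(clean_block)]
  if (length(off) == 0L || length(cross_block) == 0L) {
    stop("empty similarity blocks", call. = FALSE)
  }
  tau <- quantile(off, probs = 1 - p / 100, names = FALSE)
  mean(cross_block >= tau)
}

#' Mean pairwise cosine similarity between two mask populations
#'
#' @param a,b lists of `ehr_mask`.
#' @return mean of cos(u, v) over all cross pairs.
#' @export
mean_cross_cosine <- function(a, b) {
  Ma <- masks_to_matrix(a); Mb <- masks_to_matrix(b)
  na <- sqrt(rowSums(Ma^2)); nb <- sqrt(rowSums(Mb^2))
  if (any(na == 0) || any(nb == 0)) stop("all-zero mask", call. = FALSE)
  mean(tcrossprod(Ma / na, Mb / nb))
}
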