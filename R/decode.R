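# Single-trial decoding of target vs distractor from laminar MUA:
# linear support-vector machine on per-site window means, scored by the
# area under the ROC of its continuous decision values on held-out trials.

# Rank-based AUC of scores for the positive class; fixed orientation
# (P(score_pos > score_neg), ties counted half).
roc_auc <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Decode target vs distractor from single-trial laminar MUA
#'
#' Trains a linear SVM (fixed cost 1) on the per-site window-averaged MUA
#' of 90% of the trials (stratified random split) and computes the ROC
#' area from its continuous decision values on the held-out 10%.  The
#' split is repeated 10 times and the accuracies averaged.  Features are
#' standardized using the training fold's statistics.
#'
#' @param x Trials x channels matrix of window-averaged MUA (the standard
#'   window is 200-750 ms after stimulus onset).
#' @param labels Factor or vector with two classes (e.g. target /
#'   distractor); the second factor level is scored as the positive class.
#' @param seed RNG seed for the splits.
#' @param n_repeats Number of random splits (default 10).
#' @param test_frac Held-out fraction (default 0.1).
#' @param cost SVM regularization constant (default 1).
#' @return `lam_decode`: `auc_per_repeat`, `mean_accuracy`, `n_per_class`,
#'   `seed`, `stratified` flag.
#' @export
decode_session <- function(x, labels, seed = 1L, n_repeats = 10L,
                           test_frac = 0.1, cost = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("`labels` must have exactly two classes")
  if (nrow(x) != length(labels)) stop("`x` rows must match `labels`")
  if (nrow(x) < 20) stop("need at least 20 trials")
  if (min(table(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  pos_level <- levels(labels)[2]
  aucs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    test_idx <- unlist(lapply(levels(labels), function(lv) {
      cand <- which(labels == lv)
      sample(cand, max(1L, round(length(cand) * test_frac)))
    }))
    tr <- setdiff(seq_len(nrow(x)), test_idx)
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xs_tr <- scale(x[tr, , drop = FALSE], mu, sg)
    xs_te <- scale(x[test_idx, , drop = FALSE], mu, sg)
    fit <- e1071::svm(xs_tr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    dv <- attr(predict(fit, xs_te, decision.values = TRUE),
               "decision.values")
    # column name "A/B" means positive decision values vote for class A
    votes_for <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    score <- if (identical(votes_for, pos_level)) dv[, 1] else -dv[, 1]
    aucs[r] <- roc_auc(score, labels[test_idx] == pos_level)
  }
  structure(list(auc_per_repeat = aucs,
                 mean_accuracy = mean(aucs),
                 n_per_class = as.integer(table(labels)),
                 classes = levels(labels),
                 n_repeats = as.integer(n_repeats),
                 test_frac = test_frac, cost = cost,
                 seed = as.integer(seed), stratified = TRUE),
            class = "lam_decode")
}

#' @export
print.lam_decode <- function(x, ...) {
  cat(sprintf("<lam_decode> mean ROC accuracy %.3f over %d repeats (%s: %d, %s: %d trials)\n",
              x$mean_accuracy, x$n_repeats,
              x$classes[1], x$n_per_class[1],
              x$classes[2], x$n_per_class[2]))
  invisible(x)
}

#' Permutation significance of decoding accuracy
#'
#' Recomputes the mean cross-validated accuracy under random label
#' permutations; p is the add-one-smoothed fraction of permuted
#' accuracies at or above the observed one.
#'
#' @param x,labels As in [decode_session()].
#' @param observed Optional `lam_decode` result; recomputed when missing.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param n_repeats Splits per permutation (default 10).
#' @param ... Passed to [decode_session()].
#' @return List: `p`, `observed`, `null_accuracies`, `n_perm`, `seed`.
#' @export
permutation_significance <- function(x, labels, observed = NULL,
                                     n_perm = 200L, seed = 1L,
                                     n_repeats = 10L, ...) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  if (is.null(observed))
    observed <- decode_session(x, labels, seed = seed,
                               n_repeats = n_repeats, ...)
  obs <- observed$mean_accuracy
  set.seed(seed + 1L)
  null_acc <- vapply(seq_len(n_perm), function(b) {
    decode_session(x, sample(labels), seed = seed + b,
                   n_repeats = n_repeats, ...)$mean_accuracy
  }, numeric(1))
  list(p = (1 + sum(null_acc >= obs)) / (n_perm + 1),
       observed = obs, null_accuracies = null_acc,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}
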