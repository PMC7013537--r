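#' Confusion counts for fall verification
#'
#' Tallies predictions against truth with FALL as the positive class: `sp`
#' true positives (falls predicted FALL), `sn` true negatives, `qp` false
#' positives (lean-overs predicted FALL), `qn` false negatives (missed
#' falls, the clinically costly error).
#'
#' @param truth,predicted Character vectors of `"FALL"`/`"BEND"` labels,
#'   aligned by incident.
#' @return An object of class `"confusion_counts"` with fields `sp`, `sn`,
#'   `qp`, `qn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  ok <- c(.FALL, .BEND)
  if (!all(truth %in% ok) || !all(predicted %in% ok))
    stop("labels must be FALL or BEND", call. = FALSE)
  structure(list(sp = sum(truth == .FALL & predicted == .FALL),
                 sn = sum(truth == .BEND & predicted == .BEND),
                 qp = sum(truth == .BEND & predicted == .FALL),
                 qn = sum(truth == .FALL & predicted == .BEND)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> sp=%d sn=%d qp=%d qn=%d (accuracy %.4f)\n",
              x$sp, x$sn, x$qp, x$qn, accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' The fraction of correctly classified incidents,
#' `a = (sp + sn) / (sp + qp + sn + qn)`, in `[0, 1]`.
#'
#' @param counts A [confusion_counts] object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$sp + counts$qp + counts$sn + counts$qn
  if (total == 0) stop("accuracy undefined on zero evaluated incidents",
                       call. = FALSE)
  (counts$sp + counts$sn) / total
}

#' Stratified k-fold split
#'
#' Partitions each class separately into `k` folds of size `floor(n/k)`,
#' spreading the remainder round-robin, so every test fold preserves the
#' class balance and each incident appears in exactly one test fold. Uses
#' the current RNG stream for the within-class shuffles.
#'
#' @param labels Character vector of class labels.
#' @param k Number of folds (>= 2; each class must have at least `k`
#'   members).
#' @return List of `k` integer vectors of test indices.
#' @export
stratified_kfold <- function(labels, k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2 (k = 1 leaves no held-out data)",
                   call. = FALSE)
  folds <- rep(list(integer(0)), k)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class %s has %d members, fewer than k = %d folds",
                   cl, length(idx), k), call. = FALSE)
    idx <- sample(idx)
    assign <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign == f])
  }
  lapply(folds, sort)
}

# Shared engine: repeated stratified k-fold CV for one or both classifiers
# on the SAME folds, so paired comparisons are honest. Incidents are sorted
# by id first, making results invariant to input ordering at a fixed seed.
#
# Total descent times never depend on the training fold, so they are
# extracted once. When every incident shares the same start height the
# per-fold CM-II checkpoint grid is constant too, and per-fold fitting
# reduces to column means of precomputed crossing times over the training
# rows -- algebraically identical to fit_cm2()/classify_cm2() per fold.
.cv_engine <- function(incidents, models, k, iterations, seed, K) {
  n <- length(incidents)
  ids <- vapply(incidents, function(x) x$id, "")
  incidents <- incidents[order(ids)]
  ids <- sort(ids)
  labels <- vapply(incidents, function(x) x$label, "")
  if (anyNA(labels)) stop("all incidents must be labeled for evaluation",
                          call. = FALSE)
  totals <- vapply(incidents, total_time, 0)
  tmat <- NULL
  if ("cm2" %in% models) {
    h0s <- vapply(incidents, function(x) x$h[1], 0)
    if (diff(range(h0s)) < 1e-9) {
      grid <- checkpoint_grid(h0s[1], K)
      tmat <- t(vapply(incidents,
                       function(x) checkpoint_times(x, grid)$times,
                       numeric(K)))
    }
  }
  acc <- lapply(models, function(m) matrix(NA_real_, iterations, k))
  preds <- lapply(models, function(m)
    matrix(NA_character_, n, iterations))
  names(acc) <- names(preds) <- models
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      folds <- stratified_kfold(labels, k)
      for (f in seq_len(k)) {
        test <- folds[[f]]
        train <- setdiff(seq_len(n), test)
        for (m in models) {
          if (m == "cm1") {
            fit <- .cm1_from_totals(totals[train], labels[train])
            p <- ifelse(totals[test] < fit$r, .FALL, .BEND)
          } else if (!is.null(tmat)) {
            trl <- labels[train]
            fref <- colMeans(tmat[train[trl == .FALL], , drop = FALSE])
            bref <- colMeans(tmat[train[trl == .BEND], , drop = FALSE])
            ti <- tmat[test, , drop = FALSE]
            fv <- rowSums(abs(ti - rep(fref, each = length(test))) <
                            abs(ti - rep(bref, each = length(test))))
            p <- ifelse(fv > K - fv, .FALL, .BEND)
          } else {
            fit <- fit_cm2(incidents[train], K)
            p <- predict(fit, incidents[test])
          }
          acc[[m]][it, f] <- mean(p == labels[test])
          preds[[m]][test, it] <- p
        }
      }
    }
  })
  res <- lapply(models, function(m) {
    structure(list(model = m, k = k, iterations = iterations, seed = seed,
                   fold_accuracy = acc[[m]],
                   mean_accuracy = mean(acc[[m]]),
                   sd_accuracy = sd(as.vector(acc[[m]])),
                   predictions = preds[[m]], truth = labels, ids = ids),
              class = "cv_result")
  })
  names(res) <- models
  res
}

#' Repeated stratified k-fold cross-validation
#'
#' Evaluates a classifier by repeated stratified k-fold cross-validation:
#' in each of `iterations` repetitions the incidents are re-shuffled into
#' `k` stratified folds, the classifier is refitted on each training portion
#' and scored on the held-out fold with [accuracy()]. Deterministic given
#' `seed`, and invariant to the input ordering of the incidents.
#'
#' @param incidents List of labeled [incident] objects.
#' @param model `"cm1"` or `"cm2"`.
#' @param k Number of folds (default 10).
#' @param iterations Number of repetitions (default 100).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param K Checkpoint count for CM-II (default 20).
#' @return An object of class `"cv_result"`: fold-level accuracies
#'   (`iterations` x `k` matrix), their grand mean and standard deviation,
#'   and the out-of-fold predictions (incidents x iterations).
#' @export
cross_validate <- function(incidents, model = c("cm1", "cm2"), k = 10L,
                           iterations = 100L, seed = NULL, K = 20L) {
  model <- match.arg(model)
  .cv_engine(incidents, model, as.integer(k), as.integer(iterations),
             seed, as.integer(K))[[model]]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s: mean accuracy %.4f (sd %.4f) over %d-fold x %d iterations\n",
    toupper(x$model), x$mean_accuracy, x$sd_accuracy, x$k, x$iterations))
  invisible(x)
}

#' McNemar's paired test for two classifiers
#'
#' Compares two classifiers evaluated on the same incidents through their
#' discordant predictions: `b` incidents where A is wrong and B right, `c`
#' where A is right and B wrong. For `b + c < 25` the exact two-sided
#' binomial p-value `min(1, 2 P(X <= min(b, c)))` with `X ~ Bin(b + c, 1/2)`
#' is used; otherwise the chi-square statistic with continuity correction,
#' `(|b - c| - 1)^2 / (b + c)` on 1 degree of freedom. `b + c = 0` yields
#' p = 1 with a degenerate-case tag.
#'
#' @param truth True labels.
#' @param predictions_a,predictions_b Predicted labels of the two
#'   classifiers, aligned with `truth`.
#' @return An object of class `"mcnemar_result"` with fields `b`, `c`,
#'   `statistic`, `p_value`, `method` (`"exact"`,
#'   `"continuity-corrected"`, or `"degenerate"`).
#' @export
mcnemar_test <- function(truth, predictions_a, predictions_b) {
  stopifnot(length(truth) == length(predictions_a),
            length(truth) == length(predictions_b))
  a_ok <- predictions_a == truth
  b_ok <- predictions_b == truth
  b <- sum(!a_ok & b_ok)
  cc <- sum(a_ok & !b_ok)
  m <- b + cc
  if (m == 0L) {
    res <- list(b = b, c = cc, statistic = NA_real_, p_value = 1,
                method = "degenerate")
  } else if (m < 25L) {
    res <- list(b = b, c = cc, statistic = min(b, cc),
                p_value = min(1, 2 * pbinom(min(b, cc), m, 0.5)),
                method = "exact")
  } else {
    stat <- (abs(b - cc) - 1)^2 / m
    res <- list(b = b, c = cc, statistic = stat,
                p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                method = "continuity-corrected")
  }
  structure(res, class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> b=%d c=%d, p = %.4g (%s)\n",
              x$b, x$c, x$p_value, x$method))
  invisible(x)
}

#' Paired comparison of CM-I and CM-II
#'
#' Runs both classifiers through the same repeated stratified k-fold splits
#' (identical folds per iteration) and compares them with [mcnemar_test()]
#' on the pooled out-of-fold predictions across all iterations.
#'
#' @inheritParams cross_validate
#' @return List with `cm1` and `cm2` (`"cv_result"`s) and `mcnemar`
#'   (`"mcnemar_result"`).
#' @export
compare_models <- function(incidents, k = 10L, iterations = 100L,
                           seed = NULL, K = 20L) {
  res <- .cv_engine(incidents, c("cm1", "cm2"), as.integer(k),
                    as.integer(iterations), seed, as.integer(K))
  truth <- rep(res$cm1$truth, ncol(res$cm1$predictions))
  list(cm1 = res$cm1, cm2 = res$cm2,
       mcnemar = mcnemar_test(truth,
                              as.vector(res$cm1$predictions),
                              as.vector(res$cm2$predictions)))
}
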