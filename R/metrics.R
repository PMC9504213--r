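#' Macro-averaged F1 score
#'
#' Mean over the classes in `class_set` of the per-class F1
#' `2 * precision * recall / (precision + recall)`; a class for which
#' precision + recall is zero (never predicted and never recovered, or absent)
#' contributes 0.
#'
#' @param predictions integer predicted class ids.
#' @param truths integer true class ids (same length).
#' @param class_set non-empty integer vector of classes to average over.
#' @return a value in `[0, 1]`.
#' @export
macro_f1 <- function(predictions, truths, class_set) {
  stopifnot(length(predictions) == length(truths), length(class_set) > 0L)
  mean(per_class_f1(predictions, truths, class_set))
}

#' Per-class F1 scores
#'
#' @inheritParams macro_f1
#' @return named numeric vector of F1 values, one per class in `class_set`.
#' @export
per_class_f1 <- function(predictions, truths, class_set) {
  vapply(stats::setNames(as.integer(class_set), class_set), function(k) {
    tp <- sum(predictions == k & truths == k)
    fp <- sum(predictions == k & truths != k)
    fn <- sum(predictions != k & truths == k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
}

#' Construct a metrics ledger
#'
#' The ledger records, per run and evaluation step, the per-class performance
#' `a[t, j]` (per-class F1 on held-out test windows) and the Base/New/Overall
#' macro-F1 summaries, plus the bookkeeping needed by the forgetting and
#' intransigence measures: the base-class set, the step each class was first
#' seen, and the offline reference performance `a*[j]`.
#'
#' @param base_classes integer vector of base class ids.
#' @return an object of class `metrics_ledger`.
#' @export
metrics_ledger <- function(base_classes = integer(0)) {
  structure(list(
    class_history = data.frame(run = integer(0), step = integer(0),
                               class = integer(0), f1 = numeric(0)),
    summary_history = data.frame(run = integer(0), step = integer(0),
                                 split = character(0), f1 = numeric(0)),
    reference = numeric(0),
    base_classes = as.integer(base_classes),
    class_first_seen = data.frame(run = integer(0), class = integer(0),
                                  step = integer(0))),
    class = "metrics_ledger")
}

#' @export
print.metrics_ledger <- function(x, ...) {
  cat(sprintf("<metrics_ledger> %d runs, %d evaluation rows, %d base classes\n",
              length(unique(x$summary_history$run)),
              nrow(x$summary_history), length(x$base_classes)))
  invisible(x)
}

# Append one evaluation step's records to a ledger.
ledger_record <- function(ledger, run, step, per_class, summaries,
                          first_seen = NULL) {
  if (length(per_class) > 0L) {
    bad <- per_class < 0 | per_class > 1
    stopifnot(!any(bad))
    ledger$class_history <- rbind(
      ledger$class_history,
      data.frame(run = run, step = step,
                 class = as.integer(names(per_class)),
                 f1 = unname(per_class)))
  }
  if (length(summaries) > 0L)
    ledger$summary_history <- rbind(
      ledger$summary_history,
      data.frame(run = run, step = step, split = names(summaries),
                 f1 = unname(summaries)))
  if (!is.null(first_seen)) {
    fs <- ledger$class_first_seen
    for (k in names(first_seen)) {
      kk <- as.integer(k)
      if (!any(fs$run == run & fs$class == kk))
        fs <- rbind(fs, data.frame(run = run, class = kk,
                                   step = first_seen[[k]]))
    }
    ledger$class_first_seen <- fs
  }
  ledger
}

#' Forgetting measure over base classes
#'
#' For each base class `j`, forgetting at step `t` is
#' `f[t, j] = 1 - a[t, j] / max_{l < t} a[l, j]` — one minus the ratio of
#' current to historical-best performance, floored at 0 so that a class whose
#' performance is still improving (or whose historical maximum is 0) reports
#' no forgetting. The average `F[t]` is the mean over base classes. High
#' values indicate catastrophic forgetting.
#'
#' @param ledger a [metrics_ledger()] with recorded history.
#' @param run run id.
#' @param step evaluation step `t`; at least one earlier step must exist.
#' @return list with `per_class` (named vector `f[t, j]`) and `average`.
#' @export
forgetting <- function(ledger, run, step) {
  base <- ledger$run_base[[as.character(run)]] %||% ledger$base_classes
  h <- ledger$class_history
  h <- h[h$run == run & h$class %in% base, , drop = FALSE]
  prior <- h[h$step < step, , drop = FALSE]
  now <- h[h$step == step, , drop = FALSE]
  if (nrow(prior) == 0L || nrow(now) == 0L)
    stop("insufficient history: forgetting needs at least one earlier step",
         call. = FALSE)
  per <- vapply(stats::setNames(base, base), function(j) {
    mx <- max(prior$f1[prior$class == j], -Inf)
    cur <- now$f1[now$class == j]
    if (!is.finite(mx) || length(cur) == 0L) return(NA_real_)
    if (mx == 0) 0 else max(0, 1 - cur[1L] / mx)
  }, numeric(1))
  list(per_class = per, average = mean(per, na.rm = TRUE))
}

#' Intransigence measure over new classes
#'
#' For each new class `j` first seen by step `t`, intransigence is
#' `I[t, j] = a*[j] - a[t, j]`: the gap between the offline reference model's
#' performance on that class and the continual model's current performance
#' (negative values mean the continual model beats the reference). The
#' average is the mean over those classes. Low values indicate good plasticity.
#'
#' @inheritParams forgetting
#' @return list with `per_class` (named vector `I[t, j]`) and `average`.
#' @export
intransigence <- function(ledger, run, step) {
  if (length(ledger$reference) == 0L)
    stop("missing reference: populate ledger$reference from an offline run",
         call. = FALSE)
  h <- ledger$class_history
  now <- h[h$run == run & h$step == step, , drop = FALSE]
  base <- ledger$run_base[[as.character(run)]] %||% ledger$base_classes
  fs <- ledger$class_first_seen
  fs <- fs[fs$run == run & fs$step <= step, , drop = FALSE]
  new_seen <- setdiff(fs$class, base)
  if (length(new_seen) == 0L)
    return(list(per_class = numeric(0), average = NA_real_))
  per <- vapply(stats::setNames(new_seen, new_seen), function(j) {
    ref <- ledger$reference[as.character(j)]
    if (is.na(ref))
      stop("missing reference for class ", j, call. = FALSE)
    cur <- now$f1[now$class == j]
    if (length(cur) == 0L) return(NA_real_)
    unname(ref - cur[1L])
  }, numeric(1))
  list(per_class = per, average = mean(per, na.rm = TRUE))
}
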