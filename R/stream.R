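#' Plan of a streaming experiment
#'
#' Defines the base/new class split, the pretrain/stream data split and the
#' non-i.i.d. batch schedule of the task-free data-incremental protocol:
#' a subset of classes is available for offline pretraining (half of their
#' training windows by default), and the remainder of the training data is
#' streamed in small batches containing at most a handful of distinct classes.
#'
#' @param n_base number of base classes (default 5).
#' @param base_classes optional fixed integer vector of base class ids; when
#'   `NULL` they are drawn uniformly at random under `seed`.
#' @param pretrain_fraction fraction of each base class's training windows
#'   used for offline pretraining (default 0.5).
#' @param stream_batch_size windows per stream batch (default 20).
#' @param max_classes_per_batch maximum distinct classes per stream batch
#'   (default 5); must not exceed `stream_batch_size`.
#' @param pretrain_batch_size windows per pretraining episode batch
#'   (default 200).
#' @param epochs pretraining epochs (default 100).
#' @param episodes_per_epoch episodes (gradient steps) per epoch (default 1).
#' @param seed integer seed governing the split and the schedule.
#' @return an object of class `stream_plan`.
#' @export
stream_plan <- function(n_base = 5L, base_classes = NULL,
                        pretrain_fraction = 0.5, stream_batch_size = 20L,
                        max_classes_per_batch = 5L, pretrain_batch_size = 200L,
                        epochs = 100L, episodes_per_epoch = 1L, seed = 1L) {
  plan <- list(n_base = as.integer(n_base),
               base_classes = if (!is.null(base_classes)) as.integer(base_classes),
               pretrain_fraction = pretrain_fraction,
               stream_batch_size = as.integer(stream_batch_size),
               max_classes_per_batch = as.integer(max_classes_per_batch),
               pretrain_batch_size = as.integer(pretrain_batch_size),
               epochs = as.integer(epochs),
               episodes_per_epoch = as.integer(episodes_per_epoch),
               seed = as.integer(seed))
  stopifnot(plan$n_base >= 1L, pretrain_fraction > 0, pretrain_fraction < 1,
            plan$episodes_per_epoch >= 1L,
            plan$stream_batch_size >= 1L, plan$epochs >= 1L,
            plan$max_classes_per_batch >= 1L,
            plan$max_classes_per_batch <= plan$stream_batch_size)
  structure(plan, class = "stream_plan")
}

#' Segment a continuous multichannel signal into labelled windows
#'
#' Windows are cut at offsets `0, step_len, 2*step_len, ...`; only full-length
#' windows are kept (a trailing remainder is dropped). Each window's label is
#' the majority per-sample label within it, with ties resolved to the label at
#' the window's last timestep.
#'
#' @param signal `samples x channels` numeric matrix.
#' @param labels per-sample integer class ids (length `samples`).
#' @param window_len window length in samples; must not exceed `samples`.
#' @param step_len hop between window starts in samples.
#' @return a [window_batch()].
#' @export
sliding_windows <- function(signal, labels, window_len, step_len) {
  signal <- as.matrix(signal)
  n_samp <- nrow(signal)
  window_len <- as.integer(window_len); step_len <- as.integer(step_len)
  if (window_len > n_samp)
    stop("window_len exceeds the number of samples", call. = FALSE)
  stopifnot(step_len >= 1L, length(labels) == n_samp)
  labels <- as.integer(labels)
  starts <- seq.int(1L, n_samp - window_len + 1L, by = step_len)
  C <- ncol(signal)
  w <- array(0, dim = c(length(starts), C, window_len))
  lab <- integer(length(starts))
  for (i in seq_along(starts)) {
    rng <- starts[i]:(starts[i] + window_len - 1L)
    w[i, , ] <- t(signal[rng, , drop = FALSE])
    ll <- labels[rng]
    tab <- table(ll)
    top <- as.integer(names(tab)[tab == max(tab)])
    lab[i] <- if (length(top) == 1L) top else ll[window_len]
  }
  window_batch(w, lab)
}

#' Split a dataset into pretraining, stream pool and test sets
#'
#' Base classes are chosen (randomly under the plan seed unless pinned in the
#' plan); `pretrain_fraction` of each base class's training windows forms the
#' offline pretraining set; the remaining base-class training windows together
#' with all new-class training windows form the stream pool.
#'
#' @param data a list with elements `train` and `test`, each a
#'   [window_batch()].
#' @param plan a [stream_plan()].
#' @return a list with `pretrain`, `stream_pool`, `base_test`, `full_test`
#'   ([window_batch()]s) and `base_classes`, `new_classes` (integer vectors).
#' @export
split_experiment <- function(data, plan) {
  stopifnot(inherits(plan, "stream_plan"),
            inherits(data$train, "window_batch"),
            inherits(data$test, "window_batch"))
  classes <- sort(unique(data$train$labels))
  if (length(classes) < plan$n_base + 1L)
    stop(sprintf("insufficient classes: need at least %d, found %d",
                 plan$n_base + 1L, length(classes)), call. = FALSE)
  base <- if (!is.null(plan$base_classes)) {
    stopifnot(all(plan$base_classes %in% classes))
    sort(plan$base_classes)
  } else {
    with_seed(derive_seed(plan$seed, "split-classes"),
              sort(sample(classes, plan$n_base)))
  }
  new_classes <- setdiff(classes, base)
  pre_idx <- with_seed(derive_seed(plan$seed, "split-pretrain"), {
    unlist(lapply(base, function(k) {
      idx <- which(data$train$labels == k)
      sample(idx, round(plan$pretrain_fraction * length(idx)))
    }))
  })
  pool_idx <- setdiff(seq_len(n_windows(data$train)), pre_idx)
  pool_idx <- pool_idx[data$train$labels[pool_idx] %in% c(base, new_classes)]
  list(pretrain = wb_subset(data$train, pre_idx),
       stream_pool = wb_subset(data$train, pool_idx),
       base_test = wb_subset(data$test, which(data$test$labels %in% base)),
       full_test = data$test,
       base_classes = base, new_classes = new_classes)
}

#' Schedule a non-i.i.d. stream from a pool of windows
#'
#' Batches are drawn without replacement until the pool is exhausted: for each
#' batch, at most `max_classes_per_batch` classes are chosen uniformly among
#' those with remaining windows, then the batch slots are filled uniformly
#' from the chosen classes' remaining windows. Every pool window appears in
#' exactly one batch; the final batch may be short.
#'
#' @param pool a [window_batch()].
#' @param plan a [stream_plan()].
#' @return a list of [window_batch()]es with consecutive `step_index`.
#' @export
schedule_stream <- function(pool, plan) {
  stopifnot(inherits(pool, "window_batch"), n_windows(pool) > 0L)
  with_seed(derive_seed(plan$seed, "schedule"), {
    remaining <- seq_len(n_windows(pool))
    batches <- list()
    step <- 1L
    while (length(remaining) > 0L) {
      cls_avail <- unique(pool$labels[remaining])
      k <- min(plan$max_classes_per_batch, length(cls_avail))
      chosen <- if (length(cls_avail) == 1L) cls_avail else sample(cls_avail, k)
      cand <- remaining[pool$labels[remaining] %in% chosen]
      m <- min(plan$stream_batch_size, length(cand))
      take <- if (length(cand) == 1L) cand else sample(cand, m)
      batches[[step]] <- wb_subset(pool, take)
      batches[[step]]$step_index <- step
      remaining <- setdiff(remaining, take)
      step <- step + 1L
    }
    batches
  })
}

#' Read a labelled-window dataset from disk
#'
#' Two plain-text layouts are supported, described by a small YAML/list format
#' descriptor:
#' \describe{
#'   \item{`kind: windows`}{`windows` CSV with one row per window (values
#'     flattened channel-fastest, i.e. `c(window[channel, time])`), a `labels`
#'     file with one class id per line, plus `channels` and `window_len`.}
#'   \item{`kind: raw`}{a delimited file of per-sample rows with channel
#'     columns and a label column, segmented via [sliding_windows()]; fields:
#'     `file`, `delimiter`, `label_col`, `channel_cols`, `window_len`,
#'     `step_len` (both in samples).}
#' }
#' Rows containing missing channel values are dropped; the number dropped is
#' reported via a message and the `"dropped"` attribute.
#'
#' @param path directory containing the files named in the descriptor (or the
#'   raw file's directory).
#' @param format a list, or path to a YAML file, with the fields above.
#' @return a [window_batch()] with attribute `dropped`.
#' @export
read_dataset <- function(path, format) {
  if (is.character(format) && length(format) == 1L)
    format <- yaml::read_yaml(format)
  stopifnot(is.list(format), !is.null(format$kind))
  if (format$kind == "windows") {
    wfile <- file.path(path, format$windows %||% "windows.csv")
    lfile <- file.path(path, format$labels %||% "labels.csv")
    vals <- utils::read.csv(wfile, header = FALSE)
    labels <- as.integer(readLines(lfile))
    C <- as.integer(format$channels); T <- as.integer(format$window_len)
    if (ncol(vals) != C * T)
      stop(sprintf("windows file has %d columns; expected channels*window_len = %d",
                   ncol(vals), C * T), call. = FALSE)
    keep <- stats::complete.cases(vals)
    dropped <- which(!keep)
    if (length(dropped) > 0L)
      message(sprintf("read_dataset: dropped %d window row(s) with missing values (rows %s)",
                      length(dropped), paste(dropped, collapse = ", ")))
    vals <- as.matrix(vals[keep, , drop = FALSE])
    labels <- labels[keep]
    if (nrow(vals) == 0L) stop("no complete windows in file", call. = FALSE)
    w <- array(0, dim = c(nrow(vals), C, T))
    for (i in seq_len(nrow(vals))) w[i, , ] <- matrix(vals[i, ], C, T)
    out <- window_batch(w, labels)
  } else if (format$kind == "raw") {
    rfile <- file.path(path, format$file)
    df <- utils::read.table(rfile, sep = format$delimiter %||% ",",
                            header = isTRUE(format$header))
    ch_cols <- format$channel_cols
    keep <- stats::complete.cases(df[, ch_cols, drop = FALSE])
    dropped <- which(!keep)
    if (length(dropped) > 0L)
      message(sprintf("read_dataset: dropped %d sample row(s) with missing values (rows %s)",
                      length(dropped), paste(dropped, collapse = ", ")))
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0L) stop("no complete samples in file", call. = FALSE)
    out <- sliding_windows(as.matrix(df[, ch_cols, drop = FALSE]),
                           df[[format$label_col]],
                           format$window_len, format$step_len)
  } else {
    stop("unknown dataset kind: ", format$kind, call. = FALSE)
  }
  attr(out, "dropped") <- if (exists("dropped")) dropped else integer(0)
  out
}
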