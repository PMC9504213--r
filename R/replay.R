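#' Create an empty replay buffer
#'
#' A fixed-capacity per-class store of *raw* windows (not embeddings), so
#' exemplars can be re-embedded under any later encoder state. Exemplars are
#' selected by uniform random sampling without replacement; a class once
#' stored is never evicted entirely, only its contents are resampled.
#'
#' @param capacity_per_class maximum windows stored per class (default 6).
#' @param seed integer seed for the buffer's own sampling sub-stream.
#' @return an object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity_per_class = 6L, seed = 1L) {
  stopifnot(capacity_per_class >= 1L)
  structure(list(store = list(), capacity_per_class = as.integer(capacity_per_class),
                 seed = as.integer(seed), n_updates = 0L),
            class = "replay_buffer")
}

#' @export
print.replay_buffer <- function(x, ...) {
  n <- vapply(x$store, function(a) dim(a)[1L], integer(1))
  cat(sprintf("<replay_buffer> %d classes, %d windows stored, capacity %d/class\n",
              length(x$store), sum(n), x$capacity_per_class))
  invisible(x)
}

#' Classes currently stored in a replay buffer
#' @param buffer a [replay_buffer()].
#' @return sorted integer vector of class ids.
#' @export
buffer_classes <- function(buffer) sort(as.integer(names(buffer$store)))

#' All buffered windows as one batch
#' @param buffer a [replay_buffer()].
#' @return a [window_batch()], or `NULL` when the buffer is empty.
#' @export
buffer_contents <- function(buffer) {
  if (length(buffer$store) == 0L) return(NULL)
  keys <- as.character(buffer_classes(buffer))
  ws <- lapply(keys, function(k) buffer$store[[k]])
  n <- vapply(ws, function(a) dim(a)[1L], integer(1))
  d <- dim(ws[[1L]])[-1L]
  out <- array(0, dim = c(sum(n), d))
  at <- 0L
  for (a in ws) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  window_batch(out, rep(as.integer(keys), n))
}

#' Resample the replay buffer from the current combined batch
#'
#' `batch` is the combined set of the current step (the stream batch joined
#' with the current buffer contents). For every class present in the batch the
#' new store is a uniform without-replacement sample of
#' `min(capacity, available)` of its windows; stored classes absent from the
#' batch keep their windows. An empty batch is a no-op. Sampling uses the
#' buffer's own seeded sub-stream, so buffer contents are reproducible for a
#' fixed batch sequence regardless of surrounding RNG use.
#'
#' @param buffer a [replay_buffer()].
#' @param batch a [window_batch()] (the union of the stream batch and the
#'   buffer contents), or `NULL`.
#' @return the updated buffer.
#' @export
update_buffer <- function(buffer, batch) {
  stopifnot(inherits(buffer, "replay_buffer"))
  if (is.null(batch) || n_windows(batch) == 0L) return(buffer)
  buffer$n_updates <- buffer$n_updates + 1L
  b <- buffer$capacity_per_class
  with_seed(derive_seed(buffer$seed, paste0("update", buffer$n_updates)), {
    for (k in sort(unique(batch$labels))) {
      idx <- which(batch$labels == k)
      take <- if (length(idx) <= b) idx else sample(idx, b)
      buffer$store[[as.character(k)]] <-
        batch$windows[take, , , drop = FALSE]
    }
  })
  buffer
}

#' Form the combined query set of a step
#'
#' Concatenates the incoming stream batch with all buffered exemplars and
#' shuffles the order (under the ambient RNG, i.e. the run seed).
#'
#' @param buffer a [replay_buffer()].
#' @param stream_batch a [window_batch()].
#' @return a [window_batch()] whose label multiset is the union of the batch
#'   and buffer label multisets.
#' @export
make_query_set <- function(buffer, stream_batch) {
  held <- buffer_contents(buffer)
  q <- if (is.null(held)) stream_batch else wb_concat(stream_batch, held)
  perm <- sample.int(n_windows(q))
  out <- wb_subset(q, perm)
  out$step_index <- stream_batch$step_index
  out
}
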