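#' Construct a batch of labelled sensor windows
#'
#' The unit of streaming: `n` fixed-length multichannel segments stored as an
#' `n x channels x timesteps` array with one integer activity label per window.
#'
#' @param windows numeric array of dimension `n x channels x timesteps`, all
#'   values finite.
#' @param labels integer vector of length `n` of class ids.
#' @param step_index nonnegative integer position of this batch in a stream.
#' @return an object of class `window_batch`.
#' @export
window_batch <- function(windows, labels, step_index = 0L) {
  if (length(dim(windows)) != 3L)
    stop("`windows` must be an n x channels x timesteps array", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != dim(windows)[1L])
    stop("`labels` length must equal the number of windows", call. = FALSE)
  if (!all(is.finite(windows)))
    stop("`windows` contains non-finite values", call. = FALSE)
  structure(
    list(windows = windows, labels = labels, step_index = as.integer(step_index)),
    class = "window_batch"
  )
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_batch> %d windows, %d channels x %d timesteps, %d classes\n",
              d[1L], d[2L], d[3L], length(unique(x$labels))))
  invisible(x)
}

#' Number of windows in a batch
#' @param batch a [window_batch()].
#' @return integer count.
#' @export
n_windows <- function(batch) dim(batch$windows)[1L]

# Subset a window_batch by window index (drop = FALSE semantics throughout).
wb_subset <- function(batch, idx) {
  window_batch(batch$windows[idx, , , drop = FALSE], batch$labels[idx],
               batch$step_index)
}

# Concatenate window batches along the window axis.
wb_concat <- function(...) {
  parts <- Filter(function(b) !is.null(b) && n_windows(b) > 0L, list(...))
  if (length(parts) == 0L) stop("nothing to concatenate", call. = FALSE)
  if (length(parts) == 1L) return(parts[[1L]])
  d <- dim(parts[[1L]]$windows)[-1L]
  for (p in parts)
    if (!identical(dim(p$windows)[-1L], d))
      stop("window shapes differ across batches", call. = FALSE)
  n <- sum(vapply(parts, n_windows, integer(1)))
  w <- array(0, dim = c(n, d))
  at <- 0L
  for (p in parts) {
    np <- n_windows(p)
    w[at + seq_len(np), , ] <- p$windows
    at <- at + np
  }
  window_batch(w, unlist(lapply(parts, `[[`, "labels")),
               parts[[1L]]$step_index)
}
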