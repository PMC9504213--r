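#' Augmentation configuration
#'
#' Parameters of the four time-series augmentations applied to incoming
#' stream batches. Defaults follow common practice for inertial signals:
#' jitter at a few percent of signal scale, scaling within 20% of unity, and
#' smooth warps built from cubic splines through a handful of perturbed knots.
#'
#' @param jitter_sigma standard deviation of additive Gaussian noise.
#' @param scale_range `(low, high)` range of the per-window scaling factor.
#' @param timewarp_knots interior knots of the temporal distortion spline.
#' @param timewarp_sigma spread of the warp-speed perturbations around 1.
#' @param magwarp_knots interior knots of the magnitude-warp spline.
#' @param magwarp_sigma spread of the magnitude-curve ordinates around 1.
#' @param seed optional integer; when given, [expand_batch()] derives its
#'   randomness from it (per step), otherwise the ambient RNG is used.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(jitter_sigma = 0.03, scale_range = c(0.8, 1.2),
                           timewarp_knots = 4L, timewarp_sigma = 0.2,
                           magwarp_knots = 4L, magwarp_sigma = 0.2,
                           seed = NULL) {
  stopifnot(jitter_sigma > 0, timewarp_sigma > 0, magwarp_sigma > 0,
            length(scale_range) == 2L, scale_range[1L] > 0,
            scale_range[1L] < scale_range[2L] ||
              all(scale_range == c(1, 1)),
            timewarp_knots >= 1L, magwarp_knots >= 1L)
  structure(list(jitter_sigma = jitter_sigma, scale_range = scale_range,
                 timewarp_knots = as.integer(timewarp_knots),
                 timewarp_sigma = timewarp_sigma,
                 magwarp_knots = as.integer(magwarp_knots),
                 magwarp_sigma = magwarp_sigma,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "augment_config")
}

#' Time-series augmentations for window batches
#'
#' Four label-preserving, shape-preserving transforms:
#' * `jitter_windows()` adds i.i.d. Gaussian noise to every sample;
#' * `scale_windows()` multiplies each window by one scalar drawn uniformly
#'   from `range`;
#' * `time_warp()` resamples each window along a smooth random monotone time
#'   distortion (cubic spline through `knots` perturbed anchors, integrated
#'   and rescaled to the window length);
#' * `magnitude_warp()` multiplies each channel by a smooth random curve with
#'   ordinates around 1.
#'
#' Each transform degenerates to the identity as its parameter goes to 0
#' (or to `(1, 1)` for the scale range).
#'
#' @param batch a [window_batch()].
#' @param sigma noise / warp spread.
#' @param range scaling-factor range `(low, high)`.
#' @param knots number of interior spline knots.
#' @return a [window_batch()] of the same shape and labels.
#' @name augmentations
NULL

#' @rdname augmentations
#' @export
jitter_windows <- function(batch, sigma) {
  w <- batch$windows
  w <- w + stats::rnorm(length(w), 0, sigma)
  window_batch(w, batch$labels, batch$step_index)
}

#' @rdname augmentations
#' @export
scale_windows <- function(batch, range) {
  n <- n_windows(batch)
  f <- stats::runif(n, range[1L], range[2L])
  window_batch(batch$windows * f, batch$labels, batch$step_index)
}

# Smooth random curve of length T through `knots` interior anchors whose
# ordinates are N(center, sigma).
.random_curve <- function(T, knots, sigma, center = 1) {
  xs <- seq(1, T, length.out = knots + 2L)
  ys <- stats::rnorm(knots + 2L, center, sigma)
  stats::spline(xs, ys, xout = seq_len(T))$y
}

#' @rdname augmentations
#' @export
time_warp <- function(batch, knots, sigma) {
  d <- dim(batch$windows); n <- d[1L]; C <- d[2L]; T <- d[3L]
  out <- batch$windows
  for (i in seq_len(n)) {
    rate <- pmax(.random_curve(T, knots, sigma), 1e-3)  # positive warp speed
    pos <- cumsum(rate)
    pos <- 1 + (pos - pos[1L]) / (pos[T] - pos[1L]) * (T - 1)  # monotone, [1, T]
    for (ch in seq_len(C))
      out[i, ch, ] <- stats::approx(seq_len(T), batch$windows[i, ch, ],
                                    xout = pos, rule = 2)$y
  }
  window_batch(out, batch$labels, batch$step_index)
}

#' @rdname augmentations
#' @export
magnitude_warp <- function(batch, knots, sigma) {
  d <- dim(batch$windows); n <- d[1L]; C <- d[2L]; T <- d[3L]
  out <- batch$windows
  for (i in seq_len(n))
    for (ch in seq_len(C))
      out[i, ch, ] <- batch$windows[i, ch, ] * .random_curve(T, knots, sigma)
  window_batch(out, batch$labels, batch$step_index)
}

#' Expand a stream batch with augmented copies
#'
#' Concatenates the original batch with one copy under each of the four
#' augmentations, quintupling the batch (`n` originals + `4n` augmented).
#' Labels are replicated accordingly. With `enabled = FALSE` the batch is
#' returned unchanged.
#'
#' @param batch a [window_batch()].
#' @param config an [augment_config()].
#' @param enabled logical switch.
#' @return a [window_batch()] of `5n` windows (or the input when disabled).
#' @export
expand_batch <- function(batch, config, enabled = TRUE) {
  if (!enabled) return(batch)
  stopifnot(inherits(config, "augment_config"))
  run <- function() wb_concat(
    batch,
    jitter_windows(batch, config$jitter_sigma),
    scale_windows(batch, config$scale_range),
    time_warp(batch, config$timewarp_knots, config$timewarp_sigma),
    magnitude_warp(batch, config$magwarp_knots, config$magwarp_sigma))
  if (!is.null(config$seed))
    with_seed(derive_seed(config$seed, paste0("expand", batch$step_index)), run())
  else run()
}
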