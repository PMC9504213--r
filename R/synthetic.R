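#' Specification of a synthetic multichannel activity stream
#'
#' The generator emulates the statistical structure of wearable-sensor
#' activity data as the framework assumes it: each class has a fixed
#' multichannel signal archetype (a periodic waveform mixture or band-limited
#' noise), every window is its class archetype plus Gaussian noise, classes
#' may be imbalanced, and designated "confusable" pairs share near-duplicate
#' archetypes, mimicking activities with very similar sensor patterns.
#'
#' Archetypes are scaled to Frobenius norm `class_separation`, so the expected
#' distance between two archetypes in signal space is about
#' `class_separation * sqrt(2)` and the difficulty of the raw-space problem is
#' governed by the ratio of `class_separation` to `noise_sigma`.
#'
#' @param n_classes number of classes.
#' @param channels sensor channels per window.
#' @param window_len timesteps per window.
#' @param archetype_kind `"sinusoid-mixture"` (default) or
#'   `"band-limited-noise"`.
#' @param class_separation positive scale of the class archetypes in signal
#'   space.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param windows_per_class scalar, or one count per class (imbalance).
#' @param confusable_pairs list of integer pairs whose archetypes are
#'   perturbed copies of each other; the perturbation norm is
#'   `confusable_scale / class_separation`, so higher separation makes
#'   confusable pairs *harder* to tell apart relative to the rest.
#' @param confusable_scale numerator of the perturbation norm (default 4).
#' @param train_fraction per-class fraction assigned to the training
#'   partition (default 2/3).
#' @param seed integer seed; generation is bitwise-deterministic given it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 10L, channels = 6L, window_len = 32L,
                           archetype_kind = c("sinusoid-mixture",
                                              "band-limited-noise"),
                           class_separation = 5, noise_sigma = 1,
                           windows_per_class = 60L,
                           confusable_pairs = list(),
                           confusable_scale = 4,
                           train_fraction = 2 / 3, seed = 1L) {
  archetype_kind <- match.arg(archetype_kind)
  n_classes <- as.integer(n_classes)
  wpc <- as.integer(windows_per_class)
  if (length(wpc) == 1L) wpc <- rep(wpc, n_classes)
  if (length(wpc) != n_classes || any(wpc < 2L))
    stop("windows_per_class must be a scalar or one count (>= 2) per class",
         call. = FALSE)
  if (class_separation <= 0 || noise_sigma < 0)
    stop("class_separation must be positive and noise_sigma nonnegative",
         call. = FALSE)
  for (p in confusable_pairs)
    if (length(p) != 2L || !all(p %in% seq_len(n_classes)))
      stop("confusable_pairs must be pairs of valid class ids", call. = FALSE)
  structure(list(n_classes = n_classes, channels = as.integer(channels),
                 window_len = as.integer(window_len),
                 archetype_kind = archetype_kind,
                 class_separation = class_separation,
                 noise_sigma = noise_sigma, windows_per_class = wpc,
                 confusable_pairs = confusable_pairs,
                 confusable_scale = confusable_scale,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# One C x T archetype waveform (unit Frobenius norm before scaling).
.archetype <- function(spec) {
  C <- spec$channels; T <- spec$window_len
  a <- matrix(0, C, T)
  tt <- seq_len(T)
  for (ch in seq_len(C)) {
    if (spec$archetype_kind == "sinusoid-mixture") {
      f <- stats::runif(2L, 1, 6); ph <- stats::runif(2L, 0, 2 * pi)
      amp <- stats::runif(2L, 0.5, 1.5)
      a[ch, ] <- amp[1L] * sin(2 * pi * f[1L] * tt / T + ph[1L]) +
        amp[2L] * sin(2 * pi * f[2L] * tt / T + ph[2L])
    } else {
      x <- stats::rnorm(T + 8L)
      a[ch, ] <- stats::filter(x, rep(1 / 5, 5), sides = 2L)[5:(T + 4L)]
    }
  }
  a / sqrt(sum(a^2))
}

#' Generate a labelled synthetic activity dataset
#'
#' Draws the class archetypes, materialises every window as archetype plus
#' noise, and splits windows into stratified train/test partitions.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `train` and `test` ([window_batch()]s), the `C x T x K`
#'   `archetypes` array, and the `spec`.
#' @export
generate_stream_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  C <- spec$channels; T <- spec$window_len; K <- spec$n_classes
  arch <- with_seed(derive_seed(spec$seed, "archetypes"), {
    a <- array(0, dim = c(C, T, K))
    for (k in seq_len(K)) a[, , k] <- .archetype(spec)
    for (p in spec$confusable_pairs) {
      delta <- .archetype(spec)  # unit-norm random direction
      a[, , p[2L]] <- a[, , p[1L]] +
        delta * (spec$confusable_scale / spec$class_separation) /
          spec$class_separation
    }
    a * spec$class_separation
  })
  out <- with_seed(derive_seed(spec$seed, "windows"), {
    n_tot <- sum(spec$windows_per_class)
    w <- array(0, dim = c(n_tot, C, T))
    lab <- integer(n_tot)
    at <- 0L
    train_idx <- integer(0)
    for (k in seq_len(K)) {
      m <- spec$windows_per_class[k]
      idx <- at + seq_len(m)
      for (i in idx)
        w[i, , ] <- arch[, , k] + stats::rnorm(C * T, 0, spec$noise_sigma)
      lab[idx] <- k
      n_tr <- max(1L, round(spec$train_fraction * m))
      train_idx <- c(train_idx, sample(idx, n_tr))
      at <- at + m
    }
    list(w = w, lab = lab, train_idx = sort(train_idx))
  })
  all_idx <- seq_len(dim(out$w)[1L])
  test_idx <- setdiff(all_idx, out$train_idx)
  list(train = window_batch(out$w[out$train_idx, , , drop = FALSE],
                            out$lab[out$train_idx]),
       test = window_batch(out$w[test_idx, , , drop = FALSE],
                           out$lab[test_idx]),
       archetypes = arch, spec = spec)
}

#' Per-class accuracy table for a trained system
#'
#' Classifies the test partition with a trained encoder + prototype memory
#' and tabulates per-class accuracy, flagging confusable pairs. The full
#' confusion matrix is attached as the `"confusion"` attribute.
#'
#' @param data output of [generate_stream_data()].
#' @param state a trained [build_encoder()] state.
#' @param memory a [prototype_memory()] holding all classes.
#' @return a data.frame with columns `class`, `n`, `accuracy`,
#'   `confusable_with` (NA when not confusable); empty when the test set is
#'   empty.
#' @export
make_confusion_ledger <- function(data, state, memory) {
  test <- data$test
  if (n_windows(test) == 0L)
    return(data.frame(class = integer(0), n = integer(0),
                      accuracy = numeric(0), confusable_with = integer(0)))
  pred <- classify(memory, embed(state, test))$class
  classes <- sort(unique(test$labels))
  conf_with <- rep(NA_integer_, length(classes))
  for (p in data$spec$confusable_pairs) {
    conf_with[match(p[1L], classes)] <- p[2L]
    conf_with[match(p[2L], classes)] <- p[1L]
  }
  acc <- vapply(classes, function(k) {
    idx <- test$labels == k
    mean(pred[idx] == k)
  }, numeric(1))
  out <- data.frame(class = classes,
                    n = as.integer(table(factor(test$labels, classes))),
                    accuracy = acc, confusable_with = conf_with)
  attr(out, "confusion") <- table(truth = test$labels, predicted = pred)
  out
}
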