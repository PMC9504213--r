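#' Configuration of the convolutional-recurrent embedding network
#'
#' The encoder follows the DeepConvLSTM family widely used for wearable-sensor
#' activity recognition: a stack of valid, stride-1 temporal convolutions
#' (sensor channels as input feature maps) feeding stacked LSTM layers, with
#' the softmax head removed. The embedding of a window is the final-timestep
#' hidden state of the last LSTM layer, so the embedding dimension equals
#' `lstm_hidden` and the parameter count is independent of the number of
#' activity classes.
#'
#' @param in_channels positive integer, number of sensor channels.
#' @param window_len positive integer, timesteps per window; must exceed
#'   `conv_layers * (kernel_len - 1)` so the temporal axis survives the stack.
#' @param conv_layers number of 1-D convolutional layers (default 4).
#' @param conv_filters filters per convolutional layer (default 64).
#' @param kernel_len temporal kernel length (default 5).
#' @param lstm_layers number of LSTM layers (default 2).
#' @param lstm_hidden hidden units per LSTM layer; also the embedding
#'   dimension (default 128).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param dropout dropout probability applied between LSTM layers during
#'   training (default 0, off).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(in_channels, window_len, conv_layers = 4L,
                           conv_filters = 64L, kernel_len = 5L,
                           lstm_layers = 2L, lstm_hidden = 128L,
                           learning_rate = 0.001, dropout = 0, seed = 1L) {
  cfg <- list(in_channels = as.integer(in_channels),
              window_len = as.integer(window_len),
              conv_layers = as.integer(conv_layers),
              conv_filters = as.integer(conv_filters),
              kernel_len = as.integer(kernel_len),
              lstm_layers = as.integer(lstm_layers),
              lstm_hidden = as.integer(lstm_hidden),
              learning_rate = learning_rate,
              dropout = dropout,
              seed = as.integer(seed))
  stopifnot(cfg$in_channels > 0L, cfg$window_len > 0L, cfg$conv_layers > 0L,
            cfg$conv_filters > 0L, cfg$kernel_len > 0L, cfg$lstm_layers > 0L,
            cfg$lstm_hidden > 0L, learning_rate > 0, dropout >= 0, dropout < 1)
  if (cfg$window_len <= cfg$conv_layers * (cfg$kernel_len - 1L))
    stop(sprintf(
      "invalid config: window_len = %d does not survive %d convolutions of kernel %d (need > %d)",
      cfg$window_len, cfg$conv_layers, cfg$kernel_len,
      cfg$conv_layers * (cfg$kernel_len - 1L)), call. = FALSE)
  structure(cfg, class = "encoder_config")
}

#' Initialise an encoder
#'
#' Weights are drawn uniformly on `(-s, s)` with `s = 1/sqrt(fan_in)`;
#' LSTM forget-gate biases start at 1. Initialisation is reproducible from
#' `config$seed`.
#'
#' @param config an [encoder_config()].
#' @return an object of class `encoder_state` holding the parameters, the
#'   config, the optimiser state and a step counter.
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  params <- with_seed(derive_seed(config$seed, "init"), {
    conv <- vector("list", config$conv_layers)
    cin <- config$in_channels
    for (l in seq_len(config$conv_layers)) {
      fan <- cin * config$kernel_len
      s <- 1 / sqrt(fan)
      conv[[l]] <- list(
        W = matrix(stats::runif(fan * config$conv_filters, -s, s),
                   fan, config$conv_filters),
        b = numeric(config$conv_filters))
      cin <- config$conv_filters
    }
    lstm <- vector("list", config$lstm_layers)
    insz <- config$conv_filters
    H <- config$lstm_hidden
    for (l in seq_len(config$lstm_layers)) {
      s <- 1 / sqrt(insz)
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      lstm[[l]] <- list(
        Wx = matrix(stats::runif(insz * 4L * H, -s, s), insz, 4L * H),
        Wh = matrix(stats::runif(H * 4L * H, -1 / sqrt(H), 1 / sqrt(H)),
                    H, 4L * H),
        b = b)
      insz <- H
    }
    list(conv = conv, lstm = lstm)
  })
  structure(list(params = params, config = config, step_count = 0L,
                 opt = list(m = adam_init(params), v = adam_init(params),
                            t = 0L)),
            class = "encoder_state")
}

#' @export
print.encoder_state <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<encoder_state> %d conv x %d filters (k=%d), %d LSTM x %d hidden, d=%d, %d steps\n",
    cfg$conv_layers, cfg$conv_filters, cfg$kernel_len, cfg$lstm_layers,
    cfg$lstm_hidden, cfg$lstm_hidden, x$step_count))
  invisible(x)
}

# Full forward pass; keeps layer caches for backprop when `keep_cache = TRUE`.
encoder_forward <- function(state, X, keep_cache = FALSE, training = FALSE) {
  cfg <- state$config
  d <- dim(X)
  if (length(d) != 3L || d[2L] != cfg$in_channels || d[3L] != cfg$window_len)
    stop(sprintf("shape mismatch: expected n x %d x %d windows, got %s",
                 cfg$in_channels, cfg$window_len, paste(d, collapse = " x ")),
         call. = FALSE)
  conv_caches <- vector("list", cfg$conv_layers)
  A <- X
  for (l in seq_len(cfg$conv_layers)) {
    r <- conv1d_forward(A, state$params$conv[[l]]$W, state$params$conv[[l]]$b)
    A <- r$out
    if (keep_cache) conv_caches[[l]] <- r$cache
  }
  lstm_caches <- vector("list", cfg$lstm_layers)
  lstm_inputs <- vector("list", cfg$lstm_layers)
  drop_masks <- vector("list", cfg$lstm_layers)
  for (l in seq_len(cfg$lstm_layers)) {
    lstm_inputs[[l]] <- A
    r <- lstm_forward(A, state$params$lstm[[l]]$Wx,
                      state$params$lstm[[l]]$Wh, state$params$lstm[[l]]$b)
    A <- r$Hseq
    if (training && cfg$dropout > 0 && l < cfg$lstm_layers) {
      mask <- array(stats::rbinom(length(A), 1L, 1 - cfg$dropout) /
                      (1 - cfg$dropout), dim = dim(A))
      A <- A * mask
      drop_masks[[l]] <- mask
    }
    if (keep_cache) lstm_caches[[l]] <- r$cache
  }
  emb <- r$h_final
  list(emb = emb,
       cache = if (keep_cache)
         list(conv = conv_caches, lstm = lstm_caches,
              lstm_inputs = lstm_inputs, drop_masks = drop_masks,
              T_lstm = dim(A)[3L]))
}

# Backprop a gradient on the embeddings (n x d) down to parameter gradients.
encoder_backward <- function(state, cache, dEmb) {
  cfg <- state$config
  n <- nrow(dEmb); H <- cfg$lstm_hidden; T <- cache$T_lstm
  grads <- list(conv = vector("list", cfg$conv_layers),
                lstm = vector("list", cfg$lstm_layers))
  # seed: gradient only on the final-timestep hidden state of the last layer
  dHseq <- array(0, dim = c(n, H, T))
  dHseq[, , T] <- dEmb
  for (l in rev(seq_len(cfg$lstm_layers))) {
    p <- state$params$lstm[[l]]
    r <- lstm_backward(dHseq, cache$lstm_inputs[[l]], p$Wx, p$Wh,
                       cache$lstm[[l]])
    grads$lstm[[l]] <- list(Wx = r$dWx, Wh = r$dWh, b = r$db)
    dHseq <- r$dX
    if (l > 1L && !is.null(cache$drop_masks[[l - 1L]]))
      dHseq <- dHseq * cache$drop_masks[[l - 1L]]
  }
  dA <- dHseq
  for (l in rev(seq_len(cfg$conv_layers))) {
    r <- conv1d_backward(dA, state$params$conv[[l]]$W, cache$conv[[l]])
    grads$conv[[l]] <- list(W = r$dW, b = r$db)
    dA <- r$dX
  }
  grads
}

#' Embed a batch of windows
#'
#' Each row of the result is the embedding of one window: the convolutional
#' feature-map sequence is consumed by the LSTM stack and the final-timestep
#' hidden activation of the last layer is returned. Deterministic for fixed
#' parameters; rows are computed independently, so embedding a window alone or
#' inside a larger batch gives the same result.
#'
#' @param state an [build_encoder()] state.
#' @param windows a [window_batch()] or an `n x channels x timesteps` array.
#' @return an `n x d` numeric matrix, `d = config$lstm_hidden`.
#' @export
embed <- function(state, windows) {
  stopifnot(inherits(state, "encoder_state"))
  X <- if (inherits(windows, "window_batch")) windows$windows else windows
  encoder_forward(state, X)$emb
}

#' Apply one optimiser step
#'
#' Consumes parameter gradients (as produced by the training losses through
#' backpropagation) and applies one Adam update at `config$learning_rate`.
#' The loss value is checked for finiteness; `step_count` is incremented.
#'
#' @param state an `encoder_state`.
#' @param grads nested gradient list matching `state$params`.
#' @param loss_value the scalar loss the gradients were computed from.
#' @return the updated `encoder_state`.
#' @export
gradient_step <- function(state, grads, loss_value) {
  stopifnot(inherits(state, "encoder_state"))
  if (!is.finite(loss_value))
    stop("non-finite loss: cannot take a gradient step", call. = FALSE)
  t <- state$opt$t + 1L
  r <- adam_step(state$params, grads, state$opt$m, state$opt$v, t,
                 lr = state$config$learning_rate)
  state$params <- r$params
  state$opt <- list(m = r$m, v = r$v, t = t)
  state$step_count <- state$step_count + 1L
  state
}

# Zero-gradient template with the same structure as the parameters.
zero_grads <- function(state) adam_init(state$params)

#' Persist / restore an encoder checkpoint
#'
#' The checkpoint is a single binary file containing the parameters, the
#' optimiser state and the embedded config.
#'
#' @param state an `encoder_state`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `encoder_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "encoder_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "encoder_state"))
  state
}
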