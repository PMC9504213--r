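#' Configuration of a continual-learning run
#'
#' Bundles the encoder, stream plan and loss settings with the framework
#' hyperparameters and the mode preset:
#' \describe{
#'   \item{`full`}{replay in the loss, replay-based prototype adaptation and
#'     the contrastive term — the complete framework.}
#'   \item{`no_contrastive`}{replay and adaptation, cross-entropy only.}
#'   \item{`adapt_only`}{no replayed windows in the training loss and no
#'     contrastive term; the buffer is still maintained and used for
#'     prototype adaptation.}
#'   \item{`finetune`}{online finetuning baseline: cross-entropy on the
#'     incoming batch alone; prototypes still refined by online averaging but
#'     no replay, no adaptation, no buffer — the lower bound.}
#'   \item{`offline`}{offline supervised baseline: episodic training on all
#'     training data of all classes at once — the upper bound and the
#'     reference model for intransigence.}
#' }
#'
#' @param encoder an [encoder_config()].
#' @param plan a [stream_plan()].
#' @param loss a [loss_config()].
#' @param alpha refresh ratio in `[0, 1]` for prototype adaptation.
#' @param buffer_capacity replay-buffer capacity per class (default 6).
#' @param mode one of the presets above.
#' @param augment expand each incoming stream batch with the four
#'   augmentations (default FALSE).
#' @param augment_cfg an [augment_config()].
#' @param n_runs number of independent seeded runs (default 5).
#' @param eval_stride evaluate every `eval_stride` stream steps (default 1;
#'   the final step is always evaluated).
#' @param seed master seed; run `r` uses `seed + r - 1`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(encoder, plan, loss = loss_config(), alpha = 0.5,
                       buffer_capacity = 6L,
                       mode = c("full", "no_contrastive", "adapt_only",
                                "finetune", "offline"),
                       augment = FALSE, augment_cfg = augment_config(),
                       n_runs = 5L, eval_stride = 1L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(encoder, "encoder_config"), inherits(plan, "stream_plan"),
            inherits(loss, "loss_config"), alpha >= 0, alpha <= 1,
            buffer_capacity >= 1L, n_runs >= 1L, eval_stride >= 1L)
  structure(list(encoder = encoder, plan = plan, loss = loss, alpha = alpha,
                 buffer_capacity = as.integer(buffer_capacity), mode = mode,
                 augment = isTRUE(augment), augment_cfg = augment_cfg,
                 n_runs = as.integer(n_runs),
                 eval_stride = as.integer(eval_stride),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Mode preset flags.
.mode_flags <- function(mode, loss_cfg) {
  list(replay_in_loss = mode %in% c("full", "no_contrastive") &&
         loss_cfg$use_replay,
       contrastive = mode == "full" && loss_cfg$use_contrastive,
       adapt = mode %in% c("full", "no_contrastive", "adapt_only"),
       update_buffer = mode != "finetune")
}

# One episodic training step on `batch_idx` of `d0`: per-class 50/50
# support/query split, episode prototypes from supports (differentiated
# through), negative log-likelihood on queries, one Adam step.
.episode_step <- function(state, d0, batch_idx, distance) {
  labels <- d0$labels[batch_idx]
  sup <- integer(0); qry <- integer(0)
  for (k in unique(labels)) {
    idx <- batch_idx[labels == k]
    idx <- if (length(idx) > 1L) sample(idx) else idx
    ns <- max(1L, floor(length(idx) / 2))
    sup <- c(sup, idx[seq_len(ns)])
    if (length(idx) > ns) qry <- c(qry, idx[(ns + 1L):length(idx)])
  }
  if (length(qry) == 0L) return(state)  # nothing to score this episode
  all_idx <- c(sup, qry)
  fwd <- encoder_forward(state, d0$windows[all_idx, , , drop = FALSE],
                         keep_cache = TRUE, training = TRUE)
  ns <- length(sup)
  eg <- episode_loss_grad(fwd$emb[seq_len(ns), , drop = FALSE],
                          d0$labels[sup],
                          fwd$emb[(ns + 1L):length(all_idx), , drop = FALSE],
                          d0$labels[qry], distance)
  dE <- rbind(eg$dS, eg$dQ)
  grads <- encoder_backward(state, fwd$cache, dE)
  gradient_step(state, grads, eg$value)
}

#' Offline episodic pretraining
#'
#' Trains the encoder on the pretraining set with the few-shot episodic
#' procedure (one episode per sampled batch per epoch: prototypes from a
#' per-class support half, negative log-likelihood on the query half), then
#' computes the final base prototypes from *all* pretraining windows under
#' the trained encoder and seeds the replay buffer by random per-class
#' sampling from the pretraining set.
#'
#' @param state a fresh [build_encoder()] state.
#' @param d0 the pretraining [window_batch()]; every class needs at least two
#'   windows.
#' @param plan a [stream_plan()] (provides `epochs` and
#'   `pretrain_batch_size`).
#' @param buffer_capacity replay-buffer capacity per class.
#' @param distance prototype distance (see [prototype_memory()]).
#' @param buffer_seed seed for the buffer's sampling sub-stream.
#' @return a list with `state`, `memory` (one prototype per base class, counts
#'   equal to class sizes in `d0`) and `buffer`.
#' @export
pretrain <- function(state, d0, plan, buffer_capacity = 6L,
                     distance = "sqeuclidean", buffer_seed = 1L) {
  stopifnot(inherits(state, "encoder_state"), inherits(d0, "window_batch"))
  sizes <- table(d0$labels)
  if (any(sizes < 2L))
    stop("class with one window: cannot split support/query for class(es) ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  n <- n_windows(d0)
  bs <- min(plan$pretrain_batch_size, n)
  for (e in seq_len(plan$epochs * (plan$episodes_per_epoch %||% 1L))) {
    batch_idx <- if (bs == n) seq_len(n) else sample(n, bs)
    state <- .episode_step(state, d0, batch_idx, distance)
  }
  emb <- embed(state, d0)
  memory <- create_prototypes(prototype_memory(ncol(emb), distance),
                              emb, d0$labels)
  buffer <- update_buffer(replay_buffer(buffer_capacity, seed = buffer_seed),
                          d0)
  list(state = state, memory = memory, buffer = buffer)
}

#' Execute one continual-learning step
#'
#' Runs the per-step phase sequence on an incoming stream batch, in order:
#' (1) prototype-memory refinement under the pre-step encoder (online
#' averaging for known classes, creation for novel ones); (2) formation of
#' the query set (incoming batch joined with the replayed exemplars, when the
#' mode replays in the loss); (3) loss evaluation; (4) one gradient step;
#' (5) replay-based prototype adaptation under the post-step encoder;
#' (6) replay-buffer update. Phases 5–6 are skipped where the mode preset
#' disables them. The executed phases are recorded in the step record's
#' `event_log`.
#'
#' @param state the encoder state entering the step.
#' @param memory the [prototype_memory()].
#' @param buffer the [replay_buffer()].
#' @param batch the incoming stream [window_batch()].
#' @param config a [run_config()].
#' @return list with updated `state`, `memory`, `buffer` and a `record`
#'   (step index, loss value, classes in the batch, newly created classes,
#'   online predictions on the incoming batch, and the `event_log`).
#' @export
continual_step <- function(state, memory, buffer, batch, config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "offline")
    stop("offline mode has no streaming steps; use run_experiment()",
         call. = FALSE)
  flags <- .mode_flags(config$mode, config$loss)
  log <- character(0)

  if (config$augment)
    batch <- expand_batch(batch, config$augment_cfg)

  # (1) memory refinement under the pre-step encoder
  known_before <- memory_classes(memory)
  emb_b <- embed(state, batch)
  memory <- update_online(memory, emb_b, batch$labels)
  new_classes <- setdiff(memory_classes(memory), known_before)
  online <- classify(memory, emb_b)
  log <- c(log, "refine_memory")

  # (2) combined query set
  q <- if (flags$replay_in_loss) make_query_set(buffer, batch) else batch
  log <- c(log, "form_query_set")

  # (3) loss on the query set
  fwd <- encoder_forward(state, q$windows, keep_cache = TRUE, training = TRUE)
  ce <- ce_grad_fixed_protos(memory, fwd$emb, q$labels)
  loss_value <- ce$value
  dE <- ce$dE
  if (flags$contrastive) {
    cg <- contrastive_grad(fwd$emb, q$labels, config$loss$margin,
                           config$loss$contrastive_form)
    loss_value <- loss_value + cg$value
    dE <- dE + cg$dE
  }
  log <- c(log, "compute_loss")

  # (4) model update
  grads <- encoder_backward(state, fwd$cache, dE)
  state <- gradient_step(state, grads, loss_value)
  log <- c(log, "model_update")

  # (5) prototype adaptation under the post-step encoder
  if (flags$adapt) {
    held <- buffer_contents(buffer)
    if (!is.null(held)) {
      memory <- adapt_with_replay(memory, embed(state, held), held$labels,
                                  config$alpha)
      log <- c(log, "prototype_adapt")
    }
  }

  # (6) buffer update from the combined set
  if (flags$update_buffer) {
    q_buf <- if (flags$replay_in_loss) q else {
      held <- buffer_contents(buffer)
      if (is.null(held)) batch else wb_concat(batch, held)
    }
    buffer <- update_buffer(buffer, q_buf)
    log <- c(log, "buffer_update")
  }

  record <- list(step = batch$step_index, loss = loss_value,
                 classes = sort(unique(batch$labels)),
                 new_classes = new_classes,
                 online_pred = online$class, online_truth = batch$labels,
                 event_log = log)
  list(state = state, memory = memory, buffer = buffer, record = record)
}

# Evaluate the current model on the held-out test data: per-class F1 for base
# classes (on base-class test windows) and for seen new classes (on their
# test windows), plus Base/New/Overall macro-F1.
.evaluate_step <- function(state, memory, full_test, base_classes,
                           seen_new) {
  seen <- sort(c(base_classes, seen_new))
  idx <- which(full_test$labels %in% seen)
  pred <- classify(memory, embed(state, wb_subset(full_test, idx)))$class
  truth <- full_test$labels[idx]
  b <- truth %in% base_classes
  per_base <- per_class_f1(pred[b], truth[b], base_classes)
  summaries <- c(base = mean(per_base))
  per_new <- numeric(0)
  if (length(seen_new) > 0L) {
    nn <- truth %in% seen_new
    per_new <- per_class_f1(pred[nn], truth[nn], seen_new)
    summaries <- c(summaries, new = mean(per_new))
  }
  summaries <- c(summaries,
                 overall = macro_f1(pred, truth, seen))
  list(per_class = c(per_base, per_new), summaries = summaries)
}

#' Run a full continual-learning experiment
#'
#' For each of `n_runs` seeded runs: split the data (base/new classes,
#' pretrain/stream), pretrain offline on the base classes, schedule the
#' non-i.i.d. stream, iterate [continual_step()] over all batches and
#' evaluate on the held-out test data after pretraining and after every
#' `eval_stride`-th step (and the final step), recording per-class F1 and the
#' Base/New/Overall macro-F1 into a [metrics_ledger()].
#'
#' In `offline` mode the streaming phase is bypassed: the model is trained
#' episodically on all training data, prototypes are formed for all classes,
#' and the resulting per-class F1 (averaged over runs) fills the ledger's
#' intransigence reference.
#'
#' @param config a [run_config()].
#' @param data a list with `train` and `test` [window_batch()]s (e.g. from
#'   [generate_stream_data()]).
#' @return a [metrics_ledger()]; per-run step records (loss, classes, event
#'   log) are attached as `ledger$step_records`, and per-run base-class sets
#'   as `ledger$run_base`.
#' @export
run_experiment <- function(config, data) {
  stopifnot(inherits(config, "run_config"))
  ledger <- metrics_ledger()
  ledger$run_base <- list()
  ledger$step_records <- list()
  ref_acc <- list()
  for (r in seq_len(config$n_runs)) {
    run_seed <- config$seed + r - 1L
    plan_r <- config$plan; plan_r$seed <- run_seed
    enc_cfg <- config$encoder; enc_cfg$seed <- run_seed
    sp <- split_experiment(data, plan_r)
    ledger$run_base[[as.character(r)]] <- sp$base_classes
    if (r == 1L) ledger$base_classes <- sp$base_classes
    set.seed(derive_seed(run_seed, "run"))

    if (config$mode == "offline") {
      state <- build_encoder(enc_cfg)
      all_train <- data$train
      pre <- pretrain(state, all_train, plan_r,
                      buffer_capacity = config$buffer_capacity,
                      buffer_seed = derive_seed(run_seed, "buffer"))
      ev <- .evaluate_step(pre$state, pre$memory, data$test,
                           sp$base_classes, sp$new_classes)
      ledger <- ledger_record(ledger, r, 0L, ev$per_class, ev$summaries,
                              first_seen = stats::setNames(
                                rep(0L, length(sp$new_classes)),
                                sp$new_classes))
      ref_acc[[r]] <- ev$per_class
      next
    }

    state <- build_encoder(enc_cfg)
    pre <- pretrain(state, sp$pretrain, plan_r,
                    buffer_capacity = config$buffer_capacity,
                    buffer_seed = derive_seed(run_seed, "buffer"))
    state <- pre$state; memory <- pre$memory; buffer <- pre$buffer
    ev <- .evaluate_step(state, memory, data$test, sp$base_classes, integer(0))
    ledger <- ledger_record(ledger, r, 0L, ev$per_class, ev$summaries)

    schedule <- schedule_stream(sp$stream_pool, plan_r)
    seen_new <- integer(0)
    records <- vector("list", length(schedule))
    for (t in seq_along(schedule)) {
      st <- continual_step(state, memory, buffer, schedule[[t]], config)
      state <- st$state; memory <- st$memory; buffer <- st$buffer
      records[[t]] <- st$record
      newly <- setdiff(intersect(st$record$classes, sp$new_classes), seen_new)
      seen_new <- sort(c(seen_new, newly))
      first_seen <- if (length(newly) > 0L)
        stats::setNames(rep(t, length(newly)), newly)
      if (t %% config$eval_stride == 0L || t == length(schedule)) {
        ev <- .evaluate_step(state, memory, data$test, sp$base_classes,
                             seen_new)
        ledger <- ledger_record(ledger, r, t, ev$per_class, ev$summaries,
                                first_seen = first_seen)
      } else if (!is.null(first_seen)) {
        ledger <- ledger_record(ledger, r, t, numeric(0), numeric(0),
                                first_seen = first_seen)
      }
    }
    ledger$step_records[[as.character(r)]] <- records
  }
  if (config$mode == "offline" && length(ref_acc) > 0L) {
    classes <- sort(unique(unlist(lapply(ref_acc, names))))
    ledger$reference <- vapply(stats::setNames(classes, classes), function(k)
      mean(vapply(ref_acc, function(v) v[[k]], numeric(1))), numeric(1))
  }
  ledger
}

#' Copy the intransigence reference from an offline run
#'
#' @param ledger a [metrics_ledger()] from a streaming run.
#' @param offline_ledger a [metrics_ledger()] from `mode = "offline"`.
#' @return `ledger` with `reference` populated.
#' @export
attach_reference <- function(ledger, offline_ledger) {
  if (length(offline_ledger$reference) == 0L)
    stop("offline ledger carries no reference values", call. = FALSE)
  ledger$reference <- offline_ledger$reference
  ledger
}
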