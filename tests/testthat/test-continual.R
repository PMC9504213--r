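# Shared small experiment setup: 6 classes (3 base), reduced encoder.
make_setup <- function(seed = 60, n_classes = 6, n_base = 3,
                       windows_per_class = 24, epochs = 10) {
  data <- separable_data(n_classes = n_classes,
                         windows_per_class = windows_per_class, seed = seed)
  enc <- tiny_encoder_config(seed = seed)
  plan <- stream_plan(n_base = n_base, epochs = epochs,
                      pretrain_batch_size = 60, seed = seed)
  list(data = data, enc = enc, plan = plan)
}

test_that("pretraining fills memory and buffer per contract", {
  s <- make_setup()
  sp <- split_experiment(s$data, s$plan)
  set.seed(61)
  pre <- pretrain(build_encoder(s$enc), sp$pretrain, s$plan,
                  buffer_capacity = 4L)
  expect_setequal(memory_classes(pre$memory), sp$base_classes)
  # counts equal class sizes in the pretraining set
  for (k in sp$base_classes)
    expect_equal(unname(pre$memory$counts[[as.character(k)]]),
                 sum(sp$pretrain$labels == k))
  # buffer holds at most the capacity per base class
  expect_setequal(buffer_classes(pre$buffer), sp$base_classes)
  expect_true(all(vapply(pre$buffer$store, function(a) dim(a)[1],
                         integer(1)) <= 4L))
  # final prototypes are the all-data class means under the trained encoder
  emb <- embed(pre$state, sp$pretrain)
  naive <- naive_class_means(emb, sp$pretrain$labels)
  for (k in names(naive))
    expect_equal(unname(pre$memory$prototypes[k, ]), unname(naive[[k]]),
                 tolerance = 1e-10)
})

test_that("a class with a single window cannot be split for episodes", {
  s <- make_setup()
  one <- wb_subset(s$data$train, c(which(s$data$train$labels == 1L)[1],
                                   which(s$data$train$labels == 2L)))
  expect_error(pretrain(build_encoder(s$enc), one, s$plan),
               "class with one window")
})

test_that("well-separated base classes are mastered by pretraining", {
  s <- make_setup(seed = 62, epochs = 15)
  sp <- split_experiment(s$data, s$plan)
  set.seed(63)
  pre <- pretrain(build_encoder(s$enc), sp$pretrain, s$plan)
  pred <- classify(pre$memory, embed(pre$state, sp$base_test))$class
  expect_gte(macro_f1(pred, sp$base_test$labels, sp$base_classes), 0.95)
})

test_that("a continual step executes the phases in order", {
  s <- make_setup()
  cfg <- run_config(s$enc, s$plan, loss_config(margin = 1), alpha = 0.5,
                    mode = "full", n_runs = 1, seed = 64)
  sp <- split_experiment(s$data, s$plan)
  set.seed(64)
  pre <- pretrain(build_encoder(s$enc), sp$pretrain, s$plan)
  sched <- schedule_stream(sp$stream_pool, s$plan)
  st <- continual_step(pre$state, pre$memory, pre$buffer, sched[[1]], cfg)
  expect_identical(st$record$event_log,
                   c("refine_memory", "form_query_set", "compute_loss",
                     "model_update", "prototype_adapt", "buffer_update"))
  expect_equal(st$state$step_count, pre$state$step_count + 1L)
  expect_true(is.finite(st$record$loss))
  # a batch with a never-seen class grows the memory by exactly that class
  novel <- setdiff(unique(sched[[1]]$labels), memory_classes(pre$memory))
  expect_setequal(memory_classes(st$memory),
                  union(memory_classes(pre$memory), novel))
  expect_setequal(st$record$new_classes, novel)
})

test_that("the finetuning baseline skips adaptation and buffer maintenance", {
  s <- make_setup()
  sp <- split_experiment(s$data, s$plan)
  set.seed(65)
  pre <- pretrain(build_encoder(s$enc), sp$pretrain, s$plan)
  sched <- schedule_stream(sp$stream_pool, s$plan)
  cfg <- run_config(s$enc, s$plan, loss_config(margin = 1), mode = "finetune",
                    n_runs = 1, seed = 65)
  st <- continual_step(pre$state, pre$memory, pre$buffer, sched[[1]], cfg)
  expect_identical(st$record$event_log,
                   c("refine_memory", "form_query_set", "compute_loss",
                     "model_update"))
  # buffer untouched; memory still refined by online averaging
  expect_identical(st$buffer$store, pre$buffer$store)
  refined <- update_online(pre$memory, embed(pre$state, sched[[1]]),
                           sched[[1]]$labels)
  expect_equal(st$memory$prototypes, refined$prototypes)
  expect_equal(st$memory$counts, refined$counts)
})

test_that("alpha = 1 makes adaptation a no-op within the step", {
  s <- make_setup()
  sp <- split_experiment(s$data, s$plan)
  set.seed(66)
  pre <- pretrain(build_encoder(s$enc), sp$pretrain, s$plan)
  sched <- schedule_stream(sp$stream_pool, s$plan)
  cfg1 <- run_config(s$enc, s$plan, loss_config(margin = 1), alpha = 1,
                     mode = "full", n_runs = 1, seed = 66)
  set.seed(67)
  st <- continual_step(pre$state, pre$memory, pre$buffer, sched[[1]], cfg1)
  # memory after the step equals the refined-only memory (phases 1-4)
  refined <- update_online(pre$memory, embed(pre$state, sched[[1]]),
                           sched[[1]]$labels)
  expect_equal(st$memory$prototypes, refined$prototypes)
})

test_that("ablation modes differ from the full mode only in the disabled phases", {
  s <- make_setup()
  sp <- split_experiment(s$data, s$plan)
  set.seed(68)
  pre <- pretrain(build_encoder(s$enc), sp$pretrain, s$plan)
  sched <- schedule_stream(sp$stream_pool, s$plan)
  run_mode <- function(mode) {
    cfg <- run_config(s$enc, s$plan, loss_config(margin = 1), alpha = 0.5,
                      mode = mode, n_runs = 1, seed = 68)
    set.seed(100)  # identical ambient randomness across modes
    continual_step(pre$state, pre$memory, pre$buffer, sched[[1]], cfg)
  }
  full <- run_mode("full")
  noc <- run_mode("no_contrastive")
  adapt <- run_mode("adapt_only")
  expect_identical(noc$record$event_log, full$record$event_log)
  expect_identical(adapt$record$event_log, full$record$event_log)
  # phase-1 refinement identical everywhere (same encoder, same batch)
  expect_equal(noc$record$online_pred, full$record$online_pred)
  # the loss differs only by the contrastive term's presence
  expect_false(isTRUE(all.equal(full$record$loss, noc$record$loss)))
})

test_that("experiments aggregate per-run histories into one ledger", {
  s <- make_setup(seed = 69, epochs = 6)
  cfg <- run_config(s$enc, s$plan, loss_config(margin = 1), alpha = 0.5,
                    mode = "full", n_runs = 2, seed = 70)
  led <- run_experiment(cfg, s$data)
  expect_s3_class(led, "metrics_ledger")
  expect_setequal(unique(led$summary_history$run), 1:2)
  # distinct seeds produce distinct schedules
  labs1 <- lapply(led$step_records[["1"]], `[[`, "classes")
  labs2 <- lapply(led$step_records[["2"]], `[[`, "classes")
  expect_false(identical(labs1, labs2))
  # step 0 (post-pretraining) rows exist with base split only
  s0 <- led$summary_history[led$summary_history$step == 0, ]
  expect_setequal(s0$split, c("base", "overall"))
  # every evaluation row is a valid F1
  expect_true(all(led$summary_history$f1 >= 0 & led$summary_history$f1 <= 1))
  # final steps have base, new and overall summaries
  fin <- final_summaries(led)
  expect_setequal(unique(fin$split), c("base", "new", "overall"))
})

test_that("the offline baseline fills the intransigence reference", {
  s <- make_setup(seed = 71, epochs = 8)
  cfg <- run_config(s$enc, s$plan, loss_config(margin = 1), mode = "offline",
                    n_runs = 1, seed = 72)
  led_off <- run_experiment(cfg, s$data)
  expect_length(led_off$reference, 6L)
  expect_true(all(led_off$reference >= 0 & led_off$reference <= 1))
  # attach to a streaming ledger and compute intransigence
  cfg_s <- run_config(s$enc, s$plan, loss_config(margin = 1), mode = "full",
                      n_runs = 1, seed = 72)
  led <- attach_reference(run_experiment(cfg_s, s$data), led_off)
  last <- max(led$summary_history$step)
  i_t <- intransigence(led, 1, last)
  expect_true(is.finite(i_t$average))
})
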