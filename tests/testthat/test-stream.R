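test_that("sliding windows cut at the expected offsets with majority labels", {
  sig <- matrix(seq_len(200), 100, 2)
  wb <- sliding_windows(sig, rep(1L, 100), window_len = 50, step_len = 25)
  expect_equal(n_windows(wb), 3L)  # offsets 0, 25, 50
  expect_equal(wb$windows[2, 1, 1], 26)  # second window starts at sample 26
  expect_equal(wb$labels, rep(1L, 3))
  # window_len equal to the signal length: exactly one window
  wb1 <- sliding_windows(sig, rep(4L, 100), 100, 10)
  expect_equal(n_windows(wb1), 1L)
  expect_equal(wb1$labels, 4L)
  expect_error(sliding_windows(sig, rep(1L, 100), 101, 10), "exceeds")
})

test_that("window labels use majority vote with ties to the last timestep", {
  sig <- matrix(0, 10, 1)
  # 6 of class 1, 4 of class 2: majority 1
  wb <- sliding_windows(sig, c(rep(1L, 6), rep(2L, 4)), 10, 10)
  expect_equal(wb$labels, 1L)
  # 5/5 tie: label at the last timestep wins
  wb2 <- sliding_windows(sig, c(rep(1L, 5), rep(2L, 5)), 10, 10)
  expect_equal(wb2$labels, 2L)
  wb3 <- sliding_windows(sig, c(rep(2L, 5), rep(1L, 5)), 10, 10)
  expect_equal(wb3$labels, 1L)
})

test_that("the experiment split partitions base training data and pools the rest", {
  data <- separable_data(n_classes = 8, windows_per_class = 24, seed = 7)
  plan <- stream_plan(n_base = 5, pretrain_fraction = 0.5, seed = 3)
  sp <- split_experiment(data, plan)
  expect_length(sp$base_classes, 5L)
  expect_length(sp$new_classes, 3L)
  expect_equal(intersect(sp$base_classes, sp$new_classes), integer(0))
  # 16 training windows per class -> 8 pretrain, 8 pooled for base classes
  for (k in sp$base_classes) {
    expect_equal(sum(sp$pretrain$labels == k), 8L)
    expect_equal(sum(sp$stream_pool$labels == k), 8L)
  }
  # all new-class training windows go to the pool; the pool has all classes
  for (k in sp$new_classes)
    expect_equal(sum(sp$stream_pool$labels == k), 16L)
  expect_setequal(unique(sp$stream_pool$labels), 1:8)
  # base test set contains exactly the base-class test windows
  expect_setequal(unique(sp$base_test$labels), sp$base_classes)
  # reproducible under the plan seed
  sp2 <- split_experiment(data, plan)
  expect_identical(sp$base_classes, sp2$base_classes)
  expect_identical(sp$pretrain$labels, sp2$pretrain$labels)
  # too few classes
  small <- separable_data(n_classes = 5, windows_per_class = 10, seed = 1)
  expect_error(split_experiment(small, plan), "insufficient classes")
})

test_that("the scheduler emits bounded non-i.i.d. batches covering the pool once", {
  data <- separable_data(n_classes = 9, windows_per_class = 24, seed = 9)
  plan <- stream_plan(n_base = 5, stream_batch_size = 20,
                      max_classes_per_batch = 5, seed = 17)
  sp <- split_experiment(data, plan)
  sched <- schedule_stream(sp$stream_pool, plan)
  for (b in sched) {
    expect_lte(n_windows(b), 20L)
    expect_lte(length(unique(b$labels)), 5L)
  }
  # concatenation is a permutation of the pool (multiset equality on content)
  all_labels <- unlist(lapply(sched, `[[`, "labels"))
  expect_equal(sort(all_labels), sort(sp$stream_pool$labels))
  all_first_vals <- sort(unlist(lapply(sched, function(b) b$windows[, 1, 1])))
  expect_equal(all_first_vals, sort(sp$stream_pool$windows[, 1, 1]))
  # deterministic under the plan seed
  sched2 <- schedule_stream(sp$stream_pool, plan)
  expect_identical(lapply(sched, `[[`, "labels"),
                   lapply(sched2, `[[`, "labels"))
  expect_equal(vapply(sched, `[[`, integer(1), "step_index"),
               seq_along(sched))
})

test_that("dataset files in the flattened-window layout round-trip", {
  dir <- withr::local_tempdir()
  wb <- random_batch(10, channels = 2, window_len = 8,
                     labels = rep(1:2, 5), seed = 33)
  flat <- t(apply(wb$windows, 1, as.vector))  # channel-fastest flattening
  write.table(flat, file.path(dir, "windows.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  writeLines(as.character(wb$labels), file.path(dir, "labels.csv"))
  fmt <- list(kind = "windows", channels = 2, window_len = 8)
  out <- read_dataset(dir, fmt)
  expect_equal(n_windows(out), 10L)
  expect_equal(out$labels, wb$labels)
  expect_equal(out$windows, wb$windows, tolerance = 1e-12)
  # a malformed row is dropped and reported, not silently ignored
  flat2 <- flat; flat2[4, 3] <- NA
  write.table(flat2, file.path(dir, "windows.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_message(out2 <- read_dataset(dir, fmt), "dropped 1")
  expect_equal(n_windows(out2), 9L)
  expect_equal(attr(out2, "dropped"), 4L)
})

test_that("raw delimited signals are segmented through sliding windows", {
  dir <- withr::local_tempdir()
  df <- data.frame(a = rnorm(100), b = rnorm(100), lab = rep(1:2, each = 50))
  write.csv(df, file.path(dir, "raw.csv"), row.names = FALSE)
  fmt <- list(kind = "raw", file = "raw.csv", delimiter = ",", header = TRUE,
              label_col = "lab", channel_cols = c("a", "b"),
              window_len = 50, step_len = 25)
  out <- read_dataset(dir, fmt)
  expect_equal(n_windows(out), 3L)
  expect_equal(dim(out$windows)[2:3], c(2L, 50L))
  # the YAML descriptor form is equivalent
  yml <- file.path(dir, "fmt.yaml")
  yaml::write_yaml(fmt, yml)
  out2 <- read_dataset(dir, yml)
  expect_equal(out2$windows, out$windows)
})
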