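test_that("prototype creation averages embeddings per class", {
  mem <- prototype_memory(2)
  mem <- create_prototypes(mem, rbind(c(0, 0), c(2, 2)), c(3L, 3L))
  expect_equal(unname(mem$prototypes["3", ]), c(1, 1))
  expect_equal(unname(mem$counts[["3"]]), 2)
  # single sample: prototype equals the embedding
  mem <- create_prototypes(mem, rbind(c(5, -1)), 7L)
  expect_equal(unname(mem$prototypes["7", ]), c(5, -1))
  expect_equal(unname(mem$counts[["7"]]), 1)
  # creating an existing class is an error
  expect_error(create_prototypes(mem, rbind(c(0, 0)), 3L), "already has")
})

test_that("prototypes match a brute-force per-class average", {
  E <- with_seed(10, matrix(rnorm(30 * 4), 30, 4))
  y <- rep(1:3, each = 10)
  mem <- create_prototypes(prototype_memory(4), E, y)
  naive <- naive_class_means(E, y)
  for (k in names(naive))
    expect_equal(unname(mem$prototypes[k, ]), unname(naive[[k]]),
                 tolerance = 1e-12)
})

test_that("online refinement implements the exact running mean", {
  mem <- create_prototypes(prototype_memory(2), rbind(c(0, 0), c(2, 2)), c(1L, 1L))
  # p=(1,1), c=2; absorb (4,4): p -> (2*(1,1)+(4,4))/3 = (2,2), c=3
  mem <- update_online(mem, rbind(c(4, 4)), 1L)
  expect_equal(unname(mem$prototypes["1", ]), c(2, 2))
  expect_equal(unname(mem$counts[["1"]]), 3)
  # batch without class 1 leaves it untouched, new class delegated to creation
  mem2 <- update_online(mem, rbind(c(9, 9)), 5L)
  expect_equal(mem2$prototypes["1", ], mem$prototypes["1", ])
  expect_equal(unname(mem2$prototypes["5", ]), c(9, 9))
  expect_equal(memory_classes(mem2), c(1L, 5L))
})

test_that("streaming a class in any partition equals the all-at-once mean", {
  E <- with_seed(20, matrix(rnorm(100 * 8), 100, 8))
  batch_mean <- colMeans(E)
  for (rep in 1:5) {
    cuts <- with_seed(20 + rep, sort(sample(2:99, 6)))
    parts <- split(seq_len(100), findInterval(seq_len(100), cuts))
    mem <- prototype_memory(8)
    for (p in parts)
      mem <- update_online(mem, E[p, , drop = FALSE], rep(1L, length(p)))
    expect_equal(unname(mem$prototypes["1", ]), batch_mean, tolerance = 1e-6)
    expect_equal(unname(mem$counts[["1"]]), 100)
  }
})

test_that("replay adaptation interpolates prototypes at the refresh ratio", {
  mem <- create_prototypes(prototype_memory(2), rbind(c(2, 0), c(0, 4)),
                           c(1L, 2L))
  replay <- rbind(c(0, 2), c(0, 2))
  # alpha = 1: identity
  m1 <- adapt_with_replay(mem, replay, c(1L, 2L), alpha = 1)
  expect_equal(m1$prototypes, mem$prototypes)
  # alpha = 0: snap to the replay mean
  m0 <- adapt_with_replay(mem, replay, c(1L, 2L), alpha = 0)
  expect_equal(unname(m0$prototypes["1", ]), c(0, 2))
  # alpha = 0.5 halfway
  mh <- adapt_with_replay(mem, rbind(c(0, 2)), 1L, alpha = 0.5)
  expect_equal(unname(mh$prototypes["1", ]), c(1, 1))
  # classes absent from the replay set, and all counts, are untouched
  expect_equal(unname(mh$prototypes["2", ]), c(0, 4))
  expect_equal(mh$counts, mem$counts)
  expect_error(adapt_with_replay(mem, replay, c(1L, 2L), alpha = 1.2),
               "alpha")
})

test_that("adaptation at alpha = c/(c+m) with the batch as replay set equals online averaging", {
  E0 <- with_seed(30, matrix(rnorm(12 * 5), 12, 5))
  mem <- create_prototypes(prototype_memory(5), E0, rep(1:2, each = 6))
  newE <- with_seed(31, matrix(rnorm(8 * 5), 8, 5))
  newy <- rep(1:2, each = 4)
  via_online <- update_online(mem, newE, newy)
  via_adapt <- mem
  for (k in 1:2) {
    c_prev <- mem$counts[[as.character(k)]]
    m <- sum(newy == k)
    via_adapt <- adapt_with_replay(via_adapt, newE[newy == k, , drop = FALSE],
                                   rep(k, m), alpha = c_prev / (c_prev + m))
  }
  expect_equal(via_adapt$prototypes, via_online$prototypes)
})

test_that("classification is nearest-prototype with probabilities summing to one", {
  set.seed(40)
  for (rep in 1:20) {
    P <- matrix(rnorm(5 * 6), 5, 6)
    mem <- create_prototypes(prototype_memory(6), P, 1:5)
    Q <- matrix(rnorm(10 * 6), 10, 6)
    res <- classify(mem, Q)
    expect_equal(unname(rowSums(res$prob)), rep(1, 10), tolerance = 1e-9)
    # brute-force nearest prototype by explicit distance loop
    for (i in 1:10) {
      d <- sapply(1:5, function(k) sum((Q[i, ] - P[k, ])^2))
      expect_equal(res$class[i], which.min(d))
    }
  }
})

test_that("a query at a prototype wins; equidistant prototypes tie to the smaller id", {
  P <- rbind(c(0, 0), c(10, 0), c(0, 10))
  mem <- create_prototypes(prototype_memory(2), P, c(2L, 5L, 9L))
  res <- classify(mem, rbind(c(0, 0)))
  expect_equal(res$class, 2L)
  expect_equal(which.max(res$prob[1, ]), c("2" = 1L))
  # equidistant from prototypes 2 and 5: both probabilities ~0.5 (third is far)
  res2 <- classify(mem, rbind(c(5, 0)))
  expect_equal(unname(res2$prob[1, "2"]), unname(res2$prob[1, "5"]))
  expect_equal(res2$class, 2L)  # tie broken towards the smallest class id
  expect_error(classify(prototype_memory(2), rbind(c(0, 0))), "empty")
})

test_that("predictions are invariant to a strictly increasing distance transform", {
  E <- with_seed(41, matrix(rnorm(15 * 3), 15, 3))
  Q <- with_seed(42, matrix(rnorm(25 * 3), 25, 3))
  y <- rep(1:3, each = 5)
  m_sq <- create_prototypes(prototype_memory(3, "sqeuclidean"), E, y)
  m_eu <- create_prototypes(prototype_memory(3, "euclidean"), E, y)
  expect_equal(classify(m_sq, Q)$class, classify(m_eu, Q)$class)
})
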