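#' Create an empty prototype memory
#'
#' The prototype memory is the evolving knowledge base: one prototype vector
#' per seen class (the running mean of its embeddings) together with the count
#' of windows absorbed so far. Classification is a softmax over negative
#' distances to the prototypes, i.e. nearest-prototype classification.
#'
#' @param dim embedding dimension `d`.
#' @param distance distance used for classification: squared Euclidean
#'   (default, the convention of prototypical networks) or plain Euclidean.
#'   Argmax predictions are identical for the two.
#' @return an object of class `prototype_memory`.
#' @export
prototype_memory <- function(dim, distance = c("sqeuclidean", "euclidean")) {
  distance <- match.arg(distance)
  structure(list(prototypes = matrix(numeric(0), 0L, as.integer(dim)),
                 counts = integer(0), dim = as.integer(dim),
                 distance = distance),
            class = "prototype_memory")
}

#' @export
print.prototype_memory <- function(x, ...) {
  cat(sprintf("<prototype_memory> %d classes, d=%d, %s distance\n",
              nrow(x$prototypes), x$dim, x$distance))
  invisible(x)
}

#' Classes currently stored in a prototype memory
#' @param memory a [prototype_memory()].
#' @return sorted integer vector of class ids.
#' @export
memory_classes <- function(memory) sort(as.integer(rownames(memory$prototypes)))

# Order prototype rows by ascending class id (keeps ties deterministic).
.mem_sort <- function(memory) {
  ord <- order(as.integer(rownames(memory$prototypes)))
  memory$prototypes <- memory$prototypes[ord, , drop = FALSE]
  memory$counts <- memory$counts[ord]
  memory
}

.check_emb <- function(memory, embeddings) {
  if (!is.matrix(embeddings) || ncol(embeddings) != memory$dim)
    stop(sprintf("dimension mismatch: expected n x %d embeddings", memory$dim),
         call. = FALSE)
}

#' Create prototypes for previously unseen classes
#'
#' Each new class prototype is the mean of its embeddings; its count is the
#' number of contributing windows.
#'
#' @param memory a [prototype_memory()].
#' @param embeddings `n x d` matrix.
#' @param labels integer class ids, all absent from `memory`.
#' @return the updated memory.
#' @export
create_prototypes <- function(memory, embeddings, labels) {
  .check_emb(memory, embeddings)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(embeddings))
  new_classes <- unique(labels)
  existing <- as.integer(rownames(memory$prototypes))
  if (any(new_classes %in% existing))
    stop("class already has a prototype: ",
         paste(intersect(new_classes, existing), collapse = ", "),
         call. = FALSE)
  for (k in new_classes) {
    idx <- which(labels == k)
    p <- colMeans(embeddings[idx, , drop = FALSE])
    memory$prototypes <- rbind(memory$prototypes,
                               matrix(p, 1L, memory$dim,
                                      dimnames = list(as.character(k), NULL)))
    memory$counts <- c(memory$counts, stats::setNames(length(idx),
                                                      as.character(k)))
  }
  .mem_sort(memory)
}

#' Refine prototypes online with a labelled batch
#'
#' Known classes are updated by exact online averaging: with previous count
#' `c` and prototype `p`, and `m` matching embeddings summing to `s`, the new
#' prototype is `(c*p + s) / (c + m)` and the count becomes `c + m`. Classes
#' not yet in memory are delegated to [create_prototypes()]. Streaming a
#' class through any partition of its windows therefore yields the same
#' prototype as a single all-at-once mean (under a fixed encoder).
#'
#' @inheritParams create_prototypes
#' @return the updated memory.
#' @export
update_online <- function(memory, embeddings, labels) {
  .check_emb(memory, embeddings)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(embeddings))
  known <- as.integer(rownames(memory$prototypes))
  for (k in intersect(unique(labels), known)) {
    idx <- which(labels == k)
    key <- as.character(k)
    c_prev <- memory$counts[[key]]
    c_new <- c_prev + length(idx)
    s <- colSums(embeddings[idx, , drop = FALSE])
    memory$prototypes[key, ] <-
      (c_prev * memory$prototypes[key, ] + s) / c_new
    memory$counts[[key]] <- c_new
  }
  novel <- setdiff(unique(labels), known)
  if (length(novel) > 0L) {
    sel <- labels %in% novel
    memory <- create_prototypes(memory, embeddings[sel, , drop = FALSE],
                                labels[sel])
  }
  memory
}

#' Adapt prototypes towards replayed exemplars
#'
#' After a model update the embedding space has moved; stored prototypes are
#' pulled towards the mean embedding (under the *current* encoder) of each
#' class's replayed exemplars: `p[k] <- alpha * p[k] + (1 - alpha) * mean_k`.
#' The refresh ratio `alpha` acts as a stabilising learning rate: `alpha = 1`
#' keeps the old prototypes, `alpha = 0` snaps them to the replay means.
#' Classes absent from the replay set, and all counts, are untouched.
#'
#' @param memory a [prototype_memory()].
#' @param embeddings `n x d` matrix of replay-exemplar embeddings computed
#'   with the current encoder.
#' @param labels integer class ids of the replayed exemplars; every class must
#'   already have a prototype.
#' @param alpha refresh ratio in `[0, 1]`.
#' @return the updated memory.
#' @export
adapt_with_replay <- function(memory, embeddings, labels, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  .check_emb(memory, embeddings)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(embeddings))
  known <- as.integer(rownames(memory$prototypes))
  if (!all(unique(labels) %in% known))
    stop("replay set contains a class with no prototype: ",
         paste(setdiff(unique(labels), known), collapse = ", "), call. = FALSE)
  for (k in unique(labels)) {
    idx <- which(labels == k)
    key <- as.character(k)
    r_mean <- colMeans(embeddings[idx, , drop = FALSE])
    memory$prototypes[key, ] <-
      alpha * memory$prototypes[key, ] + (1 - alpha) * r_mean
  }
  memory
}

# Pairwise squared distances between rows of E (n x d) and P (K x d).
.sq_dists <- function(E, P) {
  en <- rowSums(E^2)
  pn <- rowSums(P^2)
  d2 <- outer(en, pn, "+") - 2 * tcrossprod(E, P)
  pmax(d2, 0)
}

#' Nearest-prototype classification
#'
#' Produces, for each embedding, a probability distribution over the stored
#' classes via a softmax over negative prototype distances, and the argmax
#' prediction. Because the softmax of negative distance is monotone, the
#' prediction is exactly the nearest prototype; exact distance ties are broken
#' towards the smallest class id.
#'
#' @param memory a non-empty [prototype_memory()].
#' @param embeddings `n x d` matrix.
#' @return a list with `class` (integer predictions) and `prob`
#'   (`n x K` matrix, columns named by class id, rows summing to 1).
#' @export
classify <- function(memory, embeddings) {
  if (nrow(memory$prototypes) == 0L)
    stop("empty prototype memory: nothing to classify against", call. = FALSE)
  .check_emb(memory, embeddings)
  d2 <- .sq_dists(embeddings, memory$prototypes)
  if (memory$distance == "euclidean") d2 <- sqrt(d2)
  prob <- softmax_rows(-d2)
  colnames(prob) <- rownames(memory$prototypes)
  ids <- as.integer(rownames(memory$prototypes))
  # rows are in ascending class-id order, so which.max's first-max rule
  # breaks ties towards the smallest class id
  pred <- ids[apply(d2, 1L, which.min)]
  list(class = pred, prob = prob)
}
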