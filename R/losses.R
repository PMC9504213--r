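#' Loss configuration
#'
#' The training loss is a prototype-softmax cross-entropy, optionally plus a
#' margin contrastive term over all unordered pairs of the combined batch.
#'
#' @param margin positive contrastive margin `m`: the minimum embedding
#'   distance enforced between samples of different classes.
#' @param use_contrastive include the contrastive term (default TRUE).
#' @param use_replay include replayed exemplars in the training query set
#'   (default TRUE).
#' @param contrastive_form form of the dissimilar-pair penalty:
#'   `"hinge_distance"` (default) is the classic margin contrastive loss
#'   `max(0, m - dist)^2`; `"hinge_sqdist"` is the variant `max(0, m - dist^2)`
#'   that hinges the margin against the squared distance.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(margin = 1, use_contrastive = TRUE, use_replay = TRUE,
                        contrastive_form = c("hinge_distance", "hinge_sqdist")) {
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0)
    stop("margin must be a single positive number", call. = FALSE)
  structure(list(margin = margin, use_contrastive = isTRUE(use_contrastive),
                 use_replay = isTRUE(use_replay),
                 contrastive_form = match.arg(contrastive_form)),
            class = "loss_config")
}

#' Prototype-softmax cross-entropy
#'
#' Mean over rows of the negative log-probability of the true class, given
#' per-row class probabilities (columns named by class id, as produced by
#' [classify()]).
#'
#' @param prob `n x K` probability matrix, rows summing to 1, columns named by
#'   class id.
#' @param labels integer true class ids; each must have a probability column.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(prob, labels) {
  labels <- as.integer(labels)
  stopifnot(is.matrix(prob), nrow(prob) == length(labels))
  cols <- match(as.character(labels), colnames(prob))
  if (anyNA(cols))
    stop("label without a prototype/probability column: ",
         paste(unique(labels[is.na(cols)]), collapse = ", "), call. = FALSE)
  p <- prob[cbind(seq_along(labels), cols)]
  mean(-log(pmax(p, 1e-300)))
}

#' Margin contrastive loss over all unordered pairs
#'
#' Same-class pairs contribute their squared embedding distance (pulling
#' similar windows together); different-class pairs contribute a hinge that is
#' active only when they are closer than the margin `m` (pushing dissimilar
#' windows at least `m` apart). The reduction over pairs is the mean, so the
#' scale is batch-size independent; fewer than two rows give 0.
#'
#' @param embeddings `n x d` matrix.
#' @param labels integer class ids.
#' @param margin positive margin `m`.
#' @param form see [loss_config()].
#' @return scalar loss.
#' @export
contrastive_loss <- function(embeddings, labels, margin,
                             form = c("hinge_distance", "hinge_sqdist")) {
  form <- match.arg(form)
  n <- nrow(embeddings)
  if (n < 2L) return(0)
  d2 <- .sq_dists(embeddings, embeddings)
  same <- outer(labels, labels, "==")
  up <- upper.tri(d2)
  sim <- d2[up & same]
  if (form == "hinge_distance") {
    dis <- pmax(0, margin - sqrt(d2[up & !same]))^2
  } else {
    dis <- pmax(0, margin - d2[up & !same])
  }
  (sum(sim) + sum(dis)) / sum(up)
}

#' Combined training loss
#'
#' Cross-entropy plus (when `config$use_contrastive`) the contrastive term.
#'
#' @param prob `n x K` probability matrix (see [cross_entropy_loss()]).
#' @param embeddings `n x d` matrix.
#' @param labels integer class ids.
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(prob, embeddings, labels, config) {
  stopifnot(inherits(config, "loss_config"))
  l <- cross_entropy_loss(prob, labels)
  if (config$use_contrastive)
    l <- l + contrastive_loss(embeddings, labels, config$margin,
                              config$contrastive_form)
  l
}

# ---- gradient helpers (internal) --------------------------------------------

# Cross-entropy through softmax(-dist(e, p)) with the prototypes held fixed
# (streaming case). Returns value, per-row probabilities, and dE.
ce_grad_fixed_protos <- function(memory, embeddings, labels) {
  res <- classify(memory, embeddings)
  prob <- res$prob
  labels <- as.integer(labels)
  cols <- match(as.character(labels), colnames(prob))
  if (anyNA(cols))
    stop("label without a prototype: ",
         paste(unique(labels[is.na(cols)]), collapse = ", "), call. = FALSE)
  n <- nrow(embeddings)
  value <- mean(-log(pmax(prob[cbind(seq_len(n), cols)], 1e-300)))
  Y <- matrix(0, n, ncol(prob))
  Y[cbind(seq_len(n), cols)] <- 1
  dlogit <- (prob - Y) / n               # logits = -distance
  P <- memory$prototypes
  if (memory$distance == "sqeuclidean") {
    # d(d2)/dE: 2 * (sum_k w_ik) e_i - 2 * sum_k w_ik p_k with w = -dlogit
    w <- -dlogit
    dE <- 2 * (rowSums(w) * embeddings - w %*% P)
  } else {
    d2 <- .sq_dists(embeddings, P)
    dd <- pmax(sqrt(d2), 1e-12)
    w <- -dlogit / dd
    dE <- rowSums(w) * embeddings - w %*% P
  }
  list(value = value, prob = prob, dE = dE)
}

# Episodic loss for pretraining: prototypes are the support-class means and
# are differentiated through. Returns value plus gradients for support and
# query embeddings.
episode_loss_grad <- function(support_emb, support_labels,
                              query_emb, query_labels,
                              distance = "sqeuclidean") {
  classes <- sort(unique(as.integer(support_labels)))
  P <- t(vapply(classes, function(k)
    colMeans(support_emb[support_labels == k, , drop = FALSE]),
    numeric(ncol(support_emb))))
  rownames(P) <- as.character(classes)
  d2 <- .sq_dists(query_emb, P)
  logits <- if (distance == "euclidean") -sqrt(d2) else -d2
  prob <- softmax_rows(logits)
  cols <- match(as.character(as.integer(query_labels)), rownames(P))
  if (anyNA(cols)) stop("query label missing from support classes", call. = FALSE)
  n <- nrow(query_emb)
  value <- mean(-log(pmax(prob[cbind(seq_len(n), cols)], 1e-300)))
  Y <- matrix(0, n, nrow(P))
  Y[cbind(seq_len(n), cols)] <- 1
  dlogit <- (prob - Y) / n
  if (distance == "sqeuclidean") {
    w <- -dlogit
    dQ <- 2 * (rowSums(w) * query_emb - w %*% P)
    dP <- 2 * (colSums(w) * P - crossprod(w, query_emb))
  } else {
    dd <- pmax(sqrt(d2), 1e-12)
    w <- -dlogit / dd
    dQ <- rowSums(w) * query_emb - w %*% P
    dP <- colSums(w) * P - crossprod(w, query_emb)
  }
  dS <- matrix(0, nrow(support_emb), ncol(support_emb))
  for (i in seq_along(classes)) {
    idx <- which(support_labels == classes[i])
    dS[idx, ] <- matrix(dP[i, ] / length(idx), length(idx),
                        ncol(support_emb), byrow = TRUE)
  }
  list(value = value, dS = dS, dQ = dQ)
}

# Contrastive loss and its embedding gradient (vectorised over pairs).
contrastive_grad <- function(embeddings, labels, margin,
                             form = "hinge_distance") {
  n <- nrow(embeddings)
  if (n < 2L) return(list(value = 0, dE = matrix(0, n, ncol(embeddings))))
  d2 <- .sq_dists(embeddings, embeddings)
  same <- outer(labels, labels, "==")
  diag(same) <- NA                        # exclude self-pairs
  np <- n * (n - 1) / 2
  # coefficient A[i, j] with dE = (2/np) * (rowSums(A) * E - A %*% E),
  # derived from d(d_ij^2)/de_i = 2 (e_i - e_j)
  A <- matrix(0, n, n)
  sim_mask <- !is.na(same) & same
  A[sim_mask] <- 1
  if (form == "hinge_distance") {
    dd <- sqrt(pmax(d2, 1e-24))
    act <- !is.na(same) & !same & (dd < margin)
    A[act] <- -(margin - dd[act]) / dd[act]
    value <- (sum(d2[upper.tri(d2) & sim_mask]) +
                sum(pmax(0, margin - sqrt(d2[upper.tri(d2) & !is.na(same) & !same]))^2)) / np
  } else {
    act <- !is.na(same) & !same & (d2 < margin)
    A[act] <- -1
    value <- (sum(d2[upper.tri(d2) & sim_mask]) +
                sum(pmax(0, margin - d2[upper.tri(d2) & !is.na(same) & !same]))) / np
  }
  # dL/de_i = (2/np) * sum_{j != i} A_ij (e_i - e_j); A is symmetric and the
  # sum over j covers each unordered pair once from e_i's side
  dE <- (2 / np) * (rowSums(A) * embeddings - A %*% embeddings)
  list(value = value, dE = dE)
}
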