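#' Construct a linear probe from explicit parameters
#'
#' A linear probe is a multinomial logistic (softmax) head over an
#' embedding space: class scores are `W x + b`. Besides being the package's
#' reference classifier, a probe built from the final affine layer of any
#' deep model can be analysed with [boundary_distances()].
#'
#' @param weights Numeric `k x d` matrix of class weight vectors.
#' @param biases Numeric length-`k` vector.
#' @param classes Character class names (rows of `weights`).
#' @return An object of class `xtal_linear_probe`.
#' @export
linear_probe <- function(weights, biases, classes = class_labels()) {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(classes) || length(biases) != length(classes)) {
    stopf("weights must be k x d and biases length k for k classes")
  }
  if (any(!is.finite(weights)) || any(!is.finite(biases))) {
    stopf("probe parameters must be finite")
  }
  structure(
    list(weights = weights, biases = as.numeric(biases),
         classes = as.character(classes), d = ncol(weights),
         loss_trace = numeric(0), meta = list()),
    class = "xtal_linear_probe"
  )
}

#' @export
print.xtal_linear_probe <- function(x, ...) {
  cat(sprintf("<xtal_linear_probe> %d classes x %d features\n",
              length(x$classes), x$d))
  invisible(x)
}

probe_loss <- function(W, b, X, Y, lambda) {
  P <- softmax_rows(X %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE))
  -mean(log(pmax(P[Y], 1e-12))) + lambda / 2 * sum(W^2)
}

#' Train a linear probe by deterministic full-batch gradient descent
#'
#' Minimises the L2-penalised multinomial logistic objective
#' `-mean log p(y | x) + lambda/2 ||W||^2` by full-batch gradient descent
#' from a zero initialisation, with a backtracking (step-halving) line
#' search so the training loss is non-increasing over epochs. Training is
#' bit-reproducible: the same inputs and seed give identical parameters.
#'
#' @param e An [embedding_set()].
#' @param labels Character labels aligned to `e$record_ids`; at least two
#'   classes must be present.
#' @param classes Class order for the probe; defaults to [class_labels()]
#'   when the labels are a subset of it, otherwise the sorted unique
#'   labels.
#' @param epochs Maximum gradient steps.
#' @param lr Initial step size.
#' @param lambda L2 penalty strength.
#' @param tol Stop when the loss improves by less than this.
#' @param seed Recorded in the probe metadata (the optimiser itself is
#'   deterministic).
#' @return An `xtal_linear_probe` with `loss_trace` and training `meta`.
#' @export
train_linear_probe <- function(e, labels, classes = NULL, epochs = 400,
                               lr = 1, lambda = 1e-3, tol = 1e-8, seed = 1) {
  stopifnot(inherits(e, "xtal_embedding_set"))
  labels <- as.character(labels)
  if (length(labels) != length(e$record_ids)) {
    stopf("labels must align with the embedding set")
  }
  if (anyNA(labels)) stopf("every record must be labelled")
  present <- unique(labels)
  if (length(present) < 2L) {
    stopf("degenerate problem: only one class present (%s)", present)
  }
  if (is.null(classes)) {
    classes <- if (all(present %in% class_labels())) class_labels() else
      sort(present)
  }
  if (!all(present %in% classes)) {
    stopf("labels outside the declared class set: %s",
          paste(setdiff(present, classes), collapse = ", "))
  }
  X <- e$vectors
  n <- nrow(X)
  k <- length(classes)
  yi <- match(labels, classes)
  Y <- cbind(seq_len(n), yi)  # index matrix of true-class entries
  Yh <- matrix(0, n, k)
  Yh[Y] <- 1

  W <- matrix(0, k, ncol(X))
  b <- numeric(k)
  loss <- probe_loss(W, b, X, Y, lambda)
  trace <- loss
  step <- lr
  for (ep in seq_len(epochs)) {
    P <- softmax_rows(X %*% t(W) + matrix(b, n, k, byrow = TRUE))
    R <- P - Yh
    gW <- crossprod(R, X) / n + lambda * W
    gb <- colMeans(R)
    improved <- FALSE
    s <- step
    for (try in 1:30) {
      W2 <- W - s * gW
      b2 <- b - s * gb
      l2 <- probe_loss(W2, b2, X, Y, lambda)
      if (l2 <= loss) { improved <- TRUE; break }
      s <- s / 2
    }
    if (!improved) break
    W <- W2; b <- b2
    delta <- loss - l2
    loss <- l2
    trace <- c(trace, loss)
    step <- min(lr, s * 2)  # allow the step to recover
    if (delta < tol) break
  }
  probe <- linear_probe(W, b, classes)
  probe$loss_trace <- trace
  probe$meta <- list(seed = seed, epochs_run = length(trace) - 1L,
                     lambda = lambda, lr = lr, final_loss = loss)
  probe
}

#' Predicted class probabilities from a probe
#'
#' Softmax of the probe's affine scores; rows sum to 1.
#'
#' @param probe An `xtal_linear_probe`.
#' @param e An [embedding_set()] with matching dimensionality.
#' @return An [prob_table()] aligned to `e$record_ids`.
#' @export
predict_probs <- function(probe, e) {
  stopifnot(inherits(probe, "xtal_linear_probe"),
            inherits(e, "xtal_embedding_set"))
  if (ncol(e$vectors) != probe$d) {
    stopf("dimension mismatch: probe expects d=%d, embeddings have d=%d",
          probe$d, ncol(e$vectors))
  }
  P <- softmax_rows(e$vectors %*% t(probe$weights) +
                      matrix(probe$biases, nrow(e$vectors),
                             length(probe$biases), byrow = TRUE))
  prob_table(e$record_ids, P, probe$classes)
}

#' Classification accuracy of a probability table
#'
#' Fraction of records whose highest-probability class (ties broken by
#' class order) equals the true label.
#'
#' @param probs An `xtal_prob_table`.
#' @param labels True labels aligned to `probs$record_ids` (no `NA`).
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(probs, labels) {
  stopifnot(inherits(probs, "xtal_prob_table"))
  labels <- as.character(labels)
  if (length(labels) != length(probs$record_ids) || anyNA(labels)) {
    stopf("labels must be complete and aligned to the probability table")
  }
  pred <- probs$classes[max.col(probs$probs, ties.method = "first")]
  mean(pred == labels)
}

#' Confusion matrix of a probability table
#'
#' Counts with rows = true class and columns = predicted class, plus the
#' row-normalised view (each row divided by its support, i.e. per-class
#' recall layout). Rows with zero support are `NA` in the normalised view.
#'
#' @inheritParams accuracy
#' @return An object of class `xtal_confusion`: list with `counts` and
#'   `normalised` `k x k` matrices.
#' @export
confusion <- function(probs, labels) {
  stopifnot(inherits(probs, "xtal_prob_table"))
  labels <- as.character(labels)
  if (length(labels) != length(probs$record_ids) || anyNA(labels)) {
    stopf("labels must be complete and aligned to the probability table")
  }
  pred <- probs$classes[max.col(probs$probs, ties.method = "first")]
  counts <- table(factor(labels, levels = probs$classes),
                  factor(pred, levels = probs$classes))
  counts <- matrix(as.integer(counts), nrow(counts),
                   dimnames = dimnames(counts))
  support <- rowSums(counts)
  normalised <- counts / support
  normalised[support == 0, ] <- NA_real_
  structure(list(counts = counts, normalised = normalised),
            class = "xtal_confusion")
}

#' @export
print.xtal_confusion <- function(x, ...) {
  cat("<xtal_confusion> rows = true, columns = predicted\n")
  print(round(x$normalised, 3))
  invisible(x)
}
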