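#' Signed distances to pairwise decision boundaries
#'
#' For each unordered pair of classes (i, j), i before j in the probe's
#' class order (six pairs for four classes), computes for every sample
#' whose true label is i or j the signed euclidean distance to the linear
#' boundary separating the pair:
#' `d = ((w_i - w_j) . x + (b_i - b_j)) / ||w_i - w_j||`.
#' The sign is positive when the pairwise score favours class i. For a
#' linear head this is exact; for a deep network's final affine layer it is
#' a first-order surrogate of the true boundary geometry. Samples near or
#' beyond a boundary are ambiguous or misclassified — the shape of these
#' distributions on a local dataset versus the training-domain test set is
#' a direct view of domain shift.
#'
#' @param probe An `xtal_linear_probe`.
#' @param e An [embedding_set()] with matching dimensionality.
#' @param labels True labels aligned to `e$record_ids`.
#' @return An object of class `xtal_boundary_report`: list with
#'   `distances` (named list of data frames `record_id`, `true_label`,
#'   `distance`, one per pair `"i|j"`) and `summary` (per pair: n,
#'   mean, sd, mean_abs, crossing_fraction).
#' @export
boundary_distances <- function(probe, e, labels) {
  stopifnot(inherits(probe, "xtal_linear_probe"),
            inherits(e, "xtal_embedding_set"))
  if (ncol(e$vectors) != probe$d) {
    stopf("dimension mismatch: probe expects d=%d, embeddings have d=%d",
          probe$d, ncol(e$vectors))
  }
  labels <- as.character(labels)
  if (length(labels) != length(e$record_ids) || anyNA(labels)) {
    stopf("labels must be complete and aligned to the embedding set")
  }
  k <- length(probe$classes)
  pairs <- utils::combn(k, 2L)
  distances <- list()
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    ci <- probe$classes[i]; cj <- probe$classes[j]
    pair_name <- paste(ci, cj, sep = "|")
    w <- probe$weights[i, ] - probe$weights[j, ]
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      stopf("degenerate boundary for pair %s: identical weight vectors",
            pair_name)
    }
    sel <- which(labels %in% c(ci, cj))
    d <- as.numeric(e$vectors[sel, , drop = FALSE] %*% w +
                      (probe$biases[i] - probe$biases[j])) / nw
    df <- data.frame(record_id = e$record_ids[sel], true_label = labels[sel],
                     distance = d, stringsAsFactors = FALSE)
    distances[[pair_name]] <- df
    # crossing: the pairwise decision (ties go to the earlier class, i)
    # lands on the wrong side of the sample's true label
    crossing <- ifelse(df$true_label == ci, d < 0, d >= 0)
    rows[[pair_name]] <- data.frame(
      pair = pair_name, n = nrow(df),
      mean = if (nrow(df)) mean(d) else NA_real_,
      sd = if (nrow(df) > 1) stats::sd(d) else NA_real_,
      mean_abs = if (nrow(df)) mean(abs(d)) else NA_real_,
      crossing_fraction = if (nrow(df)) mean(crossing) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(classes = probe$classes, distances = distances,
                 summary = summary,
                 probe_checksum = sum(probe$weights) + sum(probe$biases)),
            class = "xtal_boundary_report")
}

#' @export
print.xtal_boundary_report <- function(x, ...) {
  cat("<xtal_boundary_report>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Compare boundary-distance reports from two datasets
#'
#' Given reports computed with the same probe on two datasets (say, the
#' training-domain test set and a local laboratory's set), summarises per
#' class pair the mean absolute boundary distance and the
#' boundary-crossing fraction (samples classified toward the wrong class
#' of the pair) for each dataset, and their differences. A local set that
#' sits closer to the boundaries and crosses them more often is the
#' signature of domain shift.
#'
#' @param report_a,report_b `xtal_boundary_report` objects from the same
#'   probe.
#' @return Data frame, one row per pair: `mean_abs_a`, `mean_abs_b`,
#'   `crossing_a`, `crossing_b`, `diff_mean_abs` (b - a), `diff_crossing`
#'   (b - a). Pairs with no samples in a dataset are `NA`.
#' @export
domain_shift_summary <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "xtal_boundary_report"),
            inherits(report_b, "xtal_boundary_report"))
  if (!identical(report_a$classes, report_b$classes) ||
      abs(report_a$probe_checksum - report_b$probe_checksum) > 1e-9) {
    stopf("reports must come from the same probe")
  }
  a <- report_a$summary; b <- report_b$summary
  data.frame(
    pair = a$pair,
    mean_abs_a = a$mean_abs, mean_abs_b = b$mean_abs,
    crossing_a = a$crossing_fraction, crossing_b = b$crossing_fraction,
    diff_mean_abs = b$mean_abs - a$mean_abs,
    diff_crossing = b$crossing_fraction - a$crossing_fraction,
    stringsAsFactors = FALSE
  )
}

#' Export boundary-distance histograms
#'
#' Flattens a boundary report into a long histogram table (CSV-ready):
#' one row per (pair, bin), with fixed-width bins over the pooled distance
#' range.
#'
#' @param report An `xtal_boundary_report`.
#' @param bins Number of histogram bins.
#' @param dataset Dataset tag written to each row.
#' @return Data frame with columns `pair`, `bin_left`, `bin_right`,
#'   `count`, `dataset`.
#' @export
boundary_histograms <- function(report, bins = 30, dataset = "data") {
  stopifnot(inherits(report, "xtal_boundary_report"))
  all_d <- unlist(lapply(report$distances, `[[`, "distance"))
  if (length(all_d) == 0L) return(data.frame())
  breaks <- seq(min(all_d), max(all_d), length.out = bins + 1L)
  out <- lapply(names(report$distances), function(pair) {
    h <- graphics::hist(report$distances[[pair]]$distance, breaks = breaks,
                        plot = FALSE)
    data.frame(pair = pair, bin_left = utils::head(h$breaks, -1L),
               bin_right = h$breaks[-1L], count = h$counts,
               dataset = dataset, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Project an embedding set to two dimensions
#'
#' For scatter views of dataset structure (colour by class to see outcome
#' clusters, by source to see imaging-style batch effects). `"umap"` uses
#' the uwot implementation when available and otherwise falls back, with a
#' warning, to `"linear"` — the variance-maximising linear projection
#' (first two principal components, with a deterministic sign convention).
#'
#' @param e An [embedding_set()] with at least 3 records.
#' @param method `"linear"` (PCA) or `"umap"`.
#' @param seed Integer seed (UMAP initialisation).
#' @return Numeric `n x 2` matrix, rownames = record ids.
#' @export
project_2d <- function(e, method = c("linear", "umap"), seed = 1) {
  stopifnot(inherits(e, "xtal_embedding_set"))
  method <- match.arg(method)
  n <- nrow(e$vectors)
  if (n < 3L) stopf("projection needs at least 3 records")
  if (method == "umap") {
    if (requireNamespace("uwot", quietly = TRUE)) {
      coords <- with_seed(hash_seed(seed, "umap"), {
        uwot::umap(e$vectors, n_neighbors = min(15L, n - 1L),
                   n_threads = 1, n_sgd_threads = 0)
      })
      rownames(coords) <- e$record_ids
      return(coords)
    }
    warnf("uwot is not installed; falling back to the linear projection")
  }
  pc <- stats::prcomp(e$vectors, center = TRUE, scale. = FALSE, rank. = 2L)
  rot <- pc$rotation
  coords <- pc$x
  if (ncol(coords) < 2L) coords <- cbind(coords, 0)
  # fix signs: the largest-magnitude loading of each axis is positive
  for (a in 1:2) {
    if (a <= ncol(rot)) {
      lead <- which.max(abs(rot[, a]))
      if (rot[lead, a] < 0) coords[, a] <- -coords[, a]
    }
  }
  coords <- coords[, 1:2, drop = FALSE]
  dimnames(coords) <- list(e$record_ids, c("dim1", "dim2"))
  coords
}
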