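#' Number of clusters for a target retention fraction
#'
#' The semantic-deduplication rule keeps exactly one image per cluster, so
#' the number of agglomerative clusters formed equals the number of images
#' to be retained: removing 10% of a 100-image dataset means forming 90
#' clusters. Rounding is half-away-from-zero, with a floor of one cluster.
#'
#' @param retain_fraction Fraction of images to retain, in (0, 1].
#' @param n Dataset size (>= 1).
#' @return Integer cluster count.
#' @export
#' @examples
#' num_clusters(0.9, 100) # 90
num_clusters <- function(retain_fraction, n) {
  if (!is.numeric(retain_fraction) || length(retain_fraction) != 1L ||
      !is.finite(retain_fraction) ||
      retain_fraction <= 0 || retain_fraction > 1) {
    stopf("retain_fraction must be in (0, 1]")
  }
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  max(1L, as.integer(round_half_up(retain_fraction * n)))
}

#' Partition each class into pseudo-classes by k-means
#'
#' Agglomerative clustering scales quadratically, so large classes are first
#' split into pseudo-classes of roughly `target_size` members by k-means in
#' embedding space: a class of `m` vectors gets `max(1, ceiling(m /
#' target_size))` pseudo-classes. Deduplication then runs independently
#' inside each pseudo-class.
#'
#' @param e An [embedding_set()].
#' @param labels Character class labels aligned to `e$record_ids` (no `NA`).
#' @param target_size Intended pseudo-class size (default 10000).
#' @param seed Integer seed for the k-means initialisation.
#' @return Data frame with columns `record_id`, `class`, `pseudo_class`
#'   (e.g. `"crystal#2"`), in embedding-set order.
#' @export
make_pseudo_classes <- function(e, labels, target_size = 10000, seed = 1) {
  stopifnot(inherits(e, "xtal_embedding_set"))
  if (length(labels) != length(e$record_ids)) {
    stopf("labels must align with the embedding set (%d vs %d)",
          length(labels), length(e$record_ids))
  }
  if (anyNA(labels)) stopf("every record must be labelled")
  if (!is_count(target_size) || target_size < 1) stopf("target_size must be >= 1")
  classes <- intersect(class_labels(), unique(labels))
  classes <- c(classes, setdiff(unique(labels), class_labels()))
  empty <- setdiff(class_labels(), unique(labels))
  if (length(empty) > 0L && all(labels %in% class_labels())) {
    message("skipping empty class(es): ", paste(empty, collapse = ", "))
  }
  pseudo <- character(length(labels))
  for (cl in classes) {
    idx <- which(labels == cl)
    m <- length(idx)
    k <- max(1L, as.integer(ceiling(m / target_size)))
    assign_k <- if (k == 1L || m <= k) {
      rep(1L, m)
    } else {
      with_seed(hash_seed(seed, "pseudo", cl), {
        stats::kmeans(e$vectors[idx, , drop = FALSE], centers = k,
                      nstart = 10, iter.max = 100)$cluster
      })
    }
    pseudo[idx] <- sprintf("%s#%d", cl, assign_k)
  }
  data.frame(record_id = e$record_ids, class = labels, pseudo_class = pseudo,
             stringsAsFactors = FALSE)
}

# Pick, for each cluster, the member closest to the cluster mean vector.
# Ties are broken by lexicographically smallest record id.
centroid_representatives <- function(vectors, ids, membership) {
  vapply(split(seq_along(ids), membership), function(rows) {
    centre <- colMeans(vectors[rows, , drop = FALSE])
    d <- sqrt(colSums((t(vectors[rows, , drop = FALSE]) - centre)^2))
    cand <- rows[d <= min(d) + 1e-12]
    ids[cand[order(ids[cand])[1L]]]
  }, character(1))
}

#' Deduplicate a set of records by agglomerative clustering
#'
#' Clusters the requested records by average-linkage agglomerative
#' clustering on euclidean embedding distance, cuts the tree at
#' `n_clusters`, and retains from each cluster the single member closest to
#' the cluster mean vector (ties broken by lexicographically smallest
#' record id). Everything else is considered a semantic duplicate of its
#' retained representative.
#'
#' @param e An [embedding_set()].
#' @param ids Record ids to deduplicate (subset of `e$record_ids`).
#' @param n_clusters Number of clusters to form, `1 <= n_clusters <=
#'   length(ids)`.
#' @return Character vector of retained record ids, in the order of `ids`;
#'   always of length `n_clusters`.
#' @export
dedup_within <- function(e, ids, n_clusters) {
  stopifnot(inherits(e, "xtal_embedding_set"))
  if (!is_count(n_clusters) || n_clusters < 1) stopf("n_clusters must be >= 1")
  if (n_clusters > length(ids)) {
    stopf("n_clusters (%d) exceeds the number of records (%d)",
          n_clusters, length(ids))
  }
  if (n_clusters == length(ids)) return(ids)
  vectors <- e$vectors[embedding_rows(e, ids), , drop = FALSE]
  hc <- stats::hclust(stats::dist(vectors), method = "average")
  membership <- stats::cutree(hc, k = n_clusters)
  retained <- centroid_representatives(vectors, ids, membership)
  ids[ids %in% retained]
}

# Allocate a total cluster budget across pseudo-classes proportionally to
# their sizes (largest remainder), then repair to respect 1 <= budget <= size
# while keeping the total exact.
allocate_cluster_budget <- function(sizes, total) {
  if (total < length(sizes)) {
    stopf(paste0("cluster budget (%d) is smaller than the number of ",
                 "pseudo-classes (%d); use a larger retain fraction"),
          total, length(sizes))
  }
  if (total > sum(sizes)) stopf("cluster budget exceeds the number of records")
  alloc <- largest_remainder(sizes, total)
  alloc <- pmin(pmax(alloc, 1L), sizes)
  diff <- total - sum(alloc)
  while (diff != 0L) {
    if (diff > 0L) {
      slack <- sizes - alloc
      i <- order(-slack, seq_along(sizes))[1L]
      if (slack[i] <= 0L) stopf("cannot allocate cluster budget")
      alloc[i] <- alloc[i] + 1L
      diff <- diff - 1L
    } else {
      room <- alloc - 1L
      i <- order(-room, seq_along(sizes))[1L]
      if (room[i] <= 0L) stopf("cannot allocate cluster budget")
      alloc[i] <- alloc[i] - 1L
      diff <- diff + 1L
    }
  }
  alloc
}

#' Build a semantic-deduplication plan for a manifest
#'
#' Combines the pieces of the deduplication procedure: the total retained
#' count is [num_clusters()] of the manifest size; the manifest is split
#' into pseudo-classes with [make_pseudo_classes()]; the cluster budget is
#' divided among pseudo-classes proportionally to their sizes by largest
#' remainder (minimum one each); and [dedup_within()] runs inside each
#' pseudo-class. At `retain_fraction = 1` the plan retains every record.
#'
#' @param m A fully labelled `xtal_manifest`.
#' @param e An [embedding_set()] covering the manifest.
#' @param retain_fraction Fraction of images to retain, in (0, 1].
#' @param target_size Pseudo-class target size (default 10000).
#' @param seed Integer seed (k-means initialisation).
#' @return An object of class `xtal_dedup_plan`: list with
#'   `retain_fraction`, `pseudo_class_target`, `assignments` (the
#'   [make_pseudo_classes()] frame), `clusters_per_pseudo` (named integer)
#'   and `retained_ids` (manifest order).
#' @export
build_dedup_plan <- function(m, e, retain_fraction, target_size = 10000, seed = 1) {
  stopifnot(inherits(m, "xtal_manifest"))
  if (any(is.na(m$label))) stopf("deduplication requires a fully labelled manifest")
  pos <- embedding_rows(e, m$record_id)  # validates coverage
  total <- num_clusters(retain_fraction, nrow(m))
  labels <- m$label[match(e$record_ids, m$record_id)]
  keep <- !is.na(labels)
  sub <- embedding_set(e$vectors[keep, , drop = FALSE], e$record_ids[keep],
                       provider = e$provider)
  assignments <- make_pseudo_classes(sub, labels[keep], target_size, seed)
  if (retain_fraction == 1) {
    retained <- m$record_id
    budgets <- table(assignments$pseudo_class)
    budgets <- stats::setNames(as.integer(budgets), names(budgets))
  } else {
    groups <- split(assignments$record_id, assignments$pseudo_class)
    sizes <- lengths(groups)
    budget_vec <- allocate_cluster_budget(as.integer(sizes), total)
    budgets <- stats::setNames(budget_vec, names(groups))
    retained_all <- unlist(lapply(names(groups), function(g) {
      dedup_within(sub, groups[[g]], budgets[[g]])
    }), use.names = FALSE)
    retained <- m$record_id[m$record_id %in% retained_all]
  }
  structure(
    list(retain_fraction = retain_fraction, pseudo_class_target = target_size,
         assignments = assignments, clusters_per_pseudo = budgets,
         retained_ids = retained),
    class = "xtal_dedup_plan"
  )
}

#' @export
print.xtal_dedup_plan <- function(x, ...) {
  cat(sprintf(
    "<xtal_dedup_plan> retain %.0f%% -> %d of %d records, %d pseudo-class(es)\n",
    100 * x$retain_fraction, length(x$retained_ids), nrow(x$assignments),
    length(x$clusters_per_pseudo)
  ))
  invisible(x)
}

#' Apply a deduplication plan to a manifest
#'
#' @param m The manifest the plan was built from.
#' @param plan An `xtal_dedup_plan`.
#' @return The manifest restricted to the plan's retained records.
#' @export
apply_dedup_plan <- function(m, plan) {
  stopifnot(inherits(m, "xtal_manifest"), inherits(plan, "xtal_dedup_plan"))
  manifest(m[m$record_id %in% plan$retained_ids, , drop = FALSE],
           root = attr(m, "root"))
}

#' Stepwise redundancy curve
#'
#' Estimates how much of a dataset is semantically redundant by
#' deduplicating to a sequence of decreasing retention fractions,
#' retraining a classifier on each reduced training set, and tracking its
#' accuracy on fixed evaluation sets. A flat curve means the removed images
#' carried little extra information. Each fraction is re-clustered from
#' scratch, and each replicate uses a distinct derived seed.
#'
#' @param train_m Fully labelled training `xtal_manifest`.
#' @param train_e [embedding_set()] covering `train_m`.
#' @param eval_sets Named list; each element a list with components
#'   `manifest` and `embeddings` (embedded consistently with `train_e`).
#' @param fractions Strictly decreasing retention fractions in (0, 1].
#' @param replicates Replicates per fraction (distinct seeds).
#' @param target_size Pseudo-class target size.
#' @param seed Integer master seed.
#' @param probe_args Extra arguments passed to [train_linear_probe()].
#' @return An object of class `xtal_redundancy_curve`: list with
#'   `fractions`, `runs` (long data frame: fraction, eval_set, replicate,
#'   accuracy) and `summary` (fraction, eval_set, mean_accuracy, sd).
#' @export
redundancy_curve <- function(train_m, train_e, eval_sets,
                             fractions = seq(1.0, 0.4, by = -0.1),
                             replicates = 3, target_size = 10000, seed = 1,
                             probe_args = list()) {
  if (length(fractions) < 1L || any(diff(fractions) >= 0)) {
    stopf("fractions must be strictly decreasing")
  }
  if (is.null(names(eval_sets)) || any(names(eval_sets) == "")) {
    stopf("eval_sets must be a named list")
  }
  n_class_full <- length(unique(train_m$label))
  runs <- list()
  for (f in fractions) {
    for (r in seq_len(replicates)) {
      rseed <- hash_seed(seed, sprintf("curve/%.6f/%d", f, r))
      plan <- build_dedup_plan(train_m, train_e, f, target_size, seed = rseed)
      sub_m <- apply_dedup_plan(train_m, plan)
      if (length(unique(sub_m$label)) < n_class_full) {
        warnf("fraction %.2f replicate %d lost a class; skipped", f, r)
        next
      }
      rows <- embedding_rows(train_e, sub_m$record_id)
      probe <- do.call(train_linear_probe, c(
        list(e = embedding_set(train_e$vectors[rows, , drop = FALSE],
                               sub_m$record_id, provider = train_e$provider),
             labels = sub_m$label, seed = rseed),
        probe_args
      ))
      for (nm in names(eval_sets)) {
        ev <- eval_sets[[nm]]
        probs <- predict_probs(probe, ev$embeddings)
        acc <- accuracy(probs, ev$manifest$label[
          match(probs$record_ids, ev$manifest$record_id)])
        runs[[length(runs) + 1L]] <- data.frame(
          fraction = f, eval_set = nm, replicate = r, accuracy = acc,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(
    runs, list(runs$fraction, runs$eval_set), drop = TRUE
  ), function(d) {
    data.frame(fraction = d$fraction[1L], eval_set = d$eval_set[1L],
               mean_accuracy = mean(d$accuracy),
               sd = stats::sd(d$accuracy), stringsAsFactors = FALSE)
  }))
  summary <- summary[order(-summary$fraction, summary$eval_set), ]
  rownames(summary) <- NULL
  structure(list(fractions = fractions, runs = runs, summary = summary),
            class = "xtal_redundancy_curve")
}

#' @export
print.xtal_redundancy_curve <- function(x, ...) {
  cat("<xtal_redundancy_curve>\n")
  print(x$summary)
  invisible(x)
}
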