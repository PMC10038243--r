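#' Consensus label for one record's annotations
#'
#' Implements a two-round consensus protocol. With two annotations: if both
#' annotators agree, that label is the consensus; otherwise the record
#' needs a third opinion (`"NEEDS_THIRD"`). With three annotations: any
#' label chosen by at least two annotators wins; if all three differ the
#' record is `"AMBIGUOUS"` and should be excluded from a curated dataset.
#'
#' @param labels Character vector of 2 or 3 class labels (one per
#'   annotator).
#' @return A single string: a class label, `"NEEDS_THIRD"`, or
#'   `"AMBIGUOUS"`.
#' @export
#' @examples
#' consensus_label(c("crystal", "crystal"))          # "crystal"
#' consensus_label(c("crystal", "clear", "crystal")) # "crystal"
#' consensus_label(c("crystal", "clear", "other"))   # "AMBIGUOUS"
consensus_label <- function(labels) {
  if (length(labels) < 2L || length(labels) > 3L) {
    stopf("consensus protocol error: expected 2 or 3 annotations, got %d",
          length(labels))
  }
  check_labels(labels, what = "annotation")
  if (length(labels) == 2L) {
    if (labels[1L] == labels[2L]) return(labels[1L])
    return("NEEDS_THIRD")
  }
  counts <- table(labels)
  if (max(counts) >= 2L) return(names(counts)[which.max(counts)])
  "AMBIGUOUS"
}

#' Merge multi-annotator labels into a consensus manifest
#'
#' Every manifest record must carry 2 or 3 annotations by distinct
#' annotators. Records reaching a consensus keep the consensus label;
#' records where all three annotators disagree are excluded from the
#' returned manifest and reported separately. A record with two
#' disagreeing annotations and no third round is a protocol violation.
#'
#' @param m An `xtal_manifest`.
#' @param annotations Data frame with columns `record_id`, `annotator_id`,
#'   `label` (an annotation set).
#' @return List with `manifest` (consensus-labelled `xtal_manifest`) and
#'   `excluded` (character vector of ambiguous record ids).
#' @export
build_consensus_manifest <- function(m, annotations) {
  stopifnot(inherits(m, "xtal_manifest"))
  required <- c("record_id", "annotator_id", "label")
  if (!all(required %in% names(annotations))) {
    stopf("annotations must have columns %s", paste(required, collapse = ", "))
  }
  ann <- split(annotations, factor(annotations$record_id, levels = m$record_id))
  missing <- m$record_id[vapply(ann, nrow, 0L) == 0L]
  if (length(missing) > 0L) {
    stopf("consensus protocol error: unannotated record(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  consensus <- vapply(m$record_id, function(id) {
    a <- ann[[id]]
    if (anyDuplicated(a$annotator_id)) {
      stopf("record '%s' has repeated annotator ids", id)
    }
    res <- consensus_label(a$label)
    if (res == "NEEDS_THIRD") {
      stopf(paste0("consensus protocol error: record '%s' has two ",
                   "disagreeing annotations and no third round"), id)
    }
    res
  }, character(1))
  excluded <- m$record_id[consensus == "AMBIGUOUS"]
  kept <- m[consensus != "AMBIGUOUS", , drop = FALSE]
  kept$label <- unname(consensus[consensus != "AMBIGUOUS"])
  list(manifest = manifest(kept, root = attr(m, "root")), excluded = excluded)
}

#' Keep one image per timecourse
#'
#' Drops redundant inspections so that each well (timecourse) contributes a
#' single image: the last inspection (default — the latest image carries
#' the most outcome information), the first, or a seeded random one.
#'
#' @param m An `xtal_manifest` with `well_id` populated.
#' @param rule `"last"`, `"first"`, or `"random"`.
#' @param seed Integer seed (used by `rule = "random"`).
#' @return The filtered `xtal_manifest`, one record per `well_id`, in
#'   original row order.
#' @export
one_per_timecourse <- function(m, rule = c("last", "first", "random"), seed = 1) {
  stopifnot(inherits(m, "xtal_manifest"))
  rule <- match.arg(rule)
  keep <- unlist(lapply(split(seq_len(nrow(m)), m$well_id), function(rows) {
    if (length(rows) == 1L) return(rows)
    switch(rule,
      last = {
        cand <- rows[m$timepoint[rows] == max(m$timepoint[rows])]
        cand[order(m$record_id[cand])[1L]]
      },
      first = {
        cand <- rows[m$timepoint[rows] == min(m$timepoint[rows])]
        cand[order(m$record_id[cand])[1L]]
      },
      random = with_seed(hash_seed(seed, "timecourse", m$well_id[rows[1L]]), {
        rows[sample.int(length(rows), 1L)]
      })
    )
  }), use.names = FALSE)
  manifest(m[sort(keep), , drop = FALSE], root = attr(m, "root"))
}

#' Apportion a sample size across the four classes
#'
#' Largest-remainder apportionment of `n` draws over a class distribution:
#' each class gets the floor of its exact quota, and leftover units go to
#' the largest fractional remainders (ties broken in class order). Counts
#' always sum to `n` and each is within one of `n * p_c`.
#'
#' @param dist A class distribution (see [class_dist()]); a preset name is
#'   accepted.
#' @param n Total count (>= 0).
#' @return Named integer vector in [class_labels()] order summing to `n`.
#' @export
#' @examples
#' allocate_counts(preset_distribution("marco"), 1200)
allocate_counts <- function(dist, n) {
  if (is.character(dist)) dist <- preset_distribution(dist)
  dist <- class_dist(unname(dist))
  if (!is_count(n)) stopf("n must be a non-negative integer")
  if (n == 0L) return(stats::setNames(integer(4), class_labels()))
  stats::setNames(largest_remainder(dist, n), class_labels())
}

#' Per-record prediction probability tables
#'
#' @param record_ids Character ids, unique, aligned to `probs` rows.
#' @param probs Numeric `n x k` matrix; every row a probability vector
#'   (entries in \[0, 1\], summing to 1 within 1e-6).
#' @param classes Class names for the columns (default [class_labels()]).
#' @return An object of class `xtal_prob_table`.
#' @export
prob_table <- function(record_ids, probs, classes = class_labels()) {
  probs <- as.matrix(probs)
  record_ids <- as.character(record_ids)
  if (nrow(probs) != length(record_ids)) {
    stopf("probs rows (%d) must align with record_ids (%d)",
          nrow(probs), length(record_ids))
  }
  if (anyDuplicated(record_ids)) stopf("record_ids must be unique")
  if (ncol(probs) != length(classes)) {
    stopf("probs must have one column per class")
  }
  if (length(probs) > 0) {
    if (any(!is.finite(probs)) || any(probs < -1e-9) || any(probs > 1 + 1e-9)) {
      stopf("probabilities must lie in [0, 1]")
    }
    bad <- abs(rowSums(probs) - 1) > 1e-6
    if (any(bad)) {
      stopf("probability row(s) do not sum to 1: %s",
            paste(utils::head(record_ids[bad], 5), collapse = ", "))
    }
  }
  colnames(probs) <- classes
  rownames(probs) <- NULL
  structure(list(record_ids = record_ids, probs = probs, classes = classes),
            class = "xtal_prob_table")
}

#' @export
print.xtal_prob_table <- function(x, ...) {
  cat(sprintf("<xtal_prob_table> %d records x %d classes\n",
              length(x$record_ids), length(x$classes)))
  invisible(x)
}

validate_prob_row <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
    stopf("not a probability vector (entries in [0,1] summing to 1): %s",
          paste(signif(p, 4), collapse = ", "))
  }
  p
}

#' Prediction-entropy hardness score
#'
#' Shannon entropy of a predicted class-probability vector, in nats, with
#' the convention 0 log 0 = 0. High entropy marks images the model finds
#' hard (uncertain); the uniform prediction maximises it at `log(k)`.
#'
#' @param p Probability vector (one prediction row).
#' @return Non-negative entropy in nats.
#' @export
#' @examples
#' entropy_score(rep(0.25, 4)) # log(4)
entropy_score <- function(p) {
  p <- validate_prob_row(as.numeric(p))
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Cross-entropy hardness score against a reference label
#'
#' Negative log-probability the model assigns to the (possibly weak)
#' reference label, in nats; the probability is floored at 1e-12 so
#' confident mistakes get a large finite score.
#'
#' @param p Probability vector in the order of `classes`.
#' @param true_label The reference class label.
#' @param classes Class names aligned to `p`.
#' @return Non-negative cross-entropy in nats.
#' @export
#' @examples
#' cross_entropy_score(c(0.7, 0.1, 0.1, 0.1), "clear") # -log(0.7)
cross_entropy_score <- function(p, true_label, classes = class_labels()) {
  p <- validate_prob_row(as.numeric(p))
  idx <- match(true_label, classes)
  if (is.na(idx)) stopf("unknown label '%s'", true_label)
  -log(max(p[idx], 1e-12))
}

#' Select local images for training-set augmentation
#'
#' Three selection modes over a pool of locally collected images:
#' \describe{
#'   \item{match_distribution}{Seeded per-class random sample whose class
#'     counts are the [allocate_counts()] apportionment of `target_dist` —
#'     e.g. matching the class distribution of the original large training
#'     collection.}
#'   \item{uniform}{Equal per-class counts (largest remainder of `n/4`).}
#'   \item{hardest}{The `n` records with the largest prediction entropy
#'     (ties broken by record id); with `constrain_distribution = TRUE` the
#'     hardest records are taken per class under the `target_dist`
#'     apportionment instead of globally.}
#' }
#' Excluded ids (e.g. a validation set) are never selected.
#'
#' @param pool A labelled `xtal_manifest` of candidate images.
#' @param n_total Number of images to select (>= 0).
#' @param mode Selection mode.
#' @param target_dist Class distribution for `match_distribution` (and for
#'   the constrained hard mode); preset names accepted.
#' @param probs An `xtal_prob_table` covering the pool (required for
#'   `hardest`).
#' @param exclude_ids Record ids that must not be selected.
#' @param constrain_distribution For `hardest`: stratify by `target_dist`.
#' @param seed Integer seed for the random samples.
#' @return Character vector of selected record ids (for `hardest`, in
#'   non-increasing entropy order).
#' @export
select_local <- function(pool, n_total,
                         mode = c("match_distribution", "uniform", "hardest"),
                         target_dist = NULL, probs = NULL,
                         exclude_ids = character(0),
                         constrain_distribution = FALSE, seed = 1) {
  stopifnot(inherits(pool, "xtal_manifest"))
  mode <- match.arg(mode)
  if (!is_count(n_total)) stopf("n_total must be a non-negative integer")
  if (n_total == 0L) return(character(0))
  eligible <- pool[!(pool$record_id %in% exclude_ids), , drop = FALSE]

  pick_by_class <- function(counts, choose) {
    if (any(is.na(eligible$label))) {
      stopf("class-based selection requires a labelled pool")
    }
    sel <- character(0)
    for (cl in class_labels()) {
      want <- counts[[cl]]
      if (want == 0L) next
      ids <- eligible$record_id[eligible$label == cl]
      if (length(ids) < want) {
        stopf("insufficient pool supply for class '%s': need %d, have %d (short %d)",
              cl, want, length(ids), want - length(ids))
      }
      sel <- c(sel, choose(ids, want, cl))
    }
    sel
  }

  if (mode %in% c("match_distribution", "uniform")) {
    dist <- if (mode == "uniform") preset_distribution("uniform") else {
      if (is.null(target_dist)) {
        stopf("match_distribution mode requires target_dist")
      }
      if (is.character(target_dist)) preset_distribution(target_dist) else
        class_dist(unname(target_dist))
    }
    counts <- allocate_counts(dist, n_total)
    return(pick_by_class(counts, function(ids, want, cl) {
      with_seed(hash_seed(seed, "select", cl), sample(ids, want))
    }))
  }

  # hardest
  if (is.null(probs)) stopf("hardest mode requires a probability table")
  stopifnot(inherits(probs, "xtal_prob_table"))
  pos <- match(eligible$record_id, probs$record_ids)
  if (anyNA(pos)) {
    stopf("probability table does not cover pool record(s): %s",
          paste(utils::head(eligible$record_id[is.na(pos)], 5), collapse = ", "))
  }
  ent <- apply(probs$probs[pos, , drop = FALSE], 1L, entropy_score)
  if (constrain_distribution) {
    if (is.null(target_dist)) stopf("constrained hard mode requires target_dist")
    if (is.character(target_dist)) target_dist <- preset_distribution(target_dist)
    counts <- allocate_counts(target_dist, n_total)
    names(ent) <- eligible$record_id
    sel <- pick_by_class(counts, function(ids, want, cl) {
      ids[order(-ent[ids], ids)][seq_len(want)]
    })
    return(sel[order(-ent[sel], sel)])
  }
  if (n_total > nrow(eligible)) {
    stopf("pool has only %d eligible records, %d requested",
          nrow(eligible), n_total)
  }
  eligible$record_id[order(-ent, eligible$record_id)][seq_len(n_total)]
}
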