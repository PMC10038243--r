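#' Screen a dataset for a contaminant image type
#'
#' Workflow for finding a minority image type (e.g. lipidic-mesophase bolus
#' images hiding inside an aqueous-droplet collection): train a two-class
#' linear probe on labelled positive/negative examples, hold out 20% of
#' them (stratified, seeded) to report an honest confusion matrix, then
#' scan every remaining record of the pool and flag those whose
#' positive-class probability reaches `threshold`. Flagged images are
#' candidates for human review — at a typical operating point expect the
#' flagged list to be enriched for, not pure in, the contaminant.
#'
#' @param pool An `xtal_manifest` to scan.
#' @param e An [embedding_set()] covering the pool and the labelled ids.
#' @param positives,negatives Disjoint record-id vectors of labelled
#'   contaminant / non-contaminant examples, each with at least 20 ids.
#' @param threshold Flagging probability in \[0, 1\] (default 0.5).
#' @param seed Integer seed for the stratified split.
#' @param ... Passed to [train_linear_probe()].
#' @return List with `flagged` (record ids, scan order), `confusion`
#'   (held-out 2x2 `xtal_confusion`, classes `negative`/`positive`),
#'   `holdout_accuracy`, `probe` and `scanned` (ids scanned).
#' @export
screen_binary <- function(pool, e, positives, negatives, threshold = 0.5,
                          seed = 1, ...) {
  stopifnot(inherits(pool, "xtal_manifest"), inherits(e, "xtal_embedding_set"))
  positives <- as.character(positives)
  negatives <- as.character(negatives)
  if (length(intersect(positives, negatives)) > 0L) {
    stopf("positives and negatives must be disjoint")
  }
  if (length(positives) < 20L || length(negatives) < 20L) {
    stopf("insufficient data: need >= 20 examples per class (have %d / %d)",
          length(positives), length(negatives))
  }
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  embedding_rows(e, c(positives, negatives))  # validate coverage

  split_class <- function(ids, tag) {
    n_hold <- max(1L, floor(0.2 * length(ids)))
    hold <- with_seed(hash_seed(seed, "screen-split", tag),
                      sort(sample(ids, n_hold)))
    list(train = setdiff(ids, hold), hold = hold)
  }
  sp <- split_class(positives, "pos")
  sn <- split_class(negatives, "neg")
  train_ids <- c(sp$train, sn$train)
  hold_ids <- c(sp$hold, sn$hold)
  lab_of <- function(ids) ifelse(ids %in% positives, "positive", "negative")

  sub <- function(ids) embedding_set(
    e$vectors[embedding_rows(e, ids), , drop = FALSE], ids,
    provider = e$provider
  )
  probe <- train_linear_probe(sub(train_ids), lab_of(train_ids),
                              classes = c("negative", "positive"),
                              seed = seed, ...)
  hold_probs <- predict_probs(probe, sub(hold_ids))
  conf <- confusion(hold_probs, lab_of(hold_ids))
  hold_acc <- accuracy(hold_probs, lab_of(hold_ids))

  scanned <- setdiff(intersect(pool$record_id, e$record_ids),
                     c(positives, negatives))
  flagged <- character(0)
  if (length(scanned) > 0L) {
    scan_probs <- predict_probs(probe, sub(scanned))
    flagged <- scanned[scan_probs$probs[, "positive"] >= threshold]
  }
  list(flagged = flagged, confusion = conf, holdout_accuracy = hold_acc,
       probe = probe, scanned = scanned)
}
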