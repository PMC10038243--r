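# Shared fixtures and independent oracles for the test suite.
# Generated datasets are cached per session: several files reuse the same
# synthetic fixture without re-rendering it.

fixture_cache <- new.env(parent = emptyenv())

fixture_dataset <- function(key, n, group = 4, jitter = 0.01, seed = 3, ...) {
  if (is.null(fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("fixture-", key))
    unlink(dir, recursive = TRUE)
    cfg <- synth_config(n_images = n, duplicate_group_size = group,
                        duplicate_jitter = jitter, seed = seed, ...)
    m <- generate_dataset(cfg, dir)
    e <- baseline_embed(m)
    fixture_cache[[key]] <- list(manifest = m, embeddings = e, dir = dir,
                                 config = cfg)
  }
  fixture_cache[[key]]
}

# A small labelled manifest without any image files (for operations that
# never touch pixels).
table_manifest <- function(labels, well_id = NULL, timepoint = NULL,
                           source = "lab") {
  n <- length(labels)
  if (n == 0L) {
    return(manifest(data.frame(
      record_id = character(0), image_path = character(0),
      label = character(0), source = character(0), well_id = character(0),
      timepoint = integer(0)
    )))
  }
  manifest(data.frame(
    record_id = sprintf("r%04d", seq_len(n)),
    image_path = sprintf("images/r%04d.png", seq_len(n)),
    label = labels,
    source = source,
    well_id = if (is.null(well_id)) sprintf("w%04d", seq_len(n)) else well_id,
    timepoint = if (is.null(timepoint)) rep(0L, n) else timepoint,
    stringsAsFactors = FALSE
  ))
}

# Independent brute-force average-linkage (UPGMA) agglomeration: repeatedly
# merge the cluster pair with the smallest mean inter-point distance, using
# only the original distance matrix. Deliberately naive - the oracle for
# dedup_within().
brute_average_linkage <- function(D, k) {
  clusters <- as.list(seq_len(nrow(D)))
  while (length(clusters) > k) {
    best_i <- best_j <- NA_integer_
    best_d <- Inf
    for (i in 2:length(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best_i <- i
          best_j <- j
        }
      }
    }
    merged <- c(clusters[[best_j]], clusters[[best_i]])
    clusters <- c(clusters[-c(best_i, best_j)], list(merged))
  }
  clusters
}

# Retention rule applied to an explicit clustering: the member nearest the
# cluster mean, ties by smallest record id.
brute_retained <- function(vectors, ids, clusters) {
  sort(vapply(clusters, function(rows) {
    centre <- colMeans(vectors[rows, , drop = FALSE])
    d <- sqrt(colSums((t(vectors[rows, , drop = FALSE]) - centre)^2))
    cand <- rows[d <= min(d) + 1e-12]
    ids[cand[order(ids[cand])[1L]]]
  }, character(1)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_prob_rows <- function(n, k = 4, seed = 1) {
  set.seed(seed)
  p <- matrix(stats::rexp(n * k), n, k)
  p / rowSums(p)
}
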