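test_that("the cluster-count rule rounds half away from zero with floor 1", {
  expect_identical(num_clusters(0.9, 100), 90L)
  expect_identical(num_clusters(1.0, 57), 57L)
  expect_identical(num_clusters(0.5, 10), 5L)
  expect_identical(num_clusters(0.005, 100), 1L)   # floor of one cluster
  expect_identical(num_clusters(0.025, 100), 3L)   # 2.5 rounds away from zero
  expect_error(num_clusters(0, 10), "retain_fraction")
  expect_error(num_clusters(1.2, 10), "retain_fraction")
  expect_error(num_clusters(0.5, 0), "positive")
})

test_that("pseudo-class counts follow the ceiling rule and partition sizes", {
  z <- generate_embeddings(n_per_class = 25, dim = 4, class_separation = 6,
                           within_sd = 0.5, seed = 2)
  pa <- make_pseudo_classes(z$embeddings, z$labels, target_size = 10, seed = 1)
  for (cl in class_labels()) {
    sub <- pa[pa$class == cl, ]
    expect_equal(length(unique(sub$pseudo_class)), 3L)  # ceiling(25 / 10)
    expect_equal(nrow(sub), 25L)
  }
  # small class relative to target: a single pseudo-class
  pa1 <- make_pseudo_classes(z$embeddings, z$labels, target_size = 10000, seed = 1)
  expect_equal(length(unique(pa1$pseudo_class)), 4L)
})

test_that("pseudo-class partitions are stable across seeds on separated data", {
  skip_if_not_installed("mclust")
  # plant two well-separated lumps inside each class
  set.seed(99)
  n <- 40
  base <- matrix(rnorm(4 * n * 3, 0, 0.2), 4 * n, 3)
  lump <- rep(rep(c(0, 30), each = n / 2), times = 4)
  base[, 1] <- base[, 1] + lump + rep(c(0, 100, 200, 300), each = n)
  e <- embedding_set(base, sprintf("v%03d", seq_len(4 * n)))
  labels <- rep(class_labels(), each = n)
  p1 <- make_pseudo_classes(e, labels, target_size = n / 2, seed = 1)
  p2 <- make_pseudo_classes(e, labels, target_size = n / 2, seed = 2)
  expect_gte(ari(p1$pseudo_class, p2$pseudo_class), 0.99)
})

test_that("dedup_within keeps the centre-most member, ties by record id", {
  e <- embedding_set(matrix(c(0, 1, 10, 11), 4, 1), c("a", "b", "c", "d"))
  kept <- dedup_within(e, c("a", "b", "c", "d"), 2)
  # clusters {0,1} and {10,11}; both members equidistant from the centroid,
  # so the lexicographically smaller id wins
  expect_identical(kept, c("a", "c"))

  expect_identical(dedup_within(e, c("a", "b", "c", "d"), 4),
                   c("a", "b", "c", "d"))
  expect_error(dedup_within(e, c("a", "b"), 3), "exceeds")
})

test_that("dedup_within matches the brute-force average-linkage oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:40, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    ids <- sprintf("s%02d", sample(n))  # shuffled ids: order must not matter
    e <- embedding_set(x, ids)
    k <- sample(2:(n - 1), 1)
    D <- as.matrix(dist(x))
    expected <- brute_retained(x, ids, brute_average_linkage(D, k))
    expect_identical(sort(dedup_within(e, ids, k)), expected)
  }
})

test_that("cluster budgets are proportional with largest remainder, min 1", {
  alloc <- xtalcurate:::allocate_cluster_budget(c(50L, 50L), 90L)
  expect_equal(alloc, c(45L, 45L))
  alloc2 <- xtalcurate:::allocate_cluster_budget(c(70L, 30L), 50L)
  expect_equal(alloc2, c(35L, 15L))
  # a tiny pseudo-class still gets its one cluster
  alloc3 <- xtalcurate:::allocate_cluster_budget(c(97L, 2L, 1L), 10L)
  expect_equal(sum(alloc3), 10L)
  expect_true(all(alloc3 >= 1L))
  expect_error(xtalcurate:::allocate_cluster_budget(c(5L, 5L, 5L), 2L),
               "larger retain fraction")
})

test_that("plans retain exactly the requested number of records", {
  fix <- fixture_dataset("wells40", n = 40, group = 4, seed = 2)
  for (f in c(0.9, 0.6, 0.5)) {
    plan <- build_dedup_plan(fix$manifest, fix$embeddings, f, seed = 1)
    expect_length(plan$retained_ids, num_clusters(f, 40))
    expect_equal(sum(plan$clusters_per_pseudo), num_clusters(f, 40))
  }
})

test_that("deduplication at fraction 1 is the identity, and is idempotent", {
  fix <- fixture_dataset("wells40", n = 40, group = 4, seed = 2)
  plan <- build_dedup_plan(fix$manifest, fix$embeddings, 1.0, seed = 1)
  expect_identical(plan$retained_ids, fix$manifest$record_id)

  # dedup once at 0.5, then replanning the reduced set at 1.0 changes nothing
  plan5 <- build_dedup_plan(fix$manifest, fix$embeddings, 0.5, seed = 1)
  reduced <- apply_dedup_plan(fix$manifest, plan5)
  replan <- build_dedup_plan(reduced, fix$embeddings, 1.0, seed = 2)
  expect_identical(replan$retained_ids, reduced$record_id)
})

test_that("g-fold exact duplicates collapse to one representative per group", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_images = 48, duplicate_group_size = 4,
                      duplicate_jitter = 0, seed = 17)
  m <- generate_dataset(cfg, dir)
  e <- baseline_embed(m)
  plan <- build_dedup_plan(m, e, 1 / 4, seed = 1)
  kept <- apply_dedup_plan(m, plan)
  expect_equal(nrow(kept), 12L)
  expect_true(all(table(kept$well_id) == 1L))
  expect_length(unique(kept$well_id), 12L)
})

test_that("redundancy_curve echoes fractions and validates monotonicity", {
  fix <- fixture_dataset("wells40", n = 40, group = 4, seed = 2)
  eval_sets <- list(self = list(manifest = fix$manifest,
                                embeddings = fix$embeddings))
  expect_error(
    redundancy_curve(fix$manifest, fix$embeddings, eval_sets,
                     fractions = c(0.5, 0.9)),
    "strictly decreasing"
  )
  curve <- redundancy_curve(fix$manifest, fix$embeddings, eval_sets,
                            fractions = c(1.0, 0.5), replicates = 2, seed = 4)
  expect_identical(curve$fractions, c(1.0, 0.5))
  # at fraction 1 the curve equals plain training accuracy
  probe <- train_linear_probe(fix$embeddings, fix$manifest$label, seed = 1)
  plain <- accuracy(predict_probs(probe, fix$embeddings), fix$manifest$label)
  acc1 <- curve$summary$mean_accuracy[curve$summary$fraction == 1.0]
  expect_equal(acc1, plain)
})
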