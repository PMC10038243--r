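test_that("two-annotator agreement is consensus; disagreement needs a third", {
  expect_identical(consensus_label(c("crystal", "crystal")), "crystal")
  expect_identical(consensus_label(c("crystal", "clear")), "NEEDS_THIRD")
  expect_identical(consensus_label(c("crystal", "clear", "crystal")), "crystal")
  expect_identical(consensus_label(c("crystal", "clear", "other")), "AMBIGUOUS")
  expect_error(consensus_label("crystal"), "protocol")
  expect_error(consensus_label(rep("clear", 4)), "protocol")
})

test_that("consensus merging agrees with exhaustive triple enumeration", {
  triples <- expand.grid(a = class_labels(), b = class_labels(),
                         c = class_labels(), stringsAsFactors = FALSE)
  m <- table_manifest(rep(NA_character_, nrow(triples)))
  ann <- do.call(rbind, lapply(seq_len(nrow(triples)), function(i) {
    data.frame(record_id = m$record_id[i], annotator_id = c("u1", "u2", "u3"),
               label = unlist(triples[i, ]), stringsAsFactors = FALSE)
  }))
  res <- build_consensus_manifest(m, ann)

  # oracle: enumerate - kept iff some label appears at least twice
  oracle_kept <- apply(triples, 1L, function(tr) max(table(tr)) >= 2)
  expect_equal(nrow(res$manifest), sum(oracle_kept))
  expect_equal(nrow(res$manifest), 40L)
  expect_length(res$excluded, 24L)
  expect_setequal(res$excluded, m$record_id[!oracle_kept])
  # consensus label equals the enumerated majority label
  maj <- apply(triples[oracle_kept, ], 1L, function(tr) {
    tab <- table(tr); names(tab)[which.max(tab)]
  })
  expect_equal(res$manifest$label, unname(maj))
})

test_that("consensus protocol violations are rejected", {
  m <- table_manifest(rep(NA_character_, 2))
  ann <- data.frame(record_id = rep(m$record_id, each = 2),
                    annotator_id = c("u1", "u2", "u1", "u2"),
                    label = c("clear", "clear", "clear", "crystal"))
  expect_error(build_consensus_manifest(m, ann), "no third round")
  expect_error(build_consensus_manifest(m, ann[1:2, ]), "unannotated")
  ann_dup <- transform(ann, annotator_id = "u1")
  expect_error(build_consensus_manifest(m, ann_dup), "repeated annotator")
})

test_that("one_per_timecourse applies its rule deterministically", {
  m <- table_manifest(rep("clear", 40),
                      well_id = rep(sprintf("w%02d", 1:10), each = 4),
                      timepoint = rep(0:3, times = 10))
  last <- one_per_timecourse(m, "last")
  expect_equal(nrow(last), 10L)
  expect_true(all(last$timepoint == 3L))
  first <- one_per_timecourse(m, "first")
  expect_true(all(first$timepoint == 0L))

  # idempotent on an already-unique manifest
  expect_equal(as.data.frame(one_per_timecourse(last, "last")),
               as.data.frame(last))

  r1 <- one_per_timecourse(m, "random", seed = 11)
  r2 <- one_per_timecourse(m, "random", seed = 11)
  expect_identical(r1$record_id, r2$record_id)
  expect_equal(nrow(r1), 10L)
})

test_that("allocate_counts apportions exactly with every count within 1", {
  counts <- allocate_counts(preset_distribution("marco"), 1200)
  expect_identical(unname(counts), c(403L, 154L, 576L, 67L))
  expect_equal(sum(counts), 1200L)

  expect_identical(unname(allocate_counts(preset_distribution("uniform"), 600)),
                   rep(150L, 4))
  expect_identical(unname(allocate_counts(preset_distribution("marco"), 0)),
                   rep(0L, 4))

  # property: sums exact, each count within 1 of n * p
  set.seed(5)
  for (i in 1:20) {
    p <- class_dist(as.vector(stats::rmultinom(1, 100, rep(0.25, 4))) / 100)
    n <- sample(0:2000, 1)
    cts <- allocate_counts(p, n)
    expect_equal(sum(cts), n)
    expect_true(all(abs(cts - n * p) < 1))
  }
})

make_pool <- function(per_class = 700) {
  table_manifest(rep(class_labels(), each = per_class))
}

test_that("distribution-matched selection realises the apportioned counts", {
  pool <- make_pool()
  ids <- select_local(pool, 1200, mode = "match_distribution",
                      target_dist = "marco", seed = 2)
  got <- table(factor(pool$label[match(ids, pool$record_id)],
                      levels = class_labels()))
  expect_identical(unname(as.integer(got)), c(403L, 154L, 576L, 67L))
  expect_false(anyDuplicated(ids) > 0)

  uni <- select_local(pool, 600, mode = "uniform", seed = 2)
  gotu <- table(factor(pool$label[match(uni, pool$record_id)],
                       levels = class_labels()))
  expect_true(all(gotu == 150L))
})

test_that("selection reports shortfalls and honours exclusions", {
  pool <- make_pool(100)
  expect_error(
    select_local(pool, 1200, mode = "match_distribution", target_dist = "marco"),
    "class 'clear': need 403, have 100"
  )
  excl <- pool$record_id[pool$label == "other"][1:90]
  expect_error(
    select_local(pool, 60, mode = "uniform", exclude_ids = excl),
    "short 5"
  )
  ids <- select_local(pool, 40, mode = "uniform", exclude_ids = excl, seed = 1)
  expect_length(intersect(ids, excl), 0L)
})

test_that("hardness selection returns records in non-increasing entropy order", {
  pool <- make_pool(250)  # 1000 records
  probs <- prob_table(pool$record_id, random_prob_rows(1000, seed = 31))
  ids <- select_local(pool, 200, mode = "hardest", probs = probs, seed = 1)
  ent <- apply(probs$probs[match(ids, probs$record_ids), ], 1, entropy_score)
  expect_true(all(diff(ent) <= 1e-12))
  expect_length(ids, 200L)

  # the uniform row is the hardest possible record
  two <- table_manifest(c("clear", "crystal"))
  pt <- prob_table(two$record_id, rbind(c(1, 0, 0, 0), rep(0.25, 4)))
  expect_identical(select_local(two, 1, mode = "hardest", probs = pt),
                   two$record_id[2])

  expect_error(select_local(pool, 5, mode = "hardest"), "probability table")
  short <- prob_table(pool$record_id[1:10], random_prob_rows(10))
  expect_error(select_local(pool, 5, mode = "hardest", probs = short),
               "does not cover")
})

test_that("entropy and cross-entropy scores match their closed forms", {
  expect_equal(entropy_score(rep(0.25, 4)), log(4))
  expect_equal(entropy_score(c(1, 0, 0, 0)), 0)
  expect_equal(entropy_score(c(0.5, 0.25, 0.125, 0.125)), 1.21301, tolerance = 1e-5)
  expect_error(entropy_score(c(0.5, 0.2, 0.2, 0.2)), "probability")

  expect_equal(cross_entropy_score(c(1, 0, 0, 0), "clear"), 0)
  expect_equal(cross_entropy_score(c(0.7, 0.1, 0.1, 0.1), "clear"),
               0.356675, tolerance = 1e-5)
  expect_equal(cross_entropy_score(rep(0.25, 4), "other"), log(4))
  # confident mistakes are floored, not infinite
  expect_equal(cross_entropy_score(c(1, 0, 0, 0), "other"), -log(1e-12))
})
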