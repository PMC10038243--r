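test_that("signed boundary distance matches the closed-form expression", {
  # two classes along the first axis: boundary is the vertical axis
  probe <- linear_probe(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                        rep(0, 4))
  e <- embedding_set(rbind(c(2, 0), c(-0.5, 3), c(0, 1)), c("a", "b", "c"))
  rep1 <- boundary_distances(probe, e, c("clear", "crystal", "clear"))
  d <- rep1$distances[["clear|crystal"]]
  # ((1,0)-(-1,0)) . x / ||(2,0)|| = x1
  expect_equal(d$distance, c(2, -0.5, 0))
  # zero-distance sample sits exactly on the boundary
  expect_equal(d$distance[d$record_id == "c"], 0)
})

test_that("distance sign always agrees with the pairwise argmax", {
  set.seed(7)
  probe <- linear_probe(matrix(rnorm(4 * 6), 4, 6), rnorm(4))
  e <- embedding_set(matrix(rnorm(1000 * 6), 1000, 6), sprintf("s%04d", 1:1000))
  labels <- sample(class_labels(), 1000, replace = TRUE)
  report <- boundary_distances(probe, e, labels)
  scores <- e$vectors %*% t(probe$weights) +
    matrix(probe$biases, 1000, 4, byrow = TRUE)
  for (pair in names(report$distances)) {
    cls <- strsplit(pair, "|", fixed = TRUE)[[1]]
    i <- match(cls[1], class_labels()); j <- match(cls[2], class_labels())
    df <- report$distances[[pair]]
    rows <- match(df$record_id, e$record_ids)
    expect_identical(df$distance > 0, scores[rows, i] > scores[rows, j])
  }
})

test_that("crossing fractions equal pairwise misclassification rates", {
  z <- generate_embeddings(n_per_class = 40, dim = 6, class_separation = 3,
                           within_sd = 1.2, seed = 8)
  probe <- train_linear_probe(z$embeddings, z$labels)
  report <- boundary_distances(probe, z$embeddings, z$labels)
  scores <- z$embeddings$vectors %*% t(probe$weights) +
    matrix(probe$biases, 160, 4, byrow = TRUE)
  for (pair in names(report$distances)) {
    cls <- strsplit(pair, "|", fixed = TRUE)[[1]]
    i <- match(cls[1], class_labels()); j <- match(cls[2], class_labels())
    sel <- which(z$labels %in% cls)
    # counting oracle: restricted two-class decision, ties to the first class
    pred <- ifelse(scores[sel, i] >= scores[sel, j], cls[1], cls[2])
    mis <- mean(pred != z$labels[sel])
    expect_equal(
      report$summary$crossing_fraction[report$summary$pair == pair], mis
    )
  }
  expect_true(all(report$summary$crossing_fraction >= 0 &
                    report$summary$crossing_fraction <= 1))
  expect_equal(nrow(report$summary), 6L)
})

test_that("degenerate pairwise boundaries are reported", {
  probe <- linear_probe(matrix(1, 4, 3), rep(0, 4))
  e <- embedding_set(matrix(rnorm(9), 3, 3), c("a", "b", "c"))
  expect_error(boundary_distances(probe, e, c("clear", "crystal", "other")),
               "degenerate boundary")
})

test_that("a dataset shifted toward the boundaries is detected as shifted", {
  # same seed => identical centre directions; smaller separation shrinks
  # every class toward the decision boundaries (a pure domain shift)
  far <- generate_embeddings(n_per_class = 50, dim = 8, class_separation = 8,
                             within_sd = 0.8, seed = 10)
  near <- generate_embeddings(n_per_class = 50, dim = 8, class_separation = 2.5,
                              within_sd = 0.8, seed = 10)
  probe <- train_linear_probe(far$embeddings, far$labels)
  rep_far <- boundary_distances(probe, far$embeddings, far$labels)
  near_e <- embedding_set(near$embeddings$vectors,
                          paste0("shift-", near$embeddings$record_ids))
  rep_near <- boundary_distances(probe, near_e, near$labels)
  shift <- domain_shift_summary(rep_far, rep_near)
  expect_equal(nrow(shift), 6L)
  expect_true(all(shift$mean_abs_b < shift$mean_abs_a))
  expect_true(mean(shift$crossing_b) > mean(shift$crossing_a))

  # identical datasets show zero differences
  same <- domain_shift_summary(rep_far, rep_far)
  expect_true(all(same$diff_mean_abs == 0))
  expect_true(all(same$diff_crossing == 0))
})

test_that("boundary histograms flatten the report faithfully", {
  z <- generate_embeddings(n_per_class = 15, dim = 4, seed = 2)
  probe <- train_linear_probe(z$embeddings, z$labels)
  report <- boundary_distances(probe, z$embeddings, z$labels)
  h <- boundary_histograms(report, bins = 12, dataset = "train")
  expect_setequal(unique(h$pair), names(report$distances))
  counts_by_pair <- tapply(h$count, h$pair, sum)
  expect_equal(as.integer(counts_by_pair[report$summary$pair]),
               report$summary$n)
})

test_that("2-D projections are deterministic and structure-preserving", {
  # collinear input stays collinear under the linear projection
  e3 <- embedding_set(cbind(1:5, 2 * (1:5) + 3, 0), sprintf("c%d", 1:5))
  coords <- project_2d(e3, method = "linear")
  expect_equal(unname(abs(cor(coords[, 1], 1:5))), 1)
  expect_lt(stats::sd(coords[, 2]), 1e-9)

  z <- generate_embeddings(n_per_class = 25, dim = 10, class_separation = 1,
                           source_separation = 10, n_sources = 2,
                           within_sd = 0.3, seed = 12)
  p1 <- project_2d(z$embeddings, method = "linear", seed = 5)
  p2 <- project_2d(z$embeddings, method = "linear", seed = 5)
  expect_identical(p1, p2)

  # source-dominant embeddings stay source-dominant in 2-D
  D2 <- as.matrix(dist(p1))
  same_source <- outer(z$sources, z$sources, "==") & upper.tri(D2)
  same_class <- outer(z$labels, z$labels, "==") & upper.tri(D2)
  expect_lt(mean(D2[same_source]), mean(D2[same_class]))
})

test_that("umap projection is seed-deterministic when available", {
  skip_if_not_installed("uwot")
  z <- generate_embeddings(n_per_class = 10, dim = 6, seed = 3)
  u1 <- project_2d(z$embeddings, method = "umap", seed = 4)
  u2 <- project_2d(z$embeddings, method = "umap", seed = 4)
  expect_identical(u1, u2)
  expect_equal(dim(u1), c(40L, 2L))
})
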