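#' Generate synthetic embedding vectors with planted class/source structure
#'
#' Draws vectors from isotropic Gaussian clusters positioned at
#' class-centre + source-offset. Class centres are drawn so their expected
#' mutual euclidean distance is `class_separation`; source offsets likewise
#' at `source_separation`. With `source_separation` well above
#' `class_separation` the dominant structure in the space is the imaging
#' source, not the outcome class — the situation self-supervised features of
#' multi-laboratory crystallisation images exhibit — and an unsupervised
#' partition of the vectors agrees better with source than with class.
#'
#' @param n_per_class Vectors per outcome class.
#' @param dim Embedding dimensionality (>= 2).
#' @param class_separation Expected distance between class centres (>= 0).
#' @param source_separation Expected distance between source offsets (>= 0).
#' @param n_sources Number of sources (>= 1), assigned cyclically within
#'   each class.
#' @param within_sd Isotropic within-cluster standard deviation (> 0).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return List with `embeddings` (an [embedding_set()]), `labels`
#'   (character) and `sources` (character), all aligned.
#' @export
#' @examples
#' z <- generate_embeddings(n_per_class = 20, dim = 8, seed = 1)
#' dim(z$embeddings$vectors)
generate_embeddings <- function(n_per_class,
                                dim = 32,
                                class_separation = 4,
                                source_separation = 0,
                                n_sources = 1,
                                within_sd = 1,
                                seed = 1) {
  if (!is_count(n_per_class) || n_per_class < 1) stopf("n_per_class must be >= 1")
  if (!is_count(dim) || dim < 2) stopf("dim must be an integer >= 2")
  if (!is_count(n_sources) || n_sources < 1) stopf("n_sources must be >= 1")
  if (within_sd <= 0) stopf("within_sd must be > 0")
  if (class_separation < 0 || source_separation < 0) {
    stopf("separations must be >= 0")
  }
  k <- 4L
  # Centres ~ N(0, sep^2/(2*dim) I): E||c_i - c_j||^2 = sep^2.
  centres <- with_seed(hash_seed(seed, "class-centres"), {
    matrix(stats::rnorm(k * dim, 0, class_separation / sqrt(2 * dim)), k, dim)
  })
  offsets <- with_seed(hash_seed(seed, "source-offsets"), {
    matrix(stats::rnorm(n_sources * dim, 0, source_separation / sqrt(2 * dim)),
           n_sources, dim)
  })
  n <- n_per_class * k
  labels <- rep(class_labels(), each = n_per_class)
  ci <- rep(seq_len(k), each = n_per_class)
  si <- rep(rep_len(seq_len(n_sources), n_per_class), times = k)
  sources <- sprintf("source%02d", si)
  x <- with_seed(hash_seed(seed, "points"), {
    matrix(stats::rnorm(n * dim, 0, within_sd), n, dim)
  })
  x <- x + centres[ci, , drop = FALSE] + offsets[si, , drop = FALSE]
  ids <- sprintf("emb%06d", seq_len(n))
  list(
    embeddings = embedding_set(x, ids, provider = "synthetic"),
    labels = labels,
    sources = sources
  )
}
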