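#' Embedding sets
#'
#' An embedding set holds one dense vector per image, aligned row-wise to a
#' list of record ids. Euclidean distance in this space is the package's
#' measure of semantic similarity between images: all deduplication and
#' diagnostics downstream are agnostic to which provider produced the
#' vectors, so a deep network's penultimate-layer features can be plugged in
#' via [load_embeddings()] or this constructor as long as the invariants
#' hold (finite entries, constant dimension, ids unique and aligned).
#'
#' @param vectors Numeric `n x d` matrix.
#' @param record_ids Character vector of length `n`, unique.
#' @param provider Name of the producing embedder.
#' @param standardization Optional list with `center` and `scale` vectors
#'   used to standardise the features (stored so the same transform can be
#'   reapplied to new images).
#' @return An object of class `xtal_embedding_set`.
#' @export
embedding_set <- function(vectors, record_ids, provider = "custom",
                          standardization = NULL) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  record_ids <- as.character(record_ids)
  if (nrow(vectors) != length(record_ids)) {
    stopf("embedding set integrity error: %d vector rows but %d record ids",
          nrow(vectors), length(record_ids))
  }
  if (anyDuplicated(record_ids)) stopf("record_ids must be unique")
  if (length(vectors) > 0 && any(!is.finite(vectors))) {
    stopf("embedding vectors must be finite")
  }
  rownames(vectors) <- NULL
  structure(
    list(vectors = vectors, record_ids = record_ids, provider = provider,
         standardization = standardization),
    class = "xtal_embedding_set"
  )
}

#' @export
print.xtal_embedding_set <- function(x, ...) {
  cat(sprintf("<xtal_embedding_set> n=%d d=%d provider=%s\n",
              nrow(x$vectors), ncol(x$vectors), x$provider))
  invisible(x)
}

embedding_rows <- function(e, ids) {
  pos <- match(ids, e$record_ids)
  if (anyNA(pos)) {
    stopf("unknown record id(s) in embedding set: %s",
          paste(utils::head(ids[is.na(pos)], 5), collapse = ", "))
  }
  pos
}

read_grey_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stopf("reading JPEG images requires the 'jpeg' package")
    }
    jpeg::readJPEG(path)
  } else {
    stopf("unsupported image format '%s' (PNG or JPEG expected): %s", ext, path)
  }
  if (length(dim(img)) == 3L) {
    # RGB(A) to luminance
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img
}

# 8x8 block-mean pooling of an arbitrary-size greyscale matrix.
pool_grid <- function(img, grid = 8L) {
  ri <- as.integer(cut(seq_len(nrow(img)), grid, labels = FALSE))
  ci <- as.integer(cut(seq_len(ncol(img)), grid, labels = FALSE))
  sums <- rowsum(t(rowsum(img, ri)), ci)
  counts <- tabulate(ri, grid) %o% tabulate(ci, grid)
  as.vector(t(sums) / counts)
}

# Soft (linearly interpolated) histogram: each value splits its mass between
# the two nearest bin centres, so small intensity shifts move the descriptor
# smoothly instead of jumping at bin edges.
soft_hist <- function(x, bins, lo = 0, hi = 1) {
  p <- (pmin(pmax(x, lo), hi) - lo) / (hi - lo) * bins - 0.5
  b0 <- floor(p)
  frac <- p - b0
  lower <- pmin(pmax(b0 + 1L, 1L), bins)
  upper <- pmin(pmax(b0 + 2L, 1L), bins)
  h <- tabulate(lower, bins) * 0  # zero template
  h <- h + rowsum_vec(1 - frac, lower, bins) + rowsum_vec(frac, upper, bins)
  h / length(x)
}

rowsum_vec <- function(w, idx, bins) {
  out <- numeric(bins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

baseline_features <- function(img) {
  pooled <- pool_grid(img, 8L)
  pooled <- pooled - mean(pooled)  # spatial structure, not global brightness
  hist_int <- soft_hist(as.vector(img), 32L, 0, 1)
  gx <- img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  gy <- img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  gm <- sqrt(gx[-nrow(gx), , drop = FALSE]^2 + gy[, -ncol(gy), drop = FALSE]^2)
  hist_grad <- soft_hist(as.vector(gm), 16L, 0, sqrt(2))
  c(pooled, hist_int, hist_grad)
}

#' Deterministic hand-crafted baseline image embedder
#'
#' Computes a 112-dimensional descriptor per image: an 8x8 mean-pooled
#' luminance grid (64 dims), a 32-bin intensity histogram and a 16-bin
#' gradient-magnitude histogram. Each feature column is standardised to
#' zero mean / unit variance across the embedded set, and the
#' standardisation statistics are stored with the result; pass them back
#' via `stats` to embed new images into the same space (the train/apply
#' asymmetry of any learned or fitted embedder). The embedder is fully
#' deterministic and needs no GPU; a CNN feature extractor can replace it
#' through the [embedding_set()] provider contract.
#'
#' @param m An `xtal_manifest`; every `image_path` must be readable under
#'   the manifest root.
#' @param stats Optional `standardization` list from a previously embedded
#'   set, to reuse its transform.
#' @return An [embedding_set()] with `d = 112` and provider `"baseline"`.
#' @export
baseline_embed <- function(m, stats = NULL) {
  stopifnot(inherits(m, "xtal_manifest"))
  root <- attr(m, "root")
  feats <- matrix(NA_real_, nrow(m), 112L)
  for (i in seq_len(nrow(m))) {
    path <- file.path(root, m$image_path[i])
    img <- tryCatch(read_grey_image(path), error = function(e) {
      stopf("cannot read image for record '%s': %s", m$record_id[i],
            conditionMessage(e))
    })
    feats[i, ] <- baseline_features(img)
  }
  if (is.null(stats)) {
    center <- colMeans(feats)
    # one scale per feature block (pooled grid / intensity / gradient):
    # the block's root-mean column variance. Per-column scaling would blow
    # up near-constant histogram bins and let them dominate the distance.
    blocks <- rep(1:3, c(64L, 32L, 16L))
    colvar <- apply(feats, 2L, stats::var)
    scale <- sqrt(ave(colvar, blocks, FUN = mean))
    scale[!is.finite(scale) | scale == 0] <- 1
    stats <- list(center = center, scale = scale)
  }
  z <- sweep(sweep(feats, 2L, stats$center, "-"), 2L, stats$scale, "/")
  embedding_set(z, m$record_id, provider = "baseline", standardization = stats)
}

#' Random-projection image embedder
#'
#' Projects the raw 112-dim baseline descriptor through a seeded Gaussian
#' random matrix. Mainly a second, structurally different provider for
#' verifying that downstream curation is provider-agnostic.
#'
#' @param m An `xtal_manifest`.
#' @param dim Output dimensionality.
#' @param seed Integer seed for the projection matrix.
#' @return An [embedding_set()] with provider `"random-projection"`.
#' @export
random_projection_embed <- function(m, dim = 32, seed = 1) {
  base <- baseline_embed(m)
  proj <- with_seed(hash_seed(seed, "rproj"), {
    matrix(stats::rnorm(ncol(base$vectors) * dim, 0, 1 / sqrt(dim)),
           ncol(base$vectors), dim)
  })
  embedding_set(base$vectors %*% proj, m$record_id, provider = "random-projection")
}

#' Pairwise euclidean distances between embedded records
#'
#' @param e An [embedding_set()].
#' @param ids_a,ids_b Record id vectors; default all records. The result is
#'   symmetric with zero diagonal when `ids_a` equals `ids_b`.
#' @return `length(ids_a) x length(ids_b)` matrix of euclidean distances,
#'   dimnames set to the ids.
#' @export
pairwise_distance <- function(e, ids_a = e$record_ids, ids_b = ids_a) {
  stopifnot(inherits(e, "xtal_embedding_set"))
  a <- e$vectors[embedding_rows(e, ids_a), , drop = FALSE]
  b <- e$vectors[embedding_rows(e, ids_b), , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  dimnames(d) <- list(ids_a, ids_b)
  d
}

#' Save / load an embedding set
#'
#' `save_embeddings()` writes three plain files sharing the `path` prefix:
#' `<path>.matrix.tsv` (vectors, 17 significant digits — lossless for
#' doubles), `<path>.ids.txt` (one record id per line, bit-exact) and
#' `<path>.meta.json` (provider, dimensions, standardisation statistics).
#' `load_embeddings()` reads them back, checking that row and id counts
#' agree.
#'
#' @param e An [embedding_set()].
#' @param path File path prefix.
#' @return `save_embeddings()`: invisibly, `path`. `load_embeddings()`: the
#'   restored [embedding_set()].
#' @export
save_embeddings <- function(e, path) {
  stopifnot(inherits(e, "xtal_embedding_set"))
  lines <- apply(e$vectors, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  writeLines(as.character(lines), paste0(path, ".matrix.tsv"))
  writeLines(e$record_ids, paste0(path, ".ids.txt"))
  meta <- list(provider = e$provider, n = nrow(e$vectors), d = ncol(e$vectors),
               standardization = e$standardization)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  ids <- readLines(paste0(path, ".ids.txt"))
  lines <- readLines(paste0(path, ".matrix.tsv"))
  if (length(lines) != length(ids)) {
    stopf("embedding integrity error: %d matrix rows but %d ids",
          length(lines), length(ids))
  }
  vec <- if (length(lines) == 0L) {
    matrix(numeric(0), 0L, meta$d)
  } else {
    do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
  }
  if (ncol(vec) != meta$d) {
    stopf("embedding integrity error: matrix has %d columns, meta declares %d",
          ncol(vec), meta$d)
  }
  std <- meta$standardization
  if (!is.null(std)) std <- list(center = std$center, scale = std$scale)
  embedding_set(vec, ids, provider = meta$provider, standardization = std)
}
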