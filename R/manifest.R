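#' Dataset manifests
#'
#' A manifest is the package's inventory of one image dataset: a data frame
#' with one row per inspection image and columns
#' `record_id` (unique string), `image_path` (path relative to the manifest
#' root), `label` (one of [class_labels()], or `NA` when unlabelled),
#' `source` (free-text imaging-style tag, e.g. the contributing laboratory),
#' `well_id` (groups the images of one droplet's timecourse) and `timepoint`
#' (non-negative inspection index within the timecourse).
#'
#' @param records Data frame with the six manifest columns.
#' @param root Directory against which `image_path` is resolved.
#' @return An object of class `xtal_manifest` (a data frame).
#' @export
manifest <- function(records, root = ".") {
  required <- c("record_id", "image_path", "label", "source", "well_id", "timepoint")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stopf("manifest is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[required]
  records$record_id <- as.character(records$record_id)
  records$image_path <- as.character(records$image_path)
  records$label <- as.character(records$label)
  records$label[!is.na(records$label) & records$label == ""] <- NA_character_
  records$source <- as.character(records$source)
  records$well_id <- as.character(records$well_id)
  records$timepoint <- as.integer(records$timepoint)
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0L) {
    stopf("duplicate record_id in manifest: %s", paste(unique(dup), collapse = ", "))
  }
  check_labels(records$label, allow_na = TRUE)
  if (any(is.na(records$timepoint)) || any(records$timepoint < 0L)) {
    stopf("timepoint must be a non-negative integer for every record")
  }
  rownames(records) <- NULL
  structure(records, root = root, class = c("xtal_manifest", "data.frame"))
}

#' @export
print.xtal_manifest <- function(x, ...) {
  cat(sprintf(
    "<xtal_manifest> %d records, %d wells, root: %s\n",
    nrow(x), length(unique(x$well_id)), attr(x, "root")
  ))
  lab <- x$label[!is.na(x$label)]
  if (length(lab) > 0L) {
    counts <- table(factor(lab, levels = class_labels()))
    cat("  labels:", paste(sprintf("%s=%d", names(counts), counts), collapse = " "),
        sprintf(" unlabelled=%d\n", sum(is.na(x$label))))
  }
  invisible(x)
}

#' Read a dataset manifest from CSV
#'
#' The file must be UTF-8 CSV with the mandatory header
#' `record_id,image_path,label,source,well_id,timepoint`. Empty `label`
#' cells become absent (`NA`) labels. Row order is preserved.
#'
#' @param path CSV file path.
#' @param root Directory image paths are relative to; defaults to the
#'   directory containing the manifest file.
#' @return An `xtal_manifest`.
#' @export
read_manifest <- function(path, root = dirname(path)) {
  if (!file.exists(path)) stopf("manifest file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("record_id", "image_path", "label", "source", "well_id", "timepoint")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stopf("manifest %s is missing required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  manifest(df, root = root)
}

#' Write a dataset manifest to CSV
#'
#' Inverse of [read_manifest()]: round-trips every field, writing absent
#' labels as empty cells.
#'
#' @param m An `xtal_manifest`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "xtal_manifest"))
  out <- as.data.frame(m)
  out$label[is.na(out$label)] <- ""
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write manifest to %s", path)
  invisible(path)
}

#' Empirical class distribution of a fully labelled manifest
#'
#' @param m An `xtal_manifest` with every record labelled.
#' @return Named class distribution: the exact per-class frequency, in
#'   [class_labels()] order, summing to 1.
#' @export
#' @examples
#' m <- manifest(data.frame(
#'   record_id = c("a", "b", "c", "d"), image_path = "x.png",
#'   label = c("clear", "clear", "crystal", "other"),
#'   source = "demo", well_id = c("w1", "w2", "w3", "w4"), timepoint = 0
#' ))
#' class_distribution(m)
class_distribution <- function(m) {
  stopifnot(inherits(m, "xtal_manifest"))
  if (nrow(m) == 0L) stopf("class distribution is undefined for an empty manifest")
  if (any(is.na(m$label))) {
    stopf("class_distribution requires every record to be labelled (%d unlabelled)",
          sum(is.na(m$label)))
  }
  counts <- table(factor(m$label, levels = class_labels()))
  stats::setNames(as.numeric(counts) / nrow(m), class_labels())
}
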