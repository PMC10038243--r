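#' The four-class crystallisation outcome vocabulary
#'
#' Crystallisation inspection images are scored into four gross outcome
#' classes: `clear` (no event), `crystal`, `precipitate`, and `other`
#' (phase separation, spherulites, skins, mis-imaged drops, ...). The order
#' returned here is the canonical, project-wide order used by every vector
#' and matrix in the package (alphabetical: clear, crystal, precipitate,
#' other). Published class tables that list the classes in another order are
#' reordered to this one on load.
#'
#' @return Character vector of the four class labels in canonical order.
#' @export
#' @examples
#' class_labels()
class_labels <- function() c("clear", "crystal", "precipitate", "other")

#' Validate a four-class probability distribution
#'
#' @param p Numeric vector of four non-negative values in [class_labels()]
#'   order, summing to 1 (within 1e-9).
#' @return The distribution as a named numeric vector.
#' @export
#' @examples
#' class_dist(c(0.25, 0.25, 0.25, 0.25))
class_dist <- function(p) {
  if (!is.numeric(p) || length(p) != 4L) {
    stopf("a class distribution must be a numeric vector of length 4")
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stopf("class distribution entries must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stopf("class distribution must sum to 1 (got %.12f)", sum(p))
  }
  stats::setNames(as.numeric(p), class_labels())
}

#' Published class-distribution presets
#'
#' Class frequencies of well-known crystallisation image collections, in
#' canonical [class_labels()] order:
#' \describe{
#'   \item{marco}{The large multi-laboratory MARCO training collection:
#'     clear 33.6\%, crystal 12.8\%, precipitate 48\%, other 5.6\%.}
#'   \item{cinder}{Crowd-scored distribution from the Cinder mobile
#'     application, a plausible estimate of the native outcome distribution:
#'     clear 27\%, crystal 11\%, precipitate 50\%, other 12\%.}
#'   \item{uniform}{Equal weight on each class.}
#' }
#'
#' @param name One of `"marco"`, `"cinder"`, `"uniform"`.
#' @return A named class distribution (see [class_dist()]).
#' @export
#' @examples
#' preset_distribution("marco")
preset_distribution <- function(name = c("marco", "cinder", "uniform")) {
  name <- match.arg(name)
  p <- switch(name,
    marco   = c(clear = 0.336, crystal = 0.128, precipitate = 0.48, other = 0.056),
    cinder  = c(clear = 0.27, crystal = 0.11, precipitate = 0.50, other = 0.12),
    uniform = c(clear = 0.25, crystal = 0.25, precipitate = 0.25, other = 0.25)
  )
  class_dist(unname(p))
}

check_labels <- function(labels, allow_na = FALSE, what = "label") {
  bad <- !(labels %in% class_labels())
  if (allow_na) bad <- bad & !is.na(labels)
  if (any(bad)) {
    stopf(
      "invalid %s value(s): %s (must be one of %s)",
      what,
      paste(unique(labels[bad]), collapse = ", "),
      paste(class_labels(), collapse = ", ")
    )
  }
  invisible(labels)
}
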