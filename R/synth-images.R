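#' Imaging-style configuration for the synthetic generator
#'
#' A style bundles the optical idiosyncrasies of one imaging setup
#' (laboratory + imager): overall illumination, vignetting, sensor noise
#' and typical drop size. In real collections this source-to-source
#' variation can dominate the class-to-class variation, so styles are the
#' generator's knob for planting source structure.
#'
#' @param source_name Free-text tag written to the manifest `source` column.
#' @param background_level Mean background intensity in \[0, 1\].
#' @param vignette_strength Radial darkening toward the image corners
#'   (0 = none); intensity is multiplied by `1 - vignette_strength * r^2`
#'   with `r = 1` at the corners.
#' @param noise_sd Gaussian pixel-noise standard deviation (intensity units).
#' @param drop_radius_range Length-2 numeric, min/max drop radius as a
#'   fraction of the image width; both in (0, 0.5].
#' @return A `xtal_style` list.
#' @export
style_config <- function(source_name,
                         background_level = 0.55,
                         vignette_strength = 0.15,
                         noise_sd = 0.03,
                         drop_radius_range = c(0.25, 0.42)) {
  stopifnot(length(drop_radius_range) == 2L)
  if (drop_radius_range[1] > drop_radius_range[2] ||
      any(drop_radius_range <= 0) || any(drop_radius_range > 0.5)) {
    stopf("drop_radius_range must satisfy 0 < min <= max <= 0.5")
  }
  if (background_level < 0 || background_level > 1) {
    stopf("background_level must be in [0, 1]")
  }
  if (vignette_strength < 0 || noise_sd < 0) {
    stopf("vignette_strength and noise_sd must be >= 0")
  }
  structure(
    list(
      source_name = as.character(source_name),
      background_level = background_level,
      vignette_strength = vignette_strength,
      noise_sd = noise_sd,
      drop_radius_range = as.numeric(drop_radius_range)
    ),
    class = "xtal_style"
  )
}

#' Default set of imaging styles
#'
#' Three visibly different setups (bright low-noise, mid-grey vignetted,
#' dark noisy) standing in for distinct contributing laboratories.
#'
#' @param n Number of styles, 1 to 3.
#' @return List of [style_config()] objects.
#' @export
default_styles <- function(n = 3) {
  all <- list(
    style_config("imagerA", background_level = 0.70, vignette_strength = 0.05,
                 noise_sd = 0.02, drop_radius_range = c(0.28, 0.40)),
    style_config("imagerB", background_level = 0.50, vignette_strength = 0.30,
                 noise_sd = 0.03, drop_radius_range = c(0.24, 0.36)),
    style_config("imagerC", background_level = 0.35, vignette_strength = 0.12,
                 noise_sd = 0.05, drop_radius_range = c(0.30, 0.44))
  )
  if (!is_count(n) || n < 1 || n > length(all)) stopf("n must be 1..%d", length(all))
  all[seq_len(n)]
}

#' Synthetic dataset configuration
#'
#' @param n_images Total number of images.
#' @param image_size Side length in pixels of the square images.
#' @param class_dist Class distribution (see [class_dist()]); a preset name
#'   is also accepted.
#' @param styles List of [style_config()]; one is assigned per well.
#' @param style_weights Mixing weights over `styles` (must sum to 1).
#' @param duplicate_group_size Timecourse length: how many near-duplicate
#'   inspections are rendered per well. 1 disables planted redundancy.
#' @param duplicate_jitter Per-timepoint perturbation scale: translation up
#'   to `duplicate_jitter * image_size` pixels and brightness shift up to
#'   `duplicate_jitter` intensity units. 0 makes timecourse images
#'   bit-identical.
#' @param contaminant_fraction Fraction of wells rendered as a lipidic-bolus
#'   contaminant (an image type unlike all four outcome classes), in \[0, 1).
#' @param seed Integer master seed; all generation is a pure function of
#'   (config, seed).
#' @return A `xtal_synth_config` list.
#' @export
synth_config <- function(n_images,
                         image_size = 64,
                         class_dist = preset_distribution("marco"),
                         styles = default_styles(3),
                         style_weights = NULL,
                         duplicate_group_size = 1,
                         duplicate_jitter = 0.02,
                         contaminant_fraction = 0,
                         seed = 1) {
  if (!is_count(n_images) || n_images < 1) stopf("n_images must be a positive integer")
  if (!is_count(image_size) || image_size < 16) stopf("image_size must be an integer >= 16")
  if (is.character(class_dist)) class_dist <- preset_distribution(class_dist)
  class_dist <- class_dist(unname(class_dist))
  if (inherits(styles, "xtal_style")) styles <- list(styles)
  if (length(styles) < 1L || !all(vapply(styles, inherits, TRUE, "xtal_style"))) {
    stopf("styles must be a non-empty list of style_config() objects")
  }
  if (is.null(style_weights)) style_weights <- rep(1 / length(styles), length(styles))
  if (length(style_weights) != length(styles) || any(style_weights < 0) ||
      abs(sum(style_weights) - 1) > 1e-9) {
    stopf("style_weights must be non-negative, aligned to styles, and sum to 1")
  }
  if (!is_count(duplicate_group_size) || duplicate_group_size < 1) {
    stopf("duplicate_group_size must be an integer >= 1")
  }
  if (duplicate_jitter < 0) stopf("duplicate_jitter must be >= 0")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stopf("contaminant_fraction must be in [0, 1)")
  }
  structure(
    list(
      n_images = as.integer(n_images),
      image_size = as.integer(image_size),
      class_dist = class_dist,
      styles = styles,
      style_weights = as.numeric(style_weights),
      duplicate_group_size = as.integer(duplicate_group_size),
      duplicate_jitter = duplicate_jitter,
      contaminant_fraction = contaminant_fraction,
      seed = as.integer(seed)
    ),
    class = "xtal_synth_config"
  )
}

# Renders one droplet scene. All stochastic choices are drawn from `seed`'s
# stream in a fixed order, so the same (label, style, seed) is bit-identical.
# `offset` (fraction of width) and `brightness` are applied on top, which is
# how timecourse jitter perturbs a shared base scene without touching its RNG.
render_scene <- function(label, style, seed, size = 64,
                         offset = c(0, 0), brightness = 0) {
  with_seed(seed, {
    s <- as.integer(size)
    ax <- (seq_len(s) - 0.5) / s
    gx <- matrix(ax, s, s, byrow = TRUE)   # column coordinate
    gy <- matrix(ax, s, s)                 # row coordinate

    rr <- style$drop_radius_range
    radius <- stats::runif(1, rr[1], rr[2])
    centre <- 0.5 + stats::runif(2, -0.05, 0.05)
    cx <- centre[1] + offset[1]
    cy <- centre[2] + offset[2]
    # each drop has its own illumination fingerprint: background offset,
    # lighting tilt, two smooth interference-like texture components
    # (plate bottom, condensation) and its own sensor-noise level
    bg_off <- stats::runif(1, -0.10, 0.10)
    tilt <- stats::runif(2, -0.18, 0.18)
    tex_amp <- stats::runif(2, 0.03, 0.07)
    tex_freq <- stats::runif(4, 2, 7)
    tex_phase <- stats::runif(2, 0, 2 * pi)
    noise_scale <- stats::runif(1, 0.7, 1.3)
    noise <- matrix(stats::rnorm(s * s, 0, style$noise_sd * noise_scale), s, s)

    r2v <- ((gx - 0.5)^2 + (gy - 0.5)^2) * 2      # 1 at the corners
    img <- (style$background_level + bg_off) *
      (1 - style$vignette_strength * r2v) +
      tilt[1] * (gx - 0.5) + tilt[2] * (gy - 0.5) +
      tex_amp[1] * sin(2 * pi * (tex_freq[1] * gx + tex_freq[2] * gy) + tex_phase[1]) +
      tex_amp[2] * sin(2 * pi * (tex_freq[3] * gx + tex_freq[4] * gy) + tex_phase[2])

    # masks are anti-aliased (1-pixel linear feather) so sub-pixel
    # timecourse translation perturbs the image smoothly
    feather <- function(x) pmin(pmax(x * s, 0), 1)
    dd <- sqrt((gx - cx)^2 + (gy - cy)^2)
    w_in <- feather(radius - dd)                    # 1 inside the drop
    w_rim <- pmax(0, 1 - abs(dd - radius) * s / 1.5)
    img <- img + 0.10 * w_in                        # drop meniscus brightening
    img <- img * (1 - 0.65 * w_rim)                 # dark drop rim

    blend <- function(img, w, value) img * (1 - w) + value * w
    if (label == "crystal") {
      k <- sample.int(5L, 1L)
      for (i in seq_len(k)) {
        ang <- stats::runif(1, 0, pi)
        clen <- stats::runif(1, 0.55, 0.95) * radius
        cwid <- max(clen * stats::runif(1, 0.12, 0.25), 2 / s)
        pos_r <- stats::runif(1, 0, 0.45 * radius)
        pos_a <- stats::runif(1, 0, 2 * pi)
        px <- cx + pos_r * cos(pos_a)
        py <- cy + pos_r * sin(pos_a)
        u <- c(cos(ang), sin(ang))
        du <- (gx - px) * u[1] + (gy - py) * u[2]
        dv <- -(gx - px) * u[2] + (gy - py) * u[1]
        w <- feather(clen / 2 - abs(du)) * feather(cwid / 2 - abs(dv)) * w_in
        img <- blend(img, w, 0.95)
      }
    } else if (label == "precipitate") {
      w_core <- feather(0.8 * radius - dd)
      grain <- matrix(stats::rnorm(s * s, 0, 0.22), s, s)
      img <- img + grain * w_core
    } else if (label == "other") {
      # wobbly ring: phase separation / spherulite caricature
      phi <- stats::runif(1, 0, 2 * pi)
      wob <- stats::runif(1, 0.15, 0.3)
      theta <- atan2(gy - cy, gx - cx)
      r_ring <- 0.5 * radius * (1 + wob * sin(3 * theta + phi))
      w <- feather(0.1 * radius - abs(dd - r_ring)) * w_in
      img <- blend(img, w, 0.78)
    } else if (label == "contaminant") {
      # large irregular bolus filling most of the drop, unlike any class
      phi <- stats::runif(1, 0, 2 * pi)
      theta <- atan2(gy - cy, gx - cx)
      r_bol <- radius * (0.82 + 0.13 * sin(4 * theta + phi))
      img <- blend(img, feather(r_bol - dd) * w_in, 0.88)
      w_edge <- pmax(0, 1 - abs(dd - r_bol) * s / 1.5) * w_in
      img <- blend(img, w_edge, 0.20)
    } else if (label != "clear") {
      stopf("unknown droplet label: %s", label)
    }

    img <- img + noise + brightness
    img[img < 0] <- 0
    img[img > 1] <- 1
    round(img * 255) / 255   # 8-bit quantisation: reproducible across I/O
  })
}

#' Render a single synthetic droplet image
#'
#' Produces a square 8-bit greyscale image of a crystallisation drop with
#' the visual signature of the requested class: `clear` shows the bare drop,
#' `crystal` 1–5 bright elongated laths, `precipitate` granular
#' high-frequency texture, `other` an irregular ring, and `"contaminant"`
#' (the extra non-class type) a large bolus filling most of the drop.
#' Rendering is a pure function of `(label, style, seed)`.
#'
#' @param label One of [class_labels()] or `"contaminant"`.
#' @param style A [style_config()].
#' @param seed Integer RNG seed for this image.
#' @param size Image side length in pixels.
#' @return Numeric matrix `size x size` with values in \[0, 1\] quantised to
#'   256 levels.
#' @export
#' @examples
#' img <- render_droplet("crystal", style_config("demo"), seed = 7)
#' dim(img)
render_droplet <- function(label, style, seed, size = 64) {
  if (!label %in% c(class_labels(), "contaminant")) {
    stopf("label must be one of %s or 'contaminant'",
          paste(class_labels(), collapse = ", "))
  }
  stopifnot(inherits(style, "xtal_style"))
  render_scene(label, style, as.integer(seed), size = size)
}

#' Generate a synthetic labelled droplet dataset on disk
#'
#' Writes PNG images plus a `manifest.csv` under `out_dir` and returns the
#' manifest. Records are grouped into timecourses (`well_id`) of
#' `duplicate_group_size` near-duplicate inspections rendered from one base
#' scene with per-timepoint translation/brightness jitter, emulating the
#' redundancy of repeatedly imaged drops. Class counts follow the
#' largest-remainder allocation of `class_dist` over wells (exactly the
#' image-level allocation when `duplicate_group_size` is 1 or divides the
#' per-class image counts). A `contaminant_fraction` of wells is rendered as
#' lipidic-bolus contaminants: they keep a class label but get a
#' `"+lcp"`-suffixed source tag and are listed in a `contaminants.txt`
#' sidecar.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return The dataset `xtal_manifest` (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "xtal_synth_config"))
  img_dir <- file.path(out_dir, "images")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stopf("cannot create output directory %s", img_dir)

  n <- cfg$n_images
  g <- cfg$duplicate_group_size
  n_wells <- as.integer(ceiling(n / g))
  well_sizes <- rep(g, n_wells)
  if (n %% g != 0L) well_sizes[n_wells] <- n %% g   # final group truncated

  per_class_wells <- largest_remainder(cfg$class_dist, n_wells)
  well_labels <- rep(class_labels(), per_class_wells)

  style_idx <- with_seed(hash_seed(cfg$seed, "styles"), {
    sample.int(length(cfg$styles), n_wells, replace = TRUE, prob = cfg$style_weights)
  })
  n_cont <- as.integer(round(cfg$contaminant_fraction * n_wells))
  cont_wells <- if (n_cont > 0L) {
    with_seed(hash_seed(cfg$seed, "contaminants"),
              sort(sample.int(n_wells, n_cont)))
  } else integer(0)

  rows <- vector("list", n)
  cont_ids <- character(0)
  idx <- 0L
  for (w in seq_len(n_wells)) {
    well_id <- sprintf("well%05d", w)
    style <- cfg$styles[[style_idx[w]]]
    is_cont <- w %in% cont_wells
    render_label <- if (is_cont) "contaminant" else well_labels[w]
    well_seed <- hash_seed(cfg$seed, well_id)
    for (t in seq_len(well_sizes[w]) - 1L) {
      idx <- idx + 1L
      record_id <- sprintf("%s_t%02d", well_id, t)
      jit <- with_seed(hash_seed(cfg$seed, record_id), stats::runif(3, -1, 1))
      img <- render_scene(
        render_label, style, well_seed, size = cfg$image_size,
        offset = jit[1:2] * cfg$duplicate_jitter,
        brightness = jit[3] * cfg$duplicate_jitter
      )
      rel <- file.path("images", paste0(record_id, ".png"))
      png::writePNG(img, file.path(out_dir, rel))
      if (is_cont) cont_ids <- c(cont_ids, record_id)
      rows[[idx]] <- data.frame(
        record_id = record_id, image_path = rel, label = well_labels[w],
        source = if (is_cont) paste0(style$source_name, "+lcp") else style$source_name,
        well_id = well_id, timepoint = t, stringsAsFactors = FALSE
      )
    }
  }
  m <- manifest(do.call(rbind, rows), root = out_dir)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  if (cfg$contaminant_fraction > 0) {
    writeLines(cont_ids, file.path(out_dir, "contaminants.txt"))
  }
  m
}
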