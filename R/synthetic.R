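# Synthetic single-cell image generator and simulated experiment tables.
#
# The generator emulates the composition of the published stamen-hair cell
# dataset: two balanced classes (blue and pink), bounding boxes between 13 and
# 256 px, per-class Gaussian RGB color models matching the published per-class
# pixel means and standard deviations, four cell shapes (round, oval,
# rectangular, elongated), optional brighter vacuoles, a minority fraction of
# pixels drawn from the opposite class's color model ("blue cell with pinkish
# pixels"), and a pure white background.

CELL_CLASSES <- c("blue", "pink")
CELL_SHAPES <- c("round", "oval", "rectangular", "elongated")

#' Default per-class RGB color models
#'
#' Per-channel pixel means and standard deviations of blue and pink
#' stamen-hair cells, the published population statistics of the Trad-204
#' dataset (background excluded).
#'
#' @return A list with elements `blue` and `pink`, each holding `mean` and
#'   `sd` RGB triples on the 0--255 scale.
#' @export
class_color_defaults <- function() {
  list(
    blue = list(mean = c(97.6, 91.7, 122.0), sd = c(25.0, 31.8, 45.7)),
    pink = list(mean = c(143.9, 97.1, 140.2), sd = c(33.6, 34.1, 39.4))
  )
}

#' Specification of a single synthetic cell
#'
#' @param label cell class, `"blue"` or `"pink"`.
#' @param shape one of `"round"`, `"oval"`, `"rectangular"`, `"elongated"`.
#' @param side_px target bounding-box side in pixels, in `[13, 256]`.
#' @param minority_fraction proportion of cell pixels drawn from the opposite
#'   class's color model, in `[0, 0.45]` (the label stays the majority color).
#' @param vacuole_count non-negative number of brighter interior vacuoles.
#' @param rng_seed integer seed making the cell bit-reproducible.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(label, shape = "round", side_px = 64L,
                      minority_fraction = 0, vacuole_count = 0L,
                      rng_seed = 1L) {
  if (!label %in% CELL_CLASSES) {
    stop("unknown cell label '", label, "'; expected one of: ",
         paste(CELL_CLASSES, collapse = ", "))
  }
  if (!shape %in% CELL_SHAPES) {
    stop("unknown cell shape '", shape, "'; expected one of: ",
         paste(CELL_SHAPES, collapse = ", "))
  }
  side_px <- as.integer(side_px)
  if (side_px < 13L || side_px > 256L) {
    stop("side_px must lie in [13, 256], got ", side_px)
  }
  if (minority_fraction < 0 || minority_fraction > 0.45) {
    stop("minority_fraction must lie in [0, 0.45], got ", minority_fraction)
  }
  if (vacuole_count < 0) stop("vacuole_count must be non-negative")
  structure(list(label = label, shape = shape, side_px = side_px,
                 minority_fraction = minority_fraction,
                 vacuole_count = as.integer(vacuole_count),
                 rng_seed = as.integer(rng_seed)),
            class = "cell_spec")
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults mirror the published dataset composition: 102 images per class,
#' bounding boxes from 13 to 256 px, class color models from
#' [class_color_defaults()], and a white background. The minority
#' contamination range is a modeling choice (the source images show visible
#' cross-class pixels but no printed fraction).
#'
#' @param n_per_class images generated per class.
#' @param size_range integer pair of admissible bounding-box sides.
#' @param class_colors per-class color models as in [class_color_defaults()].
#' @param minority_fraction_range range the per-cell contamination fraction is
#'   drawn from; must stay below 0.5.
#' @param vacuole_range integer pair; per-cell vacuole count range.
#' @param background_value RGB triple of the background (pure white).
#' @param seed master seed for the whole dataset.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_class = 102L,
                             size_range = c(13L, 256L),
                             class_colors = class_color_defaults(),
                             minority_fraction_range = c(0.05, 0.25),
                             vacuole_range = c(0L, 2L),
                             background_value = c(255L, 255L, 255L),
                             seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  size_range <- as.integer(size_range)
  if (size_range[1] < 13L || size_range[2] > 256L ||
      size_range[1] > size_range[2]) {
    stop("size_range must be an increasing pair within [13, 256]")
  }
  stopifnot(all(c("blue", "pink") %in% names(class_colors)))
  if (minority_fraction_range[2] >= 0.5) {
    stop("minority_fraction_range must stay below 0.5 so the label remains ",
         "the majority color")
  }
  structure(list(n_per_class = n_per_class, size_range = size_range,
                 class_colors = class_colors,
                 minority_fraction_range = minority_fraction_range,
                 vacuole_range = as.integer(vacuole_range),
                 background_value = as.integer(background_value),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Boolean cell mask for a shape on an H x W canvas. Shapes are filled
# ellipses (round/oval), rounded rectangles (rectangular) and high-aspect
# capsules (elongated).
shape_mask <- function(shape, H, W) {
  y <- seq_len(H) - (H + 1) / 2
  x <- seq_len(W) - (W + 1) / 2
  ay <- H / 2 - 0.5
  ax <- W / 2 - 0.5
  if (shape %in% c("round", "oval")) {
    return(outer(y / ay, x / ax, function(u, v) u^2 + v^2 <= 1))
  }
  r <- if (shape == "elongated") ax else 0.2 * min(H, W)
  dy <- outer(abs(y) - (ay - r), rep(1, W))
  dx <- outer(rep(1, H), abs(x) - (ax - r))
  (dy <= 0 & dx <= 0) | (pmax(dy, 0)^2 + pmax(dx, 0)^2 <= r^2)
}

# Canvas height/width for a spec; secondary side follows a shape-dependent
# aspect ratio, clamped to the admissible [13, 256] range.
canvas_dims <- function(shape, side_px) {
  aspect <- switch(shape, round = 1, oval = 0.62, rectangular = 0.7,
                   elongated = 0.28)
  H <- side_px
  W <- max(13L, min(256L, as.integer(round(aspect * side_px))))
  c(H, W)
}

#' Generate one synthetic stamen-hair cell image
#'
#' Draws cell pixels from the labeled class's Gaussian RGB model, replaces a
#' `minority_fraction` of them with draws from the opposite class's model,
#' optionally brightens vacuole regions, and sets everything outside the cell
#' mask to the background color. Deterministic given `spec$rng_seed`.
#'
#' @param spec a [cell_spec()].
#' @param config a [generator_config()] supplying the color models and
#'   background.
#' @return A [cell_image()] with 8-bit pixels.
#' @export
generate_cell_image <- function(spec, config = generator_config()) {
  stopifnot(inherits(spec, "cell_spec"))
  d <- canvas_dims(spec$shape, spec$side_px)
  H <- d[1]; W <- d[2]
  mask <- shape_mask(spec$shape, H, W)
  n_cell <- sum(mask)
  own <- config$class_colors[[spec$label]]
  other <- config$class_colors[[setdiff(CELL_CLASSES, spec$label)]]

  px <- with_seed(spec$rng_seed, {
    px <- array(rep(config$background_value, each = H * W), dim = c(H, W, 3))
    cell_idx <- which(mask)
    n_minor <- as.integer(round(spec$minority_fraction * n_cell))
    minor <- if (n_minor > 0) sample(cell_idx, n_minor) else integer(0)
    major <- setdiff(cell_idx, minor)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[major] <- stats::rnorm(length(major), own$mean[ch], own$sd[ch])
      if (n_minor > 0) {
        plane[minor] <- stats::rnorm(n_minor, other$mean[ch], other$sd[ch])
      }
      px[, , ch] <- plane
    }
    if (spec$vacuole_count > 0) {
      for (k in seq_len(spec$vacuole_count)) {
        cy <- stats::runif(1, 0.3, 0.7) * H
        cx <- stats::runif(1, 0.3, 0.7) * W
        ry <- max(2, stats::runif(1, 0.06, 0.16) * H)
        rx <- max(2, stats::runif(1, 0.06, 0.16) * W)
        vac <- outer((seq_len(H) - cy) / ry, (seq_len(W) - cx) / rx,
                     function(u, v) u^2 + v^2 <= 1) & mask
        if (any(vac)) {
          for (ch in 1:3) {
            plane <- px[, , ch]
            # vacuoles read brighter: pull colors halfway toward white
            plane[vac] <- plane[vac] + 0.5 * (255 - plane[vac])
            px[, , ch] <- plane
          }
        }
      }
    }
    px
  })
  px <- round(pmin(pmax(px, 0), 255))
  storage.mode(px) <- "integer"
  cell_image(px, spec$label,
             source_id = sprintf("synthetic_%s_%s_%d", spec$label, spec$shape,
                                 spec$rng_seed))
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_per_class` cell specifications per class (shape, size,
#' contamination fraction, vacuoles sampled per `config`) and renders each
#' with [generate_cell_image()]. Class balance is exact and the result is
#' deterministic given `config$seed`. Bounding-box sides are drawn
#' log-uniformly over `size_range`, reflecting the many small and few large
#' cells in stamen-hair crops.
#'
#' @param config a [generator_config()].
#' @return A [labeled_dataset()].
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  specs <- with_seed(config$seed, {
    out <- list()
    for (label in CELL_CLASSES) {
      for (i in seq_len(config$n_per_class)) {
        side <- round(exp(stats::runif(1, log(config$size_range[1]),
                                       log(config$size_range[2]))))
        out[[length(out) + 1L]] <- cell_spec(
          label = label,
          shape = sample(CELL_SHAPES, 1),
          side_px = min(max(side, 13L), 256L),
          minority_fraction = stats::runif(1, config$minority_fraction_range[1],
                                           config$minority_fraction_range[2]),
          vacuole_count = sample(seq(config$vacuole_range[1],
                                     config$vacuole_range[2]), 1),
          rng_seed = sample.int(2147483646L, 1)
        )
      }
    }
    out
  })
  images <- lapply(specs, generate_cell_image, config = config)
  for (i in seq_along(images)) {
    images[[i]]$source_id <- sprintf("%s_%03d", images[[i]]$label,
                                     ((i - 1) %% config$n_per_class) + 1L)
  }
  labeled_dataset(images)
}

#' Configuration for simulated dose-response tables
#'
#' Defaults reproduce the diesel-contaminated-soil experiment: doses 0
#' (control), 100, 1000, 10000 and 100000 mg oil per kg soil, and the
#' saturating response curve fitted in the source study,
#' y = 4.78 x / (125.12 + x) + 0.03 pink cells per 1000 stamen hairs.
#' The highest dose killed the plants and yields no observations, so it is
#' excluded from the default simulated doses.
#'
#' @param concentrations doses in mg/kg, all non-negative.
#' @param m saturation level (response units).
#' @param h half-saturation dose (mg/kg), positive.
#' @param b baseline response (bias).
#' @param noise_sd Gaussian noise SD on the response.
#' @param n_replicates rows simulated per dose.
#' @param seed integer seed.
#' @return A `dose_response_sim_config` list.
#' @export
dose_response_sim_config <- function(concentrations = c(0, 100, 1000, 10000),
                                     m = 4.78, h = 125.12, b = 0.03,
                                     noise_sd = 0.2, n_replicates = 5L,
                                     seed = 1L) {
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (m <= 0 || h <= 0) stop("m and h must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(concentrations = concentrations, m = m, h = h, b = b,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "dose_response_sim_config")
}

#' Simulate a dose-response table
#'
#' Evaluates the saturating curve y = m x / (h + x) + b at each configured
#' dose and adds Gaussian noise, with `n_replicates` rows per dose.
#'
#' @param cfg a [dose_response_sim_config()].
#' @return A data.frame with columns `concentration` and `response`.
#' @export
simulate_dose_response <- function(cfg = dose_response_sim_config()) {
  stopifnot(inherits(cfg, "dose_response_sim_config"))
  x <- rep(cfg$concentrations, each = cfg$n_replicates)
  mu <- eval_saturating(x, cfg$m, cfg$h, cfg$b)
  y <- with_seed(cfg$seed, mu + stats::rnorm(length(x), 0, cfg$noise_sd))
  data.frame(concentration = x, response = y)
}

#' Configuration for simulated exposure series
#'
#' Defaults follow the particulate-matter exposure analysis, where pink-cell
#' appearance per 1000 stamen hairs relates to windowed PM averages through a
#' no-intercept line (slope 7.00 for PM10, 12.82 for PM2.5).
#'
#' @param slope response units per microgram per cubic meter.
#' @param n_points number of (x, y) points, at least 2.
#' @param x_range PM concentration range sampled uniformly.
#' @param noise_sd Gaussian noise SD on the response.
#' @param seed integer seed.
#' @return An `exposure_sim_config` list.
#' @export
exposure_sim_config <- function(slope = 7.00, n_points = 50L,
                                x_range = c(5, 40), noise_sd = 5,
                                seed = 1L) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  if (!is.finite(slope)) stop("slope must be finite")
  structure(list(slope = slope, n_points = n_points, x_range = x_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "exposure_sim_config")
}

#' Simulate a PM-exposure / pink-cell-appearance table
#'
#' @param cfg an [exposure_sim_config()].
#' @return A data.frame with columns `pm_average` and `pink_appearance`.
#' @export
simulate_exposure_series <- function(cfg = exposure_sim_config()) {
  stopifnot(inherits(cfg, "exposure_sim_config"))
  with_seed(cfg$seed, {
    x <- stats::runif(cfg$n_points, cfg$x_range[1], cfg$x_range[2])
    y <- cfg$slope * x + stats::rnorm(cfg$n_points, 0, cfg$noise_sd)
    data.frame(pm_average = x, pink_appearance = y)
  })
}
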