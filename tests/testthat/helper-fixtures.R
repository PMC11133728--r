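# Shared fixtures, built in code. Small image sizes keep the suite fast; the
# generator's statistical structure is unchanged.

# Color models centered on the published baseline interval centers, with
# spreads narrow enough that the fixed-interval classifier is a perfect
# oracle on uncontaminated cells.
profile_matched_colors <- function(sd = 8) {
  list(blue = list(mean = c(70.99, 75.87, 163.05), sd = rep(sd, 3)),
       pink = list(mean = c(133.83, 75.84, 182.24), sd = rep(sd, 3)))
}

small_config <- function(n_per_class = 6, seed = 101, ...) {
  generator_config(n_per_class = n_per_class, size_range = c(13, 48),
                   seed = seed, ...)
}

# Separable dataset reused across expensive tests (built once per run).
.fixture_cache <- new.env(parent = emptyenv())

separable_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    cfg <- small_config(n_per_class = 8, seed = 202,
                        class_colors = profile_matched_colors(),
                        minority_fraction_range = c(0, 0),
                        vacuole_range = c(0, 1))
    .fixture_cache$ds <- generate_dataset(cfg)
  }
  .fixture_cache$ds
}

# A deterministic flat-color image (constant RGB triple).
flat_image <- function(rgb, label = "blue", h = 16, w = 16, id = "flat") {
  px <- array(rep(as.integer(round(rgb)), each = h * w), dim = c(h, w, 3))
  storage.mode(px) <- "integer"
  cell_image(px, label, source_id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Central finite-difference gradient of scalar-valued f at array x.
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
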