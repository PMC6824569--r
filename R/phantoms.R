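#' Ellipse phantom
#'
#' A parametric ground-truth object: an ordered set of ellipses, each with a
#' centre (pixels, relative to the image centre), semi-axes, rotation and an
#' additive attenuation coefficient. Overlapping ellipses add (attenuation is
#' additive along rays), which keeps the analytic fan-beam projection exact.
#' Every ellipse must lie inside the image's inscribed support disk.
#'
#' @param ellipses Data frame with columns `cx, cy, a, b, theta, mu`
#'   (centre, semi-axes, rotation in radians, attenuation).
#' @param grid_size Raster side length in pixels (default 512).
#' @return An object of class `ellipse_phantom`.
#' @export
ellipse_phantom <- function(ellipses, grid_size = 512) {
  cols <- c("cx", "cy", "a", "b", "theta", "mu")
  if (nrow(ellipses) > 0) {
    if (!all(cols %in% names(ellipses))) stop("missing ellipse columns")
    ellipses <- as.data.frame(ellipses)[, cols]
    if (any(ellipses$a <= 0 | ellipses$b <= 0))
      stop("semi-axes must be positive")
    ext <- sqrt(ellipses$cx^2 + ellipses$cy^2) + pmax(ellipses$a, ellipses$b)
    if (any(ext > grid_size / 2 + 1e-9))
      stop("ellipse ", which.max(ext), " extends beyond the support disk")
  } else {
    ellipses <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                           b = numeric(0), theta = numeric(0), mu = numeric(0))
  }
  structure(list(ellipses = ellipses, grid_size = as.integer(grid_size)),
            class = "ellipse_phantom")
}

#' @export
print.ellipse_phantom <- function(x, ...) {
  cat(sprintf("ellipse_phantom: %d ellipses on a %d x %d grid\n",
              nrow(x$ellipses), x$grid_size, x$grid_size))
  invisible(x)
}

#' Seeded random ellipse phantom
#'
#' Draws a phantom of "tens of ellipses" with random attenuations, sizes,
#' locations and orientations. The defaults are the package's documented
#' stand-in for unstated generator distributions: ellipse count uniform on
#' `[n_ellipses_min, n_ellipses_max]`, semi-axes uniform on
#' `[grid_size/32, grid_size/6]`, attenuation uniform on `(0, 1]`, rotation
#' uniform on `[0, pi)`, and the centre uniform on the disk that keeps the
#' whole ellipse inside the inscribed support disk.
#'
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @param n_ellipses_min,n_ellipses_max Inclusive range of the ellipse count.
#' @param grid_size Raster side length in pixels.
#' @return An `ellipse_phantom`.
#' @examples
#' p <- generate_random_phantom(7, grid_size = 128)
#' nrow(p$ellipses)
#' @export
generate_random_phantom <- function(seed, n_ellipses_min = 10,
                                    n_ellipses_max = 40, grid_size = 512) {
  if (n_ellipses_min < 1 || n_ellipses_max < n_ellipses_min)
    stop("need 1 <= n_ellipses_min <= n_ellipses_max")
  if (grid_size < 16) stop("grid_size must be >= 16")
  R <- grid_size / 2
  withr::with_seed(as.integer(seed), {
    k <- sample(seq(n_ellipses_min, n_ellipses_max), 1)
    a <- stats::runif(k, grid_size / 32, grid_size / 6)
    b <- stats::runif(k, grid_size / 32, grid_size / 6)
    rmax <- pmax(a, b)
    rad <- (R - rmax) * sqrt(stats::runif(k))
    ang <- stats::runif(k, 0, 2 * pi)
    ellipses <- data.frame(cx = rad * cos(ang), cy = rad * sin(ang),
                           a = a, b = b,
                           theta = stats::runif(k, 0, pi),
                           mu = 1 - stats::runif(k))  # uniform on (0, 1]
  })
  ellipse_phantom(ellipses, grid_size)
}

#' Stream of seeded phantoms
#'
#' Derives one sub-seed per phantom from a single top-level seed, so
#' arbitrarily large reproducible datasets can be generated (and re-generated
#' item by item).
#'
#' @param seed Top-level integer seed.
#' @param n Number of phantoms.
#' @param ... Passed to [generate_random_phantom()].
#' @return List of `ellipse_phantom` objects; each carries its sub-seed as
#'   attribute `"seed"` and an `"id"` attribute `phantom_<i>`.
#' @export
phantom_dataset <- function(seed, n, ...) {
  subseeds <- withr::with_seed(as.integer(seed),
                               sample.int(.Machine$integer.max, n))
  lapply(seq_len(n), function(i) {
    p <- generate_random_phantom(subseeds[i], ...)
    attr(p, "seed") <- subseeds[i]
    attr(p, "id") <- sprintf("phantom_%03d", i)
    p
  })
}

#' Rasterize a phantom
#'
#' Realizes the phantom as a pixel image: each pixel takes the sum of the
#' attenuations of the ellipses containing its centre (no anti-aliasing).
#'
#' @param phantom An `ellipse_phantom`.
#' @return A `ct_image` of side `grid_size`.
#' @export
rasterize <- function(phantom) {
  n <- phantom$grid_size
  if (nrow(phantom$ellipses) == 0) return(ct_image(matrix(0, n, n)))
  ct_image(cpp_rasterize(as.matrix(phantom$ellipses), n))
}

#' Analytic fan-beam projection of an ellipse phantom
#'
#' Exact line integrals: each sinogram entry is the sum over ellipses of
#' attenuation times the chord length of the source-to-channel ray through
#' the ellipse, in closed form (no raster involved).
#'
#' @param phantom An `ellipse_phantom` inside the geometry's field of view.
#' @param geometry A `fan_geometry`.
#' @return A complete-tagged `sinogram`.
#' @export
analytic_fan_projection <- function(phantom, geometry) {
  e <- phantom$ellipses
  if (nrow(e) > 0) {
    D <- geometry$source_distance
    half <- (geometry$n_channels - 1) / 2 * geometry$channel_spacing
    re <- sqrt(e$cx^2 + e$cy^2) + pmax(e$a, e$b)
    if (any(re >= D))
      stop("ellipse ", which.max(re), " reaches the source orbit")
    tangent <- D * re / sqrt(D^2 - re^2)
    if (any(tangent > half))
      stop("ellipse ", which.max(tangent),
           " exceeds the detector field of view")
    vals <- cpp_analytic_fan(as.matrix(e), view_angles(geometry), D,
                             geometry$n_channels, geometry$channel_spacing)
  } else {
    vals <- matrix(0, geometry$n_views, geometry$n_channels)
  }
  sinogram(vals, geometry)
}

#' Write / read phantom parameter files (JSON)
#'
#' @param phantom An `ellipse_phantom`.
#' @param path File path.
#' @return `read_phantom` returns an `ellipse_phantom`; `write_phantom`
#'   returns `path` invisibly.
#' @export
write_phantom <- function(phantom, path) {
  jsonlite::write_json(list(grid_size = phantom$grid_size,
                            ellipses = phantom$ellipses),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ell <- as.data.frame(obj$ellipses)
  ellipse_phantom(ell, obj$grid_size)
}
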