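#' Equi-spaced fan-beam scan geometry
#'
#' Describes a 2-D fan-beam acquisition with a point source rotating on a
#' circle of radius `source_distance` around the image centre and a virtual
#' flat detector through the rotation centre. Channels are equally spaced on
#' the detector and centred on the central ray; view angles are
#' `k * angular_range / n_views` for `k = 0, ..., n_views - 1`
#' (endpoint-exclusive, so 720 views over a full turn step by 0.5 degrees).
#'
#' Coordinates: pixel (0, 0) at the top-left, x rightward, y downward,
#' rotation centre at the image centre, angles counter-clockwise in that
#' frame. At angle `phi` the source sits at `D * (cos phi, sin phi)`.
#'
#' @param source_distance Source-to-rotation-centre distance, in pixels.
#' @param n_views Number of views over `angular_range`.
#' @param angular_range Total angular range in radians (default full turn).
#' @param n_channels Number of detector channels (odd, symmetric detector).
#' @param channel_spacing Channel pitch in pixels on the virtual detector.
#' @return An object of class `fan_geometry`.
#' @examples
#' g <- fan_geometry()            # the full-size 720 x 731 profile
#' g$n_views
#' @export
fan_geometry <- function(source_distance = 2700, n_views = 720,
                         angular_range = 2 * pi, n_channels = 731,
                         channel_spacing = 1) {
  if (n_views < 1) stop("n_views must be >= 1")
  if (n_channels < 3 || n_channels %% 2 == 0)
    stop("n_channels must be odd and >= 3")
  if (source_distance <= 0 || channel_spacing <= 0 || angular_range <= 0)
    stop("source_distance, channel_spacing and angular_range must be positive")
  structure(list(source_distance = source_distance,
                 n_views = as.integer(n_views),
                 angular_range = angular_range,
                 n_channels = as.integer(n_channels),
                 channel_spacing = channel_spacing),
            class = "fan_geometry")
}

#' Scaled-down geometry for a given phantom grid
#'
#' Derives a geometry proportional to the full-size profile (512-pixel grid,
#' source distance 2700, 720 views, 731 channels): the source distance and
#' view count scale with the grid, and the channel count is the smallest odd
#' number whose detector half-width covers the fan-projected circumscribed
#' circle, `2 * ceil(D * Rc / sqrt(D^2 - Rc^2)) + 1` with
#' `Rc = (grid_size/2) * sqrt(2)`. A 512 grid keeps the canonical 731
#' channels; a 128 grid yields 180 views and 185 channels.
#'
#' @param grid_size Phantom/reconstruction grid side, in pixels.
#' @param n_views Number of views (default scales the 720-view full scan).
#' @return A `fan_geometry`.
#' @export
scaled_geometry <- function(grid_size, n_views = round(720 * grid_size / 512)) {
  D <- 2700 * grid_size / 512
  if (grid_size == 512) {
    nch <- 731L
  } else {
    rc <- (grid_size / 2) * sqrt(2)
    nch <- 2L * as.integer(ceiling(D * rc / sqrt(D^2 - rc^2))) + 1L
  }
  fan_geometry(source_distance = D, n_views = n_views, n_channels = nch)
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf("fan_geometry: D = %g px, %d views over %.1f deg, %d channels (pitch %g px)\n",
              x$source_distance, x$n_views, x$angular_range * 180 / pi,
              x$n_channels, x$channel_spacing))
  invisible(x)
}

#' View angles of a geometry
#' @param geometry A `fan_geometry`.
#' @return Numeric vector of `n_views` angles in radians.
#' @export
view_angles <- function(geometry) {
  (seq_len(geometry$n_views) - 1) * geometry$angular_range / geometry$n_views
}

# detector channel offsets (pixels, centred on the central ray)
channel_offsets <- function(geometry) {
  (seq_len(geometry$n_channels) - 1 - (geometry$n_channels - 1) / 2) *
    geometry$channel_spacing
}

# check that geometry can see the full circumscribed circle of an n-pixel grid
check_coverage <- function(geometry, grid_size) {
  rc <- (grid_size / 2) * sqrt(2)
  if (geometry$source_distance <= rc)
    stop("source_distance must exceed the circumscribed support radius ",
         sprintf("(%.1f <= %.1f)", geometry$source_distance, rc))
  half <- (geometry$n_channels - 1) / 2 * geometry$channel_spacing
  if (half < (grid_size / 2) * sqrt(2) - geometry$channel_spacing)
    stop("detector half-width does not cover the reconstruction support")
  invisible(TRUE)
}

#' Sinogram container
#'
#' A `views x channels` grid of fan-beam line integrals together with the
#' angles actually measured, the acquisition geometry and a completeness tag.
#'
#' @param values Numeric matrix, one row per measured view.
#' @param geometry A `fan_geometry`.
#' @param angles View angles (radians) of the rows; defaults to the full scan.
#' @param kind One of `"complete"`, `"sparse"`, `"limited"`, `"corrupted"`,
#'   `"restored"`.
#' @param factor,max_angle Degradation parameters recorded on the tag.
#' @param view_index 1-based positions of the rows within the full scan.
#' @param mask Logical vector over the full scan marking measured views.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, angles = view_angles(geometry),
                     kind = "complete", factor = NULL, max_angle = NULL,
                     view_index = seq_len(nrow(values)), mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(angles))
    stop("row count must equal the number of view angles")
  if (ncol(values) != geometry$n_channels)
    stop("column count must equal geometry$n_channels")
  kind <- match.arg(kind,
                    c("complete", "sparse", "limited", "corrupted", "restored"))
  if (kind %in% c("complete", "corrupted", "restored") &&
      nrow(values) != geometry$n_views)
    stop(sprintf("a %s sinogram must have geometry$n_views rows", kind))
  structure(list(values = values, view_angles = angles, geometry = geometry,
                 kind = kind, factor = factor, max_angle = max_angle,
                 view_index = as.integer(view_index), mask = mask),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  extra <- switch(x$kind,
                  sparse = sprintf(" (factor %d)", x$factor),
                  limited = sprintf(" (max %.1f deg)", x$max_angle * 180 / pi),
                  "")
  cat(sprintf("sinogram: %d x %d, %s%s\n", nrow(x$values), ncol(x$values),
              x$kind, extra))
  invisible(x)
}

#' CT image container
#'
#' @param values Square numeric matrix of attenuation values.
#' @param pixel_size Pixel size (1 by convention).
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(values, pixel_size = 1) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("CT image must be square")
  if (!all(is.finite(values))) stop("CT image values must be finite")
  structure(list(values = values, pixel_size = pixel_size),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("ct_image: %d x %d, range [%.3g, %.3g]\n", nrow(x$values),
              ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Raster fan-beam forward projection
#'
#' Ray-driven line integrals of a raster image: each source-to-channel ray is
#' sampled every `step` pixels with bilinear interpolation (Joseph-style),
#' over the segment crossing the circumscribed support circle.
#'
#' @param image A `ct_image` or square numeric matrix.
#' @param geometry A `fan_geometry` covering the image support.
#' @param step Sampling step along each ray, in pixels.
#' @return A complete-tagged `sinogram`.
#' @export
forward_project <- function(image, geometry, step = 0.5) {
  if (inherits(image, "ct_image")) image <- image$values
  image <- as.matrix(image)
  if (nrow(image) != ncol(image)) stop("image must be square")
  check_coverage(geometry, nrow(image))
  vals <- cpp_forward_project(image, view_angles(geometry),
                              geometry$source_distance, geometry$n_channels,
                              geometry$channel_spacing, step)
  sinogram(vals, geometry)
}

# exact adjoint of forward_project (unfiltered transpose); internal,
# used for adjoint-consistency checks
backsmear <- function(sino, out_size, step = 0.5) {
  g <- sino$geometry
  cpp_backsmear(sino$values, sino$view_angles, g$source_distance,
                g$channel_spacing, out_size, step)
}

#' Sparse-view subsampling
#'
#' Keeps every `factor`-th view starting from the first, emulating a
#' sparse-view scan: a 720-view scan at factor 8 keeps 90 views, at factor
#' 12 keeps 60.
#'
#' @param sino A complete `sinogram`.
#' @param factor Positive integer dividing the number of views.
#' @return A `sinogram` tagged `sparse`.
#' @export
subsample_views <- function(sino, factor) {
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  nv <- nrow(sino$values)
  if (nv %% factor != 0) stop("factor must divide the number of views")
  if (factor == 1) return(sino)
  keep <- seq(1, nv, by = factor)
  mask <- rep(FALSE, sino$geometry$n_views)
  mask[sino$view_index[keep]] <- TRUE
  sinogram(sino$values[keep, , drop = FALSE], sino$geometry,
           angles = sino$view_angles[keep], kind = "sparse",
           factor = as.integer(factor), view_index = sino$view_index[keep],
           mask = mask)
}

#' Limited-angle truncation
#'
#' Keeps the views with angle in `[0, max_angle)`: 720 views over a full
#' turn limited to 120 degrees keep 240 views, to 90 degrees keep 180.
#'
#' @param sino A complete `sinogram`.
#' @param max_angle Upper angular limit in radians,
#'   `0 < max_angle <= angular_range`.
#' @return A `sinogram` tagged `limited` (or the input when the limit spans
#'   the full range).
#' @export
limit_angle <- function(sino, max_angle) {
  rng <- sino$geometry$angular_range
  if (max_angle <= 0 || max_angle > rng + 1e-12)
    stop("max_angle must lie in (0, angular_range]")
  if (max_angle >= rng) return(sino)
  keep <- which(sino$view_angles < max_angle - 1e-12)
  mask <- rep(FALSE, sino$geometry$n_views)
  mask[sino$view_index[keep]] <- TRUE
  sinogram(sino$values[keep, , drop = FALSE], sino$geometry,
           angles = sino$view_angles[keep], kind = "limited",
           max_angle = max_angle, view_index = sino$view_index[keep],
           mask = mask)
}

#' Zero-fill an incomplete sinogram to the full scan grid
#'
#' Copies the measured rows into their full-scan positions and fills the
#' missing views with zeros, so incomplete data can enter the fixed-size FBP
#' and network input. The measured-view mask is recorded on the result.
#'
#' @param sino A `sinogram` (sparse or limited; complete input is returned
#'   unchanged).
#' @return A full-size `sinogram` with a `mask` attribute of measured views.
#' @export
embed_incomplete <- function(sino) {
  if (sino$kind == "complete") return(sino)
  if (!sino$kind %in% c("sparse", "limited"))
    stop("embed_incomplete expects a sparse, limited or complete sinogram")
  g <- sino$geometry
  full <- matrix(0, g$n_views, g$n_channels)
  full[sino$view_index, ] <- sino$values
  mask <- rep(FALSE, g$n_views)
  mask[sino$view_index] <- TRUE
  out <- sinogram(full, g, kind = sino$kind, factor = sino$factor,
                  max_angle = sino$max_angle, angles = view_angles(g),
                  view_index = seq_len(g$n_views), mask = mask)
  out
}
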