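#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10( MAX(G)^2 / MSE )` in dB, with `MSE` the mean squared
#' error between ground truth `G` and test image `K` and `MAX(G)` the
#' per-image maximum of the ground truth. Identical images give `Inf`.
#' Image-domain comparisons are conventionally restricted to the
#' reconstruction support circle via `mask`.
#'
#' @param ground_truth,test Numeric grids of identical shape (`ct_image`s
#'   accepted); the ground truth must not be all zero.
#' @param mask Optional logical grid selecting the pixels entering the MSE.
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @examples
#' psnr(matrix(1, 4, 4), matrix(0.5, 4, 4))   # 6.0206 dB
#' @export
psnr <- function(ground_truth, test, mask = NULL) {
  g <- if (inherits(ground_truth, "ct_image")) ground_truth$values else ground_truth
  k <- if (inherits(test, "ct_image")) test$values else test
  if (!identical(dim(g), dim(k))) stop("shape mismatch")
  if (!is.null(mask)) { g <- g[mask]; k <- k[mask] }
  if (all(g == 0)) stop("ground truth is all zero")
  mse <- mean((g - k)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(g)^2 / mse)
}

#' Average PSNR over an ensemble
#'
#' @param values Non-empty numeric vector of finite PSNR values (dB).
#' @return Their arithmetic mean.
#' @export
apsnr <- function(values) {
  if (length(values) == 0) stop("empty PSNR list")
  if (!all(is.finite(values))) stop("PSNR values must be finite")
  mean(values)
}

# degrade a complete sinogram according to a condition spec
degrade <- function(complete, condition) {
  if (condition$kind == "sparse") subsample_views(complete, condition$factor)
  else if (condition$kind == "limited") limit_angle(complete, condition$max_angle)
  else stop("unknown degradation kind: ", condition$kind)
}

condition_label <- function(condition) {
  if (!is.null(condition$name)) return(condition$name)
  if (condition$kind == "sparse") sprintf("sparse_%d", condition$factor)
  else sprintf("limited_%.0f", condition$max_angle * 180 / pi)
}

#' Per-condition quality report
#'
#' Evaluates trained networks on a held-out phantom set and reports, per
#' degradation condition, the PSNR of four stages: the corrupted sinogram
#' and the restored sinogram (both against the complete sinogram), and the
#' direct-FBP image and the network-restored (DLFBP) image (both against the
#' ground-truth phantom raster, inside the support circle). `apsnr` is the
#' arithmetic mean of the per-item PSNR values.
#'
#' @param test_phantoms List of `ellipse_phantom`s (the held-out set).
#' @param nets Named list of trained `sino_unet`s, one per condition label.
#' @param geometry A `fan_geometry`.
#' @param conditions List of condition specs, each
#'   `list(kind = "sparse", factor = )` or
#'   `list(kind = "limited", max_angle = )`, optionally with `name`.
#' @param out_size Reconstruction side (defaults to the phantom grid).
#' @param train_ids Optional character vector of training-set identifiers;
#'   an overlap with the test identifiers is an error.
#' @return A data frame (class `metrics_report`) with one row per
#'   (condition, stage); per-item PSNR vectors are kept in the
#'   `"psnr_values"` attribute.
#' @export
evaluate_suite <- function(test_phantoms, nets, geometry, conditions,
                           out_size = test_phantoms[[1]]$grid_size,
                           train_ids = NULL) {
  ids <- vapply(test_phantoms, function(p) {
    id <- attr(p, "id"); if (is.null(id)) NA_character_ else id
  }, character(1))
  if (!is.null(train_ids) && any(stats::na.omit(ids) %in% train_ids))
    stop("train/test overlap: ",
         paste(intersect(ids, train_ids), collapse = ", "))
  mask <- support_mask(out_size)
  stages <- c("corrupted_sinogram", "restored_sinogram",
              "fbp_image", "dlfbp_image")
  rows <- list(); values <- list()
  for (cond in conditions) {
    lab <- condition_label(cond)
    net <- nets[[lab]]
    if (is.null(net)) stop("no trained network for condition ", lab)
    ps <- matrix(NA_real_, length(test_phantoms), length(stages),
                 dimnames = list(NULL, stages))
    for (j in seq_along(test_phantoms)) {
      p <- test_phantoms[[j]]
      truth <- rasterize(p)$values
      complete <- analytic_fan_projection(p, geometry)
      incomplete <- degrade(complete, cond)
      corrupted <- make_corrupted(incomplete, geometry, out_size)
      inf <- dlfbp_infer(incomplete, net, geometry, out_size,
                         corrupted = corrupted)
      fbp_img <- fbp_reconstruct(embed_incomplete(incomplete), geometry,
                                 out_size)
      ps[j, ] <- c(psnr(complete$values, corrupted$values),
                   psnr(complete$values, inf$restored$values),
                   psnr(truth, fbp_img$values, mask),
                   psnr(truth, inf$image$values, mask))
    }
    for (s in stages) {
      rows[[length(rows) + 1]] <-
        data.frame(condition = lab, stage = s, n = nrow(ps),
                   apsnr = apsnr(ps[, s]))
      values[[paste(lab, s, sep = ".")]] <- ps[, s]
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "psnr_values") <- values
  class(report) <- c("metrics_report", class(report))
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
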