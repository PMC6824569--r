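#' Training configuration
#'
#' Bundles the optimisation hyper-parameters of the framework: Nadam with
#' its canonical moment constants, batch size 1 (the published operating
#' regime), an initial learning rate of 1e-4 decayed exponentially by a
#' factor `decay_rate^int(step / decay_steps)` where the global step is the
#' outer-iteration (epoch) index, and 50 outer iterations by default -- so
#' the schedule traverses 1e-4, 1e-5, 1e-6 at epochs 0, 20, 40.
#'
#' @param initial_learning_rate Initial learning rate.
#' @param decay_rate Multiplicative decay factor per schedule stage.
#' @param decay_steps Epochs per schedule stage.
#' @param outer_iterations Number of epochs (full passes over the pairs).
#' @param batch_size Samples per update (1 reproduces the reference regime).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param beta1,beta2,epsilon Nadam moment constants.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_learning_rate = 1e-4, decay_rate = 0.1,
                         decay_steps = 20, outer_iterations = 50,
                         batch_size = 1, seed = 1,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(initial_learning_rate > 0, decay_rate > 0, decay_steps >= 1,
            outer_iterations >= 1, batch_size >= 1)
  structure(list(initial_learning_rate = initial_learning_rate,
                 decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 outer_iterations = as.integer(outer_iterations),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "train_config")
}

#' Exponentially decayed learning rate
#'
#' `initial_rate * decay_rate ^ int(global_step / decay_steps)` with integer
#' division; non-increasing in `global_step`.
#'
#' @param config A `train_config`.
#' @param global_step Non-negative integer step (epoch index, 0-based).
#' @return The decayed learning rate.
#' @examples
#' cfg <- train_config()
#' decayed_learning_rate(cfg, 0)    # 1e-4
#' decayed_learning_rate(cfg, 20)   # 1e-5
#' @export
decayed_learning_rate <- function(config, global_step) {
  if (global_step < 0) stop("global_step must be >= 0")
  config$initial_learning_rate *
    config$decay_rate^(global_step %/% config$decay_steps)
}

#' Mean squared error loss
#'
#' `E = 1/(2m) * sum((Y - Yhat)^2)` with the sum over all grid entries of
#' the batch and `m` the number of samples in the batch.
#'
#' @param predicted,target `normalized_grid`s (or plain grids) of equal
#'   shape.
#' @param m Batch size.
#' @return Non-negative scalar loss.
#' @export
mse_loss <- function(predicted, target, m = 1) {
  p <- if (inherits(predicted, "normalized_grid")) predicted$values else predicted
  y <- if (inherits(target, "normalized_grid")) target$values else target
  if (!identical(dim(p), dim(y)) || length(p) != length(y))
    stop("shape mismatch between predicted and target")
  sum((y - p)^2) / (2 * m)
}

#' Corrupted sinogram of incomplete data
#'
#' The network's input domain: zero-fill the incomplete sinogram to the full
#' scan grid, reconstruct with FBP, and forward-project the initial image
#' back to a complete-size sinogram. The result carries the streak/shadow
#' structure of the incomplete acquisition, spread over all views.
#'
#' @param incomplete A `sinogram` tagged sparse or limited (complete input
#'   round-trips through the same chain).
#' @param geometry A `fan_geometry`.
#' @param out_size Side of the intermediate reconstruction (defaults to the
#'   largest grid the geometry covers, `floor(2 * half_width / sqrt(2))`).
#' @return A `sinogram` tagged `corrupted`.
#' @export
make_corrupted <- function(incomplete, geometry = incomplete$geometry,
                           out_size = NULL) {
  if (is.null(out_size)) {
    half <- (geometry$n_channels - 1) / 2 * geometry$channel_spacing
    out_size <- floor(2 * half / sqrt(2))
  }
  emb <- embed_incomplete(incomplete)
  img <- fbp_reconstruct(emb, geometry, out_size)
  proj <- forward_project(img, geometry)
  sinogram(proj$values, geometry, kind = "corrupted")
}

#' Training pair
#'
#' One supervised example: the incomplete sinogram, its complete
#' counterpart, and the derived corrupted sinogram that the network sees.
#'
#' @param incomplete A sparse or limited `sinogram`.
#' @param complete The complete `sinogram` of the same object.
#' @param out_size Intermediate reconstruction size for [make_corrupted()].
#' @return An object of class `training_pair`.
#' @export
training_pair <- function(incomplete, complete, out_size = NULL) {
  if (!identical(dim(complete$values),
                 c(complete$geometry$n_views, complete$geometry$n_channels)))
    stop("complete sinogram must be full-size")
  corrupted <- make_corrupted(incomplete, complete$geometry, out_size)
  structure(list(incomplete = incomplete, complete = complete,
                 corrupted = corrupted),
            class = "training_pair")
}

# --- Nadam ------------------------------------------------------------------
# Canonical Nadam (Adam with Nesterov momentum):
#   m <- b1 m + (1-b1) g ;  v <- b2 v + (1-b2) g^2
#   theta <- theta - lr * (b1 m/(1-b1^t) + (1-b1) g/(1-b1^t)) / (sqrt(v/(1-b2^t)) + eps)
nadam_step <- function(theta, g, state, lr, b1, b2, eps, t) {
  if (is.null(state)) state <- list(m = theta * 0, v = theta * 0)
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  upd <- lr * (b1 * mhat + (1 - b1) * g / (1 - b1^t)) / (sqrt(vhat) + eps)
  list(theta = theta - upd, state = state)
}

#' Train the sinogram restoration network
#'
#' Runs the training mode: for each outer iteration every pair is visited
#' once (order shuffled deterministically under the run seed); for each pair
#' the corrupted and complete sinograms are normalized, the network forward
#' pass produces the restored estimate, the mean-squared-error loss is
#' back-propagated, and every parameter is updated with Nadam at the epoch's
#' decayed learning rate.
#'
#' @param pairs List of `training_pair`s (at least one).
#' @param net A `sino_unet`; initialized with `config$seed` if its
#'   parameters are unset.
#' @param config A `train_config`.
#' @param verbose Print per-epoch loss lines.
#' @param epoch_offset Number of epochs already trained (for resuming from
#'   a checkpoint): the decayed learning-rate schedule continues from this
#'   global-step position and the history's epoch column follows on.
#'   Optimizer moments restart at zero on resume.
#' @return List with elements `net` (trained network) and `history` (data
#'   frame of epoch, mean loss and learning rate).
#' @export
train <- function(pairs, net, config = train_config(), verbose = FALSE,
                  epoch_offset = 0L) {
  if (length(pairs) < 1) stop("need at least one training pair")
  if (is.null(net$params)) net <- initialize_parameters(net, config$seed)
  opt <- vector("list", length(net$nodes))
  t_step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        learning_rate = numeric(0))
  norm_cache <- lapply(pairs, function(pr) {
    list(x = normalize_grid(pr$corrupted$values),
         y = normalize_grid(pr$complete$values))
  })
  for (epoch in epoch_offset + seq_len(config$outer_iterations)) {
    lr <- decayed_learning_rate(config, epoch - 1L)
    order <- withr::with_seed(config$seed + epoch, sample(length(pairs)))
    losses <- numeric(length(pairs))
    for (k in seq_along(order)) {
      pr <- norm_cache[[order[k]]]
      fw <- unet_forward(net, pr$x$values, train = TRUE)
      loss <- mse_loss(fw$out, pr$y$values, m = config$batch_size)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, pair %d", epoch, order[k]))
      losses[k] <- loss
      dY <- (fw$out - pr$y$values) / config$batch_size
      pg <- unet_backward(net, fw, dY)
      t_step <- t_step + 1L
      for (i in seq_along(pg)) {
        if (is.null(pg[[i]])) next
        for (nm in names(pg[[i]])) {
          res <- nadam_step(net$params[[i]][[nm]], pg[[i]][[nm]],
                            opt[[i]][[nm]], lr, config$beta1, config$beta2,
                            config$epsilon, t_step)
          net$params[[i]][[nm]] <- res$theta
          if (is.null(opt[[i]])) opt[[i]] <- list()
          opt[[i]][[nm]] <- res$state
        }
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses),
                                learning_rate = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.6g  lr %.2g", epoch, mean(losses), lr))
  }
  list(net = net, history = history)
}

#' End-to-end inference (working mode)
#'
#' Feeds an incomplete sinogram through the trained framework: build the
#' corrupted sinogram (zero-fill, FBP, re-project), normalize it, run the
#' network, invert the normalization with the corrupted sinogram's own
#' statistics (the ones available at inference time), and reconstruct the
#' final CT image from the restored complete sinogram with FBP.
#'
#' @param incomplete A sparse or limited `sinogram`.
#' @param net A trained `sino_unet`.
#' @param geometry A `fan_geometry`.
#' @param out_size Side of the reconstructed image.
#' @param corrupted Optionally a precomputed corrupted sinogram (skips the
#'   initial FBP + re-projection).
#' @return List with `image` (a `ct_image`), `restored` and `corrupted`
#'   (`sinogram`s).
#' @export
dlfbp_infer <- function(incomplete, net, geometry = incomplete$geometry,
                        out_size, corrupted = NULL) {
  if (is.null(net$params)) stop("network is not trained")
  if (is.null(corrupted))
    corrupted <- make_corrupted(incomplete, geometry)
  xn <- normalize_grid(corrupted$values)
  yn <- forward_pass(net, xn)
  restored <- sinogram(denormalize_grid(yn), geometry, kind = "restored")
  image <- fbp_reconstruct(restored, geometry, out_size)
  list(image = image, restored = restored, corrupted = corrupted)
}
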