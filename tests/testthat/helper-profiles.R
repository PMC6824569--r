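# Shared scaled-down profiles and a lazy fixture cache. Heavy objects
# (trained networks, phantom ensembles) are computed once per test run and
# reused across test blocks.

# reduced test profile: 64-pixel phantoms, 96 x 93 sinograms, 8 base
# channels, depth 2 -- every architectural relation of the full-size
# configuration at a per-step cost that fits the suite's time budget
test_grid <- 64L
test_geom <- function() scaled_geometry(test_grid, n_views = 96)
test_base_channels <- 8L
test_depth <- 2L
test_epochs <- 30L

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# a small fixed 3-ellipse phantom used by several oracles
three_ellipse_phantom <- function(grid = 512L) {
  s <- grid / 512
  ellipse_phantom(data.frame(
    cx = c(0, 60, -80) * s, cy = c(0, -40, 70) * s,
    a = c(150, 50, 30) * s, b = c(120, 35, 45) * s,
    theta = c(0, 0.5, 2.0), mu = c(0.6, 0.4, 0.8)), grid)
}

# training pairs for a degradation condition at the test profile
test_pairs <- function(phantoms, cond, geom = test_geom()) {
  lapply(phantoms, function(p) {
    s <- analytic_fan_projection(p, geom)
    training_pair(fanrec:::degrade(s, cond), s, out_size = test_grid)
  })
}

train_test_net <- function(cond, pooling_mode = "strided_conv",
                           seed = 7L) {
  geom <- test_geom()
  phantoms <- cached("train_phantoms",
                     phantom_dataset(101, 20, grid_size = test_grid))
  pairs <- cached(paste0("pairs_", fanrec:::condition_label(cond)),
                  test_pairs(phantoms, cond, geom))
  net <- build_unet(c(geom$n_views, geom$n_channels), test_base_channels,
                    test_depth, pooling_mode = pooling_mode)
  train(pairs, net,
        train_config(outer_iterations = test_epochs, seed = seed))
}

eval_test_net <- function(fit, cond) {
  geom <- test_geom()
  test_ph <- cached("test_phantoms",
                    phantom_dataset(202, 20, grid_size = test_grid))
  nets <- stats::setNames(list(fit$net), fanrec:::condition_label(cond))
  evaluate_suite(test_ph, nets, geom, list(cond), out_size = test_grid)
}

report_apsnr <- function(report, stage_name) {
  report$apsnr[report$stage == stage_name]
}

# Central finite-difference check of the analytic loss gradients on a tiny
# network. A finite-difference quotient is only meaningful when both
# perturbed forward passes stay in the same smooth region, so samples whose
# perturbation flips a ReLU sign or a max-pool argmax are redrawn.
# Returns the worst relative error over `n_checks` kink-free samples
# (gradients that vanish analytically, e.g. conv biases absorbed by batch
# normalization, are compared with an absolute floor of 1e-6).
max_grad_error <- function(pooling_mode = "strided_conv", n_checks = 20,
                           sample_seed = 3, h = 1e-5) {
  net <- initialize_parameters(build_unet(c(8, 9), 2, 1, pooling_mode), 1)
  set.seed(2)
  x <- matrix(rnorm(72), 8, 9)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- matrix(rnorm(72), 8, 9)
  fw <- fanrec:::unet_forward(net, x, train = TRUE)
  pg <- fanrec:::unet_backward(net, fw, fw$out - y)
  param_nodes <- which(!vapply(pg, is.null, logical(1)))
  same_kinks <- function(fp, fm) {
    for (nd in net$nodes) {
      i <- nd$idx
      if (!nd$kind %in% c("conv", "down", "convt")) next
      if (identical(nd$act, "relu") &&
          !identical(fp$acts[[i]] > 0, fm$acts[[i]] > 0)) return(FALSE)
      if (nd$kind == "down" && nd$pool_mode == "max_pool" &&
          !identical(fp$cache[[i]]$pool$argmax, fm$cache[[i]]$pool$argmax))
        return(FALSE)
    }
    TRUE
  }
  set.seed(sample_seed)
  worst <- 0; n_done <- 0; n_tried <- 0
  while (n_done < n_checks && n_tried < 10 * n_checks) {
    n_tried <- n_tried + 1
    i <- sample(param_nodes, 1)
    nm <- sample(names(pg[[i]]), 1)
    j <- sample(length(pg[[i]][[nm]]), 1)
    tp <- net; tp$params[[i]][[nm]][j] <- tp$params[[i]][[nm]][j] + h
    tm <- net; tm$params[[i]][[nm]][j] <- tm$params[[i]][[nm]][j] - h
    fp <- fanrec:::unet_forward(tp, x, train = TRUE)
    fm <- fanrec:::unet_forward(tm, x, train = TRUE)
    if (!same_kinks(fp, fm)) next
    num <- (mse_loss(fp$out, y) - mse_loss(fm$out, y)) / (2 * h)
    ana <- pg[[i]][[nm]][j]
    err <- if (abs(num) < 1e-6 && abs(ana) < 1e-6) 0
           else abs(num - ana) / max(abs(num), abs(ana))
    worst <- max(worst, err)
    n_done <- n_done + 1
  }
  stopifnot(n_done == n_checks)
  worst
}
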