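# Distance-weighted maps, edge labels, the two losses, and the architecture
# contracts of the dual-decoder segmentation network.

test_that("distance weight map equals exp(-EDT) with the brute-force oracle", {
  lab <- array(0L, c(9, 9, 9))
  lab[3:7, 3:7, 3:7] <- 1L # 5^3 cube centred in a 9^3 grid
  lv <- label_volume(lab)
  dwm <- compute_distance_weight_map(lv, classes = 1L)[, , , 1]

  bnd <- which(shouldermorph:::boundary6(lab == 1L), arr.ind = TRUE)
  grid <- as.matrix(expand.grid(1:9, 1:9, 1:9))
  d2 <- outer(rowSums(grid^2), rowSums(bnd^2), "+") - 2 * tcrossprod(grid, bnd)
  oracle <- array(exp(-sqrt(pmax(apply(d2, 1, min), 0))), c(9, 9, 9))
  expect_equal(dwm, oracle, tolerance = 1e-10)

  expect_true(all(dwm > 0 & dwm <= 1))
  expect_true(all(dwm[bnd] == 1)) # boundary voxels: EDT = 0, weight exp(0) = 1
  # a voxel two axis-aligned steps from the boundary: weight exp(-2)
  expect_equal(dwm[5, 5, 5], exp(-2), tolerance = 1e-12)
  expect_error(compute_distance_weight_map(lv, classes = 2L), "class 2 absent")
})

test_that("edge labels are the 6-connectivity class boundaries", {
  empty <- label_volume(array(0L, c(6, 6, 6)))
  expect_true(all(as.array(extract_edge_labels(empty)) == 0L))

  iso <- array(0L, c(5, 5, 5)); iso[3, 3, 3] <- 1L
  e <- as.array(extract_edge_labels(label_volume(iso)))
  expect_identical(which(e == 1L), which(iso == 1L))

  cube <- array(0L, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- 2L
  e <- as.array(extract_edge_labels(label_volume(cube)))
  expect_identical(sum(e == 2L), 26L) # 3^3 solid cube: all but the centre
  expect_identical(e[4, 4, 4], 0L)
})

test_that("region loss follows its closed form on toy inputs", {
  # 2-voxel, 2-class toy: hand arithmetic oracle
  p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  y <- rbind(c(1, 0), c(0, 1))
  w <- matrix(1, 2, 2)
  cfg <- loss_config(alpha = 0.5, class_weights = c(1, 1), normalize = TRUE)
  dice <- c(2 * 0.8 / (1.2 + 1), 2 * 0.6 / (0.8 + 1))
  D <- mean(dice) # equal class weights
  ce <- -(log(0.8) + log(0.6)) / 2
  expect_equal(region_loss(p, y, w, cfg), 0.5 * (1 - D) + 0.5 * ce,
               tolerance = 1e-12)

  # alpha = 1: exactly 1 - class-weighted Dice
  cfg1 <- loss_config(alpha = 1, class_weights = c(1, 1))
  expect_equal(region_loss(p, y, w, cfg1), 1 - D, tolerance = 1e-12)

  # perfect prediction: loss bounded by the clipping constant
  eps <- 1e-7
  perf <- region_loss(y, y, w, loss_config(alpha = 0.5, epsilon = eps))
  expect_lt(perf, 2 * eps + 1e-9)
})

test_that("region loss properties: permutation invariance, weight scaling, monotone mixing", {
  set.seed(3)
  n <- 40
  logits <- matrix(rnorm(n * 3), n, 3)
  p <- exp(logits) / rowSums(exp(logits))
  y <- matrix(0, n, 3); y[cbind(1:n, sample(1:3, n, TRUE))] <- 1
  w <- matrix(runif(n * 3, 0.3, 1), n, 3)
  cfg <- loss_config(alpha = 0.5, class_weights = c(1, 2, 3))

  perm <- sample(n)
  expect_equal(region_loss(p, y, w, cfg),
               region_loss(p[perm, ], y[perm, ], w[perm, ], cfg),
               tolerance = 1e-12)

  # scaling all class weights by a constant scales the raw CE term
  cfg_a <- loss_config(alpha = 0, class_weights = c(1, 2, 3), normalize = FALSE)
  cfg_b <- loss_config(alpha = 0, class_weights = 5 * c(1, 2, 3), normalize = FALSE)
  expect_equal(5 * region_loss(p, y, w, cfg_a), region_loss(p, y, w, cfg_b),
               tolerance = 1e-10)

  # convex mixing toward the truth decreases the loss monotonically
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(t) {
    region_loss((1 - t) * p + t * y, y, w, cfg)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0))
})

test_that("edge loss follows its closed form and the beta = 1 reduction", {
  p <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  y <- rbind(c(1, 0), c(0, 1))
  w <- rbind(c(0.5, 1), c(1, 0.25))
  kc <- c(1, 2)
  cfg <- loss_config(beta = 0.6, class_weights = kc, normalize = TRUE)
  # forward: -sum kc w y log p / sum(kc w y)
  num_f <- -(1 * 0.5 * log(0.7) + 2 * 0.25 * log(0.8))
  den_f <- 1 * 0.5 + 2 * 0.25
  # reverse: -sum kc w (1-y) log(1-p) / sum(kc w (1-y))
  num_r <- -(2 * 1 * log(1 - 0.3) + 1 * 1 * log(1 - 0.2))
  den_r <- 2 * 1 + 1 * 1
  expect_equal(edge_loss(p, y, w, cfg),
               0.6 * num_f / den_f + 0.4 * num_r / den_r, tolerance = 1e-12)

  cfg_b1 <- loss_config(beta = 1, class_weights = kc)
  expect_equal(edge_loss(p, y, w, cfg_b1), num_f / den_f, tolerance = 1e-12)

  eps <- 1e-7
  expect_lt(edge_loss(y, y, w, loss_config(epsilon = eps)), 1e-5)
})

test_that("loss inputs are validated", {
  p <- matrix(0.5, 4, 2); y <- matrix(c(1, 0), 4, 2); w <- matrix(1, 4, 2)
  expect_error(region_loss(p[1:3, ], y, w), "shape")
  bad <- p; bad[1] <- NaN
  expect_error(region_loss(bad, y, w), "non-finite")
  expect_error(edge_loss(p, y, w[, 1, drop = FALSE]), "shape")
  expect_error(loss_config(alpha = 1.2), "alpha")
  expect_error(loss_config(class_weights = c(1, -1)), "positive")
})

test_that("architecture contracts: shapes, determinism, fusion parameters", {
  arch <- arch_config(depth = 3, base_channels = 4)
  m <- build_cel_unet(arch, seed = 1)
  cs <- generate_phantom(phantom_config(grid_shape = c(24, 24, 24),
                                        spacing = c(2, 2, 2), seed = 1))
  pred <- predict_segmentation(m, cs)
  expect_identical(dim(pred$region_probs), c(24L, 24L, 24L, 3L))
  expect_identical(dim(pred$edge_probs), c(24L, 24L, 24L, 3L))
  expect_identical(dim(as.array(pred$labels)), c(24L, 24L, 24L))
  # probabilities sum to one at every voxel
  sums <- apply(pred$region_probs, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)

  # construction determinism
  expect_identical(n_parameters(build_cel_unet(arch, seed = 9)),
                   n_parameters(build_cel_unet(arch, seed = 2)))
  expect_identical(build_cel_unet(arch, seed = 9)$params,
                   build_cel_unet(arch, seed = 9)$params)

  # removing edge->region fusion drops exactly the fusion weights
  unfused <- arch_config(depth = 3, base_channels = 4, fuse_edges = FALSE)
  expect_identical(n_parameters(build_cel_unet(arch, 1)) -
                     n_parameters(build_cel_unet(unfused, 1)),
                   as.integer(fusion_parameter_count(arch)))

  # grid not divisible by 2^depth is rejected
  bad <- voxel_volume(array(0, c(20, 24, 24)), spacing = c(2, 2, 2))
  expect_error(predict_segmentation(m, bad), "divisible")
})

test_that("training decreases the loss and respects the patience contract", {
  cases <- make_phantom_set(3, seed0 = 50)
  fit <- train_segmentation(cases[1:2], cases[3],
                            arch = arch_config(depth = 3, base_channels = 3),
                            lr = 1e-2, max_epochs = 4, patience = 10, seed = 1)
  h <- fit$history
  expect_true(all(c("epoch", "loss_region", "loss_edge", "val_loss", "val_dice")
                  %in% names(h)))
  expect_lt(h$loss_region[nrow(h)], h$loss_region[1])

  # patience = 0 stops at the first epoch whose validation loss fails to improve
  fit0 <- train_segmentation(cases[1:2], cases[3],
                             arch = arch_config(depth = 3, base_channels = 3),
                             lr = 0.5, max_epochs = 8, patience = 0, seed = 1)
  h0 <- fit0$history
  worse <- which(diff(h0$val_loss) >= -1e-8)
  if (length(worse) > 0) {
    expect_identical(nrow(h0), worse[1] + 1L)
  } else {
    expect_identical(nrow(h0), 8L)
  }

  expect_error(train_segmentation(cases[1], cases[2]), "two training cases")
  expect_error(train_segmentation(cases[1:2], list()), "validation case")
})
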