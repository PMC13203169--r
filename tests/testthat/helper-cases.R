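# Shared fixture builders (everything generated in code at test time).

# Mixed-grade phantom set; coarse 24^3 grid at 2 mm spacing unless overridden.
make_phantom_set <- function(n, seed0, grid = c(24L, 24L, 24L),
                             spacing = c(2, 2, 2), noise_sd = 0.03,
                             label_noise_p = 0) {
  lapply(seq_len(n), function(i) {
    s <- seed0 + i
    set.seed(s)
    generate_phantom(phantom_config(
      grid_shape = grid, spacing = spacing,
      os_grade = sample(0:2, 1), js_grade = sample(0:2, 1),
      hsa_grade = sample(0:1, 1),
      noise_sd = noise_sd, label_noise_p = label_noise_p, seed = s))
  })
}

# Brute-force minimal distance between boundary voxels of two masks (mm),
# independent of the package's own closest-pair search.
brute_min_surface_dist <- function(lab, cl_a, cl_b, spacing) {
  bnd <- function(mask) {
    d <- dim(mask)
    idx <- which(mask, arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(idx)), function(r) {
      v <- idx[r, ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        w <- v
        w[ax] <- w[ax] + s
        if (any(w < 1L) || any(w > d)) return(TRUE)
        if (!mask[w[1], w[2], w[3]]) return(TRUE)
      }
      FALSE
    }, logical(1))
    idx[keep, , drop = FALSE]
  }
  a <- sweep(bnd(lab == cl_a), 2, spacing, "*")
  b <- sweep(bnd(lab == cl_b), 2, spacing, "*")
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)))
}

# Mean foreground Dice of a fitted segmentation model on held-out cases.
held_out_dice <- function(fit, cases) {
  mean(vapply(cases, function(cs) {
    pred <- predict_segmentation(fit, cs)
    segmentation_metrics(pred$labels, cs$labels)$mean_dice
  }, numeric(1)))
}

# Per-task held-out accuracy of a fitted classifier.
held_out_accuracy <- function(fit, cases, crop_size_mm = 32) {
  acc <- matrix(0, length(cases), 4)
  for (i in seq_along(cases)) {
    p <- attr(predict_classifier(fit, cases[[i]], crop_size_mm), "predicted")
    cs <- cases[[i]]
    acc[i, ] <- c(p[["OS"]] == cs$os_grade, p[["JS"]] == cs$js_grade,
                  p[["HSA"]] == cs$hsa_grade, p[["IT"]] == cs$implant)
  }
  stats::setNames(colMeans(acc), c("OS", "JS", "HSA", "IT"))
}
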