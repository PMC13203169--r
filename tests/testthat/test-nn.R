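# The conv-net engine: convolution against a direct sliding-window oracle,
# and reverse-mode gradients against central finite differences.

sm <- asNamespace("shouldermorph")

test_that("3D convolution matches a direct sliding-window evaluation", {
  set.seed(1)
  d <- c(5, 4, 6)
  cin <- 2L; cout <- 3L
  X <- matrix(rnorm(prod(d) * cin), prod(d), cin)
  attr(X, "sdim") <- d
  W <- matrix(rnorm(27 * cin * cout), 27 * cin, cout)
  b <- rnorm(cout)
  tape <- sm$new_tape()
  xid <- sm$nd_input(tape, X, d)
  model <- sm$new_model("t", list())
  model$params$W <- W; model$params$b <- b
  out <- sm$nd_conv3(tape, xid, sm$nd_param(tape, model, "W"),
                     sm$nd_param(tape, model, "b"), k = 3L, stride = 1L)
  Y <- sm$nd_value(tape, out)

  Xarr <- array(X, c(d, cin))
  # oracle: explicit loop over output voxels and kernel offsets;
  # weight row layout is offset-major ((o-1)*cin + channel)
  for (probe in 1:20) {
    v <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    oc <- sample(cout, 1)
    acc <- b[oc]
    o <- 0L
    for (cz in -1:1) for (cy in -1:1) for (cx in -1:1) {
      o <- o + 1L
      p <- v + c(cx, cy, cz)
      for (cc in seq_len(cin)) {
        xval <- if (any(p < 1) || any(p > d)) 0 else Xarr[p[1], p[2], p[3], cc]
        acc <- acc + xval * W[(o - 1L) * cin + cc, oc]
      }
    }
    expect_equal(Y[v[1] + (v[2] - 1) * d[1] + (v[3] - 1) * d[1] * d[2], oc], acc,
                 tolerance = 1e-10)
  }
})

grad_check <- function(model, loss_fn, grads, n_probe = 4, eps = 1e-5, tol = 1e-4) {
  worst <- 0
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    expect_false(is.null(g), info = paste("no gradient reached", nm))
    idx <- sample(length(model$params[[nm]]), min(n_probe, length(model$params[[nm]])))
    for (i in idx) {
      p0 <- model$params[[nm]][i]
      model$params[[nm]][i] <- p0 + eps
      lp <- loss_fn(model)
      model$params[[nm]][i] <- p0 - eps
      lm <- loss_fn(model)
      model$params[[nm]][i] <- p0
      fd <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(fd - g[i]) / max(1e-6, abs(fd) + abs(g[i])))
    }
  }
  worst
}

test_that("segmentation network gradients match finite differences", {
  set.seed(7)
  arch <- arch_config(depth = 2, base_channels = 2, n_classes = 3)
  model <- build_cel_unet(arch, seed = 3)
  # nudge parameters off the rectifier kinks so the loss is smooth locally
  for (nm in names(model$params)) {
    model$params[[nm]] <- model$params[[nm]] +
      rnorm(length(model$params[[nm]]), sd = 0.05)
  }
  d <- c(4, 4, 4); n <- prod(d)
  x <- matrix(rnorm(n), n, 1); attr(x, "sdim") <- d
  y <- matrix(0, n, 3); y[cbind(1:n, sample(1:3, n, TRUE))] <- 1
  ye <- matrix(0, n, 3); ye[cbind(1:n, sample(1:3, n, TRUE))] <- 1
  dwm <- matrix(runif(n * 3, 0.2, 1), n, 3)
  lcfg <- loss_config(alpha = 0.4, beta = 0.6)
  loss_fn <- function(model) {
    fw <- sm$celunet_forward(model, x)
    region_loss(sm$nd_value(fw$tape, fw$region), y, dwm, lcfg) +
      edge_loss(sm$nd_value(fw$tape, fw$edge), ye, dwm, lcfg)
  }
  fw <- sm$celunet_forward(model, x)
  gr <- region_loss(sm$nd_value(fw$tape, fw$region), y, dwm, lcfg, grad = TRUE)
  ge <- edge_loss(sm$nd_value(fw$tape, fw$edge), ye, dwm, lcfg, grad = TRUE)
  sm$model_zero_grads(model)
  seeds <- list()
  seeds[[as.character(fw$region)]] <- gr$grad
  seeds[[as.character(fw$edge)]] <- ge$grad
  sm$tape_backward(fw$tape, model, seeds)
  expect_lt(grad_check(model, loss_fn, model$grads), 1e-4)
})

test_that("classifier gradients match finite differences", {
  set.seed(11)
  ccfg <- cls_config(blocks = 2, base_channels = 2, projection = 8)
  model <- build_arthronet(ccfg, seed = 5)
  for (nm in names(model$params)) {
    model$params[[nm]] <- model$params[[nm]] +
      rnorm(length(model$params[[nm]]), sd = 0.05)
  }
  d <- c(8, 8, 8); n <- prod(d)
  x <- matrix(rnorm(n), n, 1); attr(x, "sdim") <- d
  labels <- list(OS = 1, JS = 2, HSA = 0, IT = 1)
  specs <- ccfg$specs
  loss_fn <- function(m) {
    fw <- sm$arthronet_forward(m, x)
    multitask_loss(lapply(fw$heads, function(id) sm$nd_value(fw$tape, id)),
                   labels, specs)
  }
  fw <- sm$arthronet_forward(model, x)
  ml <- multitask_loss(lapply(fw$heads, function(id) sm$nd_value(fw$tape, id)),
                       labels, specs, grad = TRUE)
  sm$model_zero_grads(model)
  seeds <- list()
  for (k in seq_along(specs)) seeds[[as.character(fw$heads[[k]])]] <- ml$grad[[k]]
  sm$tape_backward(fw$tape, model, seeds)
  expect_lt(grad_check(model, loss_fn, model$grads), 1e-4)
})

test_that("model checkpoints round-trip with the architecture embedded", {
  model <- build_cel_unet(arch_config(depth = 2, base_channels = 2), seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  m2 <- load_model(f)
  expect_identical(m2$params, model$params)
  expect_identical(m2$cfg$depth, model$cfg$depth)
})
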