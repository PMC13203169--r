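# Minimal CPU engine for small 3D convolutional networks.
#
# Feature maps are stored as (n_voxels x channels) matrices with the spatial
# dims carried alongside; convolutions are im2col gathers followed by BLAS
# matrix products; gradients flow through a recorded tape (reverse-mode,
# one backward closure per op). Everything is deterministic given the seed
# and single-threaded BLAS.

.conv_cache <- new.env(parent = emptyenv())

# im2col geometry for a given (spatial dims, kernel, stride, pad): linear
# indices into the zero-padded volume, one column per kernel offset.
conv_geometry <- function(d, k, stride, pad) {
  key <- paste(c(d, k, stride, pad), collapse = "_")
  g <- .conv_cache[[key]]
  if (!is.null(g)) return(g)
  dp <- d + 2L * pad
  dout <- (d + 2L * pad - k) %/% stride + 1L
  if (any((d + 2L * pad - k) %% stride != 0L) && stride > 1L) {
    # allowed: floor semantics; sizes used in the package divide exactly
  }
  b1 <- (seq_len(dout[1]) - 1L) * stride
  b2 <- (seq_len(dout[2]) - 1L) * stride
  b3 <- (seq_len(dout[3]) - 1L) * stride
  B1 <- rep(b1, times = dout[2] * dout[3])
  B2 <- rep(rep(b2, each = dout[1]), times = dout[3])
  B3 <- rep(b3, each = dout[1] * dout[2])
  nout <- prod(dout)
  K <- k^3
  M <- matrix(0L, nout, K)
  col <- 0L
  for (cz in seq_len(k)) for (cy in seq_len(k)) for (cx in seq_len(k)) {
    col <- col + 1L
    M[, col] <- (B1 + cx) + (B2 + cy - 1L) * dp[1] + (B3 + cz - 1L) * dp[1] * dp[2]
  }
  # linear indices of the unpadded interior inside the padded volume
  i1 <- pad + seq_len(d[1])
  i2 <- pad + seq_len(d[2])
  i3 <- pad + seq_len(d[3])
  interior <- as.vector(outer(outer(i1, (i2 - 1L) * dp[1], "+"),
                              (i3 - 1L) * dp[1] * dp[2], "+"))
  g <- list(d = d, dp = dp, dout = dout, M = M, K = K,
            n_in = prod(d), n_pad = prod(dp), interior = interior)
  .conv_cache[[key]] <- g
  g
}

.upsample_cache <- new.env(parent = emptyenv())

upsample_geometry <- function(d_src) {
  key <- paste(d_src, collapse = "_")
  g <- .upsample_cache[[key]]
  if (!is.null(g)) return(g)
  dout <- 2L * d_src
  ix <- (seq_len(dout[1]) + 1L) %/% 2L
  iy <- (seq_len(dout[2]) + 1L) %/% 2L
  iz <- (seq_len(dout[3]) + 1L) %/% 2L
  src <- as.vector(outer(outer(ix, (iy - 1L) * d_src[1], "+"),
                         (iz - 1L) * d_src[1] * d_src[2], "+"))
  g <- list(d_src = d_src, dout = dout, src = src)
  .upsample_cache[[key]] <- g
  g
}

# ---- tape ----

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

nd_new <- function(tape, value, sdim, parents = integer(0), back = NULL,
                   pname = NULL, extra = NULL) {
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(id = id, value = value, sdim = sdim,
                           parents = parents, back = back, pname = pname,
                           extra = extra)
  id
}

nd_value <- function(tape, id) {
  force(id) # ids may be produced by expressions that append to the tape
  tape$nodes[[id]]$value
}

nd_input <- function(tape, value, sdim) nd_new(tape, value, sdim)

nd_param <- function(tape, model, name) {
  nd_new(tape, model$params[[name]], sdim = NULL, pname = name)
}

# 3D convolution, kernel k (1 or 3), optional stride; pad preserves size for
# stride 1 and halves it for stride 2 with k = 3.
nd_conv3 <- function(tape, x_id, w_id, b_id, k = 3L, stride = 1L) {
  force(x_id); force(w_id); force(b_id)
  xn <- tape$nodes[[x_id]]
  W <- nd_value(tape, w_id)
  b <- nd_value(tape, b_id)
  d <- xn$sdim
  pad <- if (k == 1L) 0L else (k - 1L) %/% 2L
  g <- conv_geometry(d, k, stride, pad)
  X <- xn$value
  cin <- ncol(X)
  if (nrow(W) != g$K * cin) stop("conv weight/input channel mismatch")
  # patch matrix in offset-major column order: column (o-1)*cin + cc
  if (g$K == 1L && stride == 1L) {
    P <- X # 1x1x1 conv, no gather needed
  } else {
    P <- matrix(0, nrow(g$M), g$K * cin)
    XP <- matrix(0, g$n_pad, cin)
    XP[g$interior, ] <- X
    for (o in seq_len(g$K)) {
      P[, ((o - 1L) * cin + 1L):(o * cin)] <- XP[g$M[, o], , drop = FALSE]
    }
  }
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  back <- function(grad, node, tape) {
    P <- node$extra$P
    g <- node$extra$g
    cin <- node$extra$cin
    W <- nd_value(tape, node$parents[2])
    dW <- crossprod(P, grad)
    db <- colSums(grad)
    dP <- grad %*% t(W)
    if (g$K == 1L && node$extra$stride == 1L) {
      dX <- dP
    } else {
      # scatter-add per offset: the voxel map is injective for fixed offset
      dXP <- matrix(0, g$n_pad, cin)
      for (o in seq_len(g$K)) {
        idx <- g$M[, o]
        dXP[idx, ] <- dXP[idx, ] + dP[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
      }
      dX <- dXP[g$interior, , drop = FALSE]
    }
    list(dX, dW, db)
  }
  nd_new(tape, Y, g$dout, parents = c(x_id, w_id, b_id), back = back,
         extra = list(P = P, g = g, cin = cin, stride = stride))
}

# leaky rectifier (slope 0.01 on the negative side): avoids dead units in
# very small networks trained with per-volume updates
nd_relu <- function(tape, x_id, slope = 0.01) {
  force(x_id)
  X <- nd_value(tape, x_id)
  pos <- X > 0
  Y <- X * (pos + slope * (!pos))
  back <- function(grad, node, tape) {
    X <- nd_value(tape, node$parents[1])
    pos <- X > 0
    list(grad * (pos + node$extra$slope * (!pos)))
  }
  nd_new(tape, Y, tape$nodes[[x_id]]$sdim, parents = x_id, back = back,
         extra = list(slope = slope))
}

nd_upsample2 <- function(tape, x_id) {
  force(x_id)
  xn <- tape$nodes[[x_id]]
  g <- upsample_geometry(xn$sdim)
  Y <- xn$value[g$src, , drop = FALSE]
  back <- function(grad, node, tape) {
    g <- node$extra$g
    dX <- rowsum(grad, group = g$src, reorder = TRUE)
    list(dX)
  }
  nd_new(tape, Y, g$dout, parents = x_id, back = back, extra = list(g = g))
}

nd_concat <- function(tape, ids) {
  force(ids)
  vals <- lapply(ids, function(i) nd_value(tape, i))
  widths <- vapply(vals, ncol, integer(1))
  Y <- do.call(cbind, vals)
  back <- function(grad, node, tape) {
    w <- node$extra$widths
    off <- cumsum(c(0L, w))
    lapply(seq_along(w), function(j) {
      grad[, (off[j] + 1L):(off[j] + w[j]), drop = FALSE]
    })
  }
  nd_new(tape, Y, tape$nodes[[ids[1]]]$sdim, parents = as.integer(ids),
         back = back, extra = list(widths = widths))
}

nd_add <- function(tape, a_id, b_id) {
  force(a_id); force(b_id)
  Y <- nd_value(tape, a_id) + nd_value(tape, b_id)
  back <- function(grad, node, tape) list(grad, grad)
  nd_new(tape, Y, tape$nodes[[a_id]]$sdim, parents = c(a_id, b_id), back = back)
}

# Row-wise softmax over channels.
nd_softmax <- function(tape, x_id) {
  force(x_id)
  X <- nd_value(tape, x_id)
  m <- X[, 1L]
  for (j in seq_len(ncol(X))[-1L]) m <- pmax(m, X[, j])
  E <- exp(X - m)
  Y <- E / rowSums(E)
  back <- function(grad, node, tape) {
    Y <- node$value
    list(Y * (grad - rowSums(grad * Y)))
  }
  nd_new(tape, Y, tape$nodes[[x_id]]$sdim, parents = x_id, back = back)
}

# Global average pooling: (n_vox x C) -> (1 x C).
nd_gap <- function(tape, x_id) {
  force(x_id)
  X <- nd_value(tape, x_id)
  Y <- matrix(colMeans(X), 1L)
  back <- function(grad, node, tape) {
    X <- nd_value(tape, node$parents[1])
    list(matrix(rep(grad / nrow(X), each = nrow(X)), nrow(X)))
  }
  nd_new(tape, Y, NULL, parents = x_id, back = back)
}

nd_dense <- function(tape, x_id, w_id, b_id) {
  force(x_id); force(w_id); force(b_id)
  X <- nd_value(tape, x_id)
  W <- nd_value(tape, w_id)
  b <- nd_value(tape, b_id)
  Y <- X %*% W + rep(b, each = nrow(X))
  back <- function(grad, node, tape) {
    X <- nd_value(tape, node$parents[1])
    W <- nd_value(tape, node$parents[2])
    list(grad %*% t(W), crossprod(X, grad), colSums(grad))
  }
  nd_new(tape, Y, NULL, parents = c(x_id, w_id, b_id), back = back)
}

# Reverse-mode sweep. `seeds` is a named list: node id (as character) ->
# gradient matrix. Accumulates parameter gradients into model$grads.
tape_backward <- function(tape, model, seeds) {
  n <- length(tape$nodes)
  grads <- vector("list", n)
  for (nm in names(seeds)) grads[[as.integer(nm)]] <- seeds[[nm]]
  for (id in n:1) {
    gr <- grads[[id]]
    if (is.null(gr)) next
    node <- tape$nodes[[id]]
    if (!is.null(node$pname)) {
      cur <- model$grads[[node$pname]]
      model$grads[[node$pname]] <- if (is.null(cur)) gr else cur + gr
    }
    if (is.null(node$back)) next
    pg <- node$back(gr, node, tape)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    grads[[id]] <- NULL # free memory early
  }
  invisible(NULL)
}

# ---- parameters and optimizer ----

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# Per-layer seed derived from the master seed and the layer name, so that
# initialisation depends only on (seed, name, shape) — in particular it is
# invariant to the order in which layers are declared.
layer_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

new_model <- function(type, cfg) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$cfg <- cfg
  m$params <- list()
  m$grads <- list()
  m
}

model_zero_grads <- function(model) {
  model$grads <- list()
  invisible(model)
}

#' Number of trainable parameters of a model
#' @param model A model built by [build_cel_unet()] or [build_arthronet()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

new_adam <- function(lr = 1e-2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     clip_norm = 1) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$clip_norm <- clip_norm
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(opt, model) {
  opt$t <- opt$t + 1L
  if (!is.null(opt$clip_norm) && is.finite(opt$clip_norm)) {
    # global gradient-norm clipping; the threshold sits well above typical
    # steady-state norms so it only catches spikes, which would otherwise
    # saturate the softmax into the clipped flat region of the losses
    gn <- sqrt(sum(vapply(model$grads, function(g) sum(g^2), numeric(1))))
    if (gn > opt$clip_norm) {
      sc <- opt$clip_norm / gn
      for (nm in names(model$grads)) model$grads[[nm]] <- model$grads[[nm]] * sc
    }
  }
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(model$grads)) {
    g <- model$grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    model$params[[nm]] <- model$params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(model)
}

model_state <- function(model) {
  list(type = model$type, cfg = model$cfg, params = model$params)
}

model_from_state <- function(state) {
  m <- new_model(state$type, state$cfg)
  m$params <- state$params
  m
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized state file with the architecture
#' configuration embedded, so `load_model()` needs no other input.
#'
#' @param model A model environment.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model_state(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model_from_state(readRDS(path))
}
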