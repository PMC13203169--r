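#' Architecture configuration for the dual-decoder segmentation network
#'
#' The network is a U-Net with one encoder and two parallel decoders: a region
#' decoder producing per-voxel class probabilities and an edge decoder
#' producing per-voxel boundary-class probabilities through a pyramidal
#' multi-scale module. The edge decoder output at every resolution level is
#' fused (concatenated) into the corresponding region decoder block, so edge
#' evidence guides the region prediction.
#'
#' @param depth Number of resolution levels (>= 2); input grid dims must be
#'   divisible by `2^depth`.
#' @param base_channels Channels at full resolution; doubled at each level.
#' @param in_channels Input image channels (1 for CT).
#' @param n_classes Segmentation classes (background, humerus, scapula).
#' @param pyramid_levels How many edge-decoder levels feed the multi-scale
#'   edge module (capped at `depth - 1`).
#' @param edge_branch Build the edge decoder at all (`FALSE` gives a plain
#'   single-decoder U-Net, the ablation baseline).
#' @param fuse_edges Fuse edge-decoder features into the region decoder.
#' @return An `arch_config` list.
#' @export
arch_config <- function(depth = 3L, base_channels = 8L, in_channels = 1L,
                        n_classes = 3L, pyramid_levels = depth - 1L,
                        edge_branch = TRUE, fuse_edges = TRUE) {
  if (depth < 2L) stop("`depth` must be at least 2")
  if (base_channels < 1L) stop("`base_channels` must be positive")
  if (!edge_branch) fuse_edges <- FALSE
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 n_edge_classes = as.integer(n_classes),
                 pyramid_levels = as.integer(min(pyramid_levels, depth - 1L)),
                 edge_branch = isTRUE(edge_branch),
                 fuse_edges = isTRUE(fuse_edges)),
            class = "arch_config")
}

celunet_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

#' Build the dual-decoder segmentation model
#'
#' Weights use He initialisation (seeded); the parameter count is a
#' deterministic function of the configuration.
#'
#' @param cfg An [arch_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A model environment usable with [train_segmentation()] and
#'   [predict_segmentation()].
#' @export
build_cel_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "arch_config"))
  model <- new_model("celunet", cfg)
  ch <- celunet_channels(cfg)
  D <- cfg$depth
  F0 <- cfg$base_channels
  add_conv <- function(name, k, cin, cout) {
    with_seed(layer_seed(seed, name), {
      model$params[[paste0(name, "_W")]] <- he_init(k^3 * cin, cout, k^3 * cin)
    })
    model$params[[paste0(name, "_b")]] <- rep(0, cout)
  }
  add_conv("enc1", 3L, cfg$in_channels, ch[1])
  for (l in 2:D) add_conv(paste0("down", l), 3L, ch[l - 1], ch[l])
  if (cfg$edge_branch) {
    for (l in (D - 1L):1L) add_conv(paste0("edconv", l), 3L, ch[l + 1] + ch[l], ch[l])
    for (l in seq_len(cfg$pyramid_levels)) add_conv(paste0("pyr", l), 1L, ch[l], F0)
    add_conv("ehead", 1L, F0, cfg$n_edge_classes)
  }
  for (l in (D - 1L):1L) {
    cin <- ch[l + 1] + ch[l] + if (cfg$fuse_edges) ch[l] else 0L
    add_conv(paste0("rconv", l), 3L, cin, ch[l])
  }
  add_conv("rhead", 1L, ch[1], cfg$n_classes)
  model
}

#' Analytic parameter count of the edge-to-region fusion connections
#'
#' The extra weights a fused region decoder carries compared to an unfused
#' one: `sum_l 27 * ch_l * ch_l` over decoder levels (no extra biases).
#'
#' @param cfg An [arch_config()].
#' @return Integer.
#' @export
fusion_parameter_count <- function(cfg) {
  ch <- as.integer(celunet_channels(cfg))
  sum(vapply(seq_len(cfg$depth - 1L), function(l) 27L * ch[l] * ch[l], integer(1)))
}

# Forward pass; returns the tape plus node ids of the two probability outputs.
celunet_forward <- function(model, x) {
  cfg <- model$cfg
  d <- attr(x, "sdim")
  if (is.null(d)) stop("input must carry spatial dims")
  if (any(d %% 2L^cfg$depth != 0L)) {
    stop(sprintf("input grid %s not divisible by 2^depth = %d",
                 paste(d, collapse = "x"), 2L^cfg$depth))
  }
  D <- cfg$depth
  tape <- new_tape()
  conv <- function(x_id, name, k = 3L, stride = 1L) {
    nd_conv3(tape, x_id,
             nd_param(tape, model, paste0(name, "_W")),
             nd_param(tape, model, paste0(name, "_b")), k = k, stride = stride)
  }
  xin <- nd_input(tape, x, d)
  enc <- vector("list", D)
  enc[[1]] <- nd_relu(tape, conv(xin, "enc1"))
  for (l in 2:D) {
    enc[[l]] <- nd_relu(tape, conv(enc[[l - 1]], paste0("down", l), stride = 2L))
  }

  edge_probs_id <- NULL
  G <- vector("list", D - 1L)
  if (cfg$edge_branch) {
    prev <- enc[[D]]
    for (l in (D - 1L):1L) {
      up <- nd_upsample2(tape, prev)
      G[[l]] <- nd_relu(tape, conv(nd_concat(tape, c(up, enc[[l]])),
                                   paste0("edconv", l)))
      prev <- G[[l]]
    }
    agg <- NULL
    for (l in seq_len(cfg$pyramid_levels)) {
      t_id <- conv(G[[l]], paste0("pyr", l), k = 1L)
      if (l > 1L) for (i in seq_len(l - 1L)) t_id <- nd_upsample2(tape, t_id)
      agg <- if (is.null(agg)) t_id else nd_add(tape, agg, t_id)
    }
    edge_probs_id <- nd_softmax(tape, conv(nd_relu(tape, agg), "ehead", k = 1L))
  }

  prev <- enc[[D]]
  for (l in (D - 1L):1L) {
    up <- nd_upsample2(tape, prev)
    parts <- c(up, enc[[l]])
    if (cfg$fuse_edges) parts <- c(parts, G[[l]])
    prev <- nd_relu(tape, conv(nd_concat(tape, parts), paste0("rconv", l)))
  }
  region_probs_id <- nd_softmax(tape, conv(prev, "rhead", k = 1L))

  list(tape = tape, region = region_probs_id, edge = edge_probs_id, sdim = d)
}

# Per-volume z-scored network input (standard CT preprocessing).
normalize_volume_input <- function(img) {
  d <- dim(img)
  v <- as.numeric(img)
  s <- stats::sd(v)
  if (s == 0) s <- 1
  x <- matrix((v - mean(v)) / s, prod(d), 1L)
  attr(x, "sdim") <- d
  x
}

# Prepared tensors for one training case.
prepare_seg_case <- function(case, n_classes = 3L) {
  img <- as.array(case$image)
  d <- dim(img)
  x <- normalize_volume_input(img)
  lab <- as.vector(as.array(case$labels))
  y <- matrix(0, prod(d), n_classes)
  for (cc in seq_len(n_classes)) y[lab == cc - 1L, cc] <- 1
  edge <- as.vector(as.array(extract_edge_labels(case$labels)))
  ye <- matrix(0, prod(d), n_classes)
  ye[, 1] <- 1 # non-edge channel
  for (cc in 2:n_classes) {
    sel <- edge == cc - 1L
    ye[sel, cc] <- 1
    ye[sel, 1] <- 0
  }
  dwm <- compute_distance_weight_map(case$labels, classes = 0:(n_classes - 1L))
  dwm <- matrix(as.numeric(dwm), prod(d), n_classes)
  list(x = x, y = y, ye = ye, dwm = dwm, d = d, lab = lab)
}

seg_case_losses <- function(model, prep, loss_cfg) {
  fw <- celunet_forward(model, prep$x)
  p_region <- nd_value(fw$tape, fw$region)
  lr <- region_loss(p_region, prep$y, prep$dwm, loss_cfg, grad = TRUE)
  out <- list(fw = fw, lr = lr$value, lr_grad = lr$grad, le = NA_real_,
              le_grad = NULL, p_region = p_region)
  if (!is.null(fw$edge)) {
    p_edge <- nd_value(fw$tape, fw$edge)
    le <- edge_loss(p_edge, prep$ye, prep$dwm, loss_cfg, grad = TRUE)
    out$le <- le$value
    out$le_grad <- le$grad
  }
  out
}

mean_foreground_dice <- function(pred_lab, true_lab, n_classes = 3L) {
  ds <- vapply(seq_len(n_classes - 1L), function(cc) {
    a <- pred_lab == cc
    b <- true_lab == cc
    s <- sum(a) + sum(b)
    if (s == 0) return(1)
    2 * sum(a & b) / s
  }, numeric(1))
  mean(ds)
}

#' Train the segmentation network on phantom cases
#'
#' Per-volume Adam updates with both losses (region always; edge when the
#' architecture has an edge branch), validation-loss early stopping, and the
#' best-validation weights restored at the end. Deterministic given `seed`.
#'
#' @param cases List of `phantom_case` training cases (>= 2).
#' @param val_cases List of validation cases (>= 1) used for early stopping.
#' @param arch An [arch_config()].
#' @param loss A [loss_config()].
#' @param lr Adam learning rate.
#' @param max_epochs Maximum epochs.
#' @param patience Early stopping patience: training stops once the validation
#'   loss has failed to improve for more than `patience` consecutive epochs
#'   (`patience = 0` stops at the first non-improving epoch).
#' @param edge_weight Weight of the edge loss when both losses are combined
#'   for the parameter update and the validation loss.
#' @param seed Integer seed (weights, shuffling).
#' @param verbose Print per-epoch progress.
#' @return A `seg_fit` list: `model` (trained state), `history` (data frame
#'   with per-epoch region loss, edge loss, validation loss and validation
#'   foreground Dice), `arch`, `loss`.
#' @export
train_segmentation <- function(cases, val_cases, arch = arch_config(),
                               loss = loss_config(), lr = 1e-2,
                               max_epochs = 30L, patience = 5L,
                               edge_weight = 1, seed = 1L, verbose = FALSE) {
  if (length(cases) < 2L) stop("need at least two training cases")
  if (length(val_cases) < 1L) stop("need at least one validation case")
  n_classes <- arch$n_classes
  prep_tr <- lapply(cases, prepare_seg_case, n_classes = n_classes)
  prep_va <- lapply(val_cases, prepare_seg_case, n_classes = n_classes)
  history <- NULL
  model <- NULL
  with_seed(seed, {
    model <- build_cel_unet(arch, seed = sample.int(2^30, 1))
    opt <- new_adam(lr)
    best_val <- Inf
    best_params <- model$params
    wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(length(prep_tr))
      lr_sum <- 0; le_sum <- 0
      for (i in ord) {
        res <- seg_case_losses(model, prep_tr[[i]], loss)
        lr_sum <- lr_sum + res$lr
        seeds <- list()
        seeds[[as.character(res$fw$region)]] <- res$lr_grad
        if (!is.null(res$le_grad)) {
          le_sum <- le_sum + res$le
          seeds[[as.character(res$fw$edge)]] <- edge_weight * res$le_grad
        }
        model_zero_grads(model)
        tape_backward(res$fw$tape, model, seeds)
        adam_step(opt, model)
      }
      # validation
      val_loss <- 0; val_dice <- 0
      for (pv in prep_va) {
        res <- seg_case_losses(model, pv, loss)
        val_loss <- val_loss + res$lr +
          if (!is.na(res$le)) edge_weight * res$le else 0
        pred_lab <- max.col(res$p_region, ties.method = "first") - 1L
        val_dice <- val_dice + mean_foreground_dice(pred_lab, pv$lab, n_classes)
      }
      val_loss <- val_loss / length(prep_va)
      val_dice <- val_dice / length(prep_va)
      history <- rbind(history, data.frame(
        epoch = epoch, loss_region = lr_sum / length(prep_tr),
        loss_edge = if (arch$edge_branch) le_sum / length(prep_tr) else NA_real_,
        val_loss = val_loss, val_dice = val_dice))
      if (verbose) {
        message(sprintf("epoch %d: Lr %.4f Le %.4f val %.4f dice %.4f",
                        epoch, lr_sum / length(prep_tr),
                        if (arch$edge_branch) le_sum / length(prep_tr) else NA,
                        val_loss, val_dice))
      }
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss
        best_params <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > patience) break
      }
    }
    model$params <- best_params
  })
  structure(list(model = model_state(model), history = history,
                 arch = arch, loss = loss),
            class = "seg_fit")
}

#' Segment a volume with a trained model
#'
#' @param fit A `seg_fit` from [train_segmentation()] (or a model environment).
#' @param image A [voxel_volume()] or `phantom_case`.
#' @return List with `labels` (a [label_volume()]), `region_probs` and
#'   `edge_probs` (4D arrays, `NULL` edge for ablation models).
#' @export
predict_segmentation <- function(fit, image) {
  model <- if (inherits(fit, "seg_fit")) model_from_state(fit$model) else fit
  if (inherits(image, "phantom_case")) image <- image$image
  img <- as.array(image)
  d <- dim(img)
  x <- normalize_volume_input(img)
  fw <- celunet_forward(model, x)
  pr <- nd_value(fw$tape, fw$region)
  lab <- array(max.col(pr, ties.method = "first") - 1L, d)
  nC <- ncol(pr)
  out <- list(labels = label_volume(lab, voxel_spacing(image)),
              region_probs = array(pr, c(d, nC)),
              edge_probs = NULL)
  if (!is.null(fw$edge)) {
    pe <- nd_value(fw$tape, fw$edge)
    out$edge_probs <- array(pe, c(d, ncol(pe)))
  }
  out
}
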