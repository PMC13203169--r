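#' Normalised inverse-frequency class weights
#'
#' For per-class counts `N_c` the weight of class `c` is
#' `(1 / N_c) / sum_i (1 / N_i)`: weights sum to 1 and smaller classes get
#' larger weights, counteracting class imbalance in the cross-entropy.
#'
#' @param counts Positive integer per-class counts.
#' @return Numeric weights summing to 1.
#' @examples
#' compute_class_weights(c(375, 125)) # c(0.25, 0.75)
#' @export
compute_class_weights <- function(counts) {
  if (any(counts <= 0)) stop("all class counts must be positive (weight undefined at 0)")
  w <- 1 / counts
  w / sum(w)
}

#' Task specification for the multi-task classifier
#'
#' The default four tasks mirror the clinical staging axes: osteophyte
#' severity (OS, 3 grades), joint-space condition (JS, 3 grades),
#' humeroscapular alignment (HSA, 2 grades) and implant type (IT, 2 classes:
#' 0 reverse, 1 anatomical).
#'
#' @param name Task name.
#' @param n_classes Number of classes.
#' @param class_weights Optional weights (summing to 1); defaults to uniform
#'   until derived from training counts.
#' @return A `task_spec` list.
#' @export
task_spec <- function(name, n_classes, class_weights = NULL) {
  if (is.null(class_weights)) class_weights <- rep(1 / n_classes, n_classes)
  if (length(class_weights) != n_classes || any(class_weights <= 0)) {
    stop("class_weights must be positive, one per class")
  }
  class_weights <- class_weights / sum(class_weights)
  structure(list(name = name, n_classes = as.integer(n_classes),
                 class_weights = class_weights), class = "task_spec")
}

#' @rdname task_spec
#' @export
default_task_specs <- function() {
  list(OS = task_spec("OS", 3L), JS = task_spec("JS", 3L),
       HSA = task_spec("HSA", 2L), IT = task_spec("IT", 2L))
}

case_label_vector <- function(case) {
  c(OS = case$os_grade, JS = case$js_grade, HSA = case$hsa_grade, IT = case$implant)
}

#' Multi-task class-weighted cross-entropy
#'
#' Sum over tasks of the class-weighted cross-entropy `-w_y log p_y`, each
#' task normalised by the total weight `sum_i w_{y_i}` of the true classes in
#' the batch, so a task's term is the weighted mean negative log-likelihood.
#'
#' @param head_probs Named list (one per task) of `n x n_classes` probability
#'   matrices.
#' @param labels Named list or matrix of integer labels in `0 .. n_classes-1`,
#'   one column/element per task.
#' @param specs List of [task_spec()]s matching `head_probs`.
#' @param epsilon Probability clipping constant.
#' @param grad If `TRUE`, also return per-task gradients w.r.t. the
#'   probabilities.
#' @return Scalar loss, or list `value`, `per_task`, `grad`.
#' @export
multitask_loss <- function(head_probs, labels, specs, epsilon = 1e-7,
                           grad = FALSE) {
  if (is.matrix(labels) || is.data.frame(labels)) {
    labels <- as.list(as.data.frame(as.matrix(labels)))
  }
  per_task <- numeric(length(specs))
  names(per_task) <- names(specs)
  grads <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    p <- head_probs[[k]]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    y <- as.integer(labels[[k]])
    if (any(y < 0 | y >= spec$n_classes)) {
      stop(sprintf("task %s: label out of range 0..%d", spec$name, spec$n_classes - 1L))
    }
    pc <- pmin(pmax(p, epsilon), 1 - epsilon)
    wy <- spec$class_weights[y + 1L]
    idx <- cbind(seq_along(y), y + 1L)
    wsum <- sum(wy)
    per_task[k] <- -sum(wy * log(pc[idx])) / wsum
    if (grad) {
      g <- matrix(0, nrow(p), ncol(p))
      g[idx] <- -wy / pc[idx] / wsum
      g[p < epsilon | p > 1 - epsilon] <- 0
      grads[[k]] <- g
    }
  }
  value <- sum(per_task)
  if (!grad) return(value)
  list(value = value, per_task = per_task, grad = grads)
}

#' Configuration and construction of the multi-task classifier
#'
#' A shared convolutional encoder (stride-2 blocks with doubling channels)
#' condenses the glenohumeral crop; global average pooling and a non-linear
#' projection map the features into a shared latent space; four parallel
#' softmax heads read out the tasks.
#'
#' @param blocks Number of stride-2 encoder blocks; the crop dims must be
#'   divisible by `2^blocks`.
#' @param base_channels Channels of the first block.
#' @param projection Width of the shared projection layer.
#' @param specs Task specifications, see [default_task_specs()].
#' @return A `cls_config` list.
#' @export
cls_config <- function(blocks = 3L, base_channels = 8L, projection = 64L,
                       specs = default_task_specs()) {
  if (blocks < 1L) stop("`blocks` must be >= 1")
  structure(list(blocks = as.integer(blocks),
                 base_channels = as.integer(base_channels),
                 projection = as.integer(projection), specs = specs),
            class = "cls_config")
}

#' @rdname cls_config
#' @param cfg A `cls_config`.
#' @param seed Integer seed for weight initialisation.
#' @export
build_arthronet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cls_config"))
  model <- new_model("arthronet", cfg)
  ch <- cfg$base_channels * 2L^(seq_len(cfg$blocks) - 1L)
  add_layer <- function(name, nrow, ncol, fan_in) {
    with_seed(layer_seed(seed, name), {
      model$params[[paste0(name, "_W")]] <- he_init(nrow, ncol, fan_in)
    })
    model$params[[paste0(name, "_b")]] <- rep(0, ncol)
  }
  cin <- 1L
  for (b in seq_len(cfg$blocks)) {
    add_layer(sprintf("conv%d", b), 27L * cin, ch[b], 27L * cin)
    cin <- ch[b]
  }
  add_layer("proj", cin, cfg$projection, cin)
  for (nm in names(cfg$specs)) {
    nc <- cfg$specs[[nm]]$n_classes
    add_layer(paste0("head_", nm), cfg$projection, nc, cfg$projection)
  }
  model
}

arthronet_forward <- function(model, x) {
  cfg <- model$cfg
  d <- attr(x, "sdim")
  if (is.null(d)) stop("input must carry spatial dims")
  if (any(d %% 2L^cfg$blocks != 0L)) {
    stop(sprintf("crop %s not divisible by 2^blocks = %d",
                 paste(d, collapse = "x"), 2L^cfg$blocks))
  }
  tape <- new_tape()
  cur <- nd_input(tape, x, d)
  for (b in seq_len(cfg$blocks)) {
    cur <- nd_relu(tape, nd_conv3(tape, cur,
                                  nd_param(tape, model, sprintf("conv%d_W", b)),
                                  nd_param(tape, model, sprintf("conv%d_b", b)),
                                  k = 3L, stride = 2L))
  }
  pooled <- nd_gap(tape, cur)
  proj <- nd_relu(tape, nd_dense(tape, pooled,
                                 nd_param(tape, model, "proj_W"),
                                 nd_param(tape, model, "proj_b")))
  heads <- lapply(names(cfg$specs), function(nm) {
    nd_softmax(tape, nd_dense(tape, proj,
                              nd_param(tape, model, paste0("head_", nm, "_W")),
                              nd_param(tape, model, paste0("head_", nm, "_b"))))
  })
  names(heads) <- names(cfg$specs)
  list(tape = tape, heads = heads)
}

#' Classify a glenohumeral crop
#'
#' @param fit A `cls_fit` from [train_classifier()] (or a model environment).
#' @param crop A [voxel_volume()], `gh_region`, or `phantom_case` (the crop is
#'   extracted automatically from a case).
#' @param crop_size_mm Crop size used when `crop` is a full case.
#' @return Named list of probability vectors, one per task, plus
#'   `attr(, "predicted")` with the arg-max labels (0-based).
#' @export
predict_classifier <- function(fit, crop, crop_size_mm = 32) {
  model <- if (inherits(fit, "cls_fit")) model_from_state(fit$model) else fit
  if (inherits(crop, "phantom_case")) {
    crop <- extract_gh_region(crop$labels, crop$image, crop_size_mm)$image_crop
  } else if (inherits(crop, "gh_region")) {
    crop <- crop$image_crop
  }
  x <- normalize_volume_input(as.array(crop))
  fw <- arthronet_forward(model, x)
  probs <- lapply(fw$heads, function(id) drop(nd_value(fw$tape, id)))
  pred <- vapply(probs, function(p) which.max(p) - 1L, integer(1))
  attr(probs, "predicted") <- pred
  probs
}

#' Train the multi-task classifier on phantom glenohumeral crops
#'
#' Class weights for every task are derived from the training label counts
#' via [compute_class_weights()]. Per-case Adam updates on the summed
#' class-weighted cross-entropy; early stopping on the validation loss (or
#' training loss when no validation cases are given).
#'
#' @param cases List of `phantom_case` training cases.
#' @param val_cases Optional list of validation cases.
#' @param cfg A [cls_config()].
#' @param crop_size_mm Glenohumeral crop size passed to [extract_gh_region()].
#' @param lr Adam learning rate.
#' @param max_epochs,patience As in [train_segmentation()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return A `cls_fit` list: `model`, `history` (per-epoch total and per-task
#'   losses), `cfg`, `crop_size_mm`.
#' @export
train_classifier <- function(cases, val_cases = NULL, cfg = cls_config(),
                             crop_size_mm = 32, lr = 1e-2, max_epochs = 60L,
                             patience = 8L, seed = 1L, verbose = FALSE) {
  if (length(cases) < 2L) stop("need at least two training cases")
  labs <- t(vapply(cases, case_label_vector, numeric(4)))
  colnames(labs) <- names(default_task_specs())
  specs <- cfg$specs
  for (nm in names(specs)) {
    counts <- tabulate(labs[, nm] + 1L, nbins = specs[[nm]]$n_classes)
    if (sum(counts > 0) < 2L) {
      stop(sprintf("task %s has a single observed class in the training data", nm))
    }
    if (any(counts == 0L)) counts[counts == 0L] <- 1L # unseen class: neutral weight
    specs[[nm]]$class_weights <- compute_class_weights(counts)
  }
  cfg$specs <- specs

  prep <- function(case) {
    crop <- extract_gh_region(case$labels, case$image, crop_size_mm)$image_crop
    list(x = normalize_volume_input(as.array(crop)), y = case_label_vector(case))
  }
  prep_tr <- lapply(cases, prep)
  prep_va <- if (!is.null(val_cases)) lapply(val_cases, prep) else NULL

  eval_loss <- function(model, plist) {
    tot <- 0
    for (pc in plist) {
      fw <- arthronet_forward(model, pc$x)
      probs <- lapply(fw$heads, function(id) nd_value(fw$tape, id))
      tot <- tot + multitask_loss(probs, as.list(pc$y), specs)
    }
    tot / length(plist)
  }

  history <- NULL
  model <- NULL
  with_seed(seed, {
    model <- build_arthronet(cfg, seed = sample.int(2^30, 1))
    opt <- new_adam(lr)
    best <- Inf
    best_params <- model$params
    wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(length(prep_tr))
      tr_loss <- 0
      task_loss <- numeric(length(specs))
      for (i in ord) {
        pc <- prep_tr[[i]]
        fw <- arthronet_forward(model, pc$x)
        probs <- lapply(fw$heads, function(id) nd_value(fw$tape, id))
        ml <- multitask_loss(probs, as.list(pc$y), specs, grad = TRUE)
        tr_loss <- tr_loss + ml$value
        task_loss <- task_loss + ml$per_task
        seeds <- list()
        for (k in seq_along(specs)) {
          seeds[[as.character(fw$heads[[k]])]] <- ml$grad[[k]]
        }
        model_zero_grads(model)
        tape_backward(fw$tape, model, seeds)
        adam_step(opt, model)
      }
      monitor <- if (!is.null(prep_va)) eval_loss(model, prep_va) else tr_loss / length(prep_tr)
      row <- data.frame(epoch = epoch, loss = tr_loss / length(prep_tr),
                        monitor = monitor)
      for (k in seq_along(specs)) {
        row[[paste0("loss_", names(specs)[k])]] <- task_loss[k] / length(prep_tr)
      }
      history <- rbind(history, row)
      if (verbose) message(sprintf("epoch %d: train %.4f monitor %.4f",
                                   epoch, tr_loss / length(prep_tr), monitor))
      if (monitor < best - 1e-8) {
        best <- monitor
        best_params <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > patience) break
      }
    }
    model$params <- best_params
  })
  structure(list(model = model_state(model), history = history, cfg = cfg,
                 crop_size_mm = crop_size_mm),
            class = "cls_fit")
}
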