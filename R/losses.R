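#' Loss configuration for the dual-decoder segmentation network
#'
#' @param alpha Balance between soft Dice and distance-weighted cross-entropy
#'   in the region loss, in `[0, 1]` (`alpha = 1` gives pure Dice).
#' @param beta Balance between forward and reverse cross-entropy in the edge
#'   loss, in `[0, 1]` (`beta = 1` gives the forward term alone).
#' @param class_weights Optional positive per-class weights `k_c`; when `NULL`
#'   they are derived from each target volume as the inverse relative class
#'   frequency, normalised to sum to 1.
#' @param epsilon Probability clipping constant for the logarithms.
#' @param normalize If `TRUE` (default) each cross-entropy sum is divided by
#'   the sum of its applied weights, making the loss magnitude independent of
#'   grid size.
#' @return A `loss_config` list.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5, class_weights = NULL,
                        epsilon = 1e-7, normalize = TRUE) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  if (beta < 0 || beta > 1) stop("`beta` must be in [0, 1]")
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stop("`class_weights` must be strictly positive")
  }
  if (epsilon <= 0 || epsilon >= 0.5) stop("`epsilon` must be in (0, 0.5)")
  structure(list(alpha = alpha, beta = beta, class_weights = class_weights,
                 epsilon = epsilon, normalize = normalize),
            class = "loss_config")
}

# Inverse relative frequency weights from a one-hot truth matrix (n x C),
# normalised to sum to 1. Classes absent from the volume get the weight they
# would have at one voxel, keeping the weights finite.
inverse_freq_weights <- function(truth) {
  counts <- pmax(colSums(truth), 1)
  w <- 1 / counts
  w / sum(w)
}

check_loss_inputs <- function(pred, truth, dwm) {
  if (!all(dim(pred) == dim(truth)) || !all(dim(pred) == dim(dwm))) {
    stop("pred, truth and dwm must share the same (voxels x classes) shape")
  }
  if (any(!is.finite(pred)) || any(!is.finite(truth)) || any(!is.finite(dwm))) {
    stop("non-finite values in loss inputs")
  }
}

# Flatten (dim..., C) arrays or matrices into (n_vox x C) matrices.
as_prob_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(as.numeric(x), prod(d[-length(d)]), d[length(d)])
}

#' Region segmentation loss (weighted soft Dice + distance-weighted CE)
#'
#' Computes `alpha * (1 - D) + (1 - alpha) * C`, where `D` is the
#' class-weighted soft Dice overlap between predicted probabilities and the
#' one-hot truth and `C` is the distance-weighted, class-weighted
#' cross-entropy `-sum_c k_c sum_i DWM_ci y_ci log(p_ci)`, by default
#' normalised by the total applied weight. A perfect prediction gives a loss
#' of (essentially) zero, bounded by the clipping constant.
#'
#' @param pred Predicted class probabilities, `(voxels x classes)` matrix or
#'   `(dims..., classes)` array; rows must sum to 1.
#' @param truth One-hot ground truth of the same shape.
#' @param dwm Distance-weighted map of the same shape (see
#'   [compute_distance_weight_map()]).
#' @param cfg A [loss_config()].
#' @param grad If `TRUE`, also return the gradient with respect to `pred`.
#' @return The scalar loss, or (with `grad = TRUE`) a list `value`, `grad`.
#' @export
region_loss <- function(pred, truth, dwm, cfg = loss_config(), grad = FALSE) {
  p <- as_prob_matrix(pred); y <- as_prob_matrix(truth); w <- as_prob_matrix(dwm)
  check_loss_inputs(p, y, w)
  eps <- cfg$epsilon
  kc <- if (is.null(cfg$class_weights)) inverse_freq_weights(y) else cfg$class_weights
  if (length(kc) != ncol(p)) stop("class_weights length must match class count")
  pc <- pmin(pmax(p, eps), 1 - eps)

  # class-weighted soft Dice (on the unclipped probabilities, so that
  # alpha = 1 reduces exactly to 1 - weighted Dice)
  S <- colSums(p * y)
  Pc <- colSums(p)
  Tc <- colSums(y)
  denom <- Pc + Tc
  dice_c <- ifelse(denom > 0, 2 * S / denom, 1)
  D <- sum(kc * dice_c) / sum(kc)

  # distance-weighted cross-entropy
  wk <- sweep(w * y, 2L, kc, "*")
  wsum <- if (cfg$normalize) sum(wk) else 1
  if (wsum == 0) wsum <- 1
  ce <- -sum(wk * log(pc)) / wsum

  value <- cfg$alpha * (1 - D) + (1 - cfg$alpha) * ce
  if (!grad) return(value)

  gd <- matrix(0, nrow(p), ncol(p))
  for (cc in seq_len(ncol(p))) {
    if (denom[cc] > 0) {
      gd[, cc] <- kc[cc] / sum(kc) * (2 * y[, cc] * denom[cc] - 2 * S[cc]) / denom[cc]^2
    }
  }
  gce <- -wk / pc / wsum
  gce[p < eps | p > 1 - eps] <- 0 # clipped region of the CE: flat
  g <- -cfg$alpha * gd + (1 - cfg$alpha) * gce
  list(value = value, grad = g)
}

#' Edge loss (forward + reverse distance-weighted cross-entropy)
#'
#' Computes `beta * C + (1 - beta) * Chat`, where `C` is the forward
#' distance-weighted cross-entropy of the edge probabilities and `Chat` the
#' reverse cross-entropy `-sum_c k_c sum_i DWM_ci (1 - y_ci) log(1 - p_ci)`,
#' which penalises false-positive edge mass; both terms use the same
#' normalisation convention as [region_loss()].
#'
#' @inheritParams region_loss
#' @param pred Predicted edge-class probabilities.
#' @param truth One-hot edge ground truth (see [extract_edge_labels()]).
#' @export
edge_loss <- function(pred, truth, dwm, cfg = loss_config(), grad = FALSE) {
  p <- as_prob_matrix(pred); y <- as_prob_matrix(truth); w <- as_prob_matrix(dwm)
  check_loss_inputs(p, y, w)
  eps <- cfg$epsilon
  kc <- if (is.null(cfg$class_weights)) inverse_freq_weights(y) else cfg$class_weights
  if (length(kc) != ncol(p)) stop("class_weights length must match class count")
  pc <- pmin(pmax(p, eps), 1 - eps)

  wk_f <- sweep(w * y, 2L, kc, "*")
  wsum_f <- if (cfg$normalize) sum(wk_f) else 1
  if (wsum_f == 0) wsum_f <- 1
  ce_f <- -sum(wk_f * log(pc)) / wsum_f

  wk_r <- sweep(w * (1 - y), 2L, kc, "*")
  wsum_r <- if (cfg$normalize) sum(wk_r) else 1
  if (wsum_r == 0) wsum_r <- 1
  ce_r <- -sum(wk_r * log(1 - pc)) / wsum_r

  value <- cfg$beta * ce_f + (1 - cfg$beta) * ce_r
  if (!grad) return(value)
  g <- cfg$beta * (-wk_f / pc / wsum_f) + (1 - cfg$beta) * (wk_r / (1 - pc) / wsum_r)
  g[p < eps | p > 1 - eps] <- 0
  list(value = value, grad = g)
}
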