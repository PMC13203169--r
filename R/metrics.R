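#' Confusion table from labels
#'
#' @param truth,pred Integer labels in `0 .. n_classes-1` (rows = truth,
#'   columns = prediction).
#' @param n_classes Number of classes.
#' @return Integer `n_classes x n_classes` matrix with per-class support
#'   (row sums) in `attr(, "support")`.
#' @export
confusion_table <- function(truth, pred, n_classes) {
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  if (length(truth) == 0L) stop("empty input")
  if (any(truth < 0 | truth >= n_classes | pred < 0 | pred >= n_classes)) {
    stop("labels out of range")
  }
  counts <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    counts[truth[i] + 1L, pred[i] + 1L] <- counts[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  attr(counts, "support") <- rowSums(counts)
  counts
}

# Per-class precision/recall/F1 from a confusion matrix, with the
# zero-division convention value = 0 (flagged).
prf_from_confusion <- function(counts) {
  tp <- diag(counts)
  colsum <- colSums(counts)
  rowsum_ <- rowSums(counts)
  precision <- ifelse(colsum > 0, tp / colsum, 0)
  recall <- ifelse(rowsum_ > 0, tp / rowsum_, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  list(precision = precision, recall = recall, f1 = f1,
       support = rowsum_, zero_division = any(colsum == 0 | rowsum_ == 0),
       accuracy = sum(tp) / sum(counts))
}

#' Classification report: accuracy, per-class F1, macro and weighted F1
#'
#' Macro F1 is the unweighted mean of per-class F1 scores (equal weight per
#' class); weighted F1 weights each class F1 by its support (number of true
#' instances). Per-class F1 is the harmonic mean of precision and recall,
#' defined as 0 when both are 0.
#'
#' @param truth,pred Integer labels in `0 .. n_classes-1`, or pass a
#'   ready-made confusion matrix as `counts`.
#' @param n_classes Number of classes.
#' @param counts Optional confusion matrix (rows = truth) replacing
#'   `truth`/`pred`.
#' @return A `metrics_report` list with `accuracy`, per-class `precision`,
#'   `recall`, `f1`, `support`, `macro_f1`, `weighted_f1`, `zero_division`.
#' @export
classification_report <- function(truth = NULL, pred = NULL, n_classes = NULL,
                                  counts = NULL) {
  if (is.null(counts)) {
    if (is.null(n_classes)) n_classes <- max(c(truth, pred)) + 1L
    counts <- confusion_table(truth, pred, n_classes)
  }
  m <- prf_from_confusion(counts)
  macro_f1 <- mean(m$f1)
  weighted_f1 <- if (sum(m$support) > 0) sum(m$support * m$f1) / sum(m$support) else 0
  structure(c(m, list(macro_f1 = macro_f1, weighted_f1 = weighted_f1,
                      counts = counts)),
            class = "metrics_report")
}

#' Voxel-overlap segmentation metrics
#'
#' Per-class Dice (`2|A&B| / (|A|+|B|)`), Jaccard (`|A&B| / |A|B|union`),
#' precision and recall over voxels, for every class present in either
#' volume; background (class 0) is excluded from the foreground summary
#' means.
#'
#' @param pred,truth [label_volume()]s on the same grid.
#' @return A `seg_metrics` list: per-class data frame `per_class`, foreground
#'   means `mean_dice`, `mean_jaccard`, plus the full [classification_report()]
#'   of the voxel labels.
#' @export
segmentation_metrics <- function(pred, truth) {
  pa <- as.array(pred); ta <- as.array(truth)
  if (!all(dim(pa) == dim(ta))) stop("prediction and truth grids differ")
  classes <- sort(union(unique(as.vector(pa)), unique(as.vector(ta))))
  rows <- lapply(classes, function(cc) {
    a <- pa == cc
    b <- ta == cc
    inter <- sum(a & b)
    uni <- sum(a | b)
    na <- sum(a); nb <- sum(b)
    dice <- if (na + nb > 0) 2 * inter / (na + nb) else 0
    jac <- if (uni > 0) inter / uni else 0
    data.frame(class = cc,
               dice = dice, jaccard = jac,
               precision = if (na > 0) inter / na else 0,
               recall = if (nb > 0) inter / nb else 0,
               support = nb)
  })
  per_class <- do.call(rbind, rows)
  fg <- per_class[per_class$class != 0, , drop = FALSE]
  n_classes <- max(classes) + 1L
  structure(list(per_class = per_class,
                 mean_dice = mean(fg$dice),
                 mean_jaccard = mean(fg$jaccard),
                 report = classification_report(as.vector(ta), as.vector(pa),
                                                n_classes = n_classes)),
            class = "seg_metrics")
}

#' Boundary-voxel recall of a predicted segmentation
#'
#' Fraction of ground-truth boundary voxels (per foreground class, then
#' averaged) that receive the correct class label in the prediction; a
#' directional measure of contour quality.
#'
#' @param pred,truth [label_volume()]s on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
boundary_recall <- function(pred, truth) {
  pa <- as.array(pred); ta <- as.array(truth)
  if (!all(dim(pa) == dim(ta))) stop("prediction and truth grids differ")
  edges <- as.array(extract_edge_labels(truth))
  classes <- setdiff(sort(unique(as.vector(edges))), 0L)
  mean(vapply(classes, function(cc) {
    sel <- edges == cc
    sum(pa[sel] == cc) / sum(sel)
  }, numeric(1)))
}

#' Paired comparison of two per-case metric distributions
#'
#' Two-sided paired Wilcoxon signed-rank test, the nonparametric choice for
#' per-case overlap scores of two models on the same test cases.
#'
#' @param a,b Numeric vectors of per-case scores, same cases in the same order.
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_metric_distributions <- function(a, b) {
  if (length(a) != length(b)) stop("paired comparison needs equal lengths")
  stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f, macro F1 %.4f, weighted F1 %.4f\n",
              x$accuracy, x$macro_f1, x$weighted_f1))
  df <- data.frame(class = seq_along(x$f1) - 1L, precision = x$precision,
                   recall = x$recall, f1 = x$f1, support = x$support)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("mean foreground Dice %.4f, Jaccard %.4f\n",
              x$mean_dice, x$mean_jaccard))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
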