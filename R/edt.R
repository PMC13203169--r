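# Exact Euclidean distance transform (squared-distance lower-envelope
# algorithm, applied separably along each axis) and the distance-weighted
# maps used by the boundary-aware losses.

# 1D squared distance transform of sampled function f at positions i*w
# (lower envelope of parabolas). Values must be finite; callers cap "no
# feature" at a large finite constant.
dt1d <- function(f, w = 1) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)      # parabola sites
  z <- numeric(n + 1L) # envelope breakpoints
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + (q * w)^2) - (f[p] + (p * w)^2)) / (2 * w * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1L] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q * w) k <- k + 1L
    d[q] <- (q * w - v[k] * w)^2 + f[v[k]]
  }
  d
}

# Squared EDT to the TRUE voxels of `feature`, in voxel units scaled by
# `spacing`. Exact for any feature set; errors if the set is empty.
edt_squared <- function(feature, spacing = c(1, 1, 1)) {
  if (!any(feature)) stop("edt_squared: feature set is empty")
  d <- dim(feature)
  cap <- 4 * sum((d * spacing)^2) # beyond any attainable squared distance
  f <- array(cap, d)
  f[feature] <- 0
  for (ax in 1:3) {
    w <- spacing[ax]
    others <- setdiff(1:3, ax)
    f <- apply(f, others, function(line) dt1d(line, w))
    f <- aperm(array(f, c(d[ax], d[others])), order(c(ax, others)))
  }
  f
}

#' Per-class boundary (edge) labels of a segmentation
#'
#' A voxel is an edge voxel of class `c` iff it belongs to `c` and at least one
#' of its 6 neighbours lies outside `c` (voxels beyond the grid count as
#' outside). Classes absent from the volume yield empty edge sets.
#'
#' @param labels A [label_volume()] (or integer array).
#' @return A [label_volume()] where edge voxels keep their class id and all
#'   other voxels are 0.
#' @examples
#' lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
#' sum(extract_edge_labels(label_volume(lab)) == 1) # the isolated voxel
#' @export
extract_edge_labels <- function(labels) {
  arr <- as.array(labels)
  out <- array(0L, dim(arr))
  for (cl in setdiff(sort(unique(as.vector(arr))), 0L)) {
    out[boundary6(arr == cl)] <- as.integer(cl)
  }
  label_volume(out, voxel_spacing(labels))
}

#' Distance-weighted map for boundary-aware losses
#'
#' For each requested class the map is `exp(-EDT)`, where EDT is the unsigned
#' Euclidean distance (in voxel units by default) from each voxel to the
#' nearest boundary voxel of that class region. Values therefore lie in
#' `(0, 1]` and equal 1 exactly on the boundary; the weighting concentrates
#' the cross-entropy losses on bone contours.
#'
#' @param labels A [label_volume()].
#' @param classes Integer classes to compute maps for; defaults to all classes
#'   present (including background, whose boundary is the union of foreground
#'   contours as seen from outside).
#' @param spacing_aware If `TRUE`, distances are measured in mm using the
#'   volume spacing; default `FALSE` measures in voxels.
#' @return A 4D array `c(dim(labels), length(classes))` with
#'   `attr(, "classes")` recording the class of each slab.
#' @export
compute_distance_weight_map <- function(labels, classes = NULL,
                                        spacing_aware = FALSE) {
  arr <- as.array(labels)
  present <- sort(unique(as.vector(arr)))
  if (is.null(classes)) classes <- present
  missing_cl <- setdiff(classes, present)
  if (length(missing_cl) > 0L) {
    stop(sprintf("class %s absent from labels; no boundary to weight",
                 paste(missing_cl, collapse = ", ")))
  }
  sp <- if (spacing_aware) voxel_spacing(labels) else c(1, 1, 1)
  out <- array(NA_real_, c(dim(arr), length(classes)))
  for (i in seq_along(classes)) {
    bnd <- boundary6(arr == classes[i])
    out[, , , i] <- exp(-sqrt(edt_squared(bnd, sp)))
  }
  attr(out, "classes") <- as.integer(classes)
  out
}
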