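# Surface reconstruction from label volumes and glenohumeral-region cropping.
#
# Iso-surfaces are extracted with a marching-tetrahedra scheme: every grid
# cell between voxel centres is split into the six Kuhn tetrahedra sharing the
# main diagonal, and each tetrahedron contributes 0-2 triangles by linear
# interpolation along its edges. The same diagonal orientation is used in
# every cell, so shared cell faces triangulate identically and the surface of
# a closed object is watertight by construction, with no ambiguous cases.

# corner offsets (x, y, z) in cell units, indexed 1..8
.tet_corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
# six tetrahedra along the 1 -> 8 diagonal (corner indices)
.tets <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
               c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))

#' Reconstruct a triangulated bone surface from a label volume
#'
#' Extracts the `iso_level` surface of the binary mask `labels == class_id`
#' after zero-padding (so closed objects give watertight meshes), with
#' vertices in physical mm coordinates (voxel index scaled by the spacing) and
#' outward-facing normals.
#'
#' @param labels A [label_volume()].
#' @param class_id Class to reconstruct (must be present).
#' @param iso_level Iso value on the binary mask, default 0.5.
#' @return A `surface_mesh` list: `vertices` (n x 3 mm), `faces` (m x 3
#'   indices), `class_id`.
#' @examples
#' lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
#' m <- reconstruct_mesh(label_volume(lab), class_id = 1)
#' mesh_volume(m) # close to 64 mm^3
#' @export
reconstruct_mesh <- function(labels, class_id = 1L, iso_level = 0.5) {
  arr <- as.array(labels)
  mask <- arr == class_id
  if (!any(mask)) stop(sprintf("class %d is empty; nothing to reconstruct", class_id))
  sp <- voxel_spacing(labels)
  d <- dim(mask)
  dp <- d + 2L
  f <- array(0, dp)
  f[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- as.numeric(mask)

  nc <- dp - 1L # cells per axis
  # scalar values at the 8 corners of every cell, as columns
  corner_vals <- matrix(0, prod(nc), 8L)
  for (k in 1:8) {
    o <- .tet_corners[k, ]
    corner_vals[, k] <- as.vector(
      f[(1 + o[1]):(nc[1] + o[1]), (1 + o[2]):(nc[2] + o[2]), (1 + o[3]):(nc[3] + o[3])])
  }
  # physical coordinates of cell origin corners (voxel centres, padded grid)
  cx <- ((seq_len(nc[1]) - 1L) - 0.5) * sp[1]
  cy <- ((seq_len(nc[2]) - 1L) - 0.5) * sp[2]
  cz <- ((seq_len(nc[3]) - 1L) - 0.5) * sp[3]
  O <- cbind(rep(cx, times = nc[2] * nc[3]),
             rep(rep(cy, each = nc[1]), times = nc[3]),
             rep(cz, each = nc[1] * nc[2]))

  n_inside <- rowSums(corner_vals > iso_level)
  active <- which(n_inside > 0 & n_inside < 8) # cells crossed by the surface
  corner_vals <- corner_vals[active, , drop = FALSE]
  O <- O[active, , drop = FALSE]

  tri_list <- list()
  emit <- function(p1, p2, p3, outward) {
    # orient so normals point along `outward`, then store
    n <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
               (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
               (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
    flip <- rowSums(n * outward) < 0
    tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]
    p3[flip, ] <- tmp
    tri_list[[length(tri_list) + 1L]] <<- cbind(p1, p2, p3)
  }

  for (t in seq_len(nrow(.tets))) {
    tet <- .tets[t, ]
    vals <- corner_vals[, tet, drop = FALSE]
    inside <- vals > iso_level
    cnt <- rowSums(inside)
    sel_cells <- which(cnt > 0 & cnt < 4)
    if (length(sel_cells) == 0L) next
    vals <- vals[sel_cells, , drop = FALSE]
    inside <- inside[sel_cells, , drop = FALSE]
    cnt <- cnt[sel_cells]
    Ot <- O[sel_cells, , drop = FALSE]
    tetpos <- lapply(1:4, function(k) {
      matrix(.tet_corners[tet[k], ] * sp, nrow(Ot), 3, byrow = TRUE) + Ot
    })
    ip <- function(a, b, rows) { # interp between local tet verts a, b
      fa <- vals[rows, a]; fb <- vals[rows, b]
      tt <- (iso_level - fa) / (fb - fa)
      pa <- tetpos[[a]][rows, , drop = FALSE]
      pb <- tetpos[[b]][rows, , drop = FALSE]
      pa + (pb - pa) * tt
    }
    # one vertex inside (or one outside): single triangle
    for (a in 1:4) {
      others <- setdiff(1:4, a)
      rows1 <- which(cnt == 1 & inside[, a])
      if (length(rows1)) {
        p1 <- ip(a, others[1], rows1)
        p2 <- ip(a, others[2], rows1)
        p3 <- ip(a, others[3], rows1)
        ctr <- (p1 + p2 + p3) / 3
        emit(p1, p2, p3, ctr - tetpos[[a]][rows1, , drop = FALSE])
      }
      rows3 <- which(cnt == 3 & !inside[, a])
      if (length(rows3)) {
        p1 <- ip(a, others[1], rows3)
        p2 <- ip(a, others[2], rows3)
        p3 <- ip(a, others[3], rows3)
        ctr <- (p1 + p2 + p3) / 3
        emit(p1, p2, p3, tetpos[[a]][rows3, , drop = FALSE] - ctr)
      }
    }
    # two inside / two outside: quad split into two triangles
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs[pi, 1]; b <- pairs[pi, 2]
      cd <- setdiff(1:4, c(a, b))
      rows <- which(cnt == 2 & inside[, a] & inside[, b])
      if (!length(rows)) next
      q1 <- ip(a, cd[1], rows)
      q2 <- ip(a, cd[2], rows)
      q3 <- ip(b, cd[2], rows)
      q4 <- ip(b, cd[1], rows)
      outdir <- (tetpos[[cd[1]]][rows, , drop = FALSE] + tetpos[[cd[2]]][rows, , drop = FALSE] -
                   tetpos[[a]][rows, , drop = FALSE] - tetpos[[b]][rows, , drop = FALSE]) / 2
      emit(q1, q2, q3, outdir)
      emit(q1, q3, q4, outdir)
    }
  }
  if (length(tri_list) == 0L) stop("no iso-surface crossings found")
  tri <- do.call(rbind, tri_list)
  # merge coincident vertices
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(round(pts[, 1], 6), round(pts[, 2], 6), round(pts[, 3], 6))
  uid <- match(key, unique(key))
  vertices <- pts[!duplicated(key), , drop = FALSE]
  m <- nrow(tri)
  faces <- cbind(uid[1:m], uid[(m + 1):(2 * m)], uid[(2 * m + 1):(3 * m)])
  # drop degenerate faces (interpolation can coincide at corners)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  structure(list(vertices = vertices, faces = faces, class_id = as.integer(class_id)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> class %d: %d vertices, %d faces\n",
              x$class_id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Mesh diagnostics: volume, Euler characteristic, watertightness
#'
#' `mesh_volume()` integrates the divergence theorem over the oriented faces;
#' `mesh_euler_characteristic()` returns `V - E + F`; `mesh_is_watertight()`
#' checks that every edge is shared by exactly two faces.
#'
#' @param mesh A `surface_mesh`.
#' @return A scalar (volume in mm^3, integer characteristic, or logical).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  sum(rowSums(p1 * cr)) / 6
}

#' @rdname mesh_volume
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  nrow(mesh$vertices) - length(unique(ek)) + nrow(f)
}

#' @rdname mesh_volume
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(ek) == 2L)
}

#' Write / read a binary STL file
#'
#' @param mesh A `surface_mesh`.
#' @param path STL path.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "shouldermorph binary STL"))[1:80]
  writeBin(header, con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
           (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
           (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, nf, 9)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    tri[i, ] <- rec[4:12]
  }
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(round(pts[, 1], 5), round(pts[, 2], 5), round(pts[, 3], 5))
  uid <- match(key, unique(key))
  vertices <- pts[!duplicated(key), , drop = FALSE]
  faces <- cbind(uid[1:nf], uid[(nf + 1):(2 * nf)], uid[(2 * nf + 1):(3 * nf)])
  structure(list(vertices = vertices, faces = faces, class_id = NA_integer_),
            class = "surface_mesh")
}

#' Isolate the glenohumeral joint region
#'
#' The crop is a cube of physical side `crop_size_mm` centred at the midpoint
#' of the closest boundary-voxel pair between the humerus (class 1) and
#' scapula (class 2), clamped to the grid; ties between equally close pairs
#' are broken by the lexicographically smallest voxel pair. A crop larger than
#' the grid returns the full grid.
#'
#' @param labels A [label_volume()] containing classes 1 and 2.
#' @param image Optional [voxel_volume()] on the same grid to crop alongside.
#' @param crop_size_mm Physical crop size (scalar or length 3), default 32 mm.
#' @return A `gh_region` list: `origin_voxel`, `size_voxels`, `center_voxel`,
#'   `image_crop` (when `image` given), `labels_crop`, `closest_pair_mm`.
#' @export
extract_gh_region <- function(labels, image = NULL, crop_size_mm = 32) {
  arr <- as.array(labels)
  sp <- voxel_spacing(labels)
  for (cl in c(1L, 2L)) {
    if (!any(arr == cl)) {
      stop(sprintf("class %d missing from labels; cannot locate the joint", cl))
    }
  }
  cp <- closest_boundary_pair(arr == 1L, arr == 2L, sp)
  center <- as.integer(floor((cp$pair[1, ] + cp$pair[2, ]) / 2))
  center <- pmax(pmin(center, dim(arr)), 1L)
  size_vox <- as.integer(pmin(dim(arr), pmax(1L, round(rep_len(crop_size_mm, 3L) / sp))))
  origin <- center - size_vox %/% 2L
  origin <- as.integer(pmax(1L, pmin(origin, dim(arr) - size_vox + 1L)))
  idx <- lapply(1:3, function(k) origin[k]:(origin[k] + size_vox[k] - 1L))
  lab_crop <- label_volume(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], sp)
  if (!any(lab_crop == 1L) || !any(lab_crop == 2L)) {
    stop("crop does not contain both bones; increase crop_size_mm")
  }
  img_crop <- NULL
  if (!is.null(image)) {
    img_crop <- voxel_volume(as.array(image)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], sp)
  }
  structure(list(origin_voxel = origin, size_voxels = size_vox,
                 center_voxel = center, image_crop = img_crop,
                 labels_crop = lab_crop, closest_pair_mm = cp$dist_mm),
            class = "gh_region")
}
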