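#' Configuration for a synthetic shoulder phantom
#'
#' A phantom emulates a CT subvolume of the glenohumeral joint with two
#' bone-like objects: an ellipsoidal humeral head (class 1) carrying
#' osteophyte-like hemispherical bumps on its equatorial margin, and a curved
#' glenoid-like plate (class 2, a spherical-shell cap facing the head). Three
#' pathology axes are controllable and recoverable from the geometry:
#'
#' * `os_grade` — osteophyte severity, protrusion height `<3` / `3-7` / `>7` mm
#'   (bump radii 1.5, 5 and 8 mm by default);
#' * `js_grade` — joint-space condition, inter-bone gap physiological /
#'   narrowed / non-detectable (default widths 4 / 1.5 / 0 mm);
#' * `hsa_grade` — humeroscapular alignment, concentric (offset 0) vs eccentric
#'   (default lateral head offset 5 mm).
#'
#' The implant label follows a deterministic surrogate of clinical guidance —
#' reverse prosthesis iff the alignment is eccentric, the joint space has
#' collapsed, or osteophytes are severe — optionally flipped with probability
#' `label_noise_p`.
#'
#' @param grid_shape Integer length-3 grid size in voxels (each `>= 16`).
#' @param spacing Numeric length-3 voxel size in mm.
#' @param os_grade,js_grade Ordinal grades in `{0, 1, 2}`.
#' @param hsa_grade Binary grade: 0 concentric, 1 eccentric.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise, in
#'   intensity units (bone plateau is 1.0).
#' @param label_noise_p Probability that the implant label deviates from the
#'   deterministic rule.
#' @param seed Integer seed controlling noise and label flips.
#' @param gap_mm Length-3 gap widths (mm) for `js_grade` 0/1/2; grade 2 must be 0.
#' @param offset_mm Length-2 lateral head offsets (mm) for `hsa_grade` 0/1;
#'   grade 0 must be 0 and grade 1 at least 5.
#' @param head_radius_mm,plate_thickness_mm,bump_radii_mm Geometry knobs; the
#'   defaults resolve all grade boundaries at 1 mm spacing.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L),
                           spacing = c(1, 1, 1),
                           os_grade = 0L, js_grade = 0L, hsa_grade = 0L,
                           noise_sd = 0.05, label_noise_p = 0, seed = 1L,
                           gap_mm = c(4, 1.5, 0), offset_mm = c(0, 5),
                           head_radius_mm = 10, plate_thickness_mm = 4,
                           bump_radii_mm = c(1.5, 5, 8)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    stop("`grid_shape` must be three integers, each >= 16")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("`spacing` must be three positive reals")
  for (nm in c("os_grade", "js_grade")) {
    g <- get(nm)
    if (length(g) != 1L || !g %in% 0:2) stop(sprintf("`%s` must be one of 0, 1, 2", nm))
  }
  if (length(hsa_grade) != 1L || !hsa_grade %in% 0:1) stop("`hsa_grade` must be 0 or 1")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (label_noise_p < 0 || label_noise_p > 1) stop("`label_noise_p` must be in [0, 1]")
  if (length(gap_mm) != 3L || gap_mm[3] != 0 || any(diff(gap_mm) >= 0)) {
    stop("`gap_mm` must be three decreasing widths with grade-2 width exactly 0")
  }
  if (length(offset_mm) != 2L || offset_mm[1] != 0 || offset_mm[2] < 5) {
    stop("`offset_mm` must be c(0, e) with eccentric offset e >= 5 mm")
  }
  if (length(bump_radii_mm) != 3L || any(diff(bump_radii_mm) <= 0)) {
    stop("`bump_radii_mm` must be three increasing radii")
  }
  if (!(bump_radii_mm[1] < 3 && bump_radii_mm[2] >= 3 && bump_radii_mm[2] <= 7 &&
        bump_radii_mm[3] > 7)) {
    stop("`bump_radii_mm` must fall in the grade bands <3, 3-7, >7 mm")
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 os_grade = as.integer(os_grade), js_grade = as.integer(js_grade),
                 hsa_grade = as.integer(hsa_grade),
                 noise_sd = noise_sd, label_noise_p = label_noise_p,
                 seed = as.integer(seed),
                 gap_mm = gap_mm, offset_mm = offset_mm,
                 head_radius_mm = head_radius_mm,
                 plate_thickness_mm = plate_thickness_mm,
                 bump_radii_mm = bump_radii_mm),
            class = "phantom_config")
}

# Deterministic implant rule: reverse (0) iff eccentric alignment OR collapsed
# joint space OR severe osteophytes; anatomical (1) otherwise.
implant_rule <- function(os_grade, js_grade, hsa_grade) {
  if (hsa_grade == 1L || js_grade == 2L || os_grade == 2L) 0L else 1L
}

#' Generate a synthetic shoulder phantom
#'
#' Builds the labelled geometry described in [phantom_config()], renders a
#' CT-like intensity image (trabecular plateau 1.0 with a brighter cortical rim
#' on boundary voxels, background 0, additive Gaussian noise) and assigns the
#' implant label by the deterministic rule, flipped with probability
#' `label_noise_p`. Deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_case` list with elements `image` ([voxel_volume()]),
#'   `labels` ([label_volume()] with classes 0/1/2), the three grades,
#'   `implant` (0 reverse, 1 anatomical) and `config`.
#' @examples
#' case <- generate_phantom(phantom_config(grid_shape = c(24, 24, 24),
#'                                         spacing = c(2, 2, 2)))
#' table(case$labels)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid_shape
  sp <- config$spacing
  extent <- grid * sp
  rh <- config$head_radius_mm
  gap <- config$gap_mm[config$js_grade + 1L]
  th <- config$plate_thickness_mm
  bump_r <- config$bump_radii_mm[config$os_grade + 1L]
  offset <- config$offset_mm[config$hsa_grade + 1L]

  # anchor: head centre sits left of centre along x so the plate cap fits
  c0 <- c(0.40 * extent[1], 0.5 * extent[2], 0.5 * extent[3])
  ch <- c0 + c(0, offset, 0)

  # fit check (object bounding boxes inside the grid)
  reach_lat <- rh + bump_r
  lo <- c(ch[1] - reach_lat, ch[2] - reach_lat, ch[3] - reach_lat)
  hi <- c(c0[1] + rh + gap + th, ch[2] + reach_lat, ch[3] + reach_lat)
  if (any(lo < 0) || any(hi > extent)) {
    stop(sprintf(paste0("grid too small: phantom needs [%s]-[%s] mm inside a ",
                        "%s mm volume; enlarge grid_shape or spacing"),
                 paste(round(lo, 1), collapse = ", "),
                 paste(round(hi, 1), collapse = ", "),
                 paste(round(extent, 1), collapse = " x ")))
  }

  P <- voxel_centres(grid, sp)
  # humeral head: near-spherical ellipsoid
  semi <- rh * c(1, 0.95, 0.9)
  head <- ((P[, 1] - ch[1]) / semi[1])^2 + ((P[, 2] - ch[2]) / semi[2])^2 +
    ((P[, 3] - ch[3]) / semi[3])^2 <= 1

  # osteophyte bumps: hemispherical protrusions on the equatorial margin ring
  # (directions perpendicular to the joint axis x), height ~ bump radius
  n_bumps <- 6L
  az <- 2 * pi * (seq_len(n_bumps) - 1L) / n_bumps
  for (a in az) {
    u <- c(0, cos(a), sin(a))
    bc <- ch + (rh * c(1, 0.95, 0.9) * u) # on the ellipsoid surface
    head <- head | (sqrt((P[, 1] - bc[1])^2 + (P[, 2] - bc[2])^2 +
                           (P[, 3] - bc[3])^2) <= bump_r)
  }

  # glenoid-like plate: spherical-shell cap centred at the unshifted anchor,
  # facing the head along +x within a 30 degree half-angle cone
  rel <- cbind(P[, 1] - c0[1], P[, 2] - c0[2], P[, 3] - c0[3])
  r <- sqrt(rowSums(rel^2))
  cosang <- ifelse(r > 0, rel[, 1] / r, 0)
  plate <- r >= rh + gap & r <= rh + gap + th & cosang >= cos(pi / 6)
  plate <- plate & !head # head has priority where pathology closes the gap

  labels <- integer(nrow(P))
  labels[plate] <- 2L
  labels[head] <- 1L
  lab_arr <- array(labels, grid)

  # intensity: trabecular plateau with brighter cortical rim, then noise
  img <- array(0, grid)
  bone <- lab_arr > 0L
  img[bone] <- 1.0
  img[boundary6(bone)] <- 1.3
  implant <- implant_rule(config$os_grade, config$js_grade, config$hsa_grade)
  with_seed(config$seed, {
    if (config$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), sd = config$noise_sd), grid)
    }
    if (config$label_noise_p > 0 && stats::runif(1) < config$label_noise_p) {
      implant <- 1L - implant
    }
  })

  structure(list(image = voxel_volume(img, sp),
                 labels = label_volume(lab_arr, sp),
                 os_grade = config$os_grade, js_grade = config$js_grade,
                 hsa_grade = config$hsa_grade, implant = implant,
                 config = config),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> grid %s, OS %d JS %d HSA %d, implant %s\n",
              paste(dim(x$labels), collapse = "x"),
              x$os_grade, x$js_grade, x$hsa_grade,
              if (x$implant == 0L) "reverse" else "anatomical"))
  invisible(x)
}

#' Rater profile for simulated implant-type reading panels
#'
#' @param sensitivity_anatomical,sensitivity_reverse Probability of answering
#'   correctly when the true implant is anatomical / reverse.
#' @param bias_reverse Probability mass added toward the reverse label after
#'   the sensitivity draw (models the tendency to over-call reverse implants
#'   under morphology-only reading).
#' @return A `rater_profile` list.
#' @export
rater_profile <- function(sensitivity_anatomical = 0.8,
                          sensitivity_reverse = 0.8,
                          bias_reverse = 0) {
  vals <- c(sensitivity_anatomical, sensitivity_reverse, bias_reverse)
  if (any(vals < 0 | vals > 1)) stop("all rater_profile fields must be in [0, 1]")
  structure(list(sensitivity_anatomical = sensitivity_anatomical,
                 sensitivity_reverse = sensitivity_reverse,
                 bias_reverse = bias_reverse),
            class = "rater_profile")
}

#' Simulate a panel of raters reading phantom cases
#'
#' Each rater answers each case independently: with probability equal to the
#' profile's class sensitivity the response equals the true implant label,
#' otherwise the opposite label; afterwards, with probability `bias_reverse`,
#' the response is overridden to reverse. Deterministic given `seed`.
#'
#' @param cases List of `phantom_case` objects (or any objects with an
#'   `$implant` field coded 0 reverse / 1 anatomical).
#' @param profiles List of [rater_profile()]s, one per rater (at least 2).
#' @param seed Integer seed.
#' @return Integer matrix of responses (0 reverse, 1 anatomical), cases in
#'   rows, raters `rater_01 ...` in columns, with the true labels in
#'   `attr(, "truth")`.
#' @export
generate_rater_panel <- function(cases, profiles, seed = 1L) {
  if (length(cases) < 1L) stop("at least one case is required")
  if (length(profiles) < 2L) stop("at least two raters are required")
  truth <- vapply(cases, function(x) as.integer(x$implant), integer(1))
  if (any(!truth %in% 0:1)) stop("case implant labels must be 0 or 1")
  n <- length(cases)
  k <- length(profiles)
  out <- matrix(NA_integer_, n, k,
                dimnames = list(sprintf("case_%03d", seq_len(n)),
                                sprintf("rater_%02d", seq_len(k))))
  with_seed(seed, {
    for (j in seq_len(k)) {
      pr <- profiles[[j]]
      sens <- ifelse(truth == 1L, pr$sensitivity_anatomical, pr$sensitivity_reverse)
      correct <- stats::runif(n) < sens
      resp <- ifelse(correct, truth, 1L - truth)
      resp[stats::runif(n) < pr$bias_reverse] <- 0L
      out[, j] <- resp
    }
  })
  attr(out, "truth") <- truth
  out
}

#' Tabulate panel responses into an items-by-categories count matrix
#'
#' @param ratings Matrix of categorical responses, items in rows, raters in
#'   columns (as from [generate_rater_panel()]).
#' @param categories Vector of category values; defaults to the sorted unique
#'   responses.
#' @return Integer matrix `n_items x n_categories` of rater counts, suitable
#'   for [fleiss_kappa()].
#' @export
ratings_to_counts <- function(ratings, categories = NULL) {
  ratings <- as.matrix(ratings)
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1, function(row) {
    vapply(categories, function(cc) sum(row == cc), integer(1))
  }))
  colnames(counts) <- as.character(categories)
  counts
}

#' Write / read a panel ratings table as CSV
#'
#' The CSV has a `case_id` column followed by one column per rater.
#'
#' @param ratings Response matrix from [generate_rater_panel()].
#' @param path CSV path.
#' @export
write_ratings_csv <- function(ratings, path) {
  df <- data.frame(case_id = rownames(ratings), ratings, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$case_id
  storage.mode(m) <- "integer"
  m
}
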