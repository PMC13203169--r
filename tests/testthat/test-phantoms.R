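test_that("phantom generation is deterministic and validates its inputs", {
  cfg <- phantom_config(grid_shape = c(24, 24, 24), spacing = c(2, 2, 2), seed = 7)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(as.array(a$image), as.array(b$image))
  expect_identical(as.array(a$labels), as.array(b$labels))
  expect_setequal(unique(as.vector(a$labels)), c(0L, 1L, 2L))

  expect_error(phantom_config(os_grade = 3), "os_grade")
  expect_error(phantom_config(hsa_grade = 2), "hsa_grade")
  expect_error(phantom_config(grid_shape = c(8, 24, 24)), ">= 16")
  expect_error(phantom_config(label_noise_p = 1.2), "label_noise_p")
  # grid too small to hold the geometry at 1 mm spacing
  expect_error(generate_phantom(phantom_config(grid_shape = c(16, 16, 16))),
               "grid too small")
})

test_that("implant labels follow the deterministic rule exactly", {
  for (os in 0:2) for (js in 0:2) for (hsa in 0:1) {
    cs <- generate_phantom(phantom_config(grid_shape = c(24, 24, 24),
                                          spacing = c(2, 2, 2), os_grade = os,
                                          js_grade = js, hsa_grade = hsa,
                                          label_noise_p = 0, seed = os + js + hsa))
    expected <- if (hsa == 1 || js == 2 || os == 2) 0L else 1L
    expect_identical(cs$implant, expected)
  }
  # eccentric alignment alone forces a reverse implant
  expect_identical(generate_phantom(phantom_config(hsa_grade = 1))$implant, 0L)
})

test_that("joint-space grades control the inter-bone gap (brute-force check)", {
  mk <- function(js) generate_phantom(phantom_config(js_grade = js, seed = 3))
  diag_mm <- sqrt(3)
  lab0 <- as.array(mk(0)$labels)
  d0 <- brute_min_surface_dist(lab0, 1, 2, c(1, 1, 1))
  expect_gte(d0, 4 - diag_mm) # physiological gap 4 mm
  lab2 <- as.array(mk(2)$labels)
  d2 <- brute_min_surface_dist(lab2, 1, 2, c(1, 1, 1))
  expect_lte(d2, diag_mm) # non-detectable joint space: touching
})

test_that("osteophyte grade monotonically inflates the humeral volume", {
  vols <- vapply(0:2, function(os) {
    sum(as.array(generate_phantom(phantom_config(os_grade = os, seed = 5))$labels) == 1L)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("bone classes are disjoint single 6-connected components", {
  for (js in c(0, 2)) for (hsa in 0:1) {
    lab <- as.array(generate_phantom(phantom_config(
      js_grade = js, hsa_grade = hsa, os_grade = 2, seed = 11))$labels)
    expect_true(shouldermorph:::is_single_component6(lab == 1L))
    expect_true(shouldermorph:::is_single_component6(lab == 2L))
  }
})

test_that("label noise flips the implant label at the configured rate", {
  flips <- vapply(1:200, function(s) {
    generate_phantom(phantom_config(grid_shape = c(24, 24, 24),
                                    spacing = c(2, 2, 2),
                                    label_noise_p = 0.3, seed = s))$implant
  }, integer(1))
  # rule gives anatomical for the default grades; ~30% should flip to reverse
  expect_gt(mean(flips == 0L), 0.18)
  expect_lt(mean(flips == 0L), 0.42)
})

test_that("rater panels honour profiles, determinism and preconditions", {
  cases <- make_phantom_set(12, seed0 = 400)
  perfect <- replicate(3, rater_profile(1, 1, 0), simplify = FALSE)
  r <- generate_rater_panel(cases, perfect, seed = 2)
  truth <- attr(r, "truth")
  expect_true(all(r == truth))
  expect_true(all(panel_entropy(r) == 0))
  r2 <- generate_rater_panel(cases, perfect, seed = 2)
  expect_identical(r, r2)

  expect_error(generate_rater_panel(cases, perfect[1]), "two raters")
  expect_error(generate_rater_panel(list(), perfect), "one case")
})

test_that("chance-level raters produce near-zero panel agreement", {
  cases <- make_phantom_set(50, seed0 = 600)
  cases <- rep(cases, 4) # 200 items
  coin <- replicate(10, rater_profile(0.5, 0.5, 0), simplify = FALSE)
  r <- generate_rater_panel(cases, coin, seed = 9)
  k <- fleiss_kappa(ratings_to_counts(r, categories = 0:1))
  expect_lt(abs(k$kappa), 0.1)
})

test_that("ratings round-trip through CSV", {
  cases <- make_phantom_set(4, seed0 = 300)
  prof <- replicate(3, rater_profile(0.8, 0.7, 0.1), simplify = FALSE)
  r <- generate_rater_panel(cases, prof, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(r, f)
  r2 <- read_ratings_csv(f)
  expect_identical(unname(r2), unname(r[, , drop = FALSE]))
  expect_identical(colnames(r2), colnames(r))
})
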