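# Independent evaluation of the agreement formulas, used as the oracle for
# the package implementation.
fleiss_oracle <- function(counts) {
  k <- rowSums(counts)[1]
  n <- nrow(counts)
  po_i <- vapply(seq_len(n), function(i) {
    sum(counts[i, ] * (counts[i, ] - 1)) / (k * (k - 1))
  }, numeric(1))
  po <- mean(po_i)
  pj <- colSums(counts) / (n * k)
  pe <- sum(pj^2)
  (po - pe) / (1 - pe)
}

test_that("Fleiss' kappa equals direct evaluation on enumerated matrices", {
  for (k in 2:4) {
    for (n in 1:3) {
      rows_choices <- 0:k # count in category 1; category 2 gets the rest
      combos <- as.matrix(expand.grid(rep(list(rows_choices), n)))
      for (r in seq_len(nrow(combos))) {
        counts <- cbind(combos[r, ], k - combos[r, ])
        pj <- colSums(counts) / (n * k)
        if (sum(pj^2) >= 1 - 1e-12) {
          expect_warning(st <- fleiss_kappa(counts), "undefined")
          expect_true(is.na(st$kappa))
        } else {
          expect_equal(fleiss_kappa(counts)$kappa, fleiss_oracle(counts),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("Fleiss' kappa special cases and input validation", {
  # unanimity with both categories used across items
  uni <- rbind(c(3, 0), c(0, 3))
  st <- fleiss_kappa(uni)
  expect_equal(st$po, 1)
  expect_equal(st$p_category, c(0.5, 0.5))
  expect_equal(st$pe, 0.5)
  expect_equal(st$kappa, 1)

  # perfect agreement over many items, >= 2 categories in use
  m <- rbind(c(4, 0), c(4, 0), c(0, 4))
  expect_equal(fleiss_kappa(m)$kappa, 1)

  # a single category ever used: undefined, never a silent number
  expect_warning(st1 <- fleiss_kappa(rbind(c(3, 0), c(3, 0))), "undefined")
  expect_true(st1$undefined)

  expect_error(fleiss_kappa(rbind(c(3, 0), c(1, 1))), "same number of raters")
  expect_error(fleiss_kappa(matrix(c(1, 0), 1, 2)), "two raters")
  expect_error(fleiss_kappa(rbind(c(-1, 4))), "nonnegative")
})

test_that("kappa of simulated random ratings is near zero", {
  set.seed(41)
  votes <- matrix(rbinom(500 * 10, 1, 0.5), 500, 10)
  counts <- ratings_to_counts(votes, categories = 0:1)
  expect_lt(abs(fleiss_kappa(counts)$kappa), 0.05)
})

test_that("vote entropy follows the binary Shannon formula", {
  expect_equal(case_entropy(10, 0)$H, 0)
  expect_equal(case_entropy(0, 10)$H, 0)
  expect_equal(case_entropy(5, 5)$H, 1)
  expect_equal(case_entropy(7, 3)$H,
               -0.7 * log2(0.7) - 0.3 * log2(0.3), tolerance = 1e-12)
  # symmetry
  for (n1 in 0:10) {
    expect_equal(case_entropy(n1, 10 - n1)$H, case_entropy(10 - n1, n1)$H)
  }
  # strictly increasing toward the even split (concavity in p1)
  hs <- vapply(0:5, function(n1) case_entropy(n1, 10 - n1)$H, numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_equal(which.max(vapply(0:10, function(n1) case_entropy(n1, 10 - n1)$H,
                                numeric(1))), 6L) # n1 = 5
  expect_error(case_entropy(0, 0), "at least one vote")
  expect_error(case_entropy(-1, 3), "nonnegative")
})

test_that("rater summary reproduces the surgeon panel table cells", {
  panel <- load_surgeon_panel()
  rs <- rater_summary(panel)
  per <- rs$per_rater
  r2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

  printed <- data.frame(
    id = sprintf("%02d", 1:10),
    accuracy = c(0.65, 0.62, 0.62, 0.55, 0.69, 0.51, 0.60, 0.59, 0.59, 0.68),
    a_se = c(0.58, 0.51, 0.53, 0.47, 0.64, 0.48, 0.60, 0.54, 0.38, 0.56),
    r_se = c(0.72, 0.73, 0.71, 0.63, 0.74, 0.54, 0.60, 0.64, 0.80, 0.80))
  expect_equal(r2(per$accuracy), printed$accuracy)
  expect_equal(r2(per$a_se), printed$a_se)
  expect_equal(r2(per$r_se), printed$r_se)

  # three raters have 51 anatomical cases: sensitivities must come from
  # TP/(TP+FN), not TP/50, to match the printed cells
  expect_true(any(panel$a_tp + panel$a_fn == 51))

  expect_equal(r2(rs$mean["accuracy"]), c(accuracy = 0.61))
  expect_equal(r2(rs$sd["accuracy"]), c(accuracy = 0.06))
  expect_equal(r2(rs$mean["a_se"]), c(a_se = 0.53))
  expect_equal(r2(rs$mean["r_se"]), c(r_se = 0.69))
  expect_equal(rs$mean[["a_tp"]], 26.6)
  expect_equal(r2(rs$sd["a_tp"]), c(a_tp = 3.66))
  expect_equal(range(r2(per$accuracy)), c(0.51, 0.69))

  # trivial: a rater with no false negatives is perfect
  one <- data.frame(id = "x", a_tp = 10, r_tp = 12, a_fn = 0, r_fn = 0)
  rs1 <- rater_summary(one)
  expect_equal(rs1$per_rater$accuracy, 1)
  expect_equal(rs1$per_rater$a_se, 1)
  expect_equal(rs1$per_rater$r_se, 1)
  expect_error(rater_summary(data.frame(id = "y", a_tp = 0, r_tp = 3,
                                        a_fn = 0, r_fn = 1)),
               "at least one")
})

test_that("virtual consensus recovers signal and stays at chance on noise", {
  # perfect raters: accuracy 1
  set.seed(5)
  y <- rep(0:1, each = 25)
  X <- matrix(rep(y, 4), ncol = 4)
  vc <- virtual_consensus(X, y, folds = 5, seed = 1)
  expect_equal(vc$accuracy, 1)

  # independent fair coins: chance level
  y2 <- rep(0:1, each = 100)
  X2 <- matrix(rbinom(200 * 10, 1, 0.5), 200, 10)
  vc2 <- virtual_consensus(X2, y2, folds = 5, seed = 2)
  expect_lt(abs(vc2$accuracy - 0.5), 0.1)

  expect_error(virtual_consensus(X2, rep(1, 200)), "both classes")
  expect_error(virtual_consensus(X2[95:102, ], y2[95:102], folds = 5), "per fold")
})

test_that("the consensus beats the best individual rater on a 0.75-sensitivity panel", {
  cases <- make_phantom_set(30, seed0 = 900)
  cases <- rep(cases, 4) # 120 items
  truth <- vapply(cases, function(x) x$implant, integer(1))
  profiles <- replicate(10, rater_profile(0.75, 0.75, 0), simplify = FALSE)
  wins <- 0
  for (s in 1:3) {
    r <- generate_rater_panel(cases, profiles, seed = s)
    best_single <- max(colMeans(r == truth))
    vc <- virtual_consensus(r, truth, folds = 5, seed = s)
    if (vc$accuracy > best_single) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("exact McNemar matches a direct binomial enumeration", {
  # no discordant pairs
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(mcnemar_test(a, a)$p_value, 1)

  # discordant counts b = 15, c = 3
  ca <- c(rep(TRUE, 15), rep(FALSE, 3), rep(TRUE, 10))
  cb <- c(rep(FALSE, 15), rep(TRUE, 3), rep(TRUE, 10))
  res <- mcnemar_test(ca, cb)
  expect_equal(res$b, 15)
  expect_equal(res$c, 3)
  dens <- dbinom(0:18, 18, 0.5)
  p_oracle <- sum(dens[dens <= dbinom(15, 18, 0.5) * (1 + 1e-7)])
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)

  # symmetry under swapping the inputs
  expect_equal(mcnemar_test(cb, ca)$p_value, res$p_value)
  expect_error(mcnemar_test(ca, ca[-1]), "equal length")
})
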