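# Blinded-panel agreement statistics: Fleiss' kappa, vote entropy, per-rater
# sensitivity summaries, virtual-consensus logistic regression and the exact
# McNemar test.

#' Fleiss' kappa for a fixed-size rater panel
#'
#' Chance-corrected agreement for `N` items rated by `k` raters into `C`
#' categories. With `n_ij` raters assigning item `i` to category `j`:
#' per-item observed agreement `P_i = sum_j n_ij (n_ij - 1) / (k (k - 1))`,
#' observed agreement `Po = mean_i P_i`, category proportions
#' `P_j = sum_i n_ij / (N k)`, expected agreement `Pe = sum_j P_j^2`, and
#' `kappa = (Po - Pe) / (1 - Pe)`. When a single category is ever used,
#' `Pe = 1` and kappa is undefined: the result carries `kappa = NA` and
#' `undefined = TRUE` rather than a silent number.
#'
#' @param counts Integer matrix `N x C` of rater counts per item and category
#'   (each row sums to `k`), e.g. from [ratings_to_counts()].
#' @return An `agreement_stats` list: `kappa`, `po`, `pe`, `po_item`,
#'   `p_category`, `n_items`, `n_raters`, `undefined`.
#' @examples
#' fleiss_kappa(rbind(c(3, 0), c(0, 3)))$kappa # unanimity: kappa = 1
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  rs <- rowSums(counts)
  k <- rs[1]
  if (length(unique(rs)) != 1L) stop("all items must be rated by the same number of raters")
  if (k < 2) stop("at least two raters per item are required")
  n <- nrow(counts)
  po_item <- rowSums(counts * (counts - 1)) / (k * (k - 1))
  po <- mean(po_item)
  pj <- colSums(counts) / (n * k)
  pe <- sum(pj^2)
  undefined <- pe >= 1 - 1e-12
  kappa <- if (undefined) NA_real_ else (po - pe) / (1 - pe)
  if (undefined) {
    warning("expected agreement is 1 (a single category was ever used); kappa undefined")
  }
  structure(list(kappa = kappa, po = po, pe = pe, po_item = po_item,
                 p_category = pj, n_items = n, n_raters = as.integer(k),
                 undefined = undefined),
            class = "agreement_stats")
}

#' Entropy of a binary rater vote split
#'
#' For `n1` votes for anatomical and `n2` for reverse, the base-2 entropy of
#' the vote proportions: 0 bits at complete agreement, 1 bit at a maximal
#' (even) split, with `0 log 0 := 0`.
#'
#' @param n1,n2 Nonnegative vote counts, not both zero.
#' @return An `entropy_result` list: `H` (bits), `p1`, `p2`, `n1`, `n2`.
#' @examples
#' case_entropy(10, 0)$H # 0
#' case_entropy(5, 5)$H  # 1
#' @export
case_entropy <- function(n1, n2) {
  if (n1 < 0 || n2 < 0) stop("vote counts must be nonnegative")
  n <- n1 + n2
  if (n == 0) stop("at least one vote is required")
  p <- c(n1, n2) / n
  terms <- ifelse(p > 0, -p * log2(p), 0)
  structure(list(H = sum(terms), p1 = p[1], p2 = p[2], n1 = n1, n2 = n2),
            class = "entropy_result")
}

#' Per-case entropies of a panel response matrix
#'
#' @param ratings Response matrix (0 reverse / 1 anatomical), cases in rows.
#' @return Numeric vector of per-case entropies in bits.
#' @export
panel_entropy <- function(ratings) {
  apply(as.matrix(ratings), 1L, function(row) {
    case_entropy(sum(row == 1L), sum(row == 0L))$H
  })
}

# round half away from zero, the convention used for printed 2-decimal cells
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-rater summary statistics from implant-type TP/FN counts
#'
#' For each rater with anatomical/reverse true-positive and false-negative
#' counts: anatomical sensitivity `A_SE = A_TP / (A_TP + A_FN)`, reverse
#' sensitivity `R_SE = R_TP / (R_TP + R_FN)` and accuracy
#' `(A_TP + R_TP) / (A_TP + R_TP + A_FN + R_FN)`; cohort rows report the mean
#' and the sample (n-1) standard deviation of every column.
#'
#' @param records Data frame with columns `id`, optionally `role`, and
#'   `a_tp`, `r_tp`, `a_fn`, `r_fn`.
#' @return A `rater_summary` list: `per_rater` data frame (with `accuracy`,
#'   `a_se`, `r_se`), `mean` and `sd` named vectors over all count and rate
#'   columns.
#' @export
rater_summary <- function(records) {
  req <- c("a_tp", "r_tp", "a_fn", "r_fn")
  if (!all(req %in% names(records))) {
    stop("records must have columns a_tp, r_tp, a_fn, r_fn")
  }
  if (any(records$a_tp + records$a_fn <= 0) || any(records$r_tp + records$r_fn <= 0)) {
    stop("each rater needs at least one anatomical and one reverse case")
  }
  per <- records
  per$a_se <- per$a_tp / (per$a_tp + per$a_fn)
  per$r_se <- per$r_tp / (per$r_tp + per$r_fn)
  per$accuracy <- (per$a_tp + per$r_tp) / (per$a_tp + per$r_tp + per$a_fn + per$r_fn)
  cols <- c("accuracy", "a_se", "r_se", "a_tp", "r_tp", "a_fn", "r_fn")
  mu <- vapply(cols, function(cl) mean(per[[cl]]), numeric(1))
  sdv <- vapply(cols, function(cl) stats::sd(per[[cl]]), numeric(1))
  structure(list(per_rater = per, mean = mu, sd = sdv), class = "rater_summary")
}

#' Counts from a published blinded ten-surgeon implant-type reading panel
#'
#' Per-rater anatomical/reverse true-positive and false-negative counts from a
#' blinded reading study in which ten orthopedic surgeons of mixed seniority
#' classified 100 shoulder CT reconstructions (50 anatomical, 50 reverse
#' implants) from bone morphology alone. Shipped as a plain-text fixture and
#' used to exercise [rater_summary()].
#'
#' @return Data frame with columns `id`, `role`, `a_tp`, `r_tp`, `a_fn`, `r_fn`.
#' @export
load_surgeon_panel <- function() {
  path <- system.file("extdata", "surgeon_panel_counts.csv",
                      package = "shouldermorph", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(id = "character"))
}

#' Virtual-consensus logistic regression over rater votes
#'
#' Trains a logistic regression on the raters' binary votes as features to
#' predict the true implant label, and reports stratified k-fold
#' cross-validated accuracy — an aggregate estimate of the predictive signal
#' in collective judgment.
#'
#' @param rater_predictions `N x k` binary (0/1) matrix of votes.
#' @param true_labels Length-`N` binary labels.
#' @param folds Number of stratified CV folds.
#' @param seed Integer seed for the fold assignment.
#' @return List: `accuracy`, `fold_accuracy`, `folds`, `predictions`.
#' @export
virtual_consensus <- function(rater_predictions, true_labels, folds = 5L,
                              seed = 1L) {
  X <- as.matrix(rater_predictions)
  y <- as.integer(true_labels)
  n <- length(y)
  if (nrow(X) != n) stop("votes and labels disagree in length")
  if (length(unique(y)) < 2L) stop("both classes must be present in the labels")
  if (n < 2L * folds) stop("need at least 2 cases per fold")
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  df <- data.frame(y = y, X)
  pred <- integer(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[tr, , drop = FALSE],
                                       family = stats::binomial()))
    p <- suppressWarnings(stats::predict(fit, newdata = df[!tr, , drop = FALSE],
                                         type = "response"))
    pred[!tr] <- as.integer(p > 0.5)
  }
  fold_acc <- vapply(seq_len(folds), function(f) {
    mean(pred[fold_id == f] == y[fold_id == f])
  }, numeric(1))
  list(accuracy = mean(pred == y), fold_accuracy = fold_acc, folds = folds,
       predictions = pred)
}

#' Exact McNemar test on paired correctness vectors
#'
#' Compares two classifiers (or a classifier and a panel) on the same cases
#' through the discordant pairs: `b` cases only the first got right, `c`
#' cases only the second. The two-sided p-value is the exact binomial
#' probability of a split at least as extreme as `(b, c)` under `p = 0.5`.
#'
#' @param correct_a,correct_b Logical vectors of per-case correctness.
#' @return List: `b`, `c`, `n_discordant`, `p_value`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) stop("inputs must have equal length")
  if (length(correct_a) < 1L) stop("empty input")
  a <- as.logical(correct_a)
  b_ <- as.logical(correct_b)
  b <- sum(a & !b_)
  cc <- sum(!a & b_)
  n <- b + cc
  p <- if (n == 0L) 1 else stats::binom.test(b, n, p = 0.5)$p.value
  list(b = b, c = cc, n_discordant = n, p_value = p,
       method = "exact binomial McNemar (two-sided)")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Fleiss' kappa %.4f (Po %.4f, Pe %.4f; %d items, %d raters)\n",
              x$kappa, x$po, x$pe, x$n_items, x$n_raters))
  invisible(x)
}

#' @export
print.rater_summary <- function(x, ...) {
  df <- x$per_rater
  df$a_se <- round_half_away(df$a_se)
  df$r_se <- round_half_away(df$r_se)
  df$accuracy <- round_half_away(df$accuracy)
  print(df, row.names = FALSE)
  cat(sprintf("cohort: accuracy %.2f (SD %.2f), A SE %.2f, R SE %.2f\n",
              round_half_away(x$mean["accuracy"]), round_half_away(x$sd["accuracy"]),
              round_half_away(x$mean["a_se"]), round_half_away(x$mean["r_se"])))
  invisible(x)
}
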