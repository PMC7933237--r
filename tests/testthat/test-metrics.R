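# Brute-force oracles: confusion counts assembled by explicit enumeration
# and AUC by exhaustive positive-negative pair counting.

oracle_f1 <- function(y_true, y_pred, cl) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(y_true)) {
    if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
    if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
    if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
  }
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

test_that("macro F1 matches hand-computed confusion cases", {
  expect_equal(macro_f1(rep(letters[1:4], 5), rep(letters[1:4], 5))$macro_f1, 1)
  r <- macro_f1(c("A", "A", "B", "B"), c("A", "B", "A", "B"))
  expect_equal(unname(r$per_class), c(0.5, 0.5))
  expect_equal(r$macro_f1, 0.5)
  # all predictions collapse to one class on balanced 4-class truth
  y <- rep(c("A", "B", "C", "D"), each = 10)
  r2 <- macro_f1(y, rep("A", 40), classes = c("A", "B", "C", "D"))
  expect_equal(r2$macro_f1, (2 * 0.25 / 1.25) / 4)
  expect_equal(unname(r2$per_class), c(0.4, 0, 0, 0))
  expect_error(macro_f1(character(0), character(0)), "empty")
  expect_error(macro_f1("A", c("A", "B")), "same length")
})

test_that("macro F1 agrees with the enumeration oracle on random instances", {
  set.seed(1)
  classes <- c("w", "x", "y", "z")
  for (i in 1:1000) {
    n <- sample(3:20, 1)
    yt <- sample(classes, n, replace = TRUE)
    yp <- sample(classes, n, replace = TRUE)
    r <- macro_f1(yt, yp, classes)
    per <- vapply(classes, function(cl) oracle_f1(yt, yp, cl), 0)
    expect_equal(unname(r$per_class), unname(per))
    expect_equal(r$macro_f1, mean(per))
  }
})

test_that("class-wise AUC equals exhaustive pair counting", {
  set.seed(2)
  for (i in 1:200) {
    n <- sample(6:50, 1)
    y <- cbind(rbinom(n, 1, 0.4), rbinom(n, 1, 0.6))
    s <- cbind(round(runif(n), 2), round(runif(n), 2))  # ties likely
    ok <- colSums(y) > 0 & colSums(y) < n
    if (!any(ok)) next
    aucs <- vapply(which(ok), function(j)
      oracle_auc(s[y[, j] == 1, j], s[y[, j] == 0, j]), 0)
    expect_equal(mean_classwise_auc(y[, ok, drop = FALSE],
                                    s[, ok, drop = FALSE]), mean(aucs))
  }
  expect_equal(mean_classwise_auc(cbind(c(1, 1, 0, 0)), cbind(c(1, 1, 0, 0))), 1)
  expect_equal(mean_classwise_auc(cbind(c(1, 0, 1, 0)), cbind(rep(0.5, 4))), 0.5)
  expect_error(mean_classwise_auc(cbind(c(1, 1)), cbind(c(.1, .2))), "no class")
})

test_that("sample-centric Fmax follows its definition and grid monotonicity", {
  y <- rbind(c(1, 0, 1), c(0, 1, 0))
  expect_equal(f_max(y, y), 1)
  # one sample, truth {a, b}, predicted {a}: P = 1, R = 0.5, F = 2/3
  y1 <- rbind(c(1, 1, 0))
  s1 <- rbind(c(0.9, 0.1, 0.0))
  expect_equal(f_max(y1, s1, grid = 0.5), 2 / 3)
  set.seed(3)
  y2 <- matrix(rbinom(40, 1, 0.5), 8)
  s2 <- matrix(runif(40), 8)
  coarse <- f_max(y2, s2, grid = seq(0, 1, 0.2))
  fine <- f_max(y2, s2, grid = seq(0, 1, 0.05))
  expect_gte(fine, coarse)
  expect_error(f_max(y2, s2, grid = numeric(0)), "non-empty")
})

test_that("F-beta and G-beta match their closed forms at beta 2", {
  y <- matrix(rbinom(60, 1, 0.5), 20)
  expect_equal(f_beta_g_beta(y, y), list(f_beta = 1, g_beta = 1))
  # one class, TP = 1, FN = 1, FP = 0: F2 = 5/9, G2 = 1/3
  r <- f_beta_g_beta(cbind(c(1, 1)), cbind(c(1, 0)))
  expect_equal(r$f_beta, 5 / 9)
  expect_equal(r$g_beta, 1 / 3)
  allneg <- f_beta_g_beta(y, y * 0)
  expect_equal(allneg$f_beta, 0)
  expect_equal(allneg$g_beta, 0)
})

test_that("metrics are invariant to sample order", {
  set.seed(4)
  n <- 30
  yt <- sample(c("A", "B", "C"), n, replace = TRUE)
  yp <- sample(c("A", "B", "C"), n, replace = TRUE)
  perm <- sample(n)
  expect_equal(macro_f1(yt, yp)$macro_f1, macro_f1(yt[perm], yp[perm])$macro_f1)
  y <- matrix(rbinom(n * 2, 1, 0.5), n)
  s <- matrix(runif(n * 2), n)
  expect_equal(mean_classwise_auc(y, s),
               mean_classwise_auc(y[perm, ], s[perm, ]))
  expect_equal(f_max(y, s), f_max(y[perm, ], s[perm, ]))
  expect_equal(f_beta_g_beta(y, (s > .5) * 1),
               f_beta_g_beta(y[perm, ], (s[perm, ] > .5) * 1))
})

test_that("threshold search returns the smallest maximizing grid point", {
  y <- cbind(c(1, 1, 0, 0))
  s <- cbind(c(0.9, 0.8, 0.2, 0.1))
  metric <- function(yt, yp) f_beta_g_beta(yt, yp)$f_beta
  thr <- threshold_search(y, s, metric, grid = seq(0, 1, 0.05))
  # any threshold in (0.2, 0.8] is perfect; the smallest such grid point wins
  expect_equal(thr, 0.25)
  vals <- vapply(seq(0, 1, 0.05), function(t) metric(y, (s >= t) * 1), 0)
  expect_equal(metric(y, (s >= thr) * 1), max(vals))
  expect_equal(threshold_search(y, s, metric, grid = 0.4), 0.4)
})
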