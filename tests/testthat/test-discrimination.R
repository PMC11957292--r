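# two Gaussian clouds with controllable separation
two_clouds <- function(seed, n1 = 20, n2 = 20, shift = c(0, 0),
                       scale2 = c(1, 1)) {
  set.seed(seed)
  X1 <- matrix(rnorm(2 * n1), ncol = 2)
  X2 <- sweep(matrix(rnorm(2 * n2), ncol = 2) %*% diag(scale2), 2, -shift)
  colnames(X1) <- colnames(X2) <- c("a", "b")
  list(X1 = X1, X2 = X2)
}

clouds_table <- function(cl) {
  data.frame(a = c(cl$X1[, 1], cl$X2[, 1]), b = c(cl$X1[, 2], cl$X2[, 2]),
             group = rep(c("positive", "negative"),
                         c(nrow(cl$X1), nrow(cl$X2))))
}

test_that("Pearson correlation is the covariance over sd product", {
  x <- c(1, 2, 4, 4.5, 7)
  expect_equal(pearson_corr(x, 2 * x + 1), 1)
  expect_equal(pearson_corr(x, -x), -1)
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    mab <- mean(a * b) - mean(a) * mean(b)
    r_def <- (mab * 30 / 29) /
      sqrt(sum((a - mean(a))^2) / 29 * sum((b - mean(b))^2) / 29)
    expect_equal(pearson_corr(a, b), r_def, tolerance = 1e-12)
  }
  expect_error(pearson_corr(rep(1, 5), rnorm(5)),
               class = "undefined_correlation")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(8)
  df <- as.data.frame(matrix(rnorm(200), ncol = 5))
  names(df) <- c("mean_speed_um_s", "freq_below_30", "sum_turn_angles",
                 "total_length", "quiescent_time_s")
  m <- correlation_matrix(df)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 5))
  df$quiescent_time_s <- 3
  expect_warning(m2 <- correlation_matrix(df), "constant")
  others <- setdiff(colnames(m2), "quiescent_time_s")
  expect_true(all(is.na(m2["quiescent_time_s", others])))
})

test_that("Welch test matches the textbook statistic and is monotone", {
  a <- c(1, 2, 3)
  w <- welch_t_test(a, a)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)

  ps <- vapply(c(1, 3, 6, 10), function(d) welch_t_test(a, a + d)$p,
               numeric(1))
  expect_true(all(diff(ps) < 0))

  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(9, 1, 2)
    w <- welch_t_test(x, y)
    se2 <- var(x) / 12 + var(y) / 9
    t_ref <- (mean(x) - mean(y)) / sqrt(se2)
    df_ref <- se2^2 / ((var(x) / 12)^2 / 11 + (var(y) / 9)^2 / 8)
    expect_equal(w$t, t_ref, tolerance = 1e-10)
    expect_equal(w$df, df_ref, tolerance = 1e-10)
    expect_equal(w$p, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-10)
  }
  expect_error(welch_t_test(rep(2, 4), rep(2, 4)), class = "degenerate_data")
})

test_that("pooled covariance follows the weighted two-class estimator", {
  cl <- two_clouds(21, n1 = 14, n2 = 9)
  m <- fit_lda(cl$X1, cl$X2)
  expect_equal(m$S, (13 * cov(cl$X1) + 8 * cov(cl$X2)) / 21)
  # equal covariances pool to themselves: S1 = S2 = C  =>  S = C
  expect_equal(((14 - 1) * m$S1 + (14 - 1) * m$S1) / (2 * 14 - 2), m$S1)
  # n1 = n2, S1 = 2I, S2 = 4I => S = 3I (pooling arithmetic)
  S <- ((10 - 1) * diag(c(2, 2)) + (10 - 1) * diag(c(4, 4))) / (10 + 10 - 2)
  expect_equal(S, diag(c(3, 3)))
  expect_error(fit_lda(cl$X1[1:2, ], cl$X2), class = "insufficient_data")
  # collinear features give a singular pooled covariance
  X1 <- cbind(1:5, 2 * (1:5)); X2 <- cbind(6:10, 2 * (6:10))
  expect_error(fit_lda(X1, X2), class = "fit_error")
})

test_that("Mahalanobis distances match the definitional quadratic form", {
  cl <- two_clouds(22)
  for (kind in c("lda", "qda")) {
    m <- if (kind == "lda") fit_lda(cl$X1, cl$X2) else fit_qda(cl$X1, cl$X2)
    pts <- matrix(rnorm(40), ncol = 2)
    d <- mahalanobis_sq(m, pts)
    C1 <- if (kind == "lda") m$S else m$S1
    C2 <- if (kind == "lda") m$S else m$S2
    expect_lt(max(abs(d[, "d1sq"] -
                        stats::mahalanobis(pts, m$mean1, C1))), 1e-9)
    expect_lt(max(abs(d[, "d2sq"] -
                        stats::mahalanobis(pts, m$mean2, C2))), 1e-9)
  }
})

test_that("classification is nearest-class with ties going positive", {
  cl <- two_clouds(23, shift = c(4, 0))
  m <- fit_qda(cl$X1, cl$X2)
  expect_equal(classify(m, m$mean1), "positive")
  expect_equal(classify(m, m$mean2), "negative")

  # grid labels equal the sign of d1^2 - d2^2
  g <- as.matrix(expand.grid(a = seq(-3, 7, 0.5), b = seq(-3, 3, 0.5)))
  d <- mahalanobis_sq(m, g)
  expect_identical(classify(m, g),
                   ifelse(d[, 1] - d[, 2] <= 0, "positive", "negative"))

  # exact tie: symmetric 1-D-style model, midpoint goes positive
  X1 <- cbind(c(-1, 0, 1), c(-1, 1, 0))
  X2 <- cbind(c(3, 4, 5), c(-1, 1, 0))
  mt <- fit_lda(X1, X2)
  mid <- (mt$mean1 + mt$mean2) / 2
  d <- mahalanobis_sq(mt, mid)
  expect_equal(unname(d[, 1]), unname(d[, 2]))
  expect_equal(classify(mt, mid), "positive")
})

test_that("QDA agrees with LDA when class covariances are identical", {
  set.seed(24)
  X1 <- matrix(rnorm(40), ncol = 2)
  X2 <- sweep(X1, 2, c(-3, -1))  # same sample covariance exactly
  colnames(X1) <- colnames(X2) <- c("a", "b")
  ml <- fit_lda(X1, X2); mq <- fit_qda(X1, X2)
  expect_equal(mq$S1, mq$S2)
  g <- as.matrix(expand.grid(a = seq(-4, 7, 0.25), b = seq(-4, 5, 0.25)))
  expect_identical(classify(ml, g), classify(mq, g))
})

test_that("the 1-D equal-variance boundary sits at the midpoint of means", {
  set.seed(25)
  z <- rnorm(200)
  z <- (z - mean(z)) / sd(z)          # exactly mean 0, sd 1
  X1 <- cbind(z); X2 <- cbind(z + 4)  # N(0,1) vs N(4,1)
  m <- fit_qda(X1, X2)
  eps <- 1e-9
  expect_equal(classify(m, cbind(2)), "positive")     # tie -> positive
  expect_equal(classify(m, cbind(2 - eps)), "positive")
  expect_equal(classify(m, cbind(2 + eps)), "negative")
})

test_that("classification is invariant under affine feature rescaling", {
  cl <- two_clouds(26, shift = c(2, 1), scale2 = c(1.5, 0.7))
  pts <- matrix(rnorm(60), ncol = 2)
  A <- diag(c(100, 0.01)); b <- c(-7, 3)
  tf <- function(X) sweep(X %*% A, 2, -b)
  for (fit in list(fit_lda, fit_qda)) {
    m <- fit(cl$X1, cl$X2)
    mt <- fit(tf(cl$X1), tf(cl$X2))
    expect_identical(classify(m, pts), classify(mt, tf(pts)))
  }
})

test_that("confusion metrics implement the sensitivity/specificity/accuracy formulas", {
  lab <- function(p, n) rep(c("positive", "negative"), c(p, n))
  all_ok <- confusion_metrics(lab(3, 2), lab(3, 2))
  expect_equal(c(all_ok$sensitivity, all_ok$specificity, all_ok$accuracy),
               c(1, 1, 1))
  all_bad <- confusion_metrics(lab(0, 5), lab(5, 0))
  expect_equal(all_bad$accuracy, 0)

  # constructed confusion matrix: tp 47, fn 3, tn 37, fp 13
  pred <- c(rep("positive", 47), rep("negative", 3),
            rep("negative", 37), rep("positive", 13))
  act <- c(rep("positive", 50), rep("negative", 50))
  cm <- confusion_metrics(pred, act)
  expect_equal(100 * cm$sensitivity, 94.0)
  expect_equal(100 * cm$specificity, 74.0)
  expect_equal(100 * cm$accuracy, 84.0)

  # exhaustive enumeration of all confusion matrices with counts <= 5
  for (tp in 0:5) for (fp in 0:5) for (fn in 0:5) for (tn in 0:5) {
    tot <- tp + fp + fn + tn
    if (tot == 0) next
    pred <- rep(c("positive", "positive", "negative", "negative"),
                c(tp, fp, fn, tn))
    act <- rep(c("positive", "negative", "positive", "negative"),
               c(tp, fp, fn, tn))
    cm <- confusion_metrics(pred, act)
    expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(tp, fp, fn, tn))
    if (tp + fn > 0) expect_identical(cm$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_identical(cm$specificity, tn / (tn + fp))
    expect_identical(cm$accuracy, (tp + tn) / tot)
  }
  expect_error(confusion_metrics(character(), character()), "non-empty")
})

test_that("cross-validation is stratified, seeded, and separates separable data", {
  tab <- clouds_table(two_clouds(27, n1 = 25, n2 = 25, shift = c(10, 10)))
  cv <- kfold_cv(tab, c("a", "b"), "lda", k = 10, seed = 0)
  expect_equal(cv$mean$accuracy, 1)
  expect_length(cv$folds, 10)
  # every fold holds out cells of both classes (stratification)
  for (f in cv$folds) {
    expect_gte(f$tp + f$fn, 2)  # positives held out
    expect_gte(f$tn + f$fp, 2)  # negatives held out
  }

  cv2 <- kfold_cv(tab, c("a", "b"), "lda", k = 10, seed = 0)
  expect_identical(cv, cv2)
  expect_error(kfold_cv(tab[1:12, ], c("a", "b"), "lda", k = 10),
               class = "fold_error")
})

test_that("resubstitution is at least as accurate as chance on separated data", {
  tab <- clouds_table(two_clouds(28, shift = c(3, 0)))
  rs <- resubstitution_metrics(tab, c("a", "b"), "qda")
  expect_gt(rs$accuracy, 0.5)
})

test_that("pair search covers all pairs and puts the informative pair first", {
  set.seed(29)
  n <- 60
  params <- motility_parameters()
  mk <- function(label, coupled) {
    df <- as.data.frame(matrix(rnorm(n * 10), ncol = 10))
    names(df) <- params
    if (coupled) {
      df$freq_below_30 <- df$freq_below_30 + 2.5
      df$sum_turn_angles <- df$sum_turn_angles - 2.5
    }
    df$group <- label
    df
  }
  tab <- rbind(mk("positive", TRUE), mk("negative", FALSE))
  rk <- pair_search(tab, kinds = "qda", seed = 0)
  expect_equal(nrow(rk), choose(10, 2))
  expect_setequal(c(rk$parameter_1[1], rk$parameter_2[1]),
                  c("freq_below_30", "sum_turn_angles"))
  rk2 <- pair_search(tab, kinds = c("lda", "qda"), seed = 0)
  expect_equal(nrow(rk2), 2 * choose(10, 2))
  expect_true(all(diff(rk2$accuracy) <= 0))
})

test_that("rows with missing values are dropped per pair with a note", {
  tab <- clouds_table(two_clouds(30, n1 = 15, n2 = 15, shift = c(6, 6)))
  tab$a[c(1, 30)] <- NA
  expect_message(cv <- kfold_cv(tab, c("a", "b"), "lda", seed = 1),
                 "2 cell\\(s\\) dropped")
  expect_equal(cv$pooled$tp + cv$pooled$fp + cv$pooled$fn + cv$pooled$tn, 28)
})

test_that("discriminant predictions agree with an equal-prior reference fit", {
  skip_if_not_installed("MASS")
  cl <- two_clouds(31, n1 = 30, n2 = 30, shift = c(2.5, 1), scale2 = c(2, 0.5))
  tab <- clouds_table(cl)
  pts <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a", "b")))
  ml <- fit_lda(cl$X1, cl$X2)
  ref_l <- MASS::lda(group ~ a + b, tab, prior = c(0.5, 0.5))
  pl <- predict(ref_l, as.data.frame(pts))$class
  expect_identical(classify(ml, pts),
                   ifelse(pl == "positive", "positive", "negative"))
  mq <- fit_qda(cl$X1, cl$X2)
  ref_q <- MASS::qda(group ~ a + b, tab, prior = c(0.5, 0.5))
  pq <- predict(ref_q, as.data.frame(pts))$class
  expect_identical(classify(mq, pts),
                   ifelse(pq == "positive", "positive", "negative"))
})

test_that("the sampled discrimination boundary lies on the decision surface", {
  cl <- two_clouds(32, shift = c(5, 0), scale2 = c(2, 2))
  m <- fit_qda(cl$X1, cl$X2)
  bd <- discrimination_boundary(m, c(-4, 9), c(-5, 5), n = 101)
  expect_gt(nrow(bd), 10)
  d <- mahalanobis_sq(m, as.matrix(bd[, c("x", "y")]))
  expect_lt(median(abs(d[, 1] - d[, 2])), 0.05)
})
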