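# Two-class discrimination of motility phenotypes: correlation analysis,
# Welch tests, and linear/quadratic discriminant analysis with Mahalanobis
# distances, confusion metrics, stratified k-fold cross-validation, and
# exhaustive ranking of parameter pairs.

#' Pearson correlation coefficient
#'
#' r = s_xy / (s_x s_y), the covariance over the product of standard
#' deviations.
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2L) stop2("insufficient_data", "need >= 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop2("undefined_correlation", "zero variance: correlation undefined")
  }
  stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
}

#' Correlation matrix of motility parameters
#'
#' Pairwise Pearson correlations of the per-cell parameter values for one
#' group of cells. Constant columns yield `NA` entries and a warning.
#'
#' @param features Data frame containing the parameter columns.
#' @param columns Character vector of columns (default the ten motility
#'   parameters present in `features`).
#' @param use Passed to [stats::cor()]; default drops incomplete pairs
#'   (cells with undefined migration distance between turns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features,
                               columns = intersect(motility_parameters(),
                                                   names(features)),
                               use = "pairwise.complete.obs") {
  X <- as.matrix(features[, columns, drop = FALSE])
  const <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("constant column(s): ", paste(columns[const], collapse = ", "),
            "; correlations set to NA")
  }
  suppressWarnings(m <- stats::cor(X, use = use))
  diag(m) <- 1
  m
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; two-sided p-value.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop2("insufficient_data", "each sample needs >= 2 observations")
  }
  if (stats::var(a) + stats::var(b) == 0) {
    stop2("degenerate_data", "zero combined variance")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

sample_cov <- function(X) {
  # class covariance per the definitional variance/covariance estimator
  stats::cov(X)
}

check_spd <- function(S, what) {
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop2("fit_error",
          paste0(what, " covariance is not positive definite; ",
                 "try a different parameter pair"))
  }
}

new_discriminant_model <- function(kind, m1, m2, S1, S2, S, n1, n2, params) {
  structure(list(kind = kind, mean1 = m1, mean2 = m2, S1 = S1, S2 = S2,
                 S = S, n1 = n1, n2 = n2, parameters = params),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s on (%s); n1 = %d, n2 = %d\n",
              toupper(x$kind), paste(x$parameters, collapse = ", "),
              x$n1, x$n2))
  invisible(x)
}

#' Fit a linear discriminant model
#'
#' Class means and a pooled covariance
#' S = ((n1 - 1) S1 + (n2 - 1) S2) / (n1 + n2 - 2), where S1 and S2 are the
#' sample variance-covariance matrices of the two classes. Class 1 is the
#' positive class.
#'
#' @param X1,X2 Numeric matrices (rows = cells, columns = parameters) for
#'   the positive and negative class; >= 3 rows each, no missing values.
#' @param parameters Optional column names recorded in the model.
#' @return A `discriminant_model` of kind `"lda"`.
#' @export
fit_lda <- function(X1, X2, parameters = colnames(X1)) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  check_classes(X1, X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  S1 <- sample_cov(X1); S2 <- sample_cov(X2)
  S <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  check_spd(S, "pooled")
  new_discriminant_model("lda", colMeans(X1), colMeans(X2), S1, S2, S,
                         n1, n2, parameters)
}

#' Fit a quadratic discriminant model
#'
#' As [fit_lda()] but the two class covariances are kept separate and each
#' class's Mahalanobis distance uses its own covariance.
#'
#' @inheritParams fit_lda
#' @return A `discriminant_model` of kind `"qda"`.
#' @export
fit_qda <- function(X1, X2, parameters = colnames(X1)) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  check_classes(X1, X2)
  S1 <- sample_cov(X1); S2 <- sample_cov(X2)
  check_spd(S1, "class 1"); check_spd(S2, "class 2")
  new_discriminant_model("qda", colMeans(X1), colMeans(X2), S1, S2, NULL,
                         nrow(X1), nrow(X2), parameters)
}

check_classes <- function(X1, X2) {
  if (nrow(X1) < 3L || nrow(X2) < 3L) {
    stop2("insufficient_data", "each class needs >= 3 cells")
  }
  if (ncol(X1) != ncol(X2)) stop("classes differ in dimension", call. = FALSE)
  if (anyNA(X1) || anyNA(X2)) {
    stop("missing values in fit columns; drop those rows first",
         call. = FALSE)
  }
}

#' Squared Mahalanobis distances to both class means
#'
#' d_i^2 = (x - mean_i)' S_i^{-1} (x - mean_i), with S_i the pooled
#' covariance for LDA and the class covariance for QDA.
#'
#' @param model A `discriminant_model`.
#' @param x Numeric matrix of points (rows) or a single vector.
#' @return Matrix with columns `d1sq`, `d2sq`.
#' @export
mahalanobis_sq <- function(model, x) {
  stopifnot(inherits(model, "discriminant_model"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$mean1)) {
    stop("point dimension does not match the model", call. = FALSE)
  }
  C1 <- if (model$kind == "lda") model$S else model$S1
  C2 <- if (model$kind == "lda") model$S else model$S2
  qform <- function(X, m, C) {
    d <- sweep(X, 2, m)
    rowSums((d %*% solve(C)) * d)
  }
  cbind(d1sq = qform(x, model$mean1, C1), d2sq = qform(x, model$mean2, C2))
}

#' Classify points with a discriminant model
#'
#' Nearest-class assignment by squared Mahalanobis distance; an exact tie
#' (d1^2 = d2^2) is assigned to the positive class.
#'
#' @inheritParams mahalanobis_sq
#' @param labels Length-2 character vector naming the positive and
#'   negative class (default `c("positive", "negative")`).
#' @return Character vector of class labels.
#' @export
classify <- function(model, x, labels = c("positive", "negative")) {
  d <- mahalanobis_sq(model, x)
  unname(ifelse(d[, "d1sq"] <= d[, "d2sq"], labels[1], labels[2]))
}

#' Confusion metrics
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' accuracy = (TP + TN) / total.
#'
#' @param predicted,actual Equal-length label vectors.
#' @param positive The positive-class label (default `"positive"`).
#' @return An object of class `confusion_metrics` with counts `tp`, `fp`,
#'   `fn`, `tn` and proportions `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(predicted, actual, positive = "positive") {
  if (length(predicted) != length(actual) || length(actual) == 0L) {
    stop("predicted and actual must be non-empty and of equal length",
         call. = FALSE)
  }
  p_pos <- predicted == positive
  a_pos <- actual == positive
  tp <- sum(p_pos & a_pos); fp <- sum(p_pos & !a_pos)
  fn <- sum(!p_pos & a_pos); tn <- sum(!p_pos & !a_pos)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / length(actual)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "tp %d fp %d fn %d tn %d | sensitivity %.1f%% specificity %.1f%% accuracy %.1f%%\n",
    x$tp, x$fp, x$fn, x$tn, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$accuracy))
  invisible(x)
}

# run `code` under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

prepare_feature_matrix <- function(features, parameter_pair, label_col,
                                   positive, verbose = TRUE) {
  if (!all(parameter_pair %in% names(features))) {
    stop("parameter column(s) not in table: ",
         paste(setdiff(parameter_pair, names(features)), collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[, parameter_pair, drop = FALSE])
  keep <- stats::complete.cases(X)
  if (any(!keep) && verbose) {
    message(sum(!keep), " cell(s) dropped: missing values in (",
            paste(parameter_pair, collapse = ", "), ")")
  }
  list(X = X[keep, , drop = FALSE],
       y = ifelse(features[[label_col]][keep] == positive,
                  "positive", "negative"))
}

#' Stratified k-fold cross-validation of a discriminant model
#'
#' Cells of each class are shuffled with the given seed and dealt into k
#' folds; each fold is held out once while the model is fitted on the
#' rest. Per-fold sensitivity, specificity, and accuracy are averaged.
#'
#' @param features Feature table (data frame) with a label column.
#' @param parameter_pair Character vector of feature columns (usually 2).
#' @param kind `"lda"` or `"qda"`.
#' @param k Number of folds (default 10); each class must have >= k cells.
#' @param seed Seed for the fold shuffle (default 0).
#' @param label_col Name of the label column (default `"group"`).
#' @param positive Label of the positive class.
#' @param verbose Report dropped rows.
#' @return List with `mean` (averaged metrics), `folds` (per-fold
#'   `confusion_metrics`), and `pooled` (metrics of the pooled held-out
#'   predictions).
#' @export
kfold_cv <- function(features, parameter_pair, kind = c("qda", "lda"),
                     k = 10, seed = 0, label_col = "group",
                     positive = "positive", verbose = TRUE) {
  kind <- match.arg(kind)
  pf <- prepare_feature_matrix(features, parameter_pair, label_col,
                               positive, verbose)
  X <- pf$X; y <- pf$y
  n_pos <- sum(y == "positive"); n_neg <- sum(y == "negative")
  if (min(n_pos, n_neg) < k) {
    stop2("fold_error",
          sprintf("each class needs >= k = %d cells (have %d and %d)",
                  k, n_pos, n_neg))
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in c("positive", "negative")) {
      idx <- which(y == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fit_fun <- if (kind == "lda") fit_lda else fit_qda
  preds <- character(length(y))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- fit_fun(X[tr & y == "positive", , drop = FALSE],
                 X[tr & y == "negative", , drop = FALSE],
                 parameters = parameter_pair)
    preds[!tr] <- classify(m, X[!tr, , drop = FALSE])
    folds[[f]] <- confusion_metrics(preds[!tr], y[!tr])
  }
  avg <- function(field) mean(vapply(folds, `[[`, numeric(1), field),
                              na.rm = TRUE)
  list(mean = list(sensitivity = avg("sensitivity"),
                   specificity = avg("specificity"),
                   accuracy = avg("accuracy")),
       folds = folds,
       pooled = confusion_metrics(preds, y))
}

#' Resubstitution metrics of a discriminant model
#'
#' Fits on the full table and evaluates on the same cells.
#'
#' @inheritParams kfold_cv
#' @return A `confusion_metrics`.
#' @export
resubstitution_metrics <- function(features, parameter_pair,
                                   kind = c("qda", "lda"),
                                   label_col = "group",
                                   positive = "positive", verbose = TRUE) {
  kind <- match.arg(kind)
  pf <- prepare_feature_matrix(features, parameter_pair, label_col,
                               positive, verbose)
  fit_fun <- if (kind == "lda") fit_lda else fit_qda
  m <- fit_fun(pf$X[pf$y == "positive", , drop = FALSE],
               pf$X[pf$y == "negative", , drop = FALSE],
               parameters = parameter_pair)
  confusion_metrics(classify(m, pf$X), pf$y)
}

#' Exhaustive search over parameter pairs
#'
#' Evaluates every unordered pair of the ten motility parameters (45
#' pairs) for each requested discriminant kind and ranks them by accuracy
#' (ties broken by sensitivity, then by pair name). By default pairs are
#' scored by stratified 10-fold cross-validation.
#'
#' @param features Feature table with a label column.
#' @param kinds Character vector among `"lda"`, `"qda"`.
#' @param columns Parameter columns to combine (default the ten motility
#'   parameters present in `features`).
#' @param method `"cv"` (default) or `"resubstitution"`.
#' @param k,seed Cross-validation settings.
#' @inheritParams kfold_cv
#' @return Data frame ranked by accuracy with columns `kind`,
#'   `parameter_1`, `parameter_2`, `sensitivity`, `specificity`,
#'   `accuracy`, `n_used`.
#' @export
pair_search <- function(features, kinds = c("lda", "qda"),
                        columns = intersect(motility_parameters(),
                                            names(features)),
                        method = c("cv", "resubstitution"),
                        k = 10, seed = 0, label_col = "group",
                        positive = "positive") {
  method <- match.arg(method)
  kinds <- match.arg(kinds, c("lda", "qda"), several.ok = TRUE)
  pairs <- utils::combn(sort(columns), 2)
  rows <- list()
  for (kind in kinds) {
    for (j in seq_len(ncol(pairs))) {
      pair <- pairs[, j]
      res <- tryCatch({
        if (method == "cv") {
          cv <- kfold_cv(features, pair, kind, k = k, seed = seed,
                         label_col = label_col, positive = positive,
                         verbose = FALSE)
          n_used <- sum(stats::complete.cases(features[, pair]))
          c(cv$mean$sensitivity, cv$mean$specificity, cv$mean$accuracy,
            n_used)
        } else {
          cm <- resubstitution_metrics(features, pair, kind,
                                       label_col = label_col,
                                       positive = positive, verbose = FALSE)
          c(cm$sensitivity, cm$specificity, cm$accuracy,
            cm$tp + cm$fp + cm$fn + cm$tn)
        }
      }, error = function(e) rep(NA_real_, 4))  # singular/degenerate pair
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, parameter_1 = pair[1], parameter_2 = pair[2],
        sensitivity = res[1], specificity = res[2], accuracy = res[3],
        n_used = res[4], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, -out$sensitivity,
                   out$parameter_1, out$parameter_2), ]
  rownames(out) <- NULL
  out
}

#' Sample a discrimination boundary
#'
#' Evaluates d1^2 - d2^2 on a grid over the two-parameter plane and
#' extracts the zero-level contour as polylines, for plotting the LDA/QDA
#' decision boundary over a scatter of cells.
#'
#' @param model A two-parameter `discriminant_model`.
#' @param xlim,ylim Plot ranges for the first and second parameter.
#' @param n Grid resolution per axis (default 201).
#' @return Data frame with columns `piece`, `x`, `y` describing the
#'   boundary polylines.
#' @export
discrimination_boundary <- function(model, xlim, ylim, n = 201) {
  stopifnot(length(model$mean1) == 2L)
  gx <- seq(xlim[1], xlim[2], length.out = n)
  gy <- seq(ylim[1], ylim[2], length.out = n)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  d <- mahalanobis_sq(model, grid)
  z <- matrix(d[, "d1sq"] - d[, "d2sq"], nrow = n)
  cl <- grDevices::contourLines(gx, gy, z, levels = 0)
  if (length(cl) == 0L) {
    return(data.frame(piece = integer(), x = numeric(), y = numeric()))
  }
  do.call(rbind, lapply(seq_along(cl), function(i) {
    data.frame(piece = i, x = cl[[i]]$x, y = cl[[i]]$y)
  }))
}
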