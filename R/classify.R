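#' Chi-square feature scores
#'
#' For nonnegative features, scores each column by the chi-square statistic
#' between observed per-class feature mass and its expectation under class
#' balance: `O[c, j]` is the sum of feature `j` over class-`c` samples and
#' `E[c, j] = (n_c / n) * sum_j`, giving
#' `score_j = sum_c (O[c,j] - E[c,j])^2 / E[c,j]`. Features with zero total
#' mass score 0.
#'
#' @param x Nonnegative numeric matrix or data frame (samples x features).
#' @param y Class labels (length `nrow(x)`).
#' @return Numeric score vector, one per column.
#' @export
chi2_scores <- function(x, y) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("chi-square scoring requires nonnegative features", call. = FALSE)
  stopifnot(nrow(x) == length(y))
  y <- as.factor(y)
  O <- rowsum(x, y)                       # classes x features
  share <- as.numeric(table(y)) / length(y)
  totals <- colSums(x)
  E <- outer(share, totals)
  term <- (O - E)^2 / E
  term[E == 0] <- 0
  colSums(term)
}

#' Chi-square percentile feature selection
#'
#' Keeps the top `percentile` percent of feature columns by [chi2_scores()]
#' (`ceiling(percentile / 100 * ncol(x))` columns, at least one), with ties
#' broken stably by column index.
#'
#' @inheritParams chi2_scores
#' @param percentile Percentage of features to keep, in `(0, 100]`.
#' @return Sorted integer vector of retained column indices.
#' @export
select_features_chi2 <- function(x, y, percentile = 100) {
  stopifnot(percentile > 0, percentile <= 100)
  scores <- chi2_scores(x, y)
  k <- max(1L, ceiling(percentile / 100 * length(scores)))
  sort(order(-scores, seq_along(scores))[seq_len(k)])
}

#' One-vs-rest linear SVM classification
#'
#' Fits one binary hinge-loss linear support vector machine per class
#' (penalty parameter `C`, no feature scaling) and predicts by the argmax of
#' the per-class decision scores, which are also returned for biometric
#' score analysis.
#'
#' @param train_x Training feature matrix (samples x features).
#' @param train_y Training class labels (>= 2 distinct classes, >= 1 sample
#'   each).
#' @param test_x Test feature matrix.
#' @param C Penalty parameter, default 2.4.
#' @return List of class `ovr_svm_result` with `labels` (predicted class for
#'   each test row), `scores` (test x classes decision-score matrix with
#'   class names as columns) and `classes`.
#' @export
fit_predict_linear_ovr <- function(train_x, train_y, test_x, C = 2.4) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  classes <- sort(unique(train_y))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  scores <- matrix(NA_real_, nrow(test_x), length(classes),
                   dimnames = list(NULL, as.character(classes)))
  for (ci in seq_along(classes)) {
    yy <- factor(ifelse(train_y == classes[ci], "pos", "neg"),
                 levels = c("pos", "neg"))
    fit <- e1071::svm(train_x, yy, kernel = "linear", cost = C,
                      scale = FALSE, type = "C-classification")
    pr <- stats::predict(fit, test_x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient so positive score means "belongs to this class"
    if (colnames(dv)[1] == "neg/pos") dv <- -dv
    scores[, ci] <- dv[, 1]
  }
  labels <- classes[max.col(scores, ties.method = "first")]
  structure(list(labels = labels, scores = scores, classes = classes),
            class = "ovr_svm_result")
}

#' Biometric verification metrics
#'
#' Computes identification accuracy and the verification error trade-off
#' from a one-vs-rest decision-score matrix. Each sample's true-class score
#' is a genuine score; all its other-class scores are impostor scores. A
#' decision threshold is swept over the pooled score range; at each value
#' the false acceptance rate is the fraction of impostor scores at or above
#' the threshold and the false rejection rate the fraction of genuine
#' scores below it. The equal error rate (EER) is the point where the two
#' curves cross, linearly interpolated between bracketing thresholds.
#'
#' @param scores Numeric matrix (samples x classes) of decision scores with
#'   class names as column names, or an `ovr_svm_result`.
#' @param y_true True class labels.
#' @return A `vein_metrics` object: list with `accuracy` (percent), `eer`
#'   (percent), `eer_threshold`, `sweep` (tibble of threshold/FAR/FRR),
#'   `genuine`, `impostor`, `predicted`.
#' @export
compute_metrics <- function(scores, y_true) {
  if (inherits(scores, "ovr_svm_result")) scores <- scores$scores
  stopifnot(is.matrix(scores), nrow(scores) == length(y_true))
  if (is.null(colnames(scores))) stop("score matrix needs class column names", call. = FALSE)
  true_col <- match(as.character(y_true), colnames(scores))
  if (anyNA(true_col)) stop("labels absent from score columns", call. = FALSE)
  predicted <- colnames(scores)[max.col(scores, ties.method = "first")]
  accuracy <- 100 * mean(predicted == as.character(y_true))
  genuine <- scores[cbind(seq_len(nrow(scores)), true_col)]
  impostor <- scores[-(seq_len(nrow(scores)) + (true_col - 1) * nrow(scores))]
  if (length(genuine) == 0 || length(impostor) == 0) {
    stop("empty genuine or impostor score set", call. = FALSE)
  }
  sweep_tbl <- far_frr_sweep(genuine, impostor)
  eer <- interpolate_eer(sweep_tbl)
  structure(list(accuracy = accuracy, eer = eer$eer,
                 eer_threshold = eer$threshold, sweep = sweep_tbl,
                 genuine = genuine, impostor = impostor,
                 predicted = predicted),
            class = "vein_metrics")
}

# FAR/FRR at every pooled score value (plus a bracket below the minimum)
far_frr_sweep <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  thr <- c(thr[1] - 1, thr)
  gs <- sort(genuine); is <- sort(impostor)
  fr <- findInterval(thr, gs, left.open = TRUE)     # genuine < thr
  fa <- length(is) - findInterval(thr, is, left.open = TRUE)  # impostor >= thr
  tibble::tibble(threshold = thr,
                 far = fa / length(is),
                 frr = fr / length(gs))
}

interpolate_eer <- function(sweep_tbl) {
  d <- sweep_tbl$far - sweep_tbl$frr     # non-increasing, from +1-ish to -1-ish
  ix <- which(d <= 0)[1]
  if (is.na(ix)) return(list(eer = 100 * sweep_tbl$far[nrow(sweep_tbl)],
                             threshold = sweep_tbl$threshold[nrow(sweep_tbl)]))
  if (d[ix] == 0 || ix == 1) {
    return(list(eer = 100 * sweep_tbl$far[ix], threshold = sweep_tbl$threshold[ix]))
  }
  i0 <- ix - 1
  t <- d[i0] / (d[i0] - d[ix])
  eer <- sweep_tbl$far[i0] + t * (sweep_tbl$far[ix] - sweep_tbl$far[i0])
  thr <- sweep_tbl$threshold[i0] + t * (sweep_tbl$threshold[ix] - sweep_tbl$threshold[i0])
  list(eer = 100 * eer, threshold = thr)
}

#' @export
print.vein_metrics <- function(x, ...) {
  cat(sprintf("<vein_metrics> accuracy %.2f%%, EER %.2f%% (%d genuine / %d impostor scores)\n",
              x$accuracy, x$eer, length(x$genuine), length(x$impostor)))
  invisible(x)
}

#' End-to-end recognition pipeline on a labeled image dataset
#'
#' Trains the spiking network on the training partition (labels unused
#' during feature learning), extracts binary spike features for both
#' partitions, optionally applies chi-square percentile feature selection,
#' fits the one-vs-rest linear SVM and evaluates biometric metrics on the
#' test partition.
#'
#' @param data Tibble with `class`, `sample`, `image` and `split` columns
#'   (see [split_dataset()]).
#' @param cfg An [atsnn_config()].
#' @param C SVM penalty parameter, default 2.4.
#' @param percentile Feature-selection percentile, default 100 (keep all).
#' @param verbose Print progress.
#' @return List with `model`, `metrics` (a `vein_metrics`), `result`
#'   (the `ovr_svm_result`), `features` (list of train/test matrices) and
#'   `selected` (retained feature indices).
#' @export
run_recognition_pipeline <- function(data, cfg = atsnn_config(), C = 2.4,
                                     percentile = 100, verbose = FALSE) {
  stopifnot("split" %in% names(data))
  train <- data[data$split == "train", ]
  test <- data[data$split == "test", ]
  if (nrow(train) == 0 || nrow(test) == 0) stop("both splits must be nonempty", call. = FALSE)
  model <- train_layerwise(train, cfg, verbose = verbose)
  if (verbose) message("extracting features")
  xtr <- extract_feature_matrix(train, model)
  xte <- extract_feature_matrix(test, model)
  sel <- select_features_chi2(xtr, train$class, percentile)
  res <- fit_predict_linear_ovr(xtr[, sel, drop = FALSE], train$class,
                                xte[, sel, drop = FALSE], C = C)
  metrics <- compute_metrics(res, test$class)
  list(model = model, metrics = metrics, result = res,
       features = list(train = xtr, test = xte), selected = sel)
}
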