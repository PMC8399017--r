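# Ordinal severity classification (MDS-UPDRS gait item, scores 0-3) by
# binary decomposition: three probabilistic classifiers estimate
# P(y > 0), P(y > 1), P(y > 2), and class probabilities are differences of
# adjacent cumulative probabilities after monotonicity clipping.

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances every class up to the majority count by interpolating between a
#' randomly chosen minority sample and one of its `k` nearest same-class
#' neighbours (Euclidean distance in feature space): each synthetic point is
#' `x + u (x' - x)` with `u ~ U(0, 1)`.
#'
#' @param x numeric matrix or data.frame of features.
#' @param y class labels (coerced to factor).
#' @param k number of nearest neighbours; default 5. Every class that needs
#'   up-sampling must have at least `k + 1` members.
#' @return list with the augmented `x` (matrix) and `y` (factor); original
#'   rows come first.
#' @export
smote_balance <- function(x, y, k = 5L) {
  x <- as.matrix(x)
  y <- factor(y)
  counts <- table(y)
  target <- max(counts)
  xs <- list(x)
  ys <- list(y)
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0L) next
    if (counts[[cls]] < k + 1L) {
      stop(sprintf(
        "SMOTE: class '%s' has only %d samples, fewer than k + 1 = %d; use a smaller k",
        cls, counts[[cls]], k + 1L))
    }
    xc <- x[y == cls, , drop = FALSE]
    m <- nrow(xc)
    dm <- as.matrix(dist(xc))
    # k nearest same-class neighbours of each row, excluding itself
    knn <- t(apply(dm, 1L, function(row) order(row)[2:(k + 1L)]))
    base <- sample.int(m, need, replace = TRUE)
    nb <- knn[cbind(base, sample.int(k, need, replace = TRUE))]
    u <- runif(need)
    xs[[length(xs) + 1L]] <- xc[base, , drop = FALSE] +
      u * (xc[nb, , drop = FALSE] - xc[base, , drop = FALSE])
    ys[[length(ys) + 1L]] <- factor(rep(cls, need), levels = levels(y))
  }
  list(x = do.call(rbind, xs), y = factor(unlist(lapply(ys, as.character)),
                                          levels = levels(y)))
}

.as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (any(!is.finite(x))) stop("features must be finite")
  x
}

#' Train the ordinal gait severity model
#'
#' The four-class training set is first balanced with [smote_balance()] on
#' the 4-class labels, then three binary random forests are trained on the
#' binarised labels y > 0, y > 1 and y > 2. All randomness (oversampling and
#' forest growth) derives from `seed`, so training is reproducible.
#'
#' @param features ROI-level feature table (rows = ROIs, columns in
#'   [GAIT_FEATURES] order or any fixed order).
#' @param labels integer severity ratings in 0-3, one per row.
#' @param groups optional video identifiers (stored for bookkeeping; ROIs of
#'   one video are treated as independent samples at training time).
#' @param seed integer seed controlling all randomness.
#' @param ntree trees per forest; default 500.
#' @param smote_k SMOTE neighbour count; default 5. Set `oversample = FALSE`
#'   to skip balancing.
#' @param oversample apply SMOTE before training; default TRUE.
#' @param ... further arguments to [randomForest::randomForest()] (e.g.
#'   `maxnodes`).
#' @return an object of class `ordinal_gait_model`.
#' @export
train_ordinal_model <- function(features, labels, groups = NULL, seed = 1L,
                                ntree = 500L, smote_k = 5L,
                                oversample = TRUE, ...) {
  x <- .as_feature_matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(x)) stop("labels must match feature rows")
  if (!all(y %in% 0:3)) stop("labels must be severity ratings in {0,1,2,3}")
  set.seed(seed)
  if (oversample) {
    bal <- smote_balance(x, factor(y, levels = 0:3), k = smote_k)
    xb <- bal$x
    yb <- as.integer(as.character(bal$y))
  } else {
    xb <- x
    yb <- y
  }
  classifiers <- lapply(0:2, function(th) {
    randomForest::randomForest(
      x = as.data.frame(xb),
      y = factor(as.integer(yb > th), levels = 0:1),
      ntree = ntree, ...)
  })
  structure(
    list(classifiers = classifiers,
         thresholds = 0:2,
         feature_names = colnames(x),
         seed = seed,
         ntree = ntree,
         oversample = oversample,
         smote_k = smote_k,
         n_train = nrow(x),
         groups = groups),
    class = "ordinal_gait_model"
  )
}

#' @export
print.ordinal_gait_model <- function(x, ...) {
  cat(sprintf(
    "<ordinal_gait_model> 3 binary forests (%d trees), features: %s\n",
    x$ntree, paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Compose four class probabilities from the three cumulative probabilities
#'
#' Given q1 = P(y > 0), q2 = P(y > 1), q3 = P(y > 2) from the three binary
#' classifiers, monotonicity is enforced by cumulative clipping
#' (q2 <- min(q2, q1); q3 <- min(q3, q2)), after which
#' p0 = 1 - q1, p1 = q1 - q2, p2 = q2 - q3, p3 = q3. The result is always a
#' valid probability distribution (non-negative, summing to one), whatever
#' the raw classifier outputs.
#'
#' @param q numeric vector of length 3 with entries in \[0, 1\].
#' @return named numeric vector `p0..p3`.
#' @export
compose_ordinal_probs <- function(q) {
  stopifnot(length(q) == 3L)
  q <- cummin(pmin(pmax(as.numeric(q), 0), 1))
  c(p0 = 1 - q[1L], p1 = q[1L] - q[2L], p2 = q[2L] - q[3L], p3 = q[3L])
}

.cumulative_probs <- function(model, newdata) {
  nd <- as.data.frame(newdata)
  colnames(nd) <- model$feature_names
  vapply(model$classifiers, function(cl) {
    as.numeric(predict(cl, nd, type = "prob")[, "1"])
  }, numeric(nrow(nd)))
}

#' Per-ROI class probabilities from the ordinal model
#'
#' @param model a trained [train_ordinal_model()].
#' @param newdata feature matrix/data.frame (rows = ROIs) or a single named
#'   feature vector.
#' @return matrix with one row per input row and columns `p0..p3`.
#' @export
predict_ordinal_proba <- function(model, newdata) {
  stopifnot(inherits(model, "ordinal_gait_model"))
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  q <- .cumulative_probs(model, newdata)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  out <- t(apply(q, 1L, compose_ordinal_probs))
  colnames(out) <- paste0("p", 0:3)
  out
}

#' @param object,... standard predict-method arguments; `type = "prob"`
#'   returns the probability matrix, `type = "class"` the argmax severity
#'   (ties resolved toward the lower severity).
#' @rdname predict_ordinal_proba
#' @export
predict.ordinal_gait_model <- function(object, newdata,
                                       type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_ordinal_proba(object, newdata)
  if (type == "prob") return(p)
  apply(p, 1L, which.max) - 1L
}

#' Aggregate ROI-level probabilities into a video-level prediction
#'
#' Element-wise arithmetic mean of the ROI probability vectors, renormalised;
#' the predicted label is the argmax with ties broken toward the lower
#' (clinically conservative) severity.
#'
#' @param roi_probs matrix with columns `p0..p3` (one row per ROI), or a list
#'   of probability vectors.
#' @return list with `probs` (named numeric) and `label` (integer 0-3).
#' @export
aggregate_video_prediction <- function(roi_probs) {
  if (is.list(roi_probs) && !is.data.frame(roi_probs)) {
    roi_probs <- do.call(rbind, roi_probs)
  }
  roi_probs <- as.matrix(roi_probs)
  if (nrow(roi_probs) == 0L) stop("no ROI predictions to aggregate")
  p <- colMeans(roi_probs)
  p <- p / sum(p)
  names(p) <- paste0("p", 0:3)
  list(probs = p, label = as.integer(which.max(p) - 1L))
}

# Stratified allocation of videos to folds: within each class the (shuffled)
# videos are dealt round-robin, with a rotating starting fold so overall
# fold sizes also balance. Guarantees per-class fold counts within +/- 1 of
# proportional and never splits a video across folds.
.assign_video_folds <- function(video_labels, k) {
  vids <- names(video_labels)
  fold <- setNames(integer(length(vids)), vids)
  offset <- 0L
  for (cls in sort(unique(video_labels))) {
    members <- sample(vids[video_labels == cls])
    f <- ((seq_along(members) - 1L + offset) %% k) + 1L
    fold[members] <- f
    offset <- (offset + length(members)) %% k
  }
  fold
}

.video_label_table <- function(labels, groups) {
  groups <- as.character(groups)
  vl <- tapply(as.integer(labels), groups, function(v) {
    if (length(unique(v)) != 1L) {
      stop("inconsistent labels within a video group")
    }
    v[1L]
  })
  setNames(as.integer(vl), names(vl))
}

#' Grouped, stratified k-fold cross-validation
#'
#' Folds partition *videos*, never ROIs: both ROIs of a video always land in
#' the same fold, preventing information leakage between training and test
#' data. Fold allocation is stratified on the video-level label (per-class
#' fold counts within one video of proportional). Each fold's model is
#' trained with [train_ordinal_model()] on all out-of-fold ROIs and
#' predicts the held-out ROIs, which are then aggregated per video with
#' [aggregate_video_prediction()].
#'
#' @param features ROI-level feature table.
#' @param labels per-ROI severity ratings 0-3.
#' @param groups per-ROI video identifiers.
#' @param k number of folds; default 10.
#' @param seed controls fold allocation and per-fold training randomness.
#' @param ... passed to [train_ordinal_model()] (e.g. `ntree`, `smote_k`).
#' @return list with `video` (data.frame: video_id, label, p0..p3,
#'   predicted), `folds` (named fold assignment), and `metrics`
#'   ([compute_metrics()] on the video-level predictions).
#' @export
grouped_stratified_cv <- function(features, labels, groups, k = 10L,
                                  seed = 1L, ...) {
  x <- .as_feature_matrix(features)
  y <- as.integer(labels)
  groups <- as.character(groups)
  stopifnot(length(y) == nrow(x), length(groups) == nrow(x))
  video_labels <- .video_label_table(y, groups)
  if (length(video_labels) < k) stop("fewer videos than folds")
  set.seed(seed)
  folds <- .assign_video_folds(video_labels, k)
  roi_fold <- folds[groups]
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- roi_fold == f
    if (!any(test)) next
    model <- train_ordinal_model(x[!test, , drop = FALSE], y[!test],
                                 seed = seed + f, ...)
    probs <- predict_ordinal_proba(model, x[test, , drop = FALSE])
    test_groups <- groups[test]
    per_video <- lapply(split(seq_len(nrow(probs)), test_groups), function(i) {
      agg <- aggregate_video_prediction(probs[i, , drop = FALSE])
      c(agg$probs, predicted = agg$label)
    })
    rows[[f]] <- data.frame(
      video_id = names(per_video),
      label = video_labels[names(per_video)],
      do.call(rbind, per_video),
      row.names = NULL
    )
  }
  video <- do.call(rbind, rows)
  video <- video[order(video$video_id), , drop = FALSE]
  rownames(video) <- NULL
  list(video = video,
       folds = folds,
       metrics = compute_metrics(video$label, video$predicted))
}

#' Classification metrics for ordinal severity predictions
#'
#' Balanced accuracy is the mean per-class recall. `accuracy_within_1` (and
#' `_2`) is the proportion of absolute residuals at most 1 (2), reflecting
#' that trained raters commonly differ by one point. Binary sensitivity and
#' specificity group the Parkinsonian ratings {1,2,3} as the positive class
#' against the non-Parkinsonian rating {0}.
#'
#' @param labels true ratings 0-3.
#' @param predictions predicted ratings 0-3, same length.
#' @return list with accuracy, balanced_accuracy, accuracy_within_1,
#'   accuracy_within_2, sensitivity, specificity, spearman_rho, and the
#'   4x4 `confusion` matrix (rows = true, columns = predicted).
#' @export
compute_metrics <- function(labels, predictions) {
  y <- as.integer(labels)
  p <- as.integer(predictions)
  if (length(y) == 0L || length(y) != length(p)) {
    stop("labels and predictions must be non-empty and aligned")
  }
  resid <- abs(y - p)
  recall <- vapply(sort(unique(y)), function(cls) {
    mean(p[y == cls] == cls)
  }, numeric(1))
  pos <- y > 0
  list(
    accuracy = mean(y == p),
    balanced_accuracy = mean(recall),
    accuracy_within_1 = mean(resid <= 1L),
    accuracy_within_2 = mean(resid <= 2L),
    sensitivity = if (any(pos)) mean(p[pos] > 0) else NA_real_,
    specificity = if (any(!pos)) mean(p[!pos] == 0) else NA_real_,
    spearman_rho = suppressWarnings(cor(y, p, method = "spearman")),
    confusion = table(true = factor(y, levels = 0:3),
                      predicted = factor(p, levels = 0:3))
  )
}

#' Label-permutation test of the cross-validated balanced accuracy
#'
#' Video-level labels are permuted across videos (both ROIs of a video keep
#' a common label) and the full grouped, stratified cross-validation is
#' re-run for every permutation. The two-sided p-value doubles the smaller
#' of the two one-sided permutation tail probabilities, each computed with
#' the add-one rule `(1 + #{extreme}) / (n_perm + 1)`, and caps at 1.
#'
#' @param features,labels,groups as in [grouped_stratified_cv()].
#' @param n_perm number of permutations (>= 1); default 1000.
#' @param k folds; default 10.
#' @param seed controls the observed CV, the permutations, and each
#'   permutation's CV.
#' @param ... passed to [grouped_stratified_cv()] (e.g. `ntree`).
#' @return list with `p_value` (two-sided), `p_upper`, `p_lower`,
#'   `observed` balanced accuracy, and the vector of permuted balanced
#'   accuracies.
#' @export
permutation_test <- function(features, labels, groups, n_perm = 1000L,
                             k = 10L, seed = 1L, ...) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be a positive integer")
  groups <- as.character(groups)
  obs <- grouped_stratified_cv(features, labels, groups, k = k,
                               seed = seed, ...)$metrics$balanced_accuracy
  video_labels <- .video_label_table(labels, groups)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919L * b)
    shuffled <- setNames(sample(unname(video_labels)), names(video_labels))
    perm_labels <- shuffled[groups]
    perm[b] <- grouped_stratified_cv(features, perm_labels, groups, k = k,
                                     seed = seed + b, ...)$metrics$balanced_accuracy
  }
  tol <- 1e-12
  p_upper <- (1 + sum(perm >= obs - tol)) / (n_perm + 1)
  p_lower <- (1 + sum(perm <= obs + tol)) / (n_perm + 1)
  list(p_value = min(1, 2 * min(p_upper, p_lower)),
       p_upper = p_upper,
       p_lower = p_lower,
       observed = obs,
       permuted = perm)
}
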