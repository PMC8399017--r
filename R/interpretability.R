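# Per-prediction explanation artefacts: eccentricity tables, exact Shapley
# decompositions of the three binary sub-classifiers, and impurity
# importances.

#' Eccentricity table of a feature vector against a rated reference cohort
#'
#' Entry (i, s) is the proportion of severity-s reference values of feature
#' i that are less than or equal to the query value (ties count): the
#' empirical CDF of the severity stratum evaluated at the query. A value of
#' 0.5 means the patient sits at the centre of that stratum's distribution;
#' 0 or 1 mean the value is extreme for that stratum. Being a rank
#' statistic, the table is invariant under any strictly increasing
#' transformation applied jointly to a feature's reference and query values.
#'
#' @param x named numeric feature vector (the query, e.g. one ROI or video).
#' @param reference data.frame/matrix of reference feature values with the
#'   same columns as `x`.
#' @param ratings severity rating (0-3) of each reference row; every
#'   severity stratum must be non-empty.
#' @return an `eccentricity_table`: numeric matrix, rows = features,
#'   columns = severities `"0".."3"`, entries in \[0, 1\].
#' @export
compute_eccentricity_table <- function(x, reference, ratings) {
  reference <- as.data.frame(reference)
  if (is.null(names(x))) names(x) <- colnames(reference)
  feats <- names(x)
  if (!all(feats %in% colnames(reference))) {
    stop("reference is missing feature column(s): ",
         paste(setdiff(feats, colnames(reference)), collapse = ", "))
  }
  ratings <- as.integer(ratings)
  stopifnot(length(ratings) == nrow(reference))
  C <- matrix(NA_real_, length(feats), 4L,
              dimnames = list(feats, as.character(0:3)))
  for (s in 0:3) {
    stratum <- reference[ratings == s, feats, drop = FALSE]
    if (nrow(stratum) == 0L) {
      stop(sprintf("reference has no samples with severity %d", s))
    }
    for (i in seq_along(feats)) {
      C[i, s + 1L] <- mean(stratum[[feats[i]]] <= x[[feats[i]]])
    }
  }
  class(C) <- c("eccentricity_table", class(C))
  C
}

#' Shading matrix for an eccentricity table
#'
#' Maps each CDF position to a darkness in \[0, 1\] by linear distance from
#' the distribution centre: `1 - 2 |C - 0.5|`. Central (typical) values are
#' darkest (1); extreme values are lightest (0). A patient typical of one
#' severity shows a dark column at that severity.
#'
#' @param C an [compute_eccentricity_table()] result.
#' @return matrix of the same shape with entries in \[0, 1\].
#' @export
shade_eccentricity <- function(C) {
  out <- 1 - 2 * abs(unclass(C) - 0.5)
  out
}

#' Exact Shapley values of a prediction function
#'
#' Computes exact Shapley attributions for a single input `x` under the
#' interventional value function `v(S) = mean_b f(x_S, b_(-S))`, where the
#' expectation runs over the rows of `background`. All `2^p` feature
#' coalitions are enumerated, which is exact and fast for the six gait
#' features. By construction `base_value + sum(attributions)` equals `f(x)`
#' up to floating-point error.
#'
#' @param f vectorised prediction function: takes a numeric matrix with the
#'   columns of `x`, returns one number per row.
#' @param x named numeric vector (one input).
#' @param background matrix/data.frame of reference rows defining the
#'   marginal expectations.
#' @return list with `base_value` (v of the empty coalition), `attributions`
#'   (named numeric, one per feature) and `prediction` (`f(x)`).
#' @export
shapley_values <- function(f, x, background) {
  x <- unlist(x)
  p <- length(x)
  if (p > 15L) stop("exact coalition enumeration supports at most 15 features")
  bg <- as.matrix(background)
  if (ncol(bg) != p) stop("background must have one column per feature")
  colnames(bg) <- names(x)
  nb <- nrow(bg)
  n_masks <- bitwShiftL(1L, p)
  masks <- 0:(n_masks - 1L)
  # one big prediction batch: background copies with coalition columns
  # replaced by x
  X <- bg[rep(seq_len(nb), times = n_masks), , drop = FALSE]
  for (j in seq_len(p)) {
    has_j <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L
    rows <- rep(has_j, each = nb)
    X[rows, j] <- x[j]
  }
  preds <- f(X)
  v <- rowsum(preds, rep(masks, each = nb))[, 1L] / nb
  sizes <- vapply(masks, function(m) {
    sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) > 0L)
  }, numeric(1))
  w <- numeric(length(sizes))  # weight of the full coalition is never used
  partial <- sizes < p
  w[partial] <- factorial(sizes[partial]) *
    factorial(p - sizes[partial] - 1L) / factorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- bitwAnd(masks, bit) == 0L
    m0 <- masks[without]
    phi[j] <- sum(w[without] * (v[as.character(m0 + bit)] - v[as.character(m0)]))
  }
  names(phi) <- names(x)
  list(base_value = unname(v[["0"]]),
       attributions = phi,
       prediction = unname(v[[as.character(n_masks - 1L)]]))
}

#' Shapley decomposition of an ordinal model prediction
#'
#' One exact Shapley record per binary sub-classifier, explaining its
#' predicted cumulative probability q = P(y > threshold) for the input. The
#' background expectation uses the supplied feature table (typically the
#' training set); tables larger than `max_background` rows are thinned to
#' evenly spaced rows for speed, deterministically.
#'
#' @param model a trained [train_ordinal_model()].
#' @param x named feature vector for one ROI/video.
#' @param background reference feature table.
#' @param max_background cap on background rows; default 100.
#' @return list of three records (classifiers `y>0`, `y>1`, `y>2`), each as
#'   returned by [shapley_values()].
#' @export
shap_decompose <- function(model, x, background, max_background = 100L) {
  stopifnot(inherits(model, "ordinal_gait_model"))
  bg <- .as_feature_matrix(background)[, model$feature_names, drop = FALSE]
  if (nrow(bg) > max_background) {
    keep <- unique(round(seq(1L, nrow(bg), length.out = max_background)))
    bg <- bg[keep, , drop = FALSE]
  }
  x <- unlist(x)[model$feature_names]
  out <- lapply(model$classifiers, function(cl) {
    f <- function(X) {
      nd <- as.data.frame(X)
      colnames(nd) <- model$feature_names
      as.numeric(predict(cl, nd, type = "prob")[, "1"])
    }
    shapley_values(f, x, bg)
  })
  names(out) <- paste0("y_gt_", 0:2)
  out
}

#' Impurity-based (Gini) feature importance of the three sub-classifiers
#'
#' For each binary random forest, the normalised total reduction of Gini
#' impurity attributable to splits on each feature: non-negative and
#' summing to one per sub-classifier.
#'
#' @param model a trained [train_ordinal_model()] with random-forest
#'   sub-models.
#' @return named list of three named numeric vectors.
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "ordinal_gait_model"))
  out <- lapply(model$classifiers, function(cl) {
    if (!inherits(cl, "randomForest")) {
      stop("gini_importance requires tree-based (random forest) sub-models")
    }
    imp <- cl$importance[, "MeanDecreaseGini"]
    total <- sum(imp)
    if (total <= 0) {
      rep(1 / length(imp), length(imp))
    } else {
      imp / total
    }
  })
  names(out) <- paste0("y_gt_", 0:2)
  out
}

#' Full explanation report for one prediction
#'
#' Bundles the class probabilities, eccentricity table with shading, and the
#' three Shapley records into one list, ready for JSON export.
#'
#' @param model trained ordinal model.
#' @param x named feature vector.
#' @param reference rated reference feature table.
#' @param ratings severities of the reference rows.
#' @return list with `probs`, `label`, `eccentricity`, `shading`, `shap`.
#' @export
explain_prediction <- function(model, x, reference, ratings) {
  p <- predict_ordinal_proba(model, x)[1L, ]
  C <- compute_eccentricity_table(unlist(x)[model$feature_names],
                                  reference, ratings)
  list(probs = p,
       label = as.integer(which.max(p) - 1L),
       eccentricity = unclass(C),
       shading = shade_eccentricity(C),
       shap = shap_decompose(model, x, reference))
}
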