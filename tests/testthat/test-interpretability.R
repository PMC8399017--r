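# Eccentricity tables, exact Shapley decompositions and Gini importances.

# independent double-loop oracle for the eccentricity table
ecc_oracle <- function(x, reference, ratings) {
  C <- matrix(NA_real_, length(x), 4)
  for (i in seq_along(x)) {
    for (s in 0:3) {
      vals <- reference[ratings == s, i]
      hits <- 0L
      for (v in vals) if (x[i] >= v) hits <- hits + 1L
      C[i, s + 1] <- hits / length(vals)
    }
  }
  C
}

ref_table <- function(n = 50, seed = 3) {
  set.seed(seed)
  reference <- matrix(rnorm(n * 6), ncol = 6,
                      dimnames = list(NULL, GAIT_FEATURES))
  ratings <- rep_len(0:3, n)
  list(reference = reference, ratings = ratings)
}

test_that("eccentricity entries are stratum-wise empirical CDF positions", {
  r <- ref_table()
  x <- setNames(rnorm(6), GAIT_FEATURES)
  C <- compute_eccentricity_table(x, r$reference, r$ratings)
  expect_equal(unclass(C), ecc_oracle(x, r$reference, r$ratings),
               ignore_attr = TRUE)
  expect_true(all(C >= 0 & C <= 1))
  # saturation at the extremes of a stratum
  x_hi <- setNames(rep(1e6, 6), GAIT_FEATURES)
  expect_true(all(compute_eccentricity_table(x_hi, r$reference, r$ratings) == 1))
  x_lo <- setNames(rep(-1e6, 6), GAIT_FEATURES)
  expect_true(all(compute_eccentricity_table(x_lo, r$reference, r$ratings) == 0))
})

test_that("ties count as covered and known small cases check out", {
  reference <- matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 16, ncol = 6,
                      dimnames = list(NULL, GAIT_FEATURES))
  ratings <- rep_len(0:3, 16)
  x <- setNames(rep(2, 6), GAIT_FEATURES)
  C <- compute_eccentricity_table(x, reference, ratings)
  expect_true(all(C == 0.5))  # {1,2,3,4} vs 2, ties included: 2/4
  expect_error(
    compute_eccentricity_table(x, reference[ratings != 3, ], ratings[ratings != 3]),
    "severity 3")
})

test_that("eccentricity is invariant under increasing feature transforms", {
  r <- ref_table(seed = 9)
  x <- setNames(rnorm(6), GAIT_FEATURES)
  C1 <- compute_eccentricity_table(x, r$reference, r$ratings)
  ref2 <- r$reference
  ref2[, 3] <- exp(ref2[, 3])
  x2 <- x
  x2[3] <- exp(x2[3])
  C2 <- compute_eccentricity_table(x2, ref2, r$ratings)
  expect_equal(C1, C2)
})

test_that("shading darkens the centre and lightens the extremes linearly", {
  C <- matrix(c(0.5, 0, 1, 0.75), 2, 2)
  expect_equal(shade_eccentricity(C), matrix(c(1, 0, 0, 0.5), 2, 2))
})

test_that("exact Shapley values match the closed form for linear models", {
  set.seed(2)
  bg <- matrix(rnorm(40 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- c(a = 1.5, b = -0.5, c = 2)
  f <- function(X) 2 * X[, 1] - 3 * X[, 2] + 0.5 * X[, 3] + 1
  sh <- shapley_values(f, x, bg)
  coef <- c(2, -3, 0.5)
  expect_equal(sh$attributions, setNames(coef * (x - colMeans(bg)), names(x)),
               tolerance = 1e-10)
  expect_equal(sh$base_value, mean(f(bg)), tolerance = 1e-10)
  expect_equal(sh$prediction, f(rbind(x))[1], tolerance = 1e-10)
  # a constant function attributes nothing
  sh0 <- shapley_values(function(X) rep(3.3, nrow(X)), x, bg)
  expect_equal(unname(sh0$attributions), c(0, 0, 0))
})

test_that("duplicating a feature splits its attribution, sum preserved", {
  set.seed(3)
  bg <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "a"))
  x <- c(a = 1.2)
  f <- function(X) 3 * X[, 1]
  phi <- shapley_values(f, x, bg)$attributions
  bg2 <- cbind(a1 = bg[, 1], a2 = bg[, 1])
  x2 <- c(a1 = 1.2, a2 = 1.2)
  f2 <- function(X) 1.5 * X[, 1] + 1.5 * X[, 2]
  phi2 <- shapley_values(f2, x2, bg2)$attributions
  expect_equal(sum(phi2), unname(phi["a"]), tolerance = 1e-10)
  expect_equal(phi2[["a1"]], phi2[["a2"]], tolerance = 1e-10)
})

# independent permutation-enumeration Shapley oracle
shapley_perm_oracle <- function(f, x, bg) {
  p <- length(x)
  v_of <- function(members) {
    X <- bg
    for (j in members) X[, j] <- x[j]
    mean(f(X))
  }
  phi <- numeric(p)
  perms <- NULL
  idx <- seq_len(p)
  # enumerate all p! orderings
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_perms <- permute(idx)
  for (ord in all_perms) {
    prev <- v_of(integer())
    members <- integer()
    for (j in ord) {
      members <- c(members, j)
      cur <- v_of(members)
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(all_perms)
}

test_that("model decompositions satisfy additivity and match the oracle", {
  sep <- separable_features(n_per_class = 10, seed = 21)
  # shallow trees keep the permutation oracle tractable and exercise the
  # single-split case
  model <- train_ordinal_model(sep$x, sep$labels, seed = 4, ntree = 20,
                               maxnodes = 2)
  x <- sep$x[7, ]
  bg <- sep$x[seq(1, 40, by = 4), ]
  records <- shap_decompose(model, x, bg)
  expect_length(records, 3)
  for (i in 1:3) {
    rec <- records[[i]]
    # additivity: base + sum of attributions = predicted probability
    expect_equal(rec$base_value + sum(rec$attributions), rec$prediction,
                 tolerance = 1e-6)
    q <- as.numeric(predict(model$classifiers[[i]],
                            as.data.frame(rbind(x)), type = "prob")[, "1"])
    expect_equal(rec$prediction, q, tolerance = 1e-9)
    f <- function(X) {
      nd <- as.data.frame(X)
      colnames(nd) <- model$feature_names
      as.numeric(predict(model$classifiers[[i]], nd, type = "prob")[, "1"])
    }
    oracle <- shapley_perm_oracle(f, x, bg)
    expect_equal(unname(rec$attributions), oracle, tolerance = 1e-8)
  }
})

test_that("Gini importances are normalised and find the informative feature", {
  set.seed(6)
  n <- 120
  x <- matrix(rnorm(n * 6), ncol = 6, dimnames = list(NULL, GAIT_FEATURES))
  labels <- as.integer(cut(x[, 2], c(-Inf, -0.6, 0, 0.6, Inf))) - 1L
  model <- train_ordinal_model(x, labels, seed = 3, ntree = 150)
  imp <- gini_importance(model)
  expect_length(imp, 3)
  for (v in imp) {
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
  }
  # the label-determining feature dominates each sub-classifier
  expect_equal(unname(which.max(imp[[1]])), 2L)
  expect_gt(imp[[1]][[2]], 0.5)
  # pure-noise features never dominate
  for (s in 1:3) {
    set.seed(s)
    xn <- matrix(rnorm(80 * 6), ncol = 6, dimnames = list(NULL, GAIT_FEATURES))
    yn <- rep(0:3, each = 20)
    mn <- train_ordinal_model(xn, yn, seed = s, ntree = 100)
    expect_true(all(unlist(gini_importance(mn)) < 0.5))
  }
})

test_that("explanation reports bundle probabilities, table and Shapley", {
  coh <- fixture_cohort()
  model <- train_ordinal_model(coh[, GAIT_FEATURES], coh$rating,
                               seed = 2, ntree = 100)
  x <- unlist(coh[1, GAIT_FEATURES])
  rep <- explain_prediction(model, x, coh[, GAIT_FEATURES], coh$rating)
  expect_equal(sum(rep$probs), 1, tolerance = 1e-9)
  expect_equal(dim(rep$eccentricity), c(6L, 4L))
  expect_true(all(rep$shading >= 0 & rep$shading <= 1))
  expect_length(rep$shap, 3)
})
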