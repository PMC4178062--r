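# independent naive reimplementation of the selection criterion, used as
# the exhaustive oracle: pooled covariance, D2 and Wilks computed from
# scratch with explicit matrix arithmetic
.naive_min_d2 <- function(X, g, vars) {
  Xs <- as.matrix(X[, vars, drop = FALSE])
  gl <- unique(g)
  k <- length(gl); n <- nrow(Xs)
  W <- 0
  means <- list()
  for (gg in gl) {
    Xi <- Xs[g == gg, , drop = FALSE]
    means[[gg]] <- colMeans(Xi)
    W <- W + crossprod(sweep(Xi, 2, means[[gg]]))
  }
  S <- W / (n - k)
  d2s <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    d <- means[[gl[i]]] - means[[gl[j]]]
    d2s <- c(d2s, drop(t(d) %*% solve(S) %*% d))
  }
  min(d2s)
}

.naive_wilks <- function(X, g, vars) {
  if (!length(vars)) return(1)
  Xs <- as.matrix(X[, vars, drop = FALSE])
  W <- 0
  for (gg in unique(g)) {
    Xi <- Xs[g == gg, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  Tt <- crossprod(sweep(Xs, 2, colMeans(Xs)))
  det(as.matrix(W)) / det(as.matrix(Tt))
}

.naive_partial_f <- function(X, g, base, var) {
  n <- nrow(X); k <- length(unique(g)); p <- length(base)
  ratio <- .naive_wilks(X, g, c(base, var)) / .naive_wilks(X, g, base)
  ((1 - ratio) / ratio) * (n - k - p) / (k - 1)
}

test_that("stratified subsampling: identity, determinism, allocation", {
  cfg <- toy_config(n_per_stratum = 14, seed = 2)
  spec <- generate_morphometrics(cfg)
  full <- stratified_subsample(spec, c(Group1 = 28), seed = 1)
  expect_identical(full, spec)  # target = group size

  s1 <- stratified_subsample(spec, c(Group1 = 10), seed = 7)
  s2 <- stratified_subsample(spec, c(Group1 = 10), seed = 7)
  expect_identical(s1, s2)
  expect_equal(sum(s1$group == "Group1"), 10)
  expect_equal(sum(s1$group != "Group1"), sum(spec$group != "Group1"))

  # 6 rivers x 2 sexes reduced to 36: counts within 1 of proportionality
  big <- default_synthetic_config(n_per_stratum = 14, seed = 3)
  tab <- generate_morphometrics(big)
  sub <- stratified_subsample(tab, c(Group1 = 36), seed = 9)
  g1 <- sub[sub$group == "Group1", ]
  expect_equal(nrow(g1), 36)
  counts <- table(g1$river, g1$sex)
  exact <- 14 / 168 * 36  # = 3 per stratum
  expect_true(all(abs(counts - exact) <= 1))
})

test_that("scatter matrices satisfy W + B = T and reject collinearity", {
  set.seed(20)
  X <- matrix(rnorm(30), 10, 3)
  g <- rep(c("a", "b"), 5)
  sm <- scatter_matrices(X, g)
  Tt <- crossprod(sweep(X, 2, colMeans(X)))
  expect_equal(sm$W + sm$B, Tt, tolerance = 1e-10, ignore_attr = TRUE)

  one <- scatter_matrices(X, rep("a", 10))
  expect_equal(max(abs(one$B)), 0, tolerance = 1e-10)

  Xd <- cbind(X, X[, 1])
  expect_error(scatter_matrices(Xd, g), "singular|collinear")
})

test_that("Mahalanobis D2: closed forms and a hand-inverted covariance", {
  S <- diag(2)
  expect_equal(mahalanobis_d2(c(1, 2), c(1, 2), S), 0)
  expect_equal(mahalanobis_d2(c(3, 1), c(0, 5), S), 9 + 16)
  # S = [[2,1],[1,2]], d = (1,2): S^-1 d = (0, 1), D2 = 2
  S2 <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(mahalanobis_d2(c(1, 2), c(0, 0), S2), 2, tolerance = 1e-12)
  expect_error(mahalanobis_d2(c(1, 0), c(0, 0),
                              matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("greedy stepwise trace matches the naive exhaustive oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 45
    g <- rep(c("A", "B", "C"), each = 15)
    X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
    X[, 1] <- X[, 1] + rep(c(0, 1.5, 3), each = 15)
    X[, 2] <- X[, 2] + rep(c(0, 1, 0), each = 15)
    res <- stepwise_select(X, g)

    # oracle: replay the procedure with naive linear algebra
    selected <- character(0)
    repeat {
      cand <- setdiff(colnames(X), selected)
      if (!length(cand)) break
      d2 <- vapply(cand, function(v)
        .naive_min_d2(X, g, c(selected, v)), numeric(1))
      best <- cand[which.max(d2)]
      if (.naive_partial_f(X, g, selected, best) >= 3.84) {
        selected <- c(selected, best)
        # removal check
        repeat {
          if (length(selected) < 2) break
          fo <- vapply(selected, function(v)
            .naive_partial_f(X, g, setdiff(selected, v), v), numeric(1))
          if (min(fo) < 2.71)
            selected <- setdiff(selected, names(which.min(fo)))
          else break
        }
      } else break
    }
    expect_equal(res$selected, selected)
  }
})

test_that("null data yields empty selections at the default thresholds", {
  n_runs <- 200
  empty <- 0L
  for (i in seq_len(n_runs)) {
    set.seed(3000 + i)
    X <- matrix(rnorm(90 * 3), 90, dimnames = list(NULL, paste0("v", 1:3)))
    g <- rep(c("A", "B", "C"), each = 30)
    if (!length(stepwise_select(X, g)$selected)) empty <- empty + 1L
  }
  expect_gte(empty / n_runs, 0.90)
})

test_that("discriminant fit matches an explicit generalized-eigen oracle", {
  set.seed(22)
  n <- 60
  g <- rep(c("A", "B", "C"), each = 20)
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x", "y")))
  X[, 1] <- X[, 1] + rep(c(0, 2, 4), each = 20)
  X[, 2] <- X[, 2] + rep(c(0, 1, -1), each = 20)
  m <- fit_discriminant(X, g, c("x", "y"))

  sm <- scatter_matrices(X, g)
  ev <- sort(Re(eigen(solve(sm$W) %*% sm$B)$values), decreasing = TRUE)[1:2]
  expect_equal(m$eigenvalues, ev, tolerance = 1e-9)
  expect_equal(sum(m$variance_shares), 1, tolerance = 1e-12)

  # pooled within-group variance of each score is 1
  sc <- predict(m, X)
  ssc <- scatter_matrices(sc, g)
  expect_equal(unname(diag(ssc$W / (ssc$n - ssc$k))), c(1, 1),
               tolerance = 1e-9)

  # two groups: a single function carrying all the variance
  m2 <- fit_discriminant(X[g != "C", ], g[g != "C"], c("x", "y"))
  expect_length(m2$eigenvalues, 1)
  expect_equal(m2$variance_shares, 1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scores are invariant to positive diagonal affine transforms", {
  set.seed(23)
  g <- rep(c("A", "B", "C"), each = 15)
  X <- matrix(rnorm(45 * 3), 45, dimnames = list(NULL, c("a", "b", "c")))
  X[, 1] <- X[, 1] + rep(c(0, 2, 4), each = 15)
  m1 <- fit_discriminant(X, g, c("a", "b", "c"))
  Y <- sweep(X, 2, c(2, 0.5, 10), "*")
  Y <- sweep(Y, 2, c(-3, 7, 100), "+")
  colnames(Y) <- colnames(X)
  m2 <- fit_discriminant(Y, g, c("a", "b", "c"))
  s1 <- predict(m1, X); s2 <- predict(m2, Y)
  for (f in 1:2) {
    agree <- max(abs(s1[, f] - s2[, f]))
    flip <- max(abs(s1[, f] + s2[, f]))
    expect_lt(min(agree, flip), 1e-8)
  }
})

test_that("classification: centroids, deterministic ties, Bayes agreement", {
  # 1-d two-group toy with an exact midpoint tie
  x <- matrix(c(-1, 1, 3, 5), ncol = 1, dimnames = list(NULL, "v"))
  g <- c("A", "A", "B", "B")
  m <- fit_discriminant(x, g, "v")
  expect_equal(classify(m, c(v = 0)), "A")   # at centroid A
  expect_equal(classify(m, c(v = 4)), "B")
  expect_equal(classify(m, c(v = 2)), "A")   # tie -> lowest index

  expect_error(classify(m, c(w = 1)), "missing variable.*v")

  # well-separated Gaussians: matches the Bayes rule (nearest true mean
  # under the common identity covariance) on nearly all points
  set.seed(24)
  mu <- list(A = c(0, 0), B = c(4, 0), C = c(0, 4))
  gtrain <- rep(c("A", "B", "C"), each = 40)
  Xtrain <- t(vapply(gtrain, function(gg) mu[[gg]] + rnorm(2),
                     numeric(2)))
  colnames(Xtrain) <- c("u", "v")
  mm <- fit_discriminant(Xtrain, gtrain, c("u", "v"))
  gtest <- rep(c("A", "B", "C"), each = 100)
  Xtest <- t(vapply(gtest, function(gg) mu[[gg]] + rnorm(2), numeric(2)))
  colnames(Xtest) <- c("u", "v")
  bayes <- apply(Xtest, 1, function(z)
    names(mu)[which.min(vapply(mu, function(m0) sum((z - m0)^2),
                               numeric(1)))])
  pred <- classify(mm, Xtest)
  expect_gte(mean(pred == bayes), 0.99)
})

test_that("LOOCV equals a naive per-fold lda oracle", {
  skip_if_not_installed("MASS")
  set.seed(25)
  g <- rep(c("A", "B", "C"), each = 12)
  X <- matrix(rnorm(36 * 2), 36, dimnames = list(NULL, c("x", "y")))
  X[, 1] <- X[, 1] + rep(c(0, 1.5, 3), each = 12)
  conf <- loocv_confusion(X, g, c("x", "y"))
  pred <- character(36)
  for (i in 1:36) {
    fit <- MASS::lda(X[-i, , drop = FALSE], g[-i], prior = rep(1 / 3, 3))
    pred[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
  }
  oracle <- classification_table(g, factor(pred, levels = c("A", "B", "C")))
  expect_equal(conf$counts, oracle$counts, ignore_attr = TRUE)
  expect_equal(conf$percent_correct, oracle$percent_correct,
               tolerance = 1e-12, ignore_attr = TRUE)

  # perfectly separated clusters classify at 100% per group
  Xp <- matrix(c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1),
                 rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)), ncol = 2)
  colnames(Xp) <- c("x", "y")
  gp <- rep(c("A", "B"), each = 10)
  cp <- loocv_confusion(Xp, gp, c("x", "y"))
  expect_equal(unname(cp$percent_correct), c(100, 100))

  expect_error(loocv_confusion(X[c(1, 2, 13, 25), ], g[c(1, 2, 13, 25)],
                               c("x", "y")), "fewer than 2")
})

test_that("Press's Q: published value, closed forms, monotonicity", {
  ref <- sea_lamprey_reference()
  pq <- press_q(classification_table(ref$morph_confusion))
  expect_equal(round(pq$q, 3), 16.759)
  expect_lt(pq$p_value, 0.001)

  expect_equal(press_q(10, 10, 2)$q, 10)       # perfect two-group
  expect_equal(press_q(90, 30, 3)$q, 0)        # chance level
  q_prev <- -1
  for (nc in seq(30, 87, by = 3)) {            # monotone in n_correct
    q <- press_q(87, nc, 3)$q
    expect_gt(q, q_prev)
    q_prev <- q
  }
})

test_that("potency index weights squared loadings by variance shares", {
  ref <- sea_lamprey_reference()
  pot <- potency_index(ref$morph_loadings, ref$variance_shares)
  expect_equal(round(unname(pot), 2), c(0.33, 0.27, 0.21))
  expect_equal(unname(potency_index(matrix(1), 1)), 1)
  expect_error(potency_index(matrix(2), 1))
})

test_that("score size-independence regression matches closed forms", {
  set.seed(26)
  tl <- rnorm(50, 864, 60)
  ortho <- stats::resid(stats::lm(rnorm(50) ~ tl))
  res <- score_size_independence(matrix(ortho), tl)
  expect_lt(res$r_squared, 1e-12)

  y <- 2 + 0.01 * tl + rnorm(50, 0, 3)
  r <- score_size_independence(matrix(y), tl)
  sm <- summary(stats::lm(y ~ tl))
  expect_equal(r$r_squared, sm$r.squared, tolerance = 1e-12)
})
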