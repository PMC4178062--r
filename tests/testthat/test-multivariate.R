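# brute-force SSCP oracle for a balanced two-way design
.oracle_sscp <- function(X, A, B) {
  A <- factor(A); B <- factor(B)
  grand <- colMeans(X)
  Ha <- Reduce(`+`, lapply(levels(A), function(a) {
    idx <- A == a
    d <- colMeans(X[idx, , drop = FALSE]) - grand
    sum(idx) * tcrossprod(d)
  }))
  Hb <- Reduce(`+`, lapply(levels(B), function(b) {
    idx <- B == b
    d <- colMeans(X[idx, , drop = FALSE]) - grand
    sum(idx) * tcrossprod(d)
  }))
  E <- matrix(0, ncol(X), ncol(X))
  Hab <- matrix(0, ncol(X), ncol(X))
  for (a in levels(A)) for (b in levels(B)) {
    idx <- A == a & B == b
    cellmean <- colMeans(X[idx, , drop = FALSE])
    Xc <- sweep(X[idx, , drop = FALSE], 2, cellmean)
    E <- E + crossprod(Xc)
    d <- cellmean - colMeans(X[A == a, , drop = FALSE]) -
      colMeans(X[B == b, , drop = FALSE]) + grand
    Hab <- Hab + sum(idx) * tcrossprod(d)
  }
  list(Ha = Ha, Hb = Hb, Hab = Hab, E = E)
}

test_that("two-way MANOVA matches a cell-mean SSCP oracle on balanced data", {
  set.seed(10)
  g <- factor(rep(1:3, each = 12)); s <- factor(rep(1:2, 18))
  X <- matrix(rnorm(36 * 3), 36)
  X[g == 3, 2] <- X[g == 3, 2] + 0.8
  res <- manova_two_way(X, g, s)
  o <- .oracle_sscp(X, g, s)
  V <- function(H, E) sum(diag(H %*% solve(H + E)))
  expect_equal(res$pillai[res$effect == "A"], V(o$Ha, o$E),
               tolerance = 1e-10)
  expect_equal(res$pillai[res$effect == "B"], V(o$Hb, o$E),
               tolerance = 1e-10)
  expect_equal(res$pillai[res$effect == "A:B"], V(o$Hab, o$E),
               tolerance = 1e-10)
  expect_equal(res$wilks[res$effect == "A"],
               det(o$E) / det(o$Ha + o$E), tolerance = 1e-10)
})

test_that("MANOVA agrees with stats::manova and reproduces the published df pair", {
  set.seed(11)
  g <- factor(rep(1:3, each = 24)); s <- factor(rep(1:2, 36))
  X <- matrix(rnorm(72 * 4), 72)
  res <- manova_two_way(X, g, s)
  sm <- summary(stats::manova(X ~ g * s), test = "Pillai")$stats
  expect_equal(res$pillai, unname(sm[1:3, "Pillai"]), tolerance = 1e-9)
  expect_equal(res$f, unname(sm[1:3, "approx F"]), tolerance = 1e-9)
  expect_equal(res$df1, unname(sm[1:3, "num Df"]))
  expect_equal(res$p_value, unname(sm[1:3, "Pr(>F)"]), tolerance = 1e-9)

  # 23 responses, 3 groups: hypothesis df for the group effect is 46,
  # as in the published multivariate table
  set.seed(12)
  X23 <- matrix(rnorm(210 * 23), 210)
  g3 <- factor(rep(1:3, each = 70)); s2 <- factor(rep(1:2, 105))
  r23 <- manova_two_way(X23, g3, s2)
  expect_equal(r23$df1[r23$effect == "A"], 46)
})

test_that("single response reduces to the univariate ANOVA F", {
  set.seed(13)
  y <- rnorm(48) + rep(c(0, 0.5, 1), each = 16)
  g <- factor(rep(1:3, each = 16)); s <- factor(rep(1:2, 24))
  res <- manova_two_way(matrix(y), g, s)
  an <- anova(stats::lm(y ~ g * s))
  expect_equal(res$f[res$effect == "A"], an["g", "F value"],
               tolerance = 1e-10)
  expect_equal(res$p_value[res$effect == "A"], an["g", "Pr(>F)"],
               tolerance = 1e-10)
})

test_that("Pillai's trace is invariant under full-rank affine transforms", {
  set.seed(14)
  g <- factor(rep(1:3, each = 10)); s <- factor(rep(1:2, 15))
  X <- matrix(rnorm(30 * 3), 30)
  M <- matrix(c(2, 0.5, 0, 1, 1, 0, 0.3, 0, 1), 3, 3)
  Y <- X %*% M + matrix(rep(c(5, -2, 1), each = 30), 30)
  expect_equal(manova_two_way(X, g, s)$pillai,
               manova_two_way(Y, g, s)$pillai, tolerance = 1e-9)
})

test_that("per-variable F matches the ANOVA decomposition; dimorphism filter", {
  set.seed(15)
  g <- factor(rep(1:2, each = 4)); s <- factor(rep(1:2, 4))
  X <- matrix(rnorm(8 * 3), 8, dimnames = list(NULL, c("a", "b", "c")))
  pv <- per_variable_F(X, g, s, effect = "B")
  for (j in 1:3) {
    an <- anova(stats::lm(X[, j] ~ g * s))
    expect_equal(pv$f[j], an["s", "F value"], tolerance = 1e-9)
  }

  # responses exactly symmetric in sex (every male row duplicated for a
  # female): the sex effect is identically zero for every variable
  g2 <- factor(rep(1:2, each = 4))
  s2 <- factor(rep(c(1, 2), 4))
  base <- c(1.3, 2.9, 0.7, 4.1)  # one value per (group, replicate)
  X0 <- cbind(rep(base, each = 2), rep(2 * base + 1, each = 2))
  pv0 <- per_variable_F(X0, g2, s2, effect = "B")
  expect_true(all(abs(pv0$f) < 1e-12))

  all_ns <- data.frame(variable = c("a", "b"), p_value = c(1, 1))
  expect_equal(select_nondimorphic(all_ns)$retained, c("a", "b"))
  mixed <- data.frame(variable = c("a", "b", "c"),
                      p_value = c(0.01, 0.2, 0.04))
  sel <- select_nondimorphic(mixed, alpha = 0.05)
  expect_equal(sel$retained, "b")
  expect_equal(sel$removed, c("a", "c"))
})

test_that("dimorphism screen recovers planted dimorphic characters", {
  n_runs <- 100
  hits <- 0L
  for (run in seq_len(n_runs)) {
    set.seed(500 + run)
    g <- factor(rep(1:3, each = 20)); s <- factor(rep(1:2, 30))
    X <- matrix(rnorm(60 * 8, sd = 0.05), 60,
                dimnames = list(NULL, paste0("c", 1:8)))
    dim_chars <- paste0("c", 1:4)
    X[, 1:4] <- X[, 1:4] + outer(as.integer(s) - 1.5, rep(0.1, 4))
    pv <- per_variable_F(X, g, s, effect = "B")
    sel <- select_nondimorphic(pv, alpha = 0.05)
    if (all(dim_chars %in% sel$removed)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("PERMANOVA equals classical ANOVA F in the univariate Euclidean case", {
  set.seed(16)
  y <- rnorm(48) + rep(c(0, 1), each = 24)
  g <- rep(1:2, each = 24); s <- rep(1:2, 24)
  pm <- permanova_two_way(matrix(y), g, s, n_perm = 99, seed = 1)
  an <- anova(stats::lm(scale(y) ~ factor(g) * factor(s)))
  expect_equal(pm$pseudo_f[1:3],
               an[1:3, "F value"], tolerance = 1e-10)
  expect_equal(pm$ss[1:3], an[1:3, "Sum Sq"], tolerance = 1e-10)
})

test_that("PERMANOVA partitions SS additively and agrees with vegan", {
  set.seed(17)
  X <- matrix(rpois(60 * 4, 20), 60)
  g <- rep(1:3, each = 20); s <- rep(1:2, 30)
  pm <- permanova_two_way(X, g, s, n_perm = 199, seed = 3)
  ss_terms <- sum(pm$ss[1:4])
  expect_lt(abs(ss_terms - pm$ss[5]) / pm$ss[5], 1e-6)

  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(dist(scale(X)) ~ factor(g) * factor(s),
                       permutations = 99, by = "terms")
  expect_equal(pm$ss[1:4], ad$SumOfSqs[1:4], tolerance = 1e-8)
  expect_equal(pm$pseudo_f[1:3], ad$F[1:3], tolerance = 1e-8)
})

test_that("PERMANOVA guards degenerate inputs and low n_perm", {
  X <- matrix(5, 20, 3)
  expect_error(permanova_two_way(X, rep(1:2, 10), rep(1:2, each = 10),
                                 n_perm = 99), "degenerate")
  expect_error(permanova_two_way(matrix(rnorm(20)), rep(1:2, 10),
                                 rep(1:2, each = 10), n_perm = 50),
               "at least 99")
})

test_that("permutation p is calibrated against the parametric p", {
  # Gaussian univariate input: permutation p close to the ANOVA p
  set.seed(18)
  y <- rnorm(40) + rep(c(0, 0.6), each = 20)
  g <- rep(1:2, each = 20); s <- rep(1:2, 20)
  pm <- permanova_two_way(matrix(y), g, s, n_perm = 1999, seed = 5)
  an <- anova(stats::lm(y ~ factor(g) * factor(s)))
  expect_lt(abs(pm$p_perm[1] - an[1, "Pr(>F)"]), 0.05)
})
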