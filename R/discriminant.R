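# Stepwise multiple discriminant analysis with the Mahalanobis-D2
# selection rule, leave-one-out cross-validated classification, Press's Q,
# discriminant loadings and the potency index.

#' Stratified random subsample of one (or more) groups
#'
#' Reduces a group to a target size by proportional allocation across its
#' strata (by default river x sex) with largest-remainder rounding, then
#' simple random sampling without replacement inside each stratum. Groups
#' without a target are kept whole. Deterministic given the seed.
#'
#' @param tab Specimen table with a `group` column and the stratum columns.
#' @param target_n Named integer vector, e.g. `c(Group1 = 36)`.
#' @param strata Stratum column names (default `c("river", "sex")`).
#' @param seed RNG seed.
#' @return The subsampled specimen table (row order preserved).
#' @export
stratified_subsample <- function(tab, target_n,
                                 strata = c("river", "sex"), seed = 1L) {
  stopifnot(!is.null(names(target_n)), all(names(target_n) %in% tab$group))
  set.seed(seed)
  keep <- rep(TRUE, nrow(tab))
  for (g in names(target_n)) {
    idx <- which(tab$group == g)
    ng <- length(idx)
    tn <- target_n[[g]]
    if (tn > ng)
      stop(sprintf("target_n for %s (%d) exceeds group size (%d)",
                   g, tn, ng), call. = FALSE)
    if (tn == ng) next
    key <- do.call(paste, c(tab[idx, strata, drop = FALSE], sep = "\r"))
    sizes <- table(key)
    exact <- as.numeric(sizes) / ng * tn
    alloc <- floor(exact)
    rem <- tn - sum(alloc)
    if (rem > 0) {
      # largest-remainder rounding, ties broken by stratum order
      extra <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1
    }
    names(alloc) <- names(sizes)
    over <- alloc > as.numeric(sizes)
    if (any(over)) {
      # reallocate surplus quota to strata with spare capacity
      surplus <- sum(alloc[over] - as.numeric(sizes)[over])
      alloc[over] <- as.numeric(sizes)[over]
      warning("empty or undersized stratum; quota reallocated")
      while (surplus > 0) {
        room <- which(alloc < as.numeric(sizes))
        take <- room[which.max(exact[room] - alloc[room])]
        alloc[take] <- alloc[take] + 1
        surplus <- surplus - 1
      }
    }
    drop_idx <- integer(0)
    for (s in names(alloc)) {
      in_s <- idx[key == s]
      k <- length(in_s) - alloc[[s]]
      if (k > 0)
        drop_idx <- c(drop_idx, sample(in_s, k))
    }
    keep[drop_idx] <- FALSE
  }
  tab[keep, , drop = FALSE]
}

#' Pooled within-group and between-group scatter matrices
#'
#' Decomposes the total scatter about the grand mean into the pooled
#' within-group scatter `W` (sum over groups of centered cross-products)
#' and the between-group scatter `B = T - W`.
#'
#' @param X Numeric matrix (specimens x variables).
#' @param groups Group labels.
#' @return A list with `W`, `B`, `means` (group means matrix),
#'   `grand_mean`, `n`, `k`.
#' @export
scatter_matrices <- function(X, groups) {
  X <- as.matrix(X) * 1.0
  groups <- as.factor(groups)
  counts <- table(groups)
  if (any(counts < 2))
    stop("every group needs at least 2 specimens", call. = FALSE)
  n <- nrow(X); k <- nlevels(groups); p <- ncol(X)
  if (n - k < p)
    stop("too few specimens: n - k must be >= number of variables",
         call. = FALSE)
  W <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  means <- matrix(NA_real_, k, p,
                  dimnames = list(levels(groups), colnames(X)))
  for (g in levels(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    means[g, ] <- colMeans(Xg)
    Xc <- sweep(Xg, 2, means[g, ])
    W <- W + crossprod(Xc)
  }
  grand <- colMeans(X)
  Tt <- crossprod(sweep(X, 2, grand))
  if (qr(W)$rank < p) {
    vars <- colnames(X)
    if (is.null(vars)) vars <- as.character(seq_len(p))
    stop(sprintf("singular within-group scatter; collinear variables among: %s",
                 paste(vars, collapse = ", ")), call. = FALSE)
  }
  list(W = W, B = Tt - W, means = means, grand_mean = grand,
       n = n, k = k)
}

#' Mahalanobis squared distance between two group means
#'
#' `D2 = (m_i - m_j)' S^-1 (m_i - m_j)` with `S = W / (n - k)` the pooled
#' within-group covariance.
#'
#' @param mean_i,mean_j Group mean vectors.
#' @param S Pooled within-group covariance matrix (positive definite).
#' @return The squared distance (scalar).
#' @export
mahalanobis_d2 <- function(mean_i, mean_j, S) {
  ch <- tryCatch(chol(S), error = function(e)
    stop("pooled covariance is not positive definite", call. = FALSE))
  d <- mean_i - mean_j
  sum(backsolve(ch, d, transpose = TRUE)^2)
}

# minimum pairwise Mahalanobis D2 among all group pairs for a variable set
.min_pairwise_d2 <- function(X, groups, vars) {
  sm <- scatter_matrices(X[, vars, drop = FALSE], groups)
  S <- sm$W / (sm$n - sm$k)
  combs <- utils::combn(nrow(sm$means), 2)
  min(apply(combs, 2, function(ij)
    mahalanobis_d2(sm$means[ij[1], ], sm$means[ij[2], ], S)))
}

# Wilks' Lambda for a variable set (1 when empty)
.wilks_lambda <- function(X, groups, vars) {
  if (!length(vars)) return(1)
  sm <- scatter_matrices(X[, vars, drop = FALSE], groups)
  det(sm$W) / det(sm$W + sm$B)
}

# partial F for adding/removing `var` to/from `base` (Rao's F-to-enter)
.partial_f <- function(X, groups, base, var) {
  n <- nrow(X); k <- length(unique(groups)); p <- length(base)
  ratio <- .wilks_lambda(X, groups, c(base, var)) /
    .wilks_lambda(X, groups, base)
  df2 <- n - k - p
  ((1 - ratio) / ratio) * df2 / (k - 1)
}

#' Stepwise variable selection maximizing minimum Mahalanobis D2
#'
#' At each step the candidate variable that maximizes the minimum pairwise
#' Mahalanobis D2 among groups (after inclusion) is considered; it enters
#' if its partial F-to-enter is at least `F_enter`. After each entry any
#' included variable whose partial F-to-remove falls below `F_remove` is
#' removed. Stops when no variable moves or `max_steps` is hit. An empty
#' selection (nothing passes at step 1) is returned as such, not an error.
#'
#' Default thresholds are the conventional F-to-enter 3.84 and F-to-remove
#' 2.71 of the Mahalanobis-distance stepwise method.
#'
#' @param X Numeric matrix (specimens x candidate variables, named).
#' @param groups Group labels.
#' @param F_enter,F_remove Entry/removal thresholds (`F_enter > F_remove`).
#' @param max_steps Step cap.
#' @return A list with `selected` (character vector, possibly empty) and
#'   `trace` (a `data.frame` with `step`, `action`, `variable`,
#'   `partial_f`, `min_d2`).
#' @export
stepwise_select <- function(X, groups, F_enter = 3.84, F_remove = 2.71,
                            max_steps = 50) {
  stopifnot(F_enter > F_remove)
  X <- as.matrix(X) * 1.0
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  vars <- colnames(X)
  selected <- character(0)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    changed <- FALSE
    cand <- setdiff(vars, selected)
    if (length(cand)) {
      d2 <- vapply(cand, function(v)
        .min_pairwise_d2(X, groups, c(selected, v)), numeric(1))
      best <- cand[which.max(d2)]
      f_in <- .partial_f(X, groups, selected, best)
      if (is.finite(f_in) && f_in >= F_enter) {
        selected <- c(selected, best)
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "enter", variable = best,
          partial_f = f_in, min_d2 = max(d2), stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    # removal pass: weakest variable first, repeated
    repeat {
      if (length(selected) < 2) break
      f_out <- vapply(selected, function(v)
        .partial_f(X, groups, setdiff(selected, v), v), numeric(1))
      worst <- names(which.min(f_out))
      if (f_out[worst] < F_remove) {
        selected <- setdiff(selected, worst)
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "remove", variable = worst,
          partial_f = unname(f_out[worst]),
          min_d2 = if (length(selected))
            .min_pairwise_d2(X, groups, selected) else NA_real_,
          stringsAsFactors = FALSE)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               variable = character(0), partial_f = numeric(0),
               min_d2 = numeric(0), stringsAsFactors = FALSE)
  list(selected = selected, trace = trace)
}

#' Fit canonical discriminant functions on a selected variable set
#'
#' Solves the generalized eigenproblem of the between-group scatter in the
#' metric of the pooled within-group scatter (via the Cholesky-symmetrized
#' form), keeping `min(p, k - 1)` functions. Coefficients are scaled so the
#' pooled within-group variance of each score is 1, and each function is
#' oriented so its largest-magnitude loading is positive. Reports
#' eigenvalues, variance shares, unstandardized coefficients (with
#' constants), group centroids in function space, pooled within-group
#' variable-score correlations (discriminant loadings), and Wilks' Lambda
#' with Bartlett's chi-squared test for each residual function set.
#'
#' @param X Numeric matrix (specimens x variables).
#' @param groups Group labels.
#' @param selected Variable names to use (non-empty).
#' @return An object of class `"discriminant_model"`.
#' @export
fit_discriminant <- function(X, groups, selected) {
  if (!length(selected)) stop("selected set is empty", call. = FALSE)
  X <- as.matrix(X) * 1.0
  groups <- as.factor(groups)
  sm <- scatter_matrices(X[, selected, drop = FALSE], groups)
  p <- length(selected); k <- sm$k; n <- sm$n
  m <- min(p, k - 1)
  # W = L L'; eigen of L^-1 B L'^-1 is symmetric with the same spectrum
  L <- t(chol(sm$W))
  Bs <- forwardsolve(L, t(forwardsolve(L, sm$B)))
  eg <- eigen((Bs + t(Bs)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values[seq_len(m)], 0)
  A <- backsolve(t(L), eg$vectors[, seq_len(m), drop = FALSE])
  # scale: pooled within-group score variance a' (W/(n-k)) a = 1
  Sw <- sm$W / (n - k)
  scl <- sqrt(diag(t(A) %*% Sw %*% A))
  A <- sweep(A, 2, scl, "/")
  dimnames(A) <- list(selected, paste0("F", seq_len(m)))

  # loadings: pooled within-group correlation variable x score
  cov_xs <- Sw %*% A                       # within-cov of variables, scores
  loadings <- sweep(cov_xs, 1, sqrt(diag(Sw)), "/")
  # orient each function so its largest-|loading| entry is positive
  for (f in seq_len(m)) {
    jmax <- which.max(abs(loadings[, f]))
    if (loadings[jmax, f] < 0) {
      loadings[, f] <- -loadings[, f]
      A[, f] <- -A[, f]
    }
  }
  constants <- -as.numeric(sm$grand_mean %*% A)
  centroids <- sm$means %*% A + matrix(constants, k, m, byrow = TRUE)

  shares <- if (sum(lambda) > 0) lambda / sum(lambda) else rep(NA_real_, m)
  # Bartlett's chi-squared for functions f..m
  wilks_seq <- rev(cumprod(rev(1 / (1 + lambda))))
  chisq <- -(n - 1 - (p + k) / 2) * log(wilks_seq)
  df_chi <- (p - seq_len(m) + 1) * (k - seq_len(m))
  p_chi <- stats::pchisq(chisq, df_chi, lower.tail = FALSE)

  structure(list(
    selected = selected, eigenvalues = lambda, variance_shares = shares,
    coefficients = A, constants = constants, centroids = centroids,
    loadings = loadings, wilks = wilks_seq, chisq = chisq,
    chisq_df = df_chi, chisq_p = p_chi,
    priors = stats::setNames(rep(1 / k, k), levels(groups)),
    groups = levels(groups), n = n), class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Canonical discriminant model:", length(x$selected),
      "variable(s),", length(x$eigenvalues), "function(s)\n")
  cat("Variables:", paste(x$selected, collapse = ", "), "\n")
  cat("Variance shares:",
      paste(sprintf("%.1f%%", 100 * x$variance_shares), collapse = ", "),
      "\n")
  cat("Wilks' Lambda (all functions):", format(x$wilks[1], digits = 4),
      " chi-sq =", format(x$chisq[1], digits = 4),
      " df =", x$chisq_df[1],
      " p =", format.pval(x$chisq_p[1], digits = 3), "\n")
  invisible(x)
}

#' Discriminant scores for new specimens
#'
#' @param object A `"discriminant_model"`.
#' @param newdata Matrix or data frame containing the model's selected
#'   variables.
#' @param ... Unused.
#' @return Numeric matrix of scores (specimens x functions).
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata)[, object$selected,
                                              drop = FALSE]) * 1.0
  sweep(newdata %*% object$coefficients, 2, -object$constants, "-")
}

#' Classify specimens by nearest centroid in discriminant space
#'
#' Assigns each specimen to the group whose centroid is nearest in
#' discriminant-function space (equal priors). Exact ties are broken
#' deterministically toward the lowest group index.
#'
#' @param model A `"discriminant_model"`.
#' @param x Matrix/data frame with the model's selected variables (a named
#'   vector is treated as one specimen).
#' @return Character vector of predicted group labels.
#' @export
classify <- function(model, x) {
  if (is.null(dim(x))) {
    miss <- setdiff(model$selected, names(x))
    if (length(miss))
      stop(sprintf("missing variable(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    x <- as.data.frame(as.list(x))[, model$selected, drop = FALSE]
    names(x) <- model$selected
  } else {
    miss <- setdiff(model$selected, colnames(x))
    if (length(miss))
      stop(sprintf("missing variable(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
  }
  sc <- predict(model, x)
  pred <- apply(sc, 1, function(z) {
    d2 <- colSums((t(model$centroids) - z)^2)
    which.min(d2)  # which.min takes the first (lowest-index) minimum
  })
  model$groups[pred]
}

#' Build a classification table from counts or predictions
#'
#' @param counts A square matrix of confusion counts (rows = true group),
#'   or a vector of true labels when `predicted` is given.
#' @param predicted Predicted labels (when `counts` holds true labels).
#' @return An object of class `"classification_table"`: the count matrix
#'   plus per-group and overall percent correct.
#' @examples
#' ref <- sea_lamprey_reference()
#' classification_table(ref$fa_confusion)
#' @export
classification_table <- function(counts, predicted = NULL) {
  if (!is.null(predicted)) {
    truth <- factor(counts)
    predicted <- factor(predicted, levels = levels(truth))
    counts <- as.matrix(table(truth, predicted))
  }
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts))
  n_group <- rowSums(counts)
  correct <- diag(counts)
  structure(list(
    counts = counts,
    n_group = n_group,
    percent_correct = 100 * correct / n_group,
    overall_percent = 100 * sum(correct) / sum(counts),
    N = sum(counts),
    n_correct = sum(correct),
    k = nrow(counts)), class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat("Cross-classification (rows = true group):\n")
  print(x$counts)
  cat("Percent correct:",
      paste(sprintf("%s %.1f%%", rownames(x$counts), x$percent_correct),
            collapse = ", "), "\n")
  cat(sprintf("Overall: %.1f%% (N = %d)\n", x$overall_percent, x$N))
  invisible(x)
}

#' Leave-one-out cross-validated confusion table
#'
#' For each specimen, the discriminant model is refit (same fixed variable
#' set) on the remaining n - 1 specimens and the held-out specimen is
#' classified; the K x K confusion counts and percent-correct rates are
#' assembled. The variable set is *not* reselected per fold, matching the
#' conventional cross-validated classification of stepwise discriminant
#' analysis.
#'
#' @param X Numeric matrix (specimens x variables).
#' @param groups Group labels.
#' @param selected Variable names (fixed across folds).
#' @return A `"classification_table"`.
#' @export
loocv_confusion <- function(X, groups, selected) {
  X <- as.matrix(X) * 1.0
  groups <- as.factor(groups)
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    g_train <- groups[-i]
    if (any(table(g_train) < 2))
      stop("a fold leaves a group with fewer than 2 members",
           call. = FALSE)
    m <- fit_discriminant(X[-i, , drop = FALSE], g_train, selected)
    pred[i] <- classify(m, X[i, , drop = FALSE])
  }
  classification_table(as.character(groups),
                       factor(pred, levels = levels(groups)))
}

#' Press's Q statistic for classification accuracy
#'
#' `Q = (N - n K)^2 / (N (K - 1))` where `N` is the number classified,
#' `n` the number correct and `K` the number of groups; compared against a
#' chi-squared distribution on 1 df. Q = 0 at pure chance (`n = N/K`) and
#' grows with accuracy.
#'
#' @param x A `"classification_table"`, or the total `N` when `n_correct`
#'   and `k` are given directly.
#' @param n_correct,k Number correct and number of groups (when `x` is
#'   `N`).
#' @return A list with `q`, `df` (= 1) and `p_value`.
#' @examples
#' press_q(87, 47, 3)  # published morphometric table: Q = 16.759
#' @export
press_q <- function(x, n_correct = NULL, k = NULL) {
  if (inherits(x, "classification_table")) {
    N <- x$N; n_correct <- x$n_correct; k <- x$k
  } else {
    N <- x
  }
  stopifnot(N > 0, k >= 2)
  q <- (N - n_correct * k)^2 / (N * (k - 1))
  list(q = q, df = 1,
       p_value = stats::pchisq(q, 1, lower.tail = FALSE))
}

#' Potency index of each variable
#'
#' `PI_j = sum_f loading_jf^2 * share_f`: the eigenvalue-share-weighted sum
#' of squared discriminant loadings, a single-number summary of a
#' variable's overall discriminatory contribution (at most 1).
#'
#' @param loadings Matrix of discriminant loadings (variables x functions),
#'   entries in `[-1, 1]`.
#' @param shares Variance shares of the functions (sum to 1).
#' @return Named numeric vector of potency indices.
#' @examples
#' ref <- sea_lamprey_reference()
#' potency_index(ref$morph_loadings, ref$variance_shares)
#' @export
potency_index <- function(loadings, shares) {
  loadings <- as.matrix(loadings)
  stopifnot(all(abs(loadings) <= 1 + 1e-8),
            abs(sum(shares) - 1) < 1e-6,
            ncol(loadings) == length(shares))
  drop(loadings^2 %*% shares)
}

#' Size independence check of discriminant scores
#'
#' Regresses each discriminant function's scores on total length; if size
#' adjustment worked, no function should show a significant relationship.
#'
#' @param scores Matrix of discriminant scores (specimens x functions).
#' @param lengths Total lengths.
#' @return A `data.frame` with `function_`, `r_squared`, `df`, `p_value`.
#' @export
score_size_independence <- function(scores, lengths) {
  scores <- as.matrix(scores)
  fns <- colnames(scores)
  if (is.null(fns)) fns <- paste0("F", seq_len(ncol(scores)))
  out <- lapply(seq_len(ncol(scores)), function(f) {
    fit <- stats::lm(scores[, f] ~ lengths)
    sm <- summary(fit)
    pv <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE)
    if (sm$r.squared < .Machine$double.eps) pv <- 1
    data.frame(function_ = fns[f], r_squared = sm$r.squared,
               df = unname(sm$fstatistic[3]), p_value = unname(pv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
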