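# Two-way MANOVA and PERMANOVA screening of group and sex effects.
#
# SSCP machinery uses sum-to-zero contrasts and Type-III style hypothesis
# matrices (the SPSS convention the published tables follow), so effects
# are tested adjusted for each other and the interaction even in mildly
# unbalanced designs.

.two_way_design <- function(factorA, factorB) {
  A <- as.factor(factorA); B <- as.factor(factorB)
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("both factors need at least 2 levels", call. = FALSE)
  if (any(table(A, B) == 0))
    stop("every cell of the two-way design must be non-empty",
         call. = FALSE)
  df <- data.frame(A = A, B = B)
  mm <- stats::model.matrix(~ A * B, df,
    contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  list(mm = mm, assign = attr(mm, "assign"), A = A, B = B)
}

# Type-III hypothesis SSCP for the columns of mm assigned to one term
.hypothesis_sscp <- function(coefs, xtx_inv, cols) {
  bL <- coefs[cols, , drop = FALSE]
  vL <- xtx_inv[cols, cols, drop = FALSE]
  t(bL) %*% solve(vL, bL)
}

.pillai_stats <- function(H, E, q, df_e) {
  p <- ncol(H)
  HEinv <- tryCatch(solve(H + E), error = function(e)
    stop("singular total SSCP: responses are collinear", call. = FALSE))
  V <- sum(diag(H %*% HEinv))
  lambda <- det(E) / det(H + E)
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (df_e - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f <- (df2 / df1) * (V / (s - V))
  p_val <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # SPSS-style observed power at alpha = 0.05 from the implied noncentral F
  ncp <- f * df1
  power <- stats::pf(stats::qf(0.95, df1, df2), df1, df2, ncp = ncp,
                     lower.tail = FALSE)
  list(pillai = V, wilks = lambda, f = f, df1 = df1, df2 = df2,
       p_value = p_val, partial_eps2 = V / s, power = power, s = s)
}

#' Two-way MANOVA of a response matrix on group and sex
#'
#' Fits the two-way crossed linear model with interaction and tests each
#' effect (A, B, A x B) from its hypothesis and error SSCP matrices.
#' Reports Pillai's trace `V = tr(H (H + E)^-1)`, Wilks'
#' `Lambda = det(E) / det(H + E)`, the standard Pillai approximate F with
#' its df pair, the p value, partial effect size `V / s`, and the observed
#' power at alpha = 0.05 from the noncentral F implied by the sample
#' estimate.
#'
#' @param X Numeric response matrix (specimens x variables).
#' @param factorA,factorB Factor labels (e.g. geographical group and sex).
#' @return A `data.frame` with one row per effect (`A`, `B`, `A:B`) and
#'   columns `effect`, `pillai`, `wilks`, `f`, `df1`, `df2`, `p_value`,
#'   `partial_eps2`, `power`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60 * 3), 60)
#' manova_two_way(X, rep(1:3, each = 20), rep(1:2, 30))
#' @export
manova_two_way <- function(X, factorA, factorB) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("responses must be finite", call. = FALSE)
  d <- .two_way_design(factorA, factorB)
  n <- nrow(X); p <- ncol(X)
  ncells <- nlevels(d$A) * nlevels(d$B)
  if (n <= p + ncells)
    stop("too few specimens for the response dimension", call. = FALSE)
  qrm <- qr(d$mm)
  if (qrm$rank < ncol(d$mm))
    stop("rank-deficient design", call. = FALSE)
  coefs <- qr.coef(qrm, X)
  E <- crossprod(X - d$mm %*% coefs)
  if (abs(det(E)) < .Machine$double.xmin) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- as.character(seq_len(p))
    stop(sprintf("singular error SSCP: collinear columns among %s",
                 paste(cn, collapse = ", ")), call. = FALSE)
  }
  xtx_inv <- chol2inv(qr.R(qrm))
  df_e <- n - ncol(d$mm)
  terms <- list(A = 1L, B = 2L, `A:B` = 3L)
  out <- lapply(names(terms), function(tm) {
    cols <- which(d$assign == terms[[tm]])
    H <- .hypothesis_sscp(coefs, xtx_inv, cols)
    st <- .pillai_stats(H, E, q = length(cols), df_e = df_e)
    data.frame(effect = tm, pillai = st$pillai, wilks = st$wilks,
               f = st$f, df1 = st$df1, df2 = st$df2, p_value = st$p_value,
               partial_eps2 = st$partial_eps2, power = st$power,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-variable univariate F tests for one factor of the two-way model
#'
#' The between-subjects tests accompanying [manova_two_way()]: for each
#' response column, the univariate two-way model F for the named factor
#' (Type-III, sum-to-zero contrasts).
#'
#' @param X Numeric response matrix.
#' @param factorA,factorB Factor labels; `effect` names which one is
#'   tested.
#' @param effect `"A"`, `"B"` or `"A:B"`.
#' @return A `data.frame` with `variable`, `f`, `df1`, `df2`, `p_value`.
#' @export
per_variable_F <- function(X, factorA, factorB, effect = "B") {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("responses must be finite", call. = FALSE)
  d <- .two_way_design(factorA, factorB)
  qrm <- qr(d$mm)
  coefs <- qr.coef(qrm, X)
  resid <- X - d$mm %*% coefs
  df_e <- nrow(X) - ncol(d$mm)
  xtx_inv <- chol2inv(qr.R(qrm))
  term_id <- c(A = 1L, B = 2L, `A:B` = 3L)[[effect]]
  cols <- which(d$assign == term_id)
  vars <- colnames(X)
  if (is.null(vars)) vars <- as.character(seq_len(ncol(X)))
  out <- lapply(seq_len(ncol(X)), function(j) {
    H <- .hypothesis_sscp(coefs[, j, drop = FALSE], xtx_inv, cols)
    sse <- sum(resid[, j]^2)
    f <- (H[1, 1] / length(cols)) / (sse / df_e)
    data.frame(variable = vars[j], f = f, df1 = length(cols), df2 = df_e,
               p_value = stats::pf(f, length(cols), df_e,
                                   lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Drop sexually dimorphic variables
#'
#' Retains the variables whose per-variable sex-effect p value is at least
#' `alpha`; the removed (dimorphic) set is attached as an attribute and
#' also returned in the result list.
#'
#' @param per_var Result of [per_variable_F()].
#' @param alpha Screening level (default 0.05, uncorrected, as is
#'   conventional for dimorphism screens).
#' @return A list with `retained` and `removed` character vectors.
#' @export
select_nondimorphic <- function(per_var, alpha = 0.05) {
  stopifnot(nrow(per_var) > 0)
  removed <- per_var$variable[per_var$p_value < alpha]
  list(retained = setdiff(per_var$variable, removed), removed = removed)
}

#' Two-way crossed PERMANOVA on Euclidean distances of z-scored variables
#'
#' Permutational MANOVA for the two-way crossed design. Variables are
#' column-standardized (z-scored), distances are Euclidean, and the sum of
#' squares is partitioned by sequential projection onto the design terms
#' (group, sex, interaction) -- for a balanced design this matches the
#' unique partition. `pseudo-F = MS_term / MS_residual`; significance is by
#' free (unrestricted) permutation of specimen rows, with
#' `p = (# permuted pseudo-F >= observed + 1) / (n_perm + 1)`. The number
#' of distinct permutations actually drawn is reported.
#'
#' @param X Numeric matrix of meristic counts (specimens x variables).
#' @param factorA,factorB Factor labels.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed RNG seed for the permutation stream.
#' @return A `data.frame` shaped like a PERMANOVA table: one row per term
#'   plus `Residual` and `Total`, with `df`, `ss`, `ms`, `pseudo_f`,
#'   `p_perm`, `unique_perms`.
#' @examples
#' set.seed(1)
#' X <- matrix(rpois(40 * 3, 20), 40)
#' permanova_two_way(X, rep(1:2, each = 20), rep(1:2, 20), n_perm = 199)
#' @export
permanova_two_way <- function(X, factorA, factorB, n_perm = 9999,
                              seed = 1L) {
  if (n_perm < 99)
    stop("n_perm must be at least 99 for a stable permutation p",
         call. = FALSE)
  X <- as.matrix(X) * 1.0
  d <- .two_way_design(factorA, factorB)
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0))
    stop("degenerate input: all variables are constant (all distances 0)",
         call. = FALSE)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Z <- scale(X)

  # sequential SS via projections onto cumulative designs:
  # intercept -> +A -> +B -> +A:B
  mm <- d$mm
  blocks <- list(A = which(d$assign == 1L),
                 B = which(d$assign == 2L),
                 `A:B` = which(d$assign == 3L))
  cum_cols <- Reduce(c, blocks, accumulate = TRUE)
  cum_cols <- lapply(cum_cols, function(cols) c(1L, cols))
  Qcum <- lapply(cum_cols, function(cols)
    qr.Q(qr(mm[, cols, drop = FALSE])))

  ss_of <- function(Zm) {
    base <- nrow(Zm) * sum(colMeans(Zm)^2)  # intercept projection
    cums <- vapply(Qcum, function(Qi) sum((crossprod(Qi, Zm))^2),
                   numeric(1))
    diff(c(base, cums))
  }
  Zc <- sweep(Z, 2, colMeans(Z))  # total about the grand mean
  ss_total <- sum(Zc^2)
  ss_obs <- ss_of(Z)
  df_terms <- vapply(blocks, length, integer(1))
  df_res <- n - ncol(mm)
  ss_res <- ss_total - sum(ss_obs)
  ms_terms <- ss_obs / df_terms
  ms_res <- ss_res / df_res
  f_obs <- ms_terms / ms_res

  set.seed(seed)
  exceed <- numeric(3)
  perm_keys <- character(n_perm)
  for (i in seq_len(n_perm)) {
    ord <- sample.int(n)
    perm_keys[i] <- paste(ord, collapse = ",")
    ss_p <- ss_of(Z[ord, , drop = FALSE])
    ms_p <- ss_p / df_terms
    f_p <- ms_p / ((ss_total - sum(ss_p)) / df_res)
    exceed <- exceed + (f_p >= f_obs)
  }
  p_perm <- (exceed + 1) / (n_perm + 1)
  uniq <- length(unique(perm_keys))

  out <- data.frame(
    term = c(names(blocks), "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    ss = c(ss_obs, ss_res, ss_total),
    ms = c(ms_terms, ms_res, NA),
    pseudo_f = c(f_obs, NA, NA),
    p_perm = c(p_perm, NA, NA),
    unique_perms = c(rep(uniq, 3), NA, NA),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
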