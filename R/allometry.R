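#' Log-log regression of a morphometric character on total length
#'
#' Ordinary least squares of `log(value)` on `log(length)`, the screening
#' regression used both to test whether a character covaries with body
#' size and to inspect residuals for outliers.
#'
#' @param values Positive character measurements (mm).
#' @param lengths Positive total lengths (mm), same length as `values`.
#' @param character Optional character id carried into the result.
#' @return A `data.frame` row with `character`, `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided slope test) and `n`.
#' @examples
#' regress_on_length(c(10, 12, 15, 18, 22), c(100, 120, 150, 180, 220))
#' @export
regress_on_length <- function(values, lengths, character = NA_character_) {
  ok <- is.finite(values) & is.finite(lengths)
  values <- values[ok]; lengths <- lengths[ok]
  if (length(values) < 3)
    stop("regress_on_length needs at least 3 finite pairs", call. = FALSE)
  if (any(values <= 0) || any(lengths <= 0))
    stop("values and lengths must be positive", call. = FALSE)
  x <- log(lengths); y <- log(values)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    stop("degenerate design: lengths are constant", call. = FALSE)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  n <- length(y)
  rss <- syy - slope * sxy
  r2 <- if (syy > 0) 1 - rss / syy else 0
  if (syy == 0) {
    p <- 1            # constant response: no relationship with length
  } else if (rss <= .Machine$double.eps * syy) {
    p <- 0            # exact fit with nonzero slope
    r2 <- 1
  } else {
    se <- sqrt(rss / (n - 2) / sxx)
    p <- 2 * stats::pt(abs(slope) / se, n - 2, lower.tail = FALSE)
  }
  data.frame(character = character,
             slope = slope, intercept = intercept,
             r_squared = r2, p_value = p, n = n,
             stringsAsFactors = FALSE)
}

#' ANCOVA test of slope heterogeneity and common within-group slope
#'
#' Compares the separate-slopes model
#' `log(value) ~ group + log(length):group` with the common-slope model
#' `log(value) ~ group + log(length)` by a nested-model F test
#' (the slope-heterogeneity interaction), and returns the pooled common
#' within-group slope from the common-slope fit -- the slope used for
#' allometric size adjustment.
#'
#' @param values,lengths Positive numeric vectors.
#' @param groups Group labels, one per specimen.
#' @param character Optional character id carried into the result.
#' @return A `data.frame` row with `character`, `f_interaction`, `df1`,
#'   `df2`, `p_value` and `common_slope`.
#' @examples
#' set.seed(1)
#' tl <- rep(exp(seq(6.5, 6.9, length.out = 10)), 3)
#' g <- rep(c("A", "B", "C"), each = 10)
#' v <- exp(0.5 + 1 * log(tl) + rnorm(30, 0, 0.02))
#' ancova_common_slope(v, tl, g)
#' @export
ancova_common_slope <- function(values, lengths, groups,
                                character = NA_character_) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2)
    stop("ancova_common_slope needs at least 2 groups", call. = FALSE)
  counts <- table(groups)
  if (any(counts < 3))
    stop(sprintf("insufficient data in group(s): %s (need >= 3 specimens)",
                 paste(names(counts)[counts < 3], collapse = ", ")),
         call. = FALSE)
  if (any(values <= 0) || any(lengths <= 0))
    stop("values and lengths must be positive", call. = FALSE)
  y <- log(values); x <- log(lengths)
  common <- stats::lm(y ~ groups + x)
  separate <- stats::lm(y ~ groups + x:groups)
  rss_c <- sum(stats::resid(common)^2)
  rss_s <- sum(stats::resid(separate)^2)
  df1 <- common$df.residual - separate$df.residual
  df2 <- separate$df.residual
  f <- if (rss_s <= .Machine$double.eps * max(1, rss_c)) {
    # both models interpolate: no evidence of heterogeneity
    0
  } else {
    ((rss_c - rss_s) / df1) / (rss_s / df2)
  }
  f <- max(f, 0)
  data.frame(character = character,
             f_interaction = f, df1 = df1, df2 = df2,
             p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
             common_slope = unname(stats::coef(common)["x"]),
             stringsAsFactors = FALSE)
}

#' Allometric size adjustment with a common within-group slope
#'
#' Removes the total-length component of a measurement on the log scale:
#' `adjusted = ln(value) - b_c * (ln(length) - ln(ref_length))`, the
#' standard common-within-group-slope allometric correction. At the
#' reference length the adjustment reduces to a pure log transform.
#'
#' @param values,lengths Positive numeric vectors.
#' @param b_c Common within-group slope (from [ancova_common_slope()]).
#' @param ref_length Reference length in mm; conventionally the grand mean
#'   total length of the dataset.
#' @return Numeric vector of adjusted values (natural-log scale).
#' @examples
#' adjust_for_size(c(10, 20), c(800, 900), b_c = 1, ref_length = 864)
#' @export
adjust_for_size <- function(values, lengths, b_c, ref_length) {
  if (any(values <= 0) || any(lengths <= 0) || ref_length <= 0)
    stop("values, lengths and ref_length must be positive", call. = FALSE)
  log(values) - b_c * (log(lengths) - log(ref_length))
}

#' Flag outlier specimens from regression residuals
#'
#' Standardizes each character's residuals and flags any specimen whose
#' absolute standardized residual exceeds the threshold in at least one
#' character. Characters with zero residual variance are skipped with a
#' warning.
#'
#' @param residuals Numeric matrix (specimens x characters) of regression
#'   residuals; dimnames are carried into the flags.
#' @param threshold Threshold in SD units (default 3).
#' @return A `data.frame` with columns `specimen` (row index or name) and
#'   `character` for each flagged (specimen, character) pair; zero rows
#'   when nothing is flagged.
#' @export
flag_outliers_regression <- function(residuals, threshold = 3) {
  residuals <- as.matrix(residuals)
  if (!all(is.finite(residuals)))
    stop("residual matrix must be finite", call. = FALSE)
  specs <- rownames(residuals)
  if (is.null(specs)) specs <- as.character(seq_len(nrow(residuals)))
  chars <- colnames(residuals)
  if (is.null(chars)) chars <- as.character(seq_len(ncol(residuals)))
  out <- list()
  for (j in seq_len(ncol(residuals))) {
    s <- stats::sd(residuals[, j])
    if (s == 0) {
      warning(sprintf("character '%s' has zero residual variance; skipped",
                      chars[j]))
      next
    }
    z <- (residuals[, j] - mean(residuals[, j])) / s
    hit <- which(abs(z) > threshold)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        specimen = specs[hit], character = chars[j],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(specimen = character(0), character = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag outlier counts by the boxplot (IQR fence) rule
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]`. The default
#' `k = 3` is the "extreme value" convention; `k = 1.5` gives the ordinary
#' outlier fences (and flags a superset of `k = 3`).
#'
#' @param counts Numeric/integer vector of meristic counts, or a matrix
#'   (specimens x characters).
#' @param k IQR multiplier.
#' @return For a vector, an integer vector of flagged indices. For a
#'   matrix, a `data.frame` of flagged (specimen, character) pairs.
#' @export
flag_outliers_boxplot <- function(counts, k = 3) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    specs <- rownames(counts)
    if (is.null(specs)) specs <- as.character(seq_len(nrow(counts)))
    chars <- colnames(counts)
    if (is.null(chars)) chars <- as.character(seq_len(ncol(counts)))
    out <- list()
    for (j in seq_len(ncol(counts))) {
      hit <- flag_outliers_boxplot(counts[, j], k)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          specimen = specs[hit], character = chars[j],
          stringsAsFactors = FALSE)
    }
    if (!length(out))
      return(data.frame(specimen = character(0), character = character(0),
                        stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res)
  }
  q <- stats::quantile(counts, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  which(counts < q[1] - k * iqr | counts > q[2] + k * iqr)
}

#' Per-character allometry report for a specimen table
#'
#' Convenience wrapper running [regress_on_length()] and
#' [ancova_common_slope()] for every character column, the per-character
#' slope table emitted by the morphometric pipeline.
#'
#' @param tab Specimen table (see [read_specimen_csv()]).
#' @param characters Character column names.
#' @return A `data.frame`, one row per character, with the regression and
#'   ANCOVA fields.
#' @export
allometry_report <- function(tab, characters) {
  do.call(rbind, lapply(characters, function(ch) {
    reg <- regress_on_length(tab[[ch]], tab$TL_mm, character = ch)
    anc <- ancova_common_slope(tab[[ch]], tab$TL_mm, tab$group,
                               character = ch)
    cbind(reg, anc[, setdiff(names(anc), "character"), drop = FALSE])
  }))
}
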