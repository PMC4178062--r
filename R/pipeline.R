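# Orchestration of the two analysis branches (morphometric and
# fatty-acid) plus CSV I/O. A single pipeline seed fans out to named
# substreams (subsampling, permutations) so stages can be re-run
# independently and the whole run is deterministic.

.META_COLS <- c("specimen_id", "group", "river", "sex", "TL_mm", "TM_g")

# deterministic substream seeds derived from the pipeline seed
.substream <- function(seed, name) {
  offset <- c(subsample = 101L, permutation = 211L, synthesis = 307L)[[name]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}

#' Read a specimen table from CSV
#'
#' Schema: `specimen_id`, `group`, `river`, `sex`, `TL_mm`, `TM_g`, then
#' measurement columns (morphometric characters in mm, meristic counts,
#' or fatty-acid percentage columns in Cx:y(wz) nomenclature). UTF-8.
#' `ND` cells (not-detected fatty acids) are read as exact zeros.
#' Duplicate specimen ids are an error.
#'
#' @param path CSV file path.
#' @return A `data.frame` specimen table.
#' @export
read_specimen_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("specimen_id", "group", "river", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(tab$specimen_id))
    stop(sprintf("duplicate specimen id(s): %s",
                 paste(unique(tab$specimen_id[duplicated(tab$specimen_id)]),
                       collapse = ", ")), call. = FALSE)
  for (j in setdiff(names(tab), need)) {
    if (is.character(tab[[j]])) {
      x <- tab[[j]]
      x[x %in% c("ND", "nd")] <- "0"
      num <- suppressWarnings(as.numeric(x))
      if (!any(is.na(num) & !is.na(x))) tab[[j]] <- num
    }
  }
  tab
}

#' Write a specimen table to CSV
#'
#' Inverse of [read_specimen_csv()]: UTF-8, full numeric precision, no row
#' names, so that `read_specimen_csv(write_specimen_csv(x))` round-trips.
#'
#' @param tab Specimen table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimen_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the tunables of both analysis branches with the package
#' defaults: screening alpha 0.05, outlier thresholds 3 SD (regression
#' residuals) and 3 x IQR (boxplot fences), stepwise thresholds F-to-enter
#' 3.84 / F-to-remove 2.71, 9999 permutations, and the subsampling targets
#' used when one group dwarfs the others.
#'
#' @param branch `"morphometric"`, `"fatty_acid"` or `"both"`.
#' @param alpha Screening level for dimorphism and heterogeneity tests.
#' @param outlier_sd Residual outlier threshold in SD units.
#' @param outlier_iqr_k IQR multiplier for meristic boxplot fences.
#' @param F_enter,F_remove Stepwise thresholds.
#' @param n_perm PERMANOVA permutations.
#' @param subsample_target Named vector of per-group target sizes, or
#'   `NULL` to skip subsampling.
#' @param seed Mandatory seed driving every stochastic stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(branch = "both", alpha = 0.05,
                            outlier_sd = 3, outlier_iqr_k = 3,
                            F_enter = 3.84, F_remove = 2.71,
                            n_perm = 9999, subsample_target = NULL,
                            seed = 1L) {
  stopifnot(branch %in% c("morphometric", "fatty_acid", "both"),
            alpha > 0, alpha < 1, outlier_sd > 0, outlier_iqr_k > 0,
            F_enter > F_remove, n_perm >= 99, length(seed) == 1)
  structure(list(branch = branch, alpha = alpha, outlier_sd = outlier_sd,
                 outlier_iqr_k = outlier_iqr_k, F_enter = F_enter,
                 F_remove = F_remove, n_perm = n_perm,
                 subsample_target = subsample_target,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.exclusion <- function(specimen, reason) {
  data.frame(specimen = as.character(specimen), reason = reason,
             stringsAsFactors = FALSE)
}

#' Run the morphometric stock-identification branch
#'
#' Executes the full morphometric sequence: log-log regression screening
#' against total length, ANCOVA common within-group slopes, allometric
#' size adjustment (characters uncorrelated with length are only
#' log-transformed), regression-residual outlier removal, two-way MANOVA
#' of group and sex, removal of sexually dimorphic characters, optional
#' stratified subsampling, stepwise Mahalanobis-D2 discriminant analysis,
#' leave-one-out cross-validated classification, Press's Q, and the
#' size-independence check of the discriminant scores. Every removal is
#' logged with a machine-readable reason.
#'
#' @param tab Specimen table with morphometric character columns.
#' @param characters Names of the morphometric character columns.
#' @param config A [pipeline_config()].
#' @return A report bundle (list of stage tables) of class
#'   `"stock_report"`.
#' @export
run_morphometric_pipeline <- function(tab, characters,
                                      config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  exclusions <- list()

  allom <- allometry_report(tab, characters)

  # size adjustment: common within-group slope for size-linked characters,
  # plain log transform for characters uncorrelated with length
  ref_len <- mean(tab$TL_mm)
  adj <- matrix(NA_real_, nrow(tab), length(characters),
                dimnames = list(tab$specimen_id, characters))
  for (ch in characters) {
    linked <- allom$p_value[allom$character == ch] < config$alpha
    b <- if (linked) allom$common_slope[allom$character == ch] else 0
    adj[, ch] <- adjust_for_size(tab[[ch]], tab$TL_mm, b, ref_len)
  }

  # outliers from the size-adjustment residuals within group
  resid <- adj
  for (g in unique(tab$group)) {
    idx <- tab$group == g
    resid[idx, ] <- sweep(adj[idx, , drop = FALSE], 2,
                          colMeans(adj[idx, , drop = FALSE]))
  }
  flags <- flag_outliers_regression(resid, threshold = config$outlier_sd)
  out_ids <- unique(flags$specimen)
  if (length(out_ids))
    exclusions[[length(exclusions) + 1L]] <-
      .exclusion(out_ids, "morphometric_outlier")
  keep <- !(tab$specimen_id %in% out_ids)
  tab2 <- tab[keep, , drop = FALSE]
  adj2 <- adj[keep, , drop = FALSE]

  man <- manova_two_way(adj2, tab2$group, tab2$sex)
  pvf <- per_variable_F(adj2, tab2$group, tab2$sex, effect = "B")
  dimo <- select_nondimorphic(pvf, alpha = config$alpha)

  tab3 <- tab2
  adj3 <- adj2[, dimo$retained, drop = FALSE]
  if (!is.null(config$subsample_target)) {
    sub <- stratified_subsample(tab3, config$subsample_target,
                                seed = .substream(config$seed, "subsample"))
    dropped <- setdiff(tab3$specimen_id, sub$specimen_id)
    if (length(dropped))
      exclusions[[length(exclusions) + 1L]] <-
        .exclusion(dropped, "subsample_not_drawn")
    adj3 <- adj3[tab3$specimen_id %in% sub$specimen_id, , drop = FALSE]
    tab3 <- sub
  }

  sel <- stepwise_select(adj3, tab3$group,
                         F_enter = config$F_enter,
                         F_remove = config$F_remove)
  if (!length(sel$selected)) {
    report <- list(
      branch = "morphometric", allometry = allom, manova = man,
      per_variable = pvf, dimorphic_removed = dimo$removed,
      selection = sel, model = NULL, confusion = NULL, press_q = NULL,
      size_independence = NULL,
      message = "no discriminating variables at the entry threshold",
      exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
        .exclusion(character(0), character(0)),
      config = config)
    class(report) <- "stock_report"
    return(report)
  }

  model <- fit_discriminant(adj3, tab3$group, sel$selected)
  conf <- loocv_confusion(adj3, tab3$group, sel$selected)
  pq <- press_q(conf)
  scores <- predict(model, adj3)
  sizeind <- score_size_independence(scores, tab3$TL_mm)
  pot <- potency_index(model$loadings, model$variance_shares)

  report <- list(
    branch = "morphometric", allometry = allom, manova = man,
    per_variable = pvf, dimorphic_removed = dimo$removed,
    selection = sel, model = model, confusion = conf, press_q = pq,
    potency = pot, size_independence = sizeind,
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      .exclusion(character(0), character(0)),
    config = config)
  class(report) <- "stock_report"
  report
}

#' Run the fatty-acid stock-identification branch
#'
#' Executes the fatty-acid sequence: percentage normalization per
#' specimen, the discriminant-analysis subset rules, arcsine transform,
#' two-way MANOVA (group and sex), optional stratified subsampling,
#' stepwise Mahalanobis-D2 discriminant analysis, leave-one-out
#' cross-validation, Press's Q and potency indices, plus the per-group
#' signature summary (class and omega sums, unsaturation index).
#'
#' @param tab Specimen table whose measurement columns are fatty-acid
#'   percentages (Cx:y(wz) names).
#' @param config A [pipeline_config()].
#' @return A `"stock_report"` bundle.
#' @export
run_fatty_acid_pipeline <- function(tab, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  exclusions <- list()
  fa_cols <- setdiff(names(tab), .META_COLS)
  prof <- as.matrix(tab[, fa_cols, drop = FALSE])
  prof <- t(apply(prof, 1, normalize_percent))

  fa_used <- select_fa_for_mda(prof)
  trans <- arcsine_transform(prof[, fa_used, drop = FALSE])
  rownames(trans) <- tab$specimen_id

  man <- manova_two_way(trans, tab$group, tab$sex)

  tab2 <- tab; trans2 <- trans
  if (!is.null(config$subsample_target)) {
    sub <- stratified_subsample(tab2, config$subsample_target,
                                seed = .substream(config$seed, "subsample"))
    dropped <- setdiff(tab2$specimen_id, sub$specimen_id)
    if (length(dropped))
      exclusions[[length(exclusions) + 1L]] <-
        .exclusion(dropped, "subsample_not_drawn")
    trans2 <- trans2[tab2$specimen_id %in% sub$specimen_id, , drop = FALSE]
    tab2 <- sub
  }

  sel <- stepwise_select(trans2, tab2$group,
                         F_enter = config$F_enter,
                         F_remove = config$F_remove)

  # signature summaries over the identified (parseable) components only
  parseable <- vapply(colnames(prof), function(nm)
    !inherits(tryCatch(parse_fa_name(nm), error = identity), "error"),
    logical(1))
  summary_by_group <- lapply(
    split(as.data.frame(prof[, parseable, drop = FALSE]), tab$group),
    function(d) class_sums(colMeans(d)))

  if (!length(sel$selected)) {
    report <- list(
      branch = "fatty_acid", fa_used = fa_used, manova = man,
      selection = sel, model = NULL, confusion = NULL, press_q = NULL,
      potency = NULL, group_summaries = summary_by_group,
      message = "no discriminating variables at the entry threshold",
      exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
        .exclusion(character(0), character(0)),
      config = config)
    class(report) <- "stock_report"
    return(report)
  }

  model <- fit_discriminant(trans2, tab2$group, sel$selected)
  conf <- loocv_confusion(trans2, tab2$group, sel$selected)
  pq <- press_q(conf)
  pot <- potency_index(model$loadings, model$variance_shares)

  report <- list(
    branch = "fatty_acid", fa_used = fa_used, manova = man,
    selection = sel, model = model, confusion = conf, press_q = pq,
    potency = pot, group_summaries = summary_by_group,
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      .exclusion(character(0), character(0)),
    config = config)
  class(report) <- "stock_report"
  report
}

#' @export
print.stock_report <- function(x, ...) {
  cat("Stock-identification report (", x$branch, " branch)\n", sep = "")
  if (!is.null(x$message)) cat(x$message, "\n")
  if (!is.null(x$selection))
    cat("Selected variables:",
        if (length(x$selection$selected))
          paste(x$selection$selected, collapse = ", ") else "(none)", "\n")
  if (!is.null(x$confusion)) {
    cat(sprintf("Cross-validated overall: %.1f%%\n",
                x$confusion$overall_percent))
    cat(sprintf("Press's Q = %.3f (df = 1, p = %.3g)\n",
                x$press_q$q, x$press_q$p_value))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Serializes every stage of a [run_morphometric_pipeline()] /
#' [run_fatty_acid_pipeline()] report: tables as CSV, the discriminant
#' model (variables, eigenvalues, coefficients, centroids, loadings,
#' shares) as JSON, and the exclusion log as CSV. Percentages and test
#' statistics in the CSVs keep full precision.
#'
#' @param report A `"stock_report"`.
#' @param dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stock_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(obj, fname) {
    p <- file.path(dir, fname)
    utils::write.csv(obj, p, row.names = FALSE, fileEncoding = "UTF-8")
    files <<- c(files, p)
  }
  if (!is.null(report$allometry)) wr(report$allometry, "allometry.csv")
  if (!is.null(report$manova)) wr(report$manova, "manova.csv")
  if (!is.null(report$per_variable)) wr(report$per_variable,
                                        "per_variable_sex_F.csv")
  if (!is.null(report$selection)) wr(report$selection$trace,
                                     "stepwise_trace.csv")
  if (!is.null(report$confusion)) {
    cm <- as.data.frame(report$confusion$counts)
    cm <- cbind(true_group = rownames(report$confusion$counts),
                as.data.frame.matrix(report$confusion$counts),
                percent_correct = report$confusion$percent_correct)
    wr(cm, "confusion.csv")
  }
  wr(report$exclusions, "exclusions.csv")
  if (!is.null(report$model)) {
    m <- report$model
    p <- file.path(dir, "model.json")
    jsonlite::write_json(list(
      selected = m$selected,
      eigenvalues = m$eigenvalues,
      variance_shares = m$variance_shares,
      coefficients = m$coefficients,
      constants = m$constants,
      centroids = m$centroids,
      loadings = m$loadings,
      wilks = m$wilks, groups = m$groups),
      p, digits = NA, auto_unbox = TRUE)
    files <- c(files, p)
  }
  invisible(files)
}
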