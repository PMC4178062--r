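# Fatty-acid profile arithmetic: nomenclature parsing, percentage
# normalization, the arcsine variance-stabilizing transform, class and
# omega-series sums, the unsaturation index, and the variable-subset rules
# applied before discriminant analysis.

.OMEGA <- "\u03c9"

#' Parse a fatty-acid name in Cx:y(wz) nomenclature
#'
#' Accepts names like `"C16:0"`, `"C22:6w3"` (with the omega character or
#' a plain `w`/`n-` as the series marker). The lipid class follows from
#' the number of double bonds: 0 = SFA, 1 = MUFA, >= 2 = PUFA.
#'
#' @param name Fatty-acid name string.
#' @return A list with `name` (normalized, omega character), `carbons`,
#'   `double_bonds`, `omega` (3, 6, 9 or `NA`) and `class`.
#' @examples
#' parse_fa_name("C22:6ω3")
#' parse_fa_name("C16:0")$class
#' @export
parse_fa_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  pat <- paste0("^C(\\d+):(\\d+)(?:(?:", .OMEGA, "|w|n-)(\\d+))?$")
  m <- regmatches(name, regexec(pat, name))[[1]]
  if (!length(m)) {
    # locate first offending character for the error message
    ok <- regexpr(paste0("^C\\d+:\\d+(?:(?:", .OMEGA, "|w|n-)\\d*)?"), name)
    pos <- if (ok > 0) attr(ok, "match.length") + 1L else 1L
    stop(sprintf("malformed fatty-acid name '%s' (near position %d)",
                 name, pos), call. = FALSE)
  }
  carbons <- as.integer(m[2])
  db <- as.integer(m[3])
  omega <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  if (carbons < 4)
    stop(sprintf("implausible carbon count %d in '%s'", carbons, name),
         call. = FALSE)
  cls <- if (db == 0) "SFA" else if (db == 1) "MUFA" else "PUFA"
  norm <- paste0("C", carbons, ":", db,
                 if (!is.na(omega)) paste0(.OMEGA, omega) else "")
  list(name = norm, carbons = carbons, double_bonds = db, omega = omega,
       class = cls)
}

#' Normalize raw areas to a percentage profile
#'
#' Expresses per-fatty-acid areas as percentages of their total, removing
#' concentration effects; zeros (not-detected components) are preserved.
#'
#' @param areas Named non-negative numeric vector with at least one
#'   positive entry.
#' @return Named numeric vector summing to 100.
#' @examples
#' normalize_percent(c(a = 1, b = 1, c = 2))
#' @export
normalize_percent <- function(areas) {
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  tot <- sum(areas)
  if (tot == 0)
    stop("degenerate input: all areas are zero", call. = FALSE)
  areas / tot * 100
}

#' Arcsine square-root transform of percentage data
#'
#' `t = arcsin(sqrt(p / 100))` in radians, the variance-stabilizing
#' transform conventionally applied to percentage compositions before
#' normal-theory multivariate analysis. Strictly monotone on `[0, 100]`
#' with range `[0, pi/2]`.
#'
#' @param profile Percentages in `[0, 100]` (vector or matrix).
#' @return Transformed values, same shape.
#' @examples
#' arcsine_transform(c(0, 25, 100))  # 0, pi/6, pi/2
#' @export
arcsine_transform <- function(profile) {
  if (any(profile < 0 | profile > 100, na.rm = TRUE))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  asin(sqrt(profile / 100))
}

#' Lipid class and omega-series summary of a normalized profile
#'
#' Computes the standard signature summaries: class sums (SFA, MUFA,
#' PUFA), `PUFA + MUFA`, `UFA/SFA`, omega-3 and omega-6 series sums (a
#' PUFA without a series annotation, e.g. C20:2, belongs to neither), the
#' DHA/EPA ratio (`C22:6w3 / C20:5w3`; reported `NA` with a flag when EPA
#' is absent), `EPA + DPA + DHA`, and the unsaturation index.
#'
#' @param profile Named percentage profile (sums to 100).
#' @return A list of summary statistics; `dha_epa_undefined` is `TRUE`
#'   when EPA is zero.
#' @examples
#' ref <- sea_lamprey_reference()
#' p <- ref$fa_group_means[, "Group3"]
#' p[is.na(p)] <- 0
#' class_sums(p)$sum_omega3  # 20.96
#' @export
class_sums <- function(profile) {
  stopifnot(!is.null(names(profile)))
  desc <- lapply(names(profile), parse_fa_name)
  cls <- vapply(desc, `[[`, character(1), "class")
  omega <- vapply(desc, function(d)
    ifelse(is.na(d$omega), -1L, d$omega), integer(1))
  db <- vapply(desc, `[[`, integer(1), "double_bonds")
  norm_names <- vapply(desc, `[[`, character(1), "name")

  sfa <- sum(profile[cls == "SFA"])
  mufa <- sum(profile[cls == "MUFA"])
  pufa <- sum(profile[cls == "PUFA"])
  epa <- sum(profile[norm_names == paste0("C20:5", .OMEGA, "3")])
  dpa <- sum(profile[norm_names == paste0("C22:5", .OMEGA, "3")])
  dha <- sum(profile[norm_names == paste0("C22:6", .OMEGA, "3")])
  undefined <- epa == 0
  list(
    sum_sfa = sfa, sum_mufa = mufa, sum_pufa = pufa,
    sum_pufa_mufa = pufa + mufa,
    ufa_sfa_ratio = if (sfa > 0) (mufa + pufa) / sfa else NA_real_,
    sum_omega3 = sum(profile[omega == 3]),
    sum_omega6 = sum(profile[omega == 6]),
    dha_epa_ratio = if (undefined) NA_real_ else dha / epa,
    dha_epa_undefined = undefined,
    sum_epa_dpa_dha = epa + dpa + dha,
    ui = sum(profile * db))
}

#' Unsaturation index of a profile
#'
#' Sum over unsaturated fatty acids of percentage times number of double
#' bonds; 0 for an all-saturated profile, 600 for a pure-DHA one.
#'
#' @param profile Named percentage profile.
#' @return The unsaturation index (dimensionless).
#' @export
unsaturation_index <- function(profile) {
  stopifnot(!is.null(names(profile)))
  db <- vapply(lapply(names(profile), parse_fa_name), `[[`, integer(1),
               "double_bonds")
  sum(profile * db)
}

#' Select the fatty-acid subset for discriminant analysis
#'
#' Applies the conventional membrane-phospholipid subset rules before the
#' MDA: drop chain lengths below 10 or above 22 carbons, drop C14:1 and
#' odd-chain monounsaturates, and drop fatty acids undetected (all-zero)
#' in every specimen. Each rule can be toggled off. Columns whose names
#' are not identified Cx:y(wz) fatty acids (e.g. an aggregate remainder
#' column) are never eligible.
#'
#' @param profiles Matrix or data frame of percentage profiles (specimens
#'   x fatty acids, named columns).
#' @param rules List of logical toggles `chain_length`, `odd_mufa`,
#'   `undetected` (all default `TRUE`).
#' @return Character vector of retained fatty-acid names.
#' @export
select_fa_for_mda <- function(profiles,
                              rules = list(chain_length = TRUE,
                                           odd_mufa = TRUE,
                                           undetected = TRUE)) {
  profiles <- as.matrix(profiles)
  fa <- colnames(profiles)
  parseable <- vapply(fa, function(nm)
    !inherits(tryCatch(parse_fa_name(nm), error = identity), "error"),
    logical(1))
  profiles <- profiles[, parseable, drop = FALSE]
  fa <- fa[parseable]
  desc <- lapply(fa, parse_fa_name)
  keep <- rep(TRUE, length(fa))
  if (isTRUE(rules$chain_length)) {
    carb <- vapply(desc, `[[`, integer(1), "carbons")
    keep <- keep & carb >= 10 & carb <= 22
  }
  if (isTRUE(rules$odd_mufa)) {
    carb <- vapply(desc, `[[`, integer(1), "carbons")
    db <- vapply(desc, `[[`, integer(1), "double_bonds")
    keep <- keep & !(db == 1 & (carb %% 2 == 1 | carb == 14))
  }
  if (isTRUE(rules$undetected)) {
    keep <- keep & colSums(profiles != 0) > 0
  }
  fa[keep]
}
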