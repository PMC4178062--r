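#' Published worked-example tables for the three-group sea lamprey analysis
#'
#' Reference quantities from a published stock-identification study of
#' anadromous sea lamprey (*Petromyzon marinus*) entering Portuguese river
#' basins, in which specimens were grouped a priori into a North/Central
#' group (Group 1: Minho, Lima, Cavado, Douro, Vouga, Mondego), a Tagus
#' group (Group 2) and a Guadiana group (Group 3). These tables are the
#' study's printed summaries, not its raw data (which were never
#' deposited): cross-validated confusion counts for the morphometric and
#' fatty-acid discriminant analyses, discriminant loadings and variance
#' shares for the three retained morphometric characters, size-adjusted
#' (natural-log scale) character means by sex, group mean fatty-acid
#' compositions of heart phospholipids, and meristic summary statistics.
#' They drive the worked examples and supply the magnitudes used by
#' [default_synthetic_config()].
#'
#' @return A list with components:
#' \describe{
#'   \item{morph_confusion}{3x3 matrix of cross-validated counts for the
#'     morphometric discriminant analysis (rows = true group).}
#'   \item{fa_confusion}{3x3 matrix of cross-validated counts for the
#'     heart fatty-acid discriminant analysis.}
#'   \item{morph_loadings}{3x2 matrix of discriminant loadings for
#'     characters O (eye length), lD2 (second dorsal fin length) and
#'     B1_B7 (branchial length) on the two discriminant functions.}
#'   \item{variance_shares}{Proportions of discriminated variance carried
#'     by functions 1 and 2 (0.593, 0.407).}
#'   \item{adjusted_char_means}{23x2 matrix of size-adjusted character
#'     means (natural-log mm) by sex.}
#'   \item{dimorphic_chars}{Characters with a significant sex effect at
#'     alpha = 0.05 in the published between-subjects tests.}
#'   \item{group_char_means}{Group means (log scale) of the three
#'     discriminating characters.}
#'   \item{fa_group_means}{24x3 matrix of mean fatty-acid percentages by
#'     group; NA marks components not detected (ND) in that group.}
#'   \item{meristic_summary}{Mean and SD of the 10 meristic characters.}
#' }
#' @examples
#' ref <- sea_lamprey_reference()
#' press_q(classification_table(ref$morph_confusion))
#' @export
sea_lamprey_reference <- function() {
  groups <- c("Group1", "Group2", "Group3")

  morph_confusion <- matrix(
    c(14, 11, 11,
      7, 16, 5,
      5, 1, 17),
    nrow = 3, byrow = TRUE, dimnames = list(true = groups, predicted = groups))

  fa_confusion <- matrix(
    c(26, 8, 2,
      1, 17, 1,
      0, 0, 19),
    nrow = 3, byrow = TRUE, dimnames = list(true = groups, predicted = groups))

  morph_loadings <- matrix(
    c(0.74, -0.13,
      -0.03, 0.81,
      -0.32, -0.60),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("O", "lD2", "B1_B7"), c("F1", "F2")))

  variance_shares <- c(F1 = 0.593, F2 = 0.407)

  chars <- c("d", "d_a", "a_C", "B7_C", "B7_a", "d_D1", "d_eD1", "d_D2",
             "D2_C", "lD1", "lD2", "D_D", "H", "d_O", "O", "O_B1", "Hco",
             "d_B1", "B1_B7", "d_B7", "d_n", "IO", "HW")
  adjusted_char_means <- matrix(c(
    # male, female (natural-log mm, size-adjusted)
    3.978, 3.945,
    6.449, 6.455,
    5.463, 5.448,
    6.541, 6.545,
    6.133, 6.145,
    6.099, 6.104,
    6.313, 6.316,
    6.379, 6.384,
    5.643, 5.630,
    4.671, 4.670,
    5.385, 5.369,
    3.682, 3.710,
    3.995, 4.068,
    4.130, 4.093,
    2.185, 2.176,
    3.023, 3.006,
    3.790, 3.773,
    4.486, 4.457,
    4.470, 4.466,
    5.165, 5.149,
    4.010, 3.972,
    3.857, 3.832,
    4.000, 3.990), ncol = 2, byrow = TRUE,
    dimnames = list(chars, c("male", "female")))

  # significant sex effect at alpha = 0.05 in the between-subjects tests
  dimorphic_chars <- c("d", "B7_C", "B7_a", "H", "d_O", "Hco", "d_B1",
                       "d_B7", "d_n", "IO")

  group_char_means <- matrix(c(
    2.18, 2.15, 2.22,    # O
    5.39, 5.37, 5.36,    # lD2
    4.46, 4.48, 4.47),   # B1_B7
    nrow = 3, byrow = TRUE,
    dimnames = list(c("O", "lD2", "B1_B7"), groups))

  w <- "\u03c9"  # omega
  fa_names <- c("C10:0", "C12:0", "C13:0", "C14:0", "C15:0", "C16:0",
                "C17:0", "C18:0", "C20:0", "C22:0",
                paste0("C14:1"), paste0("C16:1"),
                paste0("C18:1", w, "9"), paste0("C20:1", w, "9"),
                paste0("C22:1", w, "9"),
                paste0("C18:2", w, "6"), "C20:2",
                paste0("C20:3", w, "6"), paste0("C20:3", w, "3"),
                paste0("C20:4", w, "6"), paste0("C20:5", w, "3"),
                paste0("C22:2", w, "6"),
                paste0("C22:5", w, "3"), paste0("C22:6", w, "3"))
  fa_group_means <- matrix(c(
    # Group1, Group2, Group3 (mean percent of total; NA = not detected)
    2.84, 0.74, 3.36,
    0.08, 0.06, NA,
    7.51, 2.20, 13.47,
    1.50, 1.75, 0.70,
    NA, NA, 0.15,
    15.92, 20.39, 10.97,
    NA, NA, 0.90,
    7.06, 9.13, 5.55,
    0.20, 0.88, NA,
    0.22, 0.28, NA,
    NA, 0.06, NA,
    9.92, 13.69, 6.09,
    16.64, 22.95, 12.86,
    0.49, 1.00, 0.28,
    NA, 0.14, NA,
    0.29, 0.35, 0.30,
    0.14, 0.32, NA,
    NA, 0.16, NA,
    2.69, 3.10, 3.15,
    NA, 0.19, NA,
    2.60, 2.34, 3.11,
    0.12, NA, NA,
    3.46, 3.45, 4.25,
    8.21, 6.32, 10.45), ncol = 3, byrow = TRUE,
    dimnames = list(fa_names, groups))

  meristic_summary <- data.frame(
    meristic = c("Myo", "TNteeth", "AFteeth", "LFteeth", "PFteeth",
                 "TNrows", "AFrows", "LFrows", "PFrows", "IOcusps"),
    mean = c(73.1, 148.6, 39.5, 62.4, 37.2, 25.2, 7.0, 8.0, 9.2, 7.5),
    sd = c(1.6, 8.0, 3.8, 2.9, 2.7, 0.4, 0.0, 0.0, 0.4, 0.7),
    stringsAsFactors = FALSE)

  list(morph_confusion = morph_confusion,
       fa_confusion = fa_confusion,
       morph_loadings = morph_loadings,
       variance_shares = variance_shares,
       adjusted_char_means = adjusted_char_means,
       dimorphic_chars = dimorphic_chars,
       group_char_means = group_char_means,
       fa_group_means = fa_group_means,
       meristic_summary = meristic_summary)
}
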