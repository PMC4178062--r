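# Small configurable generator configs for simulation-based tests.

# A compact three-group design: one river per group, two sexes.
# `group_dev` is a [3 x n_char] matrix of group deviations added to a
# common log mean; `slopes` and `resid_sd` are recycled per character.
toy_config <- function(n_per_stratum = 10, n_char = 5,
                       group_dev = matrix(0, 3, n_char),
                       slopes = 0, resid_sd = 0.05,
                       base_mean = 4, tl_sd = 60,
                       fa_means = NULL, fa_dispersion = 0.3,
                       seed = 1L) {
  groups <- c("Group1", "Group2", "Group3")
  chars <- paste0("ch", seq_len(n_char))
  clm <- array(NA_real_, c(3, 2, n_char),
               dimnames = list(groups, c("male", "female"), chars))
  for (j in seq_len(n_char)) {
    clm[, "male", j] <- base_mean + group_dev[, j]
    clm[, "female", j] <- base_mean + group_dev[, j]
  }
  synthetic_config(
    n_per_stratum = n_per_stratum,
    tl_mean_mm = 864, tl_sd_mm = tl_sd,
    char_log_means = clm,
    char_slopes = stats::setNames(rep(slopes, length.out = n_char), chars),
    char_resid_sd = stats::setNames(rep(resid_sd, length.out = n_char),
                                    chars),
    fa_means = fa_means, fa_dispersion = fa_dispersion,
    rivers_by_group = list(Group1 = "R1", Group2 = "R2", Group3 = "R3"),
    seed = seed)
}

# toy fatty-acid mean matrix: 4 components, Group3 given its own profile,
# one component ND in Group3
toy_fa_means <- function() {
  m <- matrix(c(
    0.40, 0.40, 0.10,
    0.30, 0.30, 0.50,
    0.20, 0.20, 0.40,
    0.10, 0.10, NA),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("C16:0", "C18:0", "C18:1w9", "C22:6w3"),
                    c("Group1", "Group2", "Group3")))
  m
}

# character matrix (log values) straight from a generated specimen table
char_matrix <- function(spec, chars) {
  as.matrix(log(spec[, chars, drop = FALSE]))
}
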