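# Small fixtures built in code, shared across test files.

toy_counts <- function() {
  tb <- tibble::tibble(
    sample_id = c("s1", "s2"),
    gA = c(2, 1), gB = c(0, 3), gC = c(6, 0))
  validate_counts(tb, tibble::tibble(
    genus = c("gA", "gB", "gC"),
    phylum = c("Firmicutes", "Bacteroidota", "Firmicutes")))
  attr(tb, "taxonomy") <- tibble::tibble(
    genus = c("gA", "gB", "gC"),
    phylum = c("Firmicutes", "Bacteroidota", "Firmicutes"))
  tb
}

# A tiny two-group design used by inference tests: no intervention arms,
# one sampling week, effects only where a test puts them.
null_design <- function(seed, n_mice = 5, n_genera = 66, weeks = 10L,
                        groups = c("A", "B"), theta = 50) {
  sim_design(groups = groups, n_mice_per_group = n_mice, weeks = weeks,
             n_genera = n_genera, theta = theta,
             effect_table = tibble::tibble(
               group = character(0), week = integer(0),
               genus = character(0), log_fold = numeric(0)),
             seed = seed)
}

# Two-group design with a +/-delta log-fold pattern on the default key
# taxa of group "B" (single sampling week).
shifted_design <- function(seed, delta, n_mice = 5, weeks = 10L) {
  d0 <- null_design(seed, n_mice = n_mice, weeks = weeks)
  key <- d0$key_taxa
  pattern <- rep_len(c(1, -1), length(key))
  d0$effect_table <- tibble::tibble(
    group = "B", week = as.integer(weeks[length(weeks)]),
    genus = key, log_fold = pattern * delta)
  d0
}

# Ordination object built directly from a coordinate matrix, for
# invariance tests that bypass the distance computation.
ord_from_points <- function(pts) {
  colnames(pts) <- sprintf("PCo%d", seq_len(ncol(pts)))
  structure(list(
    sample_ids = rownames(pts), points = pts,
    eigenvalues = rep(1, ncol(pts)),
    proportion_explained = rep(1 / ncol(pts), ncol(pts)),
    n_negative_eigenvalues = 0L, negative_mass = 0,
    correction_applied = "none", method = "pcoa"),
    class = "ms_ordination")
}

random_orthogonal_2d <- function(angle, flip = FALSE) {
  q <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  if (flip) q[, 1] <- -q[, 1]
  q
}

matrix_to_tibble_for_test <- function(m) {
  rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}
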