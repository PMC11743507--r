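# Alpha diversity, relative-abundance normalization and the
# Firmicutes/Bacteroidota ratio.

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total count.  Already-normalized rows
#' pass through unchanged (the operation is idempotent).
#'
#' @param counts Tibble with `sample_id` plus numeric genus columns
#'   (counts or fractions).
#' @return A tibble of the same shape whose rows sum to 1; any attached
#'   taxonomy is carried along.
#' @export
to_relative <- function(counts) {
  m <- as_sample_matrix(counts, "count table")
  totals <- rowSums(m)
  zero <- rownames(m)[totals == 0]
  if (length(zero) > 0) {
    ms_abort(sprintf("zero-sum sample(s): %s", paste(zero, collapse = ", ")),
             "ms_validation_error")
  }
  rel <- matrix_to_tibble(sweep(m, 1, totals, "/"))
  attr(rel, "taxonomy") <- attr(counts, "taxonomy")
  rel
}

#' Shannon and Gini-Simpson indices of a composition
#'
#' `shannon()` is \eqn{-\sum_{p>0} p \ln p} in nats (natural log by
#' default); `simpson()` is the Gini-Simpson form \eqn{1 - \sum p^2},
#' bounded in \[0, 1 - 1/S\] for S observed genera.  Both are
#' permutation-invariant and unaffected by appending zero-abundance genera.
#'
#' @param p Numeric simplex vector (one sample's relative abundances).
#' @param base Logarithm base for Shannon (default `exp(1)`, nats).
#' @return A scalar.
#' @export
shannon <- function(p, base = exp(1)) {
  check_simplex(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
simpson <- function(p) {
  check_simplex(p)
  1 - sum(p^2)
}

#' Per-sample alpha-diversity summary
#'
#' Indices are computed on the proportions of the raw counts, without
#' rarefaction.
#'
#' @param counts Count (or relative-abundance) tibble.
#' @param base Shannon logarithm base.
#' @return Tibble with columns `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  rel <- to_relative(counts)
  m <- as_sample_matrix(rel)
  tibble(
    sample_id = rownames(m),
    shannon = unname(apply(m, 1, shannon, base = base)),
    simpson = unname(apply(m, 1, simpson)))
}

#' Firmicutes/Bacteroidota ratio
#'
#' Sums relative abundances over the genera of each of the two phyla and
#' returns their ratio, per sample or per group (group level first
#' averages the fractions across the group's samples).  A zero
#' Bacteroidota total yields a flagged `NA` ratio rather than an error.
#'
#' @param rel Relative-abundance tibble (see [to_relative()]).
#' @param taxonomy Tibble `genus`/`phylum`; defaults to the taxonomy
#'   attached to `rel`.
#' @param level `"per_sample"` or `"per_group"`.
#' @param metadata Required for `"per_group"`: tibble with `sample_id` and
#'   `group`.
#' @param firmicutes,bacteroidota Phylum labels for numerator and
#'   denominator.
#' @return Tibble with the phylum totals, `fb_ratio` and an `undefined`
#'   flag.
#' @export
fb_ratio <- function(rel, taxonomy = NULL,
                     level = c("per_sample", "per_group"),
                     metadata = NULL,
                     firmicutes = "Firmicutes", bacteroidota = "Bacteroidota") {
  level <- match.arg(level)
  taxonomy <- taxonomy %||% attr(rel, "taxonomy")
  if (is.null(taxonomy)) {
    ms_abort("fb_ratio needs a taxonomy (argument or attached attribute)",
             "ms_validation_error")
  }
  m <- as_sample_matrix(rel, "relative-abundance table")
  f_gen <- intersect(colnames(m), taxonomy$genus[taxonomy$phylum == firmicutes])
  b_gen <- intersect(colnames(m),
                     taxonomy$genus[taxonomy$phylum == bacteroidota])
  if (length(f_gen) == 0 || length(b_gen) == 0) {
    ms_abort(sprintf("taxonomy maps no genus to '%s' or '%s'",
                     firmicutes, bacteroidota), "ms_validation_error")
  }
  f_tot <- rowSums(m[, f_gen, drop = FALSE])
  b_tot <- rowSums(m[, b_gen, drop = FALSE])
  per_sample <- tibble(sample_id = rownames(m),
                       firmicutes = unname(f_tot),
                       bacteroidota = unname(b_tot))
  if (level == "per_sample") {
    out <- per_sample
  } else {
    if (is.null(metadata)) {
      ms_abort("per_group fb_ratio requires metadata", "ms_validation_error")
    }
    out <- per_sample |>
      dplyr::inner_join(metadata[c("sample_id", "group")], by = "sample_id") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(firmicutes = mean(.data$firmicutes),
                       bacteroidota = mean(.data$bacteroidota),
                       .groups = "drop")
  }
  out |>
    dplyr::mutate(
      undefined = .data$bacteroidota == 0,
      fb_ratio = dplyr::if_else(.data$undefined, NA_real_,
                                .data$firmicutes / .data$bacteroidota)) |>
    dplyr::relocate("fb_ratio", .before = "undefined")
}
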