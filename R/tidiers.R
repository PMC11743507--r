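# broom-style tidiers for the fitted/ordinated result objects.

#' Tidy an ordination into a coordinate tibble
#'
#' @param x An `ms_ordination` object.
#' @param metadata Optional sample metadata joined by `sample_id`.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per retained axis.
#' @method tidy ms_ordination
#' @export
tidy.ms_ordination <- function(x, metadata = NULL, ...) {
  out <- dplyr::bind_cols(tibble(sample_id = x$sample_ids),
                          as_tibble(x$points))
  if (!is.null(metadata)) {
    out <- dplyr::left_join(out, as_tibble(metadata), by = "sample_id")
  }
  out
}

#' @rdname tidy.ms_ordination
#' @method glance ms_ordination
#' @export
glance.ms_ordination <- function(x, ...) {
  tibble(
    method = x$method,
    n_samples = length(x$sample_ids),
    n_axes = ncol(x$points),
    prop_axis1 = x$proportion_explained[1],
    prop_axis2 = if (length(x$proportion_explained) > 1) {
      x$proportion_explained[2]
    } else NA_real_,
    n_negative_eigenvalues = x$n_negative_eigenvalues,
    negative_mass = x$negative_mass,
    correction = x$correction_applied)
}

#' Tidy a GM offset permutation test
#'
#' @param x An `ms_offset_test` object.
#' @param ... Unused.
#' @return One-row tibble with the statistic, p-value and bootstrap CI.
#' @method tidy ms_offset_test
#' @export
tidy.ms_offset_test <- function(x, ...) {
  tibble(group_a = x$group_a, group_b = x$group_b,
         gm_offset = x$gm_offset, n_axes_used = x$n_axes_used,
         permutation_p = x$permutation_p,
         n_permutations = x$n_permutations,
         ci_lo = x$bootstrap_ci[1], ci_hi = x$bootstrap_ci[2],
         conf_level = x$conf_level)
}

#' @rdname tidy.ms_offset_test
#' @method glance ms_offset_test
#' @export
glance.ms_offset_test <- function(x, ...) {
  tibble(gm_offset = x$gm_offset, permutation_p = x$permutation_p,
         n_a = x$n_a, n_b = x$n_b, seed = x$seed)
}

#' Tidy an ANOSIM result
#'
#' @param x An `ms_anosim` object.
#' @param ... Unused.
#' @return One-row tibble with `R`, `permutation_p`, `n_permutations`.
#' @method tidy ms_anosim
#' @export
tidy.ms_anosim <- function(x, ...) {
  tibble(R = x$R, permutation_p = x$permutation_p,
         n_permutations = x$n_permutations)
}

#' @rdname tidy.ms_anosim
#' @method glance ms_anosim
#' @export
glance.ms_anosim <- function(x, ...) tidy(x)
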