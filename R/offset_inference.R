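# The GM offset statistic: Euclidean distance between group centroids on
# the first ordination axes, with permutation inference, bootstrap
# intervals, and ANOSIM for overall group separation.

ord_points <- function(ord, n_axes) {
  if (!inherits(ord, "ms_ordination")) {
    ms_abort("expected an ms_ordination object", "ms_validation_error")
  }
  k <- ncol(ord$points)
  if (n_axes > k) {
    ms_abort(sprintf("requested %d axes but ordination retains %d",
                     n_axes, k), "ms_parameter_error")
  }
  ord$points[, seq_len(n_axes), drop = FALSE]
}

#' Group centroids in ordination space
#'
#' Per group, the arithmetic mean of each retained coordinate (the
#' "center point" whose pairwise distances define the offset statistic).
#'
#' @param ord An `ms_ordination` object.
#' @param metadata Tibble with `sample_id` and `group` covering every
#'   ordinated sample.
#' @param n_axes Number of leading axes (default 2).
#' @return Tibble with `group`, `n_samples` and one column per axis.
#' @export
group_centroids <- function(ord, metadata, n_axes = 2) {
  pts <- ord_points(ord, n_axes)
  grp <- metadata$group[match(rownames(pts), metadata$sample_id)]
  if (any(is.na(grp))) {
    ms_abort(sprintf("samples without a group label: %s",
                     paste(rownames(pts)[is.na(grp)], collapse = ", ")),
             "ms_join_error")
  }
  agg <- rowsum(pts, grp) / as.vector(table(grp)[sort(unique(grp))])
  dplyr::bind_cols(
    tibble(group = rownames(agg),
           n_samples = as.integer(table(grp)[rownames(agg)])),
    as_tibble(agg))
}

#' The GM offset between two groups
#'
#' The Euclidean distance between the two groups' centroid coordinates on
#' the first `n_axes` ordination axes (default 2, i.e. PCo1 and PCo2).
#' The statistic is symmetric in the two groups and invariant under any
#' orthogonal transform (sign flip, rotation) of the retained subspace.
#'
#' @inheritParams group_centroids
#' @param group_a,group_b Group labels (must be non-empty in `metadata`).
#' @return A non-negative scalar in ordination-coordinate units.
#' @export
gm_offset <- function(ord, metadata, group_a, group_b, n_axes = 2) {
  if (identical(group_a, group_b)) {
    ms_warn("group_a and group_b are the same label; offset is 0")
    return(0)
  }
  cen <- group_centroids(ord, metadata, n_axes)
  for (g in c(group_a, group_b)) {
    if (!g %in% cen$group) {
      ms_abort(sprintf("group '%s' has no samples in the ordination", g),
               "ms_validation_error")
    }
  }
  axes <- sprintf("PCo%d", seq_len(n_axes))
  a <- unlist(cen[cen$group == group_a, axes])
  b <- unlist(cen[cen$group == group_b, axes])
  sqrt(sum((a - b)^2))
}

#' Permutation test and bootstrap interval for the GM offset
#'
#' Ordinates the dissimilarity matrix once (the ordination depends only on
#' the distances, not on the labels, so permuting labels on the fixed
#' coordinates gives an exact null), permutes the group labels among the
#' two groups' samples to build the null distribution, and reports the
#' add-one permutation p-value \eqn{(1 + \#\{null \ge obs\}) / (1 + B)}.
#' A percentile bootstrap interval is obtained by resampling samples
#' within each group.
#'
#' @param d Square dissimilarity matrix (see [bray_curtis()]).
#' @param metadata Tibble with `sample_id` and `group`.
#' @param group_a,group_b Labels of the two groups to compare.
#' @param n_axes Leading axes used by the statistic (default 2).
#' @param n_permutations Number of label permutations (default 999, min 99).
#' @param n_bootstrap Bootstrap resamples for the CI (default 999; 0 skips
#'   the interval).
#' @param conf_level CI coverage (default 0.95).
#' @param seed Integer seed; identical seeds give identical results.
#' @param correction,method Passed to the ordination ([pcoa()] by default,
#'   `method = "pca"` uses [pca_relabund()]-style coordinates only if you
#'   ordinate yourself; here the ordination is always PCoA of `d`).
#' @return An object of class `ms_offset_test`.
#' @export
gm_offset_test <- function(d, metadata, group_a, group_b, n_axes = 2,
                           n_permutations = 999, n_bootstrap = 999,
                           conf_level = 0.95, seed = 1L,
                           correction = "none") {
  if (n_permutations < 99) {
    ms_abort("n_permutations must be at least 99", "ms_parameter_error")
  }
  if (inherits(d, "dist")) d <- as.matrix(d)
  ids_a <- metadata$sample_id[metadata$group == group_a]
  ids_b <- metadata$sample_id[metadata$group == group_b]
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    ms_abort("both groups must be non-empty", "ms_validation_error")
  }
  if (length(ids_a) + length(ids_b) < 4) {
    ms_abort("combined group size must be at least 4 (degenerate null)",
             "ms_parameter_error")
  }
  keep <- c(ids_a, ids_b)
  sub <- d[keep, keep, drop = FALSE]
  ord <- suppressWarnings(pcoa(sub, correction = correction))
  n_axes_used <- min(n_axes, ncol(ord$points))
  pts <- ord_points(ord, n_axes_used)
  n_a <- length(ids_a)
  n <- nrow(pts)
  cdist <- function(idx_a) {
    ca <- colMeans(pts[idx_a, , drop = FALSE])
    cb <- colMeans(pts[-idx_a, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }
  observed <- cdist(seq_len(n_a))
  withr::with_seed(seed, {
    null_dist <- vapply(seq_len(n_permutations), function(i) {
      cdist(sample.int(n, n_a))
    }, numeric(1))
    boot_ci <- c(NA_real_, NA_real_)
    boot <- numeric(0)
    if (n_bootstrap > 0) {
      boot <- vapply(seq_len(n_bootstrap), function(i) {
        ia <- sample.int(n_a, n_a, replace = TRUE)
        ib <- n_a + sample.int(n - n_a, n - n_a, replace = TRUE)
        ca <- colMeans(pts[ia, , drop = FALSE])
        cb <- colMeans(pts[ib, , drop = FALSE])
        sqrt(sum((ca - cb)^2))
      }, numeric(1))
      alpha <- (1 - conf_level) / 2
      boot_ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
    }
  })
  p <- (1 + sum(null_dist >= observed)) / (1 + n_permutations)
  structure(list(
    group_a = group_a, group_b = group_b,
    gm_offset = observed, n_axes_used = n_axes_used,
    permutation_p = p, n_permutations = n_permutations,
    null_distribution = null_dist,
    bootstrap_ci = boot_ci, bootstrap_distribution = boot,
    conf_level = conf_level,
    n_a = n_a, n_b = n - n_a, seed = as.integer(seed)
  ), class = "ms_offset_test")
}

#' @export
print.ms_offset_test <- function(x, ...) {
  cat(sprintf("<GM offset> %s vs %s: %.4f on %d axes\n",
              x$group_a, x$group_b, x$gm_offset, x$n_axes_used))
  cat(sprintf("  permutation p = %.4g (%d permutations), bootstrap %d%% CI [%.4f, %.4f]\n",
              x$permutation_p, x$n_permutations,
              round(100 * x$conf_level), x$bootstrap_ci[1], x$bootstrap_ci[2]))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between- versus within-group dissimilarities:
#' \eqn{R = (\bar r_B - \bar r_W) / (M / 4)} with M the number of sample
#' pairs, tested by label permutation.  Delegates to
#' [vegan::anosim()] with an explicit seed for reproducibility.
#'
#' @param d Square dissimilarity matrix.
#' @param metadata Tibble with `sample_id` and `group`; at least 2 groups
#'   of at least 2 samples each.
#' @param n_permutations Label permutations (default 999).
#' @param seed Integer seed.
#' @return An object of class `ms_anosim` with elements `R`,
#'   `permutation_p`, `n_permutations`, `seed`.
#' @export
gm_anosim <- function(d, metadata, n_permutations = 999, seed = 1L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  grp <- metadata$group[match(rownames(d), metadata$sample_id)]
  if (any(is.na(grp))) {
    ms_abort("samples without a group label", "ms_join_error")
  }
  sizes <- table(grp)
  if (length(sizes) < 2) {
    ms_abort("ANOSIM needs at least 2 groups", "ms_validation_error")
  }
  if (any(sizes < 2)) {
    ms_abort(sprintf("group(s) of size 1: %s",
                     paste(names(sizes)[sizes < 2], collapse = ", ")),
             "ms_validation_error")
  }
  fit <- withr::with_seed(seed, vegan::anosim(stats::as.dist(d), grp,
                                              permutations = n_permutations))
  structure(list(
    R = unname(fit$statistic),
    permutation_p = fit$signif,
    n_permutations = n_permutations,
    seed = as.integer(seed),
    vegan_fit = fit
  ), class = "ms_anosim")
}

#' @export
print.ms_anosim <- function(x, ...) {
  cat(sprintf("<ANOSIM> R = %.4f, permutation p = %.4g (%d permutations)\n",
              x$R, x$permutation_p, x$n_permutations))
  invisible(x)
}
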