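# Bray-Curtis dissimilarity and classical principal-coordinates analysis,
# implemented from first principles (Gower double-centering +
# eigendecomposition) because the centroid-offset statistic is defined on
# these coordinates and its units depend on the sqrt-eigenvalue scaling.

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} computed on
#' relative abundances (count input is normalized first, so for rows on
#' the simplex this is half the Manhattan distance).  Invariant to genus
#' reordering and to all-zero genus columns.
#'
#' @param x Count or relative-abundance tibble (`sample_id` + genus
#'   columns), at least 2 samples.
#' @return A symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], sample ids as dimnames.
#' @export
bray_curtis <- function(x) {
  rel <- to_relative(x)
  m <- as_sample_matrix(rel)
  if (nrow(m) < 2) {
    ms_abort("bray_curtis needs at least 2 samples", "ms_validation_error")
  }
  d <- as.matrix(dist(m, method = "manhattan")) / 2
  diag(d) <- 0
  d
}

#' Classical principal-coordinates analysis (PCoA)
#'
#' Eigendecomposes the Gower-centered matrix \eqn{-\frac12 J D^2 J} and
#' returns coordinates scaled by the square root of each retained positive
#' eigenvalue.  Bray-Curtis matrices are generally non-Euclidean; by
#' default negative eigenvalues are dropped with a warning reporting their
#' mass fraction, or removed beforehand with the Lingoes or Cailliez
#' additive corrections.  Eigenvector signs follow a deterministic
#' convention (the largest-magnitude loading of each axis is made
#' positive), so repeated runs are identical; the centroid-offset
#' statistic is invariant to this choice.
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`).
#' @param n_axes Number of axes to retain (default: all positive axes).
#' @param correction `"none"`, `"lingoes"` or `"cailliez"`.
#' @return An object of class `ms_ordination` with elements `sample_ids`,
#'   `points` (samples x axes, columns `PCo1`, `PCo2`, ...), `eigenvalues`
#'   (all, descending), `proportion_explained` (per retained axis, relative
#'   to the total absolute eigenvalue mass), `n_negative_eigenvalues`,
#'   `negative_mass`, `correction_applied` and `method`.
#' @export
pcoa <- function(d, n_axes = NULL, correction = c("none", "lingoes",
                                                  "cailliez")) {
  correction <- match.arg(correction)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    ms_abort("d must be a square matrix or dist", "ms_validation_error")
  }
  n <- nrow(d)
  if (max(abs(d - t(d))) > 1e-12) {
    ms_abort("dissimilarity matrix is not symmetric", "ms_validation_error")
  }
  if (any(abs(diag(d)) > 1e-12)) {
    ms_abort("dissimilarity matrix must have a zero diagonal",
             "ms_validation_error")
  }
  if (!is.null(n_axes)) {
    if (n_axes < 1) ms_abort("n_axes must be >= 1", "ms_parameter_error")
    if (n_axes > n - 1) {
      ms_abort("n_axes must be at most n_samples - 1", "ms_parameter_error")
    }
  }
  ids <- rownames(d) %||% sprintf("s%d", seq_len(n))

  ev_of <- function(dd) {
    b <- gower_center(dd)
    e <- eigen(b, symmetric = TRUE)
    e
  }
  e <- ev_of(d)
  tol <- max(abs(e$values)) * 1e-8
  if (correction != "none" && min(e$values) < -tol) {
    if (correction == "lingoes") {
      c1 <- -min(e$values)
      d2 <- d^2 + 2 * c1
      diag(d2) <- 0
      e <- ev_of(sqrt(d2))
    } else {
      c2 <- cailliez_constant(d)
      dc <- d + c2
      diag(dc) <- 0
      e <- ev_of(dc)
    }
    tol <- max(abs(e$values)) * 1e-8
  }
  values <- e$values
  n_neg <- sum(values < -tol)
  neg_mass <- if (any(values > 0)) {
    sum(abs(values[values < -tol])) / sum(abs(values))
  } else 0
  pos <- which(values > tol)
  if (length(pos) == 0) {
    ms_abort("degenerate input: no positive eigenvalues", "ms_degenerate_error")
  }
  if (correction == "none" && n_neg > 0) {
    ms_warn(sprintf(
      "non-Euclidean dissimilarities: %d negative eigenvalues (%.1f%% of eigenvalue mass) dropped",
      n_neg, 100 * neg_mass), class = "ms_negative_eigenvalues")
  }
  k <- min(n_axes %||% length(pos), length(pos))
  idx <- pos[seq_len(k)]
  vec <- e$vectors[, idx, drop = FALSE]
  vec <- fix_signs(vec)
  pts <- sweep(vec, 2, sqrt(values[idx]), "*")
  dimnames(pts) <- list(ids, sprintf("PCo%d", seq_len(k)))
  structure(list(
    sample_ids = ids,
    points = pts,
    eigenvalues = values,
    proportion_explained = values[idx] / sum(abs(values)),
    n_negative_eigenvalues = n_neg,
    negative_mass = neg_mass,
    correction_applied = correction,
    method = "pcoa"
  ), class = "ms_ordination")
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  a - outer(rm, rep(1, ncol(a))) - outer(rep(1, nrow(a)), colMeans(a)) +
    mean(a)
}

# Smallest additive constant on the dissimilarities themselves that makes
# the configuration Euclidean: largest eigenvalue of the classical 2n x 2n
# companion problem.
cailliez_constant <- function(d) {
  n <- nrow(d)
  d1 <- gower_center(d)
  d2 <- gower_center_raw(d)
  zero <- matrix(0, n, n)
  big <- rbind(cbind(zero, 2 * d1),
               cbind(-diag(n), -4 * d2))
  max(Re(eigen(big, only.values = TRUE)$values))
}

# Gower-centering of -1/2 D (not squared), used by the Cailliez constant.
gower_center_raw <- function(d) {
  a <- -0.5 * d
  rm <- rowMeans(a)
  a - outer(rm, rep(1, ncol(a))) - outer(rep(1, nrow(a)), colMeans(a)) +
    mean(a)
}

# Deterministic sign convention: largest-magnitude element positive.
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Principal components of centered relative abundances
#'
#' A fidelity mode for toolchains that ordinate community tables with a
#' principal-component routine rather than a dissimilarity eigenanalysis:
#' column-centered relative abundances decomposed by singular values, with
#' the scores as coordinates.  Axes are still labelled `PCo1`, `PCo2`, ...
#' so the downstream offset statistic can consume either mode; the
#' `method` flag distinguishes them.
#'
#' @param rel Relative-abundance (or count) tibble, at least 2 samples.
#' @param n_axes Axes to retain (default all with positive variance).
#' @return An `ms_ordination` object with `method = "pca"`.
#' @export
pca_relabund <- function(rel, n_axes = NULL) {
  rel <- to_relative(rel)
  m <- as_sample_matrix(rel)
  if (nrow(m) < 2) {
    ms_abort("pca_relabund needs at least 2 samples", "ms_validation_error")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tol <- max(ev) * 1e-12
  pos <- which(ev > tol)
  k <- min(n_axes %||% length(pos), length(pos))
  rot <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE])
  pts <- scale(m, center = TRUE, scale = FALSE) %*% rot
  dimnames(pts) <- list(rownames(m), sprintf("PCo%d", seq_len(k)))
  structure(list(
    sample_ids = rownames(m),
    points = pts,
    eigenvalues = ev,
    proportion_explained = ev[seq_len(k)] / sum(ev),
    n_negative_eigenvalues = 0L,
    negative_mass = 0,
    correction_applied = "none",
    method = "pca"
  ), class = "ms_ordination")
}

#' @export
print.ms_ordination <- function(x, ...) {
  cat(sprintf("<ms_ordination: %s> %d samples, %d axes\n", x$method,
              length(x$sample_ids), ncol(x$points)))
  cat(sprintf("  first axes explain %s\n",
              paste(sprintf("%.1f%%", 100 * head(x$proportion_explained, 3)),
                    collapse = ", ")))
  if (x$n_negative_eigenvalues > 0) {
    cat(sprintf("  %d negative eigenvalues (%.1f%% mass), correction: %s\n",
                x$n_negative_eigenvalues, 100 * x$negative_mass,
                x$correction_applied))
  }
  invisible(x)
}
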