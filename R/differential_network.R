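# Per-genus differential abundance (two-sample tests on relative
# abundances), the key-microbes intersection, core/specific genus
# partition, abundance-ratio summaries and genus-phenotype correlation
# networks.

condition_labels <- function(metadata, condition) {
  if (!condition %in% names(metadata)) {
    ms_abort(sprintf("metadata has no column '%s'", condition),
             "ms_schema_error")
  }
  as.character(metadata[[condition]])
}

#' Per-genus differential abundance between two conditions
#'
#' Welch's unequal-variance t-test per genus on relative abundances
#' (Student's variant with `var_equal = TRUE`; Kruskal-Wallis with
#' `test = "kruskal"`).  Raw p < alpha is the default retention rule;
#' apply [stats::p.adjust()] downstream if desired.  Genera observed in
#' fewer than `min_prevalence` of the samples are excluded and reported in
#' the `"excluded"` attribute.
#'
#' @param rel Relative-abundance tibble.
#' @param metadata Tibble with `sample_id` and the condition column.
#' @param cond_a,cond_b Condition labels (each needs >= 2 samples).
#' @param condition Metadata column defining conditions (default
#'   `"group"`; build a combined column for group-by-week contrasts).
#' @param alpha Significance level (default 0.05).
#' @param min_prevalence Minimum fraction of samples with nonzero
#'   abundance (default 0).
#' @param var_equal Use the pooled-variance t-test (default `FALSE`).
#' @param test `"t"` (default) or `"kruskal"`.
#' @param pseudocount Added to both means for the log2 ratio (default
#'   1e-6 on the relative-abundance scale).
#' @return Tibble sorted by p: `genus`, `mean_a`, `mean_b`, `log2_ratio`,
#'   `p_value`, `significant`.
#' @export
differential_genera <- function(rel, metadata, cond_a, cond_b,
                                condition = "group", alpha = 0.05,
                                min_prevalence = 0, var_equal = FALSE,
                                test = c("t", "kruskal"),
                                pseudocount = 1e-6) {
  test <- match.arg(test)
  if (pseudocount < 0) {
    ms_abort("pseudocount must be non-negative", "ms_parameter_error")
  }
  m <- as_sample_matrix(rel, "relative-abundance table")
  labels <- condition_labels(metadata, condition)
  names(labels) <- metadata$sample_id
  lab <- labels[rownames(m)]
  ia <- which(lab == cond_a)
  ib <- which(lab == cond_b)
  if (length(ia) < 2 || length(ib) < 2) {
    ms_abort(sprintf("both conditions need >= 2 samples ('%s': %d, '%s': %d)",
                     cond_a, length(ia), cond_b, length(ib)),
             "ms_validation_error")
  }
  sub <- m[c(ia, ib), , drop = FALSE]
  prevalence <- colMeans(sub > 0)
  keep <- prevalence >= min_prevalence
  excluded <- colnames(m)[!keep]
  res <- purrr::map_dfr(colnames(m)[keep], function(g) {
    xa <- m[ia, g]
    xb <- m[ib, g]
    p <- if (test == "kruskal") {
      if (length(unique(c(xa, xb))) == 1) 1
      else kruskal.test(list(xa, xb))$p.value
    } else if (var(xa) == 0 && var(xb) == 0) {
      # t-test undefined for constant data: identical means are trivially
      # non-significant, distinct constant means trivially significant
      if (mean(xa) == mean(xb)) 1 else 0
    } else {
      t.test(xa, xb, var.equal = var_equal)$p.value
    }
    tibble(genus = g, mean_a = mean(xa), mean_b = mean(xb),
           log2_ratio = log2((mean(xa) + pseudocount) /
                               (mean(xb) + pseudocount)),
           p_value = p)
  })
  res <- res |>
    dplyr::mutate(significant = .data$p_value < alpha) |>
    dplyr::arrange(.data$p_value)
  attr(res, "excluded") <- excluded
  attr(res, "alpha") <- alpha
  res
}

#' Key microbes: genera shifted by both interventions
#'
#' The intersection of the significant genus sets of two differential
#' contrasts (commutative and idempotent).
#'
#' @param diff_a,diff_b Results of [differential_genera()].
#' @return Sorted character vector of genus names.
#' @export
key_microbes <- function(diff_a, diff_b) {
  sort(intersect(diff_a$genus[diff_a$significant],
                 diff_b$genus[diff_b$significant]))
}

#' Core and group-specific genera
#'
#' A genus is "present" in a group when its group-mean relative abundance
#' exceeds `presence_threshold` (default 0, i.e. any nonzero mean).  Core
#' genera are present in every group; a group's specific genera are
#' present there and in no other group.
#'
#' @param rel Relative-abundance tibble.
#' @param metadata Tibble with `sample_id` and the grouping column.
#' @param presence_threshold Group-mean abundance cutoff (default 0).
#' @param group_var Metadata column to partition by (default `"group"`).
#' @return An `ms_core_partition` list: `per_group` (named list of genus
#'   sets), `core`, `specific` (named list).
#' @export
core_specific <- function(rel, metadata, presence_threshold = 0,
                          group_var = "group") {
  m <- as_sample_matrix(rel, "relative-abundance table")
  labels <- condition_labels(metadata, group_var)
  names(labels) <- metadata$sample_id
  lab <- labels[rownames(m)]
  groups <- sort(unique(lab))
  if (length(groups) < 2) {
    ms_abort("core_specific needs at least 2 groups", "ms_validation_error")
  }
  per_group <- lapply(groups, function(g) {
    mu <- colMeans(m[lab == g, , drop = FALSE])
    sort(names(mu)[mu > presence_threshold])
  })
  names(per_group) <- groups
  core <- sort(Reduce(intersect, per_group))
  specific <- lapply(groups, function(g) {
    others <- unlist(per_group[setdiff(groups, g)], use.names = FALSE)
    sort(setdiff(per_group[[g]], others))
  })
  names(specific) <- groups
  structure(list(per_group = per_group, core = core, specific = specific,
                 presence_threshold = presence_threshold),
            class = "ms_core_partition")
}

#' @export
print.ms_core_partition <- function(x, ...) {
  cat(sprintf("<core/specific partition> %d groups, %d core genera\n",
              length(x$per_group), length(x$core)))
  for (g in names(x$specific)) {
    cat(sprintf("  %s: %d present, %d specific\n", g,
                length(x$per_group[[g]]), length(x$specific[[g]])))
  }
  invisible(x)
}

#' @method tidy ms_core_partition
#' @export
tidy.ms_core_partition <- function(x, ...) {
  dplyr::bind_rows(
    tibble(genus = x$core, status = "core", group = NA_character_),
    purrr::imap_dfr(x$specific, function(gen, g) {
      if (length(gen) == 0) return(tibble())
      tibble(genus = gen, status = "specific", group = g)
    }))
}

#' Per-genus abundance ratios between two conditions
#'
#' `(mean_post + pseudocount) / (mean_pre + pseudocount)` per genus.
#'
#' @inheritParams differential_genera
#' @param cond_post,cond_pre Condition labels (numerator, denominator).
#' @return Tibble `genus`, `mean_post`, `mean_pre`, `ratio`.
#' @export
abundance_ratio <- function(rel, metadata, cond_post, cond_pre,
                            condition = "group", pseudocount = 1e-6) {
  if (pseudocount < 0) {
    ms_abort("pseudocount must be non-negative", "ms_parameter_error")
  }
  m <- as_sample_matrix(rel, "relative-abundance table")
  labels <- condition_labels(metadata, condition)
  names(labels) <- metadata$sample_id
  lab <- labels[rownames(m)]
  ip <- which(lab == cond_post)
  iq <- which(lab == cond_pre)
  if (length(ip) == 0 || length(iq) == 0) {
    ms_abort("both conditions must be non-empty", "ms_validation_error")
  }
  mp <- colMeans(m[ip, , drop = FALSE])
  mq <- colMeans(m[iq, , drop = FALSE])
  tibble(genus = colnames(m), mean_post = unname(mp), mean_pre = unname(mq),
         ratio = unname((mp + pseudocount) / (mq + pseudocount)))
}

# Correlation matrix with t-approximation p-values (the approximation used
# by the usual pairwise-correlation toolkits; Spearman via ranks).
cor_with_p <- function(x, method) {
  if (method == "spearman") x <- apply(x, 2, rank)
  n <- nrow(x)
  r <- cor(x)
  r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t_stat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Genus-genus and genus-phenotype correlation network
#'
#' All pairwise correlations among genera and between genera and body
#' features; edges are retained where the (optionally
#' Benjamini-Hochberg-adjusted) p-value is below `alpha`.  Constant
#' columns are skipped with a warning; the edge list is symmetric in the
#' node pair (each undirected edge appears once) and contains no
#' self-edges.
#'
#' @param rel Relative-abundance tibble.
#' @param features Data frame of body measurements keyed by `sample_id`,
#'   or by `mouse_id` (then `metadata` supplies the sample-to-mouse map).
#' @param metadata Optional tibble with `sample_id` and `mouse_id`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Edge retention level (default 0.05).
#' @param adjust `"none"` (default, mirrors a raw p < 0.05 rule) or
#'   `"bh"`.
#' @return Tibble of retained edges with class `ms_network`: `source`,
#'   `target`, `source_type`, `target_type`, `method`, `r`, `p`, `q`.
#' @export
correlation_network <- function(rel, features = NULL, metadata = NULL,
                                method = c("pearson", "spearman"),
                                alpha = 0.05, adjust = c("none", "bh")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  m <- as_sample_matrix(rel, "relative-abundance table")
  node_type <- setNames(rep("genus", ncol(m)), colnames(m))
  if (!is.null(features)) {
    feat <- as_tibble(features)
    if ("sample_id" %in% names(feat)) {
      ridx <- match(rownames(m), feat$sample_id)
    } else if ("mouse_id" %in% names(feat)) {
      if (is.null(metadata)) {
        ms_abort("features keyed by mouse_id need metadata to map samples",
                 "ms_join_error")
      }
      mouse_of <- metadata$mouse_id[match(rownames(m), metadata$sample_id)]
      ridx <- match(mouse_of, feat$mouse_id)
    } else {
      ms_abort("features need a 'sample_id' or 'mouse_id' column",
               "ms_schema_error")
    }
    unmatched <- rownames(m)[is.na(ridx)]
    if (length(unmatched) > 0) {
      ms_abort(sprintf("samples with no joinable features: %s",
                       paste(unmatched, collapse = ", ")), "ms_join_error")
    }
    fnum <- feat[vapply(feat, is.numeric, logical(1))]
    fmat <- as.matrix(fnum)[ridx, , drop = FALSE]
    rownames(fmat) <- rownames(m)
    node_type <- c(node_type, setNames(rep("feature", ncol(fmat)),
                                       colnames(fmat)))
    m <- cbind(m, fmat)
  }
  if (nrow(m) < 3) {
    ms_abort("need at least 3 joint observations", "ms_validation_error")
  }
  const <- apply(m, 2, function(v) var(v) == 0)
  if (any(const)) {
    ms_warn(sprintf("skipping constant column(s): %s",
                    paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
    node_type <- node_type[colnames(m)]
  }
  cp <- cor_with_p(m, method)
  idx <- which(upper.tri(cp$r), arr.ind = TRUE)
  edges <- tibble(
    source = colnames(m)[idx[, 1]],
    target = colnames(m)[idx[, 2]],
    source_type = unname(node_type[colnames(m)[idx[, 1]]]),
    target_type = unname(node_type[colnames(m)[idx[, 2]]]),
    method = method,
    r = cp$r[idx],
    p = cp$p[idx])
  # feature-feature pairs are not part of the network
  edges <- edges[!(edges$source_type == "feature" &
                     edges$target_type == "feature"), ]
  edges$q <- p.adjust(edges$p, method = "BH")
  crit <- if (adjust == "bh") edges$q else edges$p
  retained <- edges[crit < alpha, ]
  attr(retained, "n_pairs_tested") <- nrow(edges)
  attr(retained, "n_obs") <- cp$n
  class(retained) <- c("ms_network", class(retained))
  retained
}
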