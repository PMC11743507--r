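# Group-level phenotype deltas (endpoint mean minus reference mean),
# contrasts between deltas, glucose-curve areas, and the offset-phenotype
# coupling correlation.

#' Group-level body-weight and glucose deltas
#'
#' For each group, the mean body weight and fasting blood glucose at the
#' reference and endpoint weeks and their differences
#' `delta = mean(end) - mean(ref)`.  The delta is exactly linear in the
#' measurements: scaling all values by c scales it by c, adding a
#' constant leaves it unchanged.
#'
#' @param phenotype Tibble `mouse_id`/`week`/`bw`/`fbg` (a `group` column
#'   is used directly if present).
#' @param metadata Optional tibble mapping `mouse_id` to `group` (e.g.
#'   sample metadata); required when `phenotype` has no `group` column.
#' @param group Optional single group label; default summarises all groups.
#' @param week_ref,week_end Reference and endpoint weeks (defaults 4, 10).
#' @return Tibble with one row per group: `group`, `n_mice`,
#'   `bw_mean_ref`, `bw_mean_end`, `delta_bw`, `fbg_mean_ref`,
#'   `fbg_mean_end`, `delta_fbg`.
#' @export
group_delta <- function(phenotype, metadata = NULL, group = NULL,
                        week_ref = 4, week_end = 10) {
  ph <- as_tibble(phenotype)
  if (!"group" %in% names(ph)) {
    if (is.null(metadata)) {
      ms_abort("phenotype has no 'group' column and no metadata was given",
               "ms_validation_error")
    }
    map <- dplyr::distinct(metadata[c("mouse_id", "group")])
    ph <- dplyr::left_join(ph, map, by = "mouse_id")
    if (any(is.na(ph$group))) {
      ms_abort(sprintf("mice without a group: %s",
                       paste(unique(ph$mouse_id[is.na(ph$group)]),
                             collapse = ", ")), "ms_join_error")
    }
  }
  if (!is.null(group)) ph <- ph[ph$group %in% group, ]
  if (nrow(ph) == 0) {
    ms_abort("no phenotype rows for the requested group(s)",
             "ms_validation_error")
  }
  wide <- ph[ph$week %in% c(week_ref, week_end), ]
  missing <- wide |>
    dplyr::count(.data$group, .data$mouse_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(missing) > 0) {
    ms_abort(sprintf(
      "mice missing a measurement at week %s or %s: %s", week_ref, week_end,
      paste(missing$mouse_id, collapse = ", ")), "ms_validation_error")
  }
  wide |>
    dplyr::mutate(when = dplyr::if_else(.data$week == week_ref, "ref", "end")) |>
    dplyr::group_by(.data$group, .data$when) |>
    dplyr::summarise(bw = mean(.data$bw), fbg = mean(.data$fbg),
                     n_mice = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "when", values_from = c("bw", "fbg"),
                       id_cols = c("group", "n_mice")) |>
    dplyr::transmute(
      group = .data$group, n_mice = .data$n_mice,
      bw_mean_ref = .data$bw_ref, bw_mean_end = .data$bw_end,
      delta_bw = .data$bw_end - .data$bw_ref,
      fbg_mean_ref = .data$fbg_ref, fbg_mean_end = .data$fbg_end,
      delta_fbg = .data$fbg_end - .data$fbg_ref)
}

#' Contrast two group deltas
#'
#' `absolute_excess = delta_a - delta_b` and
#' `percent_excess = 100 * (delta_a - delta_b) / delta_a` (the denominator
#' is the first group's delta).  A zero `delta_a` flags the percentage as
#' undefined rather than erroring.
#'
#' @param a,b One-row delta summaries from [group_delta()].
#' @param measure `"bw"` or `"fbg"`.
#' @return One-row tibble: `measure`, `group_a`, `group_b`,
#'   `absolute_excess`, `percent_excess`, `undefined`.
#' @export
delta_contrast <- function(a, b, measure = c("bw", "fbg")) {
  measure <- match.arg(measure)
  col <- paste0("delta_", measure)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  da <- a[[col]]
  db <- b[[col]]
  undefined <- da == 0
  tibble(
    measure = measure,
    group_a = a$group, group_b = b$group,
    absolute_excess = da - db,
    percent_excess = if (undefined) NA_real_ else 100 * (da - db) / da,
    undefined = undefined)
}

#' Trapezoidal area under a glucose-tolerance curve
#'
#' Per mouse, the trapezoidal integral of glucose (mmol/L) over minutes.
#' With `baseline_subtract = TRUE` the integrand is
#' `max(glucose - glucose(0), 0)` (incremental area above fasting level).
#'
#' @param glucose Tibble `mouse_id`/`minutes`/`glucose` (see
#'   [read_glucose()]); at least 2 time points per mouse.
#' @param baseline_subtract Logical (default `FALSE`, total area).
#' @return Tibble `mouse_id`, `auc` (mmol/L x min), `baseline_subtracted`.
#' @export
glucose_auc <- function(glucose, baseline_subtract = FALSE) {
  validate_glucose(glucose)
  glucose |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(auc = {
      if (dplyr::n() < 2) {
        ms_abort(sprintf("mouse '%s' has fewer than 2 time points",
                         dplyr::cur_group()$mouse_id), "ms_validation_error")
      }
      y <- if (baseline_subtract) pmax(.data$glucose - .data$glucose[1], 0)
           else .data$glucose
      trapezoid(.data$minutes, y)
    }, .groups = "drop") |>
    dplyr::mutate(baseline_subtracted = baseline_subtract)
}

#' Correlation between community offsets and phenotype changes
#'
#' Pearson (or Spearman) correlation between community-shift magnitudes
#' and phenotype deltas.  The caller constructs the points - per mouse or
#' per group pair - as a two-column table.
#'
#' @param points Data frame whose first two numeric columns are the offset
#'   values and the phenotype deltas (canonically named `offset` and
#'   `delta`); at least 3 rows.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `method`, `r`, `p_value`, `n`, `undefined`
#'   (`TRUE` with `NA` r when either margin has zero variance).
#' @export
offset_phenotype_correlation <- function(points, method = c("pearson",
                                                            "spearman")) {
  method <- match.arg(method)
  pts <- as_tibble(points)
  num <- pts[vapply(pts, is.numeric, logical(1))]
  if (ncol(num) < 2) {
    ms_abort("points must contain two numeric columns", "ms_validation_error")
  }
  x <- num[[1]]
  y <- num[[2]]
  n <- sum(stats::complete.cases(x, y))
  if (n < 3) {
    ms_abort("need at least 3 complete observations", "ms_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(method = method, r = NA_real_, p_value = NA_real_,
                  n = n, undefined = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble(method = method, r = unname(ct$estimate),
         p_value = ct$p.value, n = n, undefined = FALSE)
}

#' Reconstruct a per-mouse phenotype table from group summaries
#'
#' Builds a synthetic per-mouse table whose group means (and, when a
#' standard deviation column is present, sample standard deviations)
#' exactly match reported group-level summaries, by placing `n_mice`
#' values symmetrically around each mean.  Useful for reproducing
#' published group-mean arithmetic when only summaries are available; the
#' reconstructed individual values are synthetic.
#'
#' @param summary Tibble with columns `group`, `week`, `mean_bw` and
#'   optionally `sd_bw`, `mean_fbg`, `sd_fbg`.
#' @param n_mice Mice per group (default 5).
#' @return A phenotype tibble (`mouse_id`, `group`, `week`, `bw`, `fbg`).
#' @export
phenotype_from_summary <- function(summary, n_mice = 5) {
  offs <- seq(-1, 1, length.out = n_mice)
  offs <- offs - mean(offs)
  offs <- offs / sd(offs)  # unit sample sd, zero mean
  purrr::pmap_dfr(as_tibble(summary), function(...) {
    row <- list(...)
    sd_bw <- row$sd_bw %||% 0
    mean_fbg <- row$mean_fbg %||% 8
    sd_fbg <- row$sd_fbg %||% 0
    tibble(
      mouse_id = sprintf("%s_m%d", gsub("[^A-Za-z0-9]+", "", row$group),
                         seq_len(n_mice)),
      group = row$group, week = as.integer(row$week),
      bw = row$mean_bw + offs * sd_bw,
      fbg = mean_fbg + offs * sd_fbg)
  })
}
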