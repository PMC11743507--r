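# One reproducible run: simulate (or read) -> diversity -> ordinate ->
# offsets -> ANOSIM -> phenotype deltas -> differential genera / network,
# with a strict config, per-stage seeds derived from one top-level seed,
# machine-readable warnings in run.log, and a deterministic report.json.

config_keys <- c("design", "counts", "taxonomy", "metadata", "phenotype",
                 "glucose", "week_ref", "week_end", "n_axes", "permutations",
                 "n_bootstrap", "alpha", "adjust", "method", "correction",
                 "presence_threshold", "min_prevalence", "control_group",
                 "reference_group", "treatment_groups", "seed", "out_dir")

#' Validate and resolve a run configuration
#'
#' Accepts a YAML path or a named list, rejects unknown keys (strict
#' mode), requires a seed (every run has stochastic stages), and fills in
#' the documented defaults: reference/endpoint weeks 4/10, 2 ordination
#' axes, 999 permutations, alpha 0.05, no multiple-testing adjustment,
#' PCoA ordination.
#'
#' @param x Path to a YAML file, or a named list.
#' @return An `ms_run_config` list with all defaults resolved.
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x) else x
  if (!is.list(cfg)) {
    ms_abort("config must be a YAML file or a named list", "ms_config_error")
  }
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown) > 0) {
    ms_abort(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")), "ms_config_error")
  }
  if (is.null(cfg$seed)) {
    ms_abort("config must set 'seed' (the run has stochastic stages)",
             "ms_config_error")
  }
  has_paths <- !is.null(cfg$counts)
  if (is.null(cfg$design) && !has_paths) {
    ms_abort("config needs either 'design' (simulation) or input paths",
             "ms_config_error")
  }
  defaults <- list(week_ref = 4L, week_end = 10L, n_axes = 2L,
                   permutations = 999L, n_bootstrap = 199L, alpha = 0.05,
                   adjust = "none", method = "pcoa", correction = "none",
                   presence_threshold = 0, min_prevalence = 0)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (!cfg$method %in% c("pcoa", "pca")) {
    ms_abort("method must be 'pcoa' or 'pca'", "ms_config_error")
  }
  if (!cfg$adjust %in% c("none", "bh")) {
    ms_abort("adjust must be 'none' or 'bh'", "ms_config_error")
  }
  if (!is.null(cfg$design)) {
    bad <- setdiff(names(cfg$design), names(formals(sim_design)))
    if (length(bad) > 0) {
      ms_abort(sprintf("unknown design key(s): %s",
                       paste(bad, collapse = ", ")), "ms_config_error")
    }
    cfg$design$seed <- cfg$design$seed %||% derive_seed(cfg$seed, "simulate")
  }
  structure(cfg, class = "ms_run_config")
}

log_line <- function(con, stage, event, ...) {
  entry <- c(list(stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full microbiota-shift analysis
#'
#' Executes every stage on simulated or file-based inputs and writes all
#' artifacts to `out_dir`: per-stage TSV/JSON outputs, `run.log`
#' (machine-readable JSON lines: stage timings, warnings,
#' negative-eigenvalue mass, derived seeds) and `report.json` aggregating
#' diversity summaries, F/B ratios, all pairwise group offsets at the
#' endpoint week (a symmetric block, zero on the diagonal), within-group
#' pre/post offsets, ANOSIM, phenotype deltas and contrast, key microbes
#' and the network edge count.  With identical config and seed every
#' output except the timings in `run.log` is byte-identical across runs.
#'
#' @param config An `ms_run_config` (see [validate_config()]) or something
#'   coercible to one.
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return Invisibly, a list with `report`, the stage `results`, and the
#'   file `manifest`.
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "ms_run_config")) config
         else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) {
    ms_abort("no output directory (config 'out_dir' or argument)",
             "ms_config_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  t_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        log_line(log_con, stage, "error", message = conditionMessage(e))
        ms_abort(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)), "ms_stage_error")
      }),
      warning = function(w) {
        log_line(log_con, stage, "warning", message = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log_line(log_con, stage, "done",
             seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    res
  }

  # ---- inputs -------------------------------------------------------------
  inputs <- t_stage("inputs", {
    if (!is.null(cfg$design)) {
      design <- do.call(sim_design, cfg$design)
      sim <- simulate_counts(design)
      pheno <- simulate_phenotypes(design, sim$ground_truth)
      list(counts = sim$counts, metadata = sim$metadata, phenotype = pheno,
           ground_truth = sim$ground_truth, glucose = NULL)
    } else {
      counts <- read_count_table(cfg$counts, cfg$taxonomy)
      metadata <- read_metadata(cfg$metadata, counts)
      pheno <- if (!is.null(cfg$phenotype)) read_phenotype(cfg$phenotype)
      glucose <- if (!is.null(cfg$glucose)) read_glucose(cfg$glucose)
      list(counts = counts, metadata = metadata, phenotype = pheno,
           ground_truth = NULL, glucose = glucose)
    }
  })
  meta <- inputs$metadata
  groups <- sort(unique(meta$group))
  for (key in c("control_group", "reference_group", "treatment_groups")) {
    bad <- setdiff(cfg[[key]], groups)
    if (length(bad) > 0) {
      ms_abort(sprintf("config %s names group(s) absent from metadata: %s",
                       key, paste(bad, collapse = ", ")), "ms_config_error")
    }
  }

  # ---- diversity ----------------------------------------------------------
  rel <- to_relative(inputs$counts)
  div <- t_stage("diversity", alpha_diversity(inputs$counts))
  fb_sample <- t_stage("fb_ratio", fb_ratio(rel, metadata = meta,
                                            level = "per_sample"))
  fb_group <- fb_ratio(rel, metadata = meta, level = "per_group")

  # ---- ordination ---------------------------------------------------------
  end_ids <- meta$sample_id[meta$week == cfg$week_end]
  end_meta <- meta[meta$week == cfg$week_end, ]
  rel_end <- rel[rel$sample_id %in% end_ids, ]
  attr(rel_end, "taxonomy") <- attr(rel, "taxonomy")
  d_end <- t_stage("ordinate", bray_curtis(rel_end))
  ord <- if (cfg$method == "pca") pca_relabund(rel_end)
         else suppressWarnings(pcoa(d_end, correction = cfg$correction))
  log_line(log_con, "ordinate", "negative_eigenvalues",
           n = ord$n_negative_eigenvalues, mass = ord$negative_mass)

  # ---- offsets ------------------------------------------------------------
  offsets <- t_stage("offset", {
    pair_res <- list()
    mat <- matrix(0, length(groups), length(groups),
                  dimnames = list(groups, groups))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      tst <- gm_offset_test(
        d_end, end_meta, pr[1], pr[2], n_axes = cfg$n_axes,
        n_permutations = cfg$permutations, n_bootstrap = cfg$n_bootstrap,
        seed = derive_seed(cfg$seed, paste("offset", pr[1], pr[2])))
      mat[pr[1], pr[2]] <- mat[pr[2], pr[1]] <- tst$gm_offset
      pair_res[[paste(pr[1], "vs", pr[2])]] <- tst
    }
    list(matrix = mat, tests = pair_res)
  })
  within <- t_stage("offset_within", {
    res <- list()
    for (g in groups) {
      sub_meta <- meta[meta$group == g, ]
      if (length(unique(sub_meta$week)) < 2) next
      wk_meta <- dplyr::mutate(sub_meta,
                               group = paste0("w", .data$week))
      rel_g <- rel[rel$sample_id %in% sub_meta$sample_id, ]
      d_g <- bray_curtis(rel_g)
      res[[g]] <- gm_offset_test(
        d_g, wk_meta, paste0("w", cfg$week_ref), paste0("w", cfg$week_end),
        n_axes = cfg$n_axes, n_permutations = cfg$permutations,
        n_bootstrap = cfg$n_bootstrap,
        seed = derive_seed(cfg$seed, paste("within", g)))
    }
    res
  })
  anosim_res <- t_stage("anosim", gm_anosim(
    d_end, end_meta, n_permutations = cfg$permutations,
    seed = derive_seed(cfg$seed, "anosim")))

  # ---- phenotype ----------------------------------------------------------
  deltas <- contrast <- NULL
  if (!is.null(inputs$phenotype)) {
    deltas <- t_stage("phenotype", group_delta(
      inputs$phenotype, meta, week_ref = cfg$week_ref,
      week_end = cfg$week_end))
    ga <- cfg$control_group %||% (if (length(groups) > 1) groups[2])
    gb <- cfg$reference_group %||% groups[1]
    if (!is.null(ga) && ga != gb) {
      contrast <- delta_contrast(deltas[deltas$group == ga, ],
                                 deltas[deltas$group == gb, ])
    }
  }
  auc <- if (!is.null(inputs$glucose)) {
    t_stage("glucose_auc", glucose_auc(inputs$glucose))
  }

  # ---- differential / network --------------------------------------------
  treat <- cfg$treatment_groups %||%
    intersect(c("HFD+PA", "HFD+Rutin"), groups)
  diff_res <- t_stage("differential", {
    lapply(setNames(treat, treat), function(g) {
      sub_meta <- meta[meta$group == g, ]
      if (length(unique(sub_meta$week)) < 2) return(NULL)
      wk_meta <- dplyr::mutate(sub_meta, condition = paste0("w", .data$week))
      rel_g <- rel[rel$sample_id %in% sub_meta$sample_id, ]
      differential_genera(rel_g, wk_meta, paste0("w", cfg$week_end),
                          paste0("w", cfg$week_ref),
                          condition = "condition", alpha = cfg$alpha,
                          min_prevalence = cfg$min_prevalence)
    })
  })
  diff_res <- diff_res[!vapply(diff_res, is.null, logical(1))]
  keys <- if (length(diff_res) >= 2) {
    key_microbes(diff_res[[1]], diff_res[[2]])
  } else character(0)
  partition <- t_stage("core_specific", core_specific(
    rel_end, end_meta, presence_threshold = cfg$presence_threshold))
  network <- NULL
  if (!is.null(inputs$phenotype)) {
    feats <- inputs$phenotype |>
      dplyr::filter(.data$week == cfg$week_end) |>
      dplyr::select("mouse_id", "bw", "fbg")
    network <- t_stage("network", correlation_network(
      rel_end, feats, metadata = end_meta, alpha = cfg$alpha,
      adjust = cfg$adjust))
  }

  # ---- report -------------------------------------------------------------
  report <- list(
    n_samples = nrow(inputs$counts),
    n_genera = ncol(inputs$counts) - 1L,
    groups = groups,
    diversity = div |>
      dplyr::inner_join(meta[c("sample_id", "group")], by = "sample_id") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(shannon = mean(.data$shannon),
                       simpson = mean(.data$simpson), .groups = "drop"),
    fb_ratio_per_group = fb_group,
    gm_offset_matrix = offsets$matrix,
    gm_offset_tests = lapply(offsets$tests, as_report_list),
    gm_offset_within = lapply(within, as_report_list),
    anosim = as_report_list(anosim_res),
    deltas = deltas,
    contrast = contrast,
    key_microbes = keys,
    n_core_genera = length(partition$core),
    n_network_edges = if (is.null(network)) NA_integer_ else nrow(network),
    negative_eigenvalue_mass = ord$negative_mass,
    seed = cfg$seed)
  report_json <- lapply(report, function(x) {
    if (is.matrix(x)) {
      lst <- apply(x, 1, as.list, simplify = FALSE)
      lst
    } else if (is.data.frame(x)) x else x
  })
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  bundle <- list(diversity = div, fb_ratio = fb_sample,
                 fb_ratio_group = fb_group,
                 ordination = tidy(ord),
                 anosim = anosim_res,
                 core_partition = partition)
  if (!is.null(deltas)) bundle$deltas <- deltas
  if (!is.null(contrast)) bundle$contrast <- contrast
  if (!is.null(auc)) bundle$auc <- auc
  if (!is.null(network)) bundle$edges <- as_tibble(network)
  for (nm in names(diff_res)) {
    bundle[[paste0("differential_", gsub("[^A-Za-z0-9]+", "_", nm))]] <-
      diff_res[[nm]]
  }
  manifest <- write_outputs(bundle, out_dir)
  manifest <- dplyr::bind_rows(manifest, tibble(
    name = "report", file = file.path(out_dir, "report.json"),
    md5 = unname(tools::md5sum(file.path(out_dir, "report.json")))))
  invisible(structure(list(report = report, manifest = manifest,
                           results = list(
                             ordination = ord, offsets = offsets,
                             within = within, anosim = anosim_res,
                             differential = diff_res, network = network,
                             partition = partition, inputs = inputs)),
                      class = "ms_report"))
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf("<microshift run> %d samples, %d genera, %d groups\n",
              x$report$n_samples, x$report$n_genera,
              length(x$report$groups)))
  cat(sprintf("  ANOSIM R = %.3f (p = %.3g); %d files written\n",
              x$report$anosim$R, x$report$anosim$permutation_p,
              nrow(x$manifest)))
  invisible(x)
}
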