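# Dirichlet-multinomial simulator of the four-arm mouse intervention
# design: 4 groups x 5 mice sampled at weeks 4 and 10, 66 genera over 9
# phyla, group-specific multiplicative shifts on a "key taxa" subset,
# overdispersed counts with log-normal library sizes, and weekly BW/FBG
# trajectories optionally coupled to each mouse's realized community shift.

default_groups <- c("CD+SPSS", "HFD+SPSS", "HFD+PA", "HFD+Rutin")

default_phyla <- c("Firmicutes", "Bacteroidota", "Actinobacteriota",
                   "Campilobacterota", "Deferribacterota", "Desulfobacterota",
                   "Patescibacteria", "Proteobacteria", "Verrucomicrobiota")

# Firmicutes and Bacteroidota dominate the mouse gut; the two big phyla
# alternate through the abundant ranks so both carry real mass, minor phyla
# take the tail.
default_phylum_assignment <- function(genera, phyla) {
  n <- length(genera)
  major <- rep(c("Firmicutes", "Bacteroidota", "Firmicutes"), length.out = n)
  minor_idx <- seq(6, n, by = 7)
  minor <- setdiff(phyla, c("Firmicutes", "Bacteroidota"))
  major[minor_idx] <- rep(minor, length.out = length(minor_idx))
  tibble(genus = genera, phylum = major)
}

# Default intervention effects on the latent log scale.  All HFD arms share
# one "HFD dysbiosis" pattern at the model-construction week; by the
# endpoint the vehicle arm keeps it while the two treatments partially
# revert it and add treatment-specific shifts, rutin more strongly than
# proanthocyanidins (mirroring the larger community offsets seen under
# rutin).  Patterns alternate in sign across the key taxa so the total
# latent mass stays roughly balanced (a compositional seesaw).
default_effect_table <- function(groups, weeks, key_taxa, effect_size = 1) {
  k <- length(key_taxa)
  hfd <- rep_len(c(1, -1), k)
  treat <- rep_len(c(1, 1, -1, -1), k)
  week_ref <- weeks[1]
  week_end <- weeks[length(weeks)]
  rows <- list()
  add <- function(group, week, pattern) {
    tibble(group = group, week = week, genus = key_taxa,
           log_fold = pattern * effect_size)
  }
  for (g in intersect(groups, c("HFD+SPSS", "HFD+PA", "HFD+Rutin"))) {
    rows[[length(rows) + 1L]] <- add(g, week_ref, hfd)
  }
  if ("HFD+SPSS" %in% groups) {
    rows[[length(rows) + 1L]] <- add("HFD+SPSS", week_end, hfd)
  }
  if ("HFD+PA" %in% groups) {
    rows[[length(rows) + 1L]] <- add("HFD+PA", week_end, 0.6 * hfd + 0.5 * treat)
  }
  if ("HFD+Rutin" %in% groups) {
    rows[[length(rows) + 1L]] <- add("HFD+Rutin", week_end, 0.2 * hfd + 0.8 * treat)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(group = character(0), week = integer(0),
                  genus = character(0), log_fold = numeric(0))
  }
  out
}

per_group_param <- function(x, groups, default, name) {
  if (is.null(x)) x <- default
  if (!is.null(names(x))) {
    miss <- setdiff(groups, names(x))
    if (length(miss) > 0 && length(x) == 1) {
      x <- setNames(rep(unname(x[1]), length(groups)), groups)
    } else if (length(miss) > 0) {
      ms_abort(sprintf("%s missing values for groups: %s", name,
                       paste(miss, collapse = ", ")), "ms_parameter_error")
    }
    x <- x[groups]
  } else {
    x <- setNames(rep_len(x, length(groups)), groups)
  }
  x
}

#' Parameterize a synthetic intervention study
#'
#' Bundles every knob of the generative model into a `sim_design` object:
#' the group/mouse/week layout, the 66-genus 9-phylum community, the
#' Dirichlet concentration `theta` (overdispersion), the per-(group, week)
#' log-fold effect table on a key-taxa subset, log-normal library sizes,
#' and per-group body-weight (g) and fasting-blood-glucose (mmol/L)
#' trajectories.  Defaults reproduce the study layout the package models:
#' four arms (chow and high-fat vehicles, proanthocyanidin and rutin
#' treatments), five mice per arm, microbiome sampling at weeks 4 and 10,
#' group BW/FBG trajectories matching the published group means, and mean
#' endpoint FBG above the 9.5 mmol/L diabetic-model threshold for the
#' untreated high-fat arm.
#'
#' @param groups Character vector of group labels.
#' @param n_mice_per_group Mice per group (default 5).
#' @param weeks Integer microbiome sampling weeks (default `c(4, 10)`).
#' @param n_genera,n_phyla Community size (defaults 66 genera, 9 phyla).
#' @param phylum_assignment Optional tibble `genus`/`phylum`.
#' @param base_log_abundance Baseline latent log-abundances (length
#'   `n_genera`); default is a geometric rank-abundance gradient spanning
#'   roughly four orders of magnitude.
#' @param theta Dirichlet concentration; larger = less compositional
#'   overdispersion (default 50).
#' @param effect_table Tibble `group`/`week`/`genus`/`log_fold` of latent
#'   log-fold shifts; defaults to the built-in intervention patterns on
#'   `key_taxa` scaled by `effect_size`.
#' @param key_taxa Genera receiving effects; default picks 12 moderately
#'   abundant ranks.
#' @param effect_size Scale of the default effect patterns (default 1).
#' @param library_size_log_mean,library_size_log_sd Log-normal library-size
#'   parameters (defaults 10.8 = about 50k reads, sd 0.3).
#' @param bw_baseline_mean,bw_baseline_sd,bw_group_slopes,bw_noise_sd Body
#'   weight model: per-group baseline mean (g) at the reference week,
#'   between-mouse baseline sd, per-group weekly slope (g/week), residual
#'   measurement sd.
#' @param fbg_baseline_mean,fbg_baseline_sd,fbg_group_slopes,fbg_noise_sd
#'   Same for fasting blood glucose (mmol/L).
#' @param coupling Scalar linking a mouse's realized community shift to its
#'   phenotype delta (default 0, uncoupled).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return A `sim_design` object (a validated list).
#' @export
sim_design <- function(groups = default_groups,
                       n_mice_per_group = 5,
                       weeks = c(4L, 10L),
                       n_genera = 66,
                       n_phyla = 9,
                       phylum_assignment = NULL,
                       base_log_abundance = NULL,
                       theta = 50,
                       effect_table = NULL,
                       key_taxa = NULL,
                       effect_size = 1,
                       library_size_log_mean = 10.8,
                       library_size_log_sd = 0.3,
                       bw_baseline_mean = NULL,
                       bw_baseline_sd = 1.5,
                       bw_group_slopes = NULL,
                       bw_noise_sd = 0.5,
                       fbg_baseline_mean = NULL,
                       fbg_baseline_sd = 0.6,
                       fbg_group_slopes = NULL,
                       fbg_noise_sd = 0.4,
                       coupling = 0,
                       seed = 1L) {
  if (theta <= 0) ms_abort("theta must be strictly positive",
                           "ms_parameter_error")
  for (nm in c("library_size_log_sd", "bw_baseline_sd", "bw_noise_sd",
               "fbg_baseline_sd", "fbg_noise_sd")) {
    if (get(nm) < 0) ms_abort(sprintf("%s must be non-negative", nm),
                              "ms_parameter_error")
  }
  if (library_size_log_mean <= 0) {
    ms_abort("library_size_log_mean must be positive", "ms_parameter_error")
  }
  if (length(groups) < 1 || anyDuplicated(groups)) {
    ms_abort("groups must be non-empty and unique", "ms_parameter_error")
  }
  weeks <- as.integer(sort(unique(weeks)))
  genera <- sprintf("genus_%02d", seq_len(n_genera))
  if (is.null(base_log_abundance)) {
    base_log_abundance <- seq(4, -4, length.out = n_genera)
  }
  if (length(base_log_abundance) != n_genera) {
    ms_abort("base_log_abundance must have length n_genera",
             "ms_parameter_error")
  }
  if (is.null(phylum_assignment)) {
    phylum_assignment <- default_phylum_assignment(
      genera, default_phyla[seq_len(min(n_phyla, length(default_phyla)))])
  }
  if (is.null(key_taxa)) {
    # moderately-to-highly abundant ranks: planted shifts there are
    # detectable by two-sample tests at the design's 5-20 mice per group
    key_taxa <- genera[seq(2, min(20, n_genera), by = 2)]
  }
  if (is.null(effect_table)) {
    effect_table <- default_effect_table(groups, weeks, key_taxa, effect_size)
  }
  effect_table <- as_tibble(effect_table)
  if (nrow(effect_table) > 0) {
    bad_g <- setdiff(effect_table$group, groups)
    bad_w <- setdiff(effect_table$week, weeks)
    bad_t <- setdiff(effect_table$genus, genera)
    if (length(bad_g) || length(bad_w) || length(bad_t)) {
      ms_abort(sprintf(
        "effect_table references undeclared cells (groups: %s; weeks: %s; genera: %s)",
        paste(bad_g, collapse = ","), paste(bad_w, collapse = ","),
        paste(bad_t, collapse = ",")), "ms_parameter_error")
    }
  }
  bw_mean_default <- setNames(
    rep(c(22.65, 29.68, 26.12, 25.39), length.out = length(groups)), groups)
  bw_slope_default <- setNames(
    rep(c(0.5583, 0.9200, -0.5193, -0.0990), length.out = length(groups)),
    groups)
  fbg_mean_default <- setNames(
    rep(c(7.0, 10.6, 10.5, 10.4), length.out = length(groups)), groups)
  fbg_slope_default <- setNames(
    rep(c(0.1100, -0.0333, -0.7567, -0.7600), length.out = length(groups)),
    groups)
  design <- structure(list(
    groups = groups,
    n_mice_per_group = as.integer(n_mice_per_group),
    weeks = weeks,
    n_genera = as.integer(n_genera),
    n_phyla = as.integer(n_phyla),
    genera = genera,
    phylum_assignment = as_tibble(phylum_assignment),
    base_log_abundance = base_log_abundance,
    theta = theta,
    effect_table = effect_table,
    key_taxa = key_taxa,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    bw_baseline_mean = per_group_param(bw_baseline_mean, groups,
                                       bw_mean_default, "bw_baseline_mean"),
    bw_baseline_sd = bw_baseline_sd,
    bw_group_slopes = per_group_param(bw_group_slopes, groups,
                                      bw_slope_default, "bw_group_slopes"),
    bw_noise_sd = bw_noise_sd,
    fbg_baseline_mean = per_group_param(fbg_baseline_mean, groups,
                                        fbg_mean_default, "fbg_baseline_mean"),
    fbg_baseline_sd = fbg_baseline_sd,
    fbg_group_slopes = per_group_param(fbg_group_slopes, groups,
                                       fbg_slope_default, "fbg_group_slopes"),
    fbg_noise_sd = fbg_noise_sd,
    coupling = coupling,
    seed = as.integer(seed)
  ), class = "sim_design")
  design
}

# Latent log-abundance vector for one (group, week) cell.
cell_log_abundance <- function(design, group, week) {
  x <- design$base_log_abundance
  names(x) <- design$genera
  eff <- design$effect_table
  eff <- eff[eff$group == group & eff$week == week, ]
  if (nrow(eff) > 0) x[eff$genus] <- x[eff$genus] + eff$log_fold
  x
}

#' Expected compositions and centroid displacements of a design
#'
#' Computes, without simulating, the expected relative abundance of every
#' (group, week) cell (the softmax of the latent log-abundances), the true
#' displacement between every pair of cells in centered log-ratio space,
#' and the set of genera that truly receive an effect somewhere.
#'
#' @param design A [sim_design()] object.
#' @return A list with `expected_relative_abundance` (tibble),
#'   `true_centroid_displacement` (tibble of cell pairs) and
#'   `genera_truly_shifted` (character).
#' @export
design_ground_truth <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  cells <- tidyr::expand_grid(group = design$groups, week = design$weeks)
  comps <- purrr::pmap(cells, function(group, week) {
    softmax(cell_log_abundance(design, group, week))
  })
  expected <- dplyr::bind_rows(purrr::pmap(
    list(cells$group, cells$week, comps),
    function(g, w, p) tibble(group = g, week = w, genus = design$genera,
                             fraction = unname(p))))
  pairs <- tidyr::expand_grid(i = seq_len(nrow(cells)), j = seq_len(nrow(cells)))
  pairs <- pairs[pairs$i < pairs$j, ]
  disp <- purrr::map2_dbl(pairs$i, pairs$j, function(i, j) {
    sqrt(sum((clr(comps[[i]]) - clr(comps[[j]]))^2))
  })
  displacement <- tibble(
    group_a = cells$group[pairs$i], week_a = cells$week[pairs$i],
    group_b = cells$group[pairs$j], week_b = cells$week[pairs$j],
    displacement = disp)
  shifted <- sort(unique(
    design$effect_table$genus[design$effect_table$log_fold != 0]))
  list(expected_relative_abundance = expected,
       true_centroid_displacement = displacement,
       genera_truly_shifted = shifted)
}

#' Simulate genus counts, metadata and ground truth
#'
#' One sample per (mouse, week).  Each sample's composition is drawn from
#' `Dirichlet(theta * softmax(base + effect))` and counts multinomially at
#' a log-normal library size.  Identical designs (including seed) yield
#' byte-identical outputs.
#'
#' @param design A [sim_design()] object.
#' @return A list with `counts` (tibble with taxonomy attached),
#'   `metadata` (tibble) and `ground_truth` (the [design_ground_truth()]
#'   list plus a per-mouse `mouse_shift` tibble: the centered-log-ratio
#'   distance between the mouse's drawn compositions at the first and last
#'   sampling weeks).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  gt <- design_ground_truth(design)
  n_g <- design$n_genera
  withr::with_seed(design$seed, {
    rows <- list()
    meta <- list()
    comps <- list()
    mouse_no <- 0L
    for (g in design$groups) {
      for (m in seq_len(design$n_mice_per_group)) {
        mouse_no <- mouse_no + 1L
        mouse_id <- sprintf("M%03d", mouse_no)
        for (w in design$weeks) {
          alpha <- design$theta * softmax(cell_log_abundance(design, g, w))
          gamma <- rgamma(n_g, shape = alpha, rate = 1)
          if (sum(gamma) == 0) gamma <- alpha  # numerically degenerate draw
          p <- gamma / sum(gamma)
          N <- max(1L, as.integer(round(rlnorm(1, design$library_size_log_mean,
                                               design$library_size_log_sd))))
          counts <- as.integer(rmultinom(1, size = N, prob = p))
          sid <- sprintf("%s_w%02d", mouse_id, w)
          rows[[sid]] <- counts
          comps[[paste(mouse_id, w)]] <- p
          meta[[sid]] <- tibble(sample_id = sid, mouse_id = mouse_id,
                                group = g, week = as.integer(w))
        }
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- design$genera
    counts <- matrix_to_tibble(m)
    metadata <- dplyr::bind_rows(meta)
  })
  counts <- validate_counts(counts, design$phylum_assignment)
  # realized per-mouse community shift between first and last sampling week
  w1 <- design$weeks[1]
  w2 <- design$weeks[length(design$weeks)]
  mice <- unique(metadata$mouse_id)
  shift <- vapply(mice, function(mm) {
    if (w1 == w2) return(0)
    p1 <- comps[[paste(mm, w1)]]
    p2 <- comps[[paste(mm, w2)]]
    p1 <- pmax(p1, 1e-12); p2 <- pmax(p2, 1e-12)
    sqrt(sum((clr(p1) - clr(p2))^2))
  }, numeric(1))
  gt$mouse_shift <- tibble(
    mouse_id = mice,
    group = metadata$group[match(mice, metadata$mouse_id)],
    shift = unname(shift))
  list(counts = counts, metadata = metadata, ground_truth = gt)
}

#' Simulate weekly body-weight and glucose trajectories
#'
#' Per mouse and week: baseline + group slope x (week - first week) +
#' coupling x mouse community shift (phased in linearly over the
#' intervention) + Gaussian noise.  FBG is floored at 0.1 mmol/L to stay
#' physical.
#'
#' @param design A [sim_design()] object.
#' @param ground_truth Optional ground-truth list from [simulate_counts()];
#'   supplies the per-mouse shifts when `coupling != 0`.
#' @return A phenotype tibble (`mouse_id`, `group`, `week`, `bw`, `fbg`)
#'   over the weekly grid spanning the design's sampling weeks.
#' @export
simulate_phenotypes <- function(design, ground_truth = NULL) {
  stopifnot(inherits(design, "sim_design"))
  w0 <- design$weeks[1]
  w_end <- design$weeks[length(design$weeks)]
  weeks <- seq(w0, w_end)
  span <- max(w_end - w0, 1L)
  shifts <- NULL
  if (!is.null(ground_truth) && !is.null(ground_truth$mouse_shift)) {
    shifts <- setNames(ground_truth$mouse_shift$shift,
                       ground_truth$mouse_shift$mouse_id)
  }
  withr::with_seed(derive_seed(design$seed, "phenotype"), {
    rows <- list()
    mouse_no <- 0L
    for (g in design$groups) {
      for (m in seq_len(design$n_mice_per_group)) {
        mouse_no <- mouse_no + 1L
        mouse_id <- sprintf("M%03d", mouse_no)
        bw0 <- rnorm(1, design$bw_baseline_mean[[g]], design$bw_baseline_sd)
        fbg0 <- rnorm(1, design$fbg_baseline_mean[[g]], design$fbg_baseline_sd)
        sh <- if (!is.null(shifts) && mouse_id %in% names(shifts)) {
          shifts[[mouse_id]]
        } else 0
        for (w in weeks) {
          frac <- (w - w0) / span
          bw <- bw0 + design$bw_group_slopes[[g]] * (w - w0) +
            design$coupling * sh * frac +
            rnorm(1, 0, design$bw_noise_sd)
          fbg <- fbg0 + design$fbg_group_slopes[[g]] * (w - w0) +
            design$coupling * sh * frac +
            rnorm(1, 0, design$fbg_noise_sd)
          rows[[length(rows) + 1L]] <- tibble(
            mouse_id = mouse_id, group = g, week = as.integer(w),
            bw = max(bw, 0.1), fbg = max(fbg, 0.1))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Scale a design's key-taxa effects along a magnitude grid
#'
#' Produces one design per requested log-fold magnitude, with the effect
#' pattern rescaled so its largest absolute entry equals the magnitude
#' (zero magnitude zeroes the effects).  Used for monotonicity and power
#' experiments.
#'
#' @param design A [sim_design()] object with a nonzero effect table.
#' @param deltas Non-negative, non-decreasing log-fold magnitudes.
#' @return A list of `sim_design` objects, one per delta.
#' @export
effect_grid <- function(design, deltas) {
  stopifnot(inherits(design, "sim_design"))
  if (length(deltas) < 1 || any(deltas < 0)) {
    ms_abort("deltas must be non-negative", "ms_parameter_error")
  }
  if (is.unsorted(deltas)) {
    ms_abort("deltas must be sorted non-decreasing", "ms_parameter_error")
  }
  base_mag <- max(abs(design$effect_table$log_fold), 0)
  if (base_mag == 0 && any(deltas > 0)) {
    ms_abort("cannot scale an all-zero effect table to a nonzero delta",
             "ms_parameter_error")
  }
  lapply(deltas, function(d) {
    out <- design
    if (d == 0) {
      out$effect_table$log_fold <- 0 * out$effect_table$log_fold
    } else {
      out$effect_table$log_fold <- out$effect_table$log_fold * (d / base_mag)
    }
    out
  })
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>\n")
  cat(sprintf("  %d groups x %d mice, weeks %s\n", length(x$groups),
              x$n_mice_per_group, paste(x$weeks, collapse = ", ")))
  cat(sprintf("  %d genera / %d phyla, theta = %g, %d effect entries\n",
              x$n_genera, x$n_phyla, x$theta, nrow(x$effect_table)))
  cat(sprintf("  coupling = %g, seed = %d\n", x$coupling, x$seed))
  invisible(x)
}
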