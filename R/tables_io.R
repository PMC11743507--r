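# Reading, validating and writing every tabular artifact the pipeline
# touches.  All tables are TSV, UTF-8, "." decimal; samples are rows and
# genera are columns.  Genus names are opaque strings.

#' Validate a genus count table
#'
#' Checks that a samples-by-genera table holds non-negative integral counts
#' with unique sample and genus identifiers, and that every genus with a
#' nonzero column sum is mapped to a phylum.  Unmapped genera are allowed
#' only as `"Unassigned"` (a warning is raised and the mapping is filled in).
#'
#' @param counts Tibble with a `sample_id` column followed by one numeric
#'   column per genus.
#' @param taxonomy Optional tibble with columns `genus` and `phylum`.
#' @return The validated counts tibble, invisibly, with the (possibly
#'   completed) taxonomy attached as attribute `"taxonomy"`.
#' @export
validate_counts <- function(counts, taxonomy = NULL) {
  m <- as_sample_matrix(counts, "count table")
  if (nrow(m) < 1 || ncol(m) < 1) {
    ms_abort("count table needs at least 1 sample and 1 genus",
             "ms_validation_error")
  }
  if (anyDuplicated(rownames(m))) {
    ms_abort(sprintf("duplicate sample identifiers: %s",
                     paste(unique(rownames(m)[duplicated(rownames(m))]),
                           collapse = ", ")),
             "ms_validation_error")
  }
  if (anyDuplicated(colnames(m))) {
    ms_abort(sprintf("duplicate genus identifiers: %s",
                     paste(unique(colnames(m)[duplicated(colnames(m))]),
                           collapse = ", ")),
             "ms_validation_error")
  }
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ms_abort(sprintf(
      "counts must be non-negative integers; offending cell: sample '%s', genus '%s' (value %s)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
      format(m[bad[1, 1], bad[1, 2]])),
      "ms_format_error")
  }
  if (!is.null(taxonomy)) {
    if (!all(c("genus", "phylum") %in% names(taxonomy))) {
      ms_abort("taxonomy needs columns 'genus' and 'phylum'",
               "ms_schema_error")
    }
    present <- colnames(m)[colSums(m) > 0]
    missing <- setdiff(present, taxonomy$genus)
    if (length(missing) > 0) {
      ms_warn(sprintf(
        "%d genera missing from taxonomy assigned phylum 'Unassigned': %s",
        length(missing), paste(head(missing, 5), collapse = ", ")))
      taxonomy <- dplyr::bind_rows(
        taxonomy, tibble(genus = missing, phylum = "Unassigned"))
    }
    attr(counts, "taxonomy") <- as_tibble(taxonomy)
  }
  invisible(counts)
}

#' Read a genus count table (and taxonomy) from TSV
#'
#' The count TSV has a header of genus names and a first column `sample_id`;
#' the taxonomy TSV has columns `genus` and `phylum`.  Row and column order
#' are preserved as read.
#'
#' @param path Path to the count TSV.
#' @param taxonomy_path Optional path to the taxonomy TSV.
#' @return A tibble of counts with the taxonomy tibble attached as attribute
#'   `"taxonomy"` (retrieve with [get_taxonomy()]).
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  prob <- readr::problems(counts)
  if (nrow(prob) > 0) {
    ms_abort(sprintf("malformed count table '%s': %s (row %d, column %d)",
                     path, prob$expected[1], prob$row[1], prob$col[1]),
             "ms_format_error")
  }
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  counts <- validate_counts(counts, taxonomy)
  counts
}

#' @rdname read_count_table
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  miss <- setdiff(c("genus", "phylum"), names(tax))
  if (length(miss) > 0) {
    ms_abort(sprintf("taxonomy file missing columns: %s",
                     paste(miss, collapse = ", ")), "ms_schema_error")
  }
  tax
}

#' Extract the taxonomy attached to a count table
#' @param counts A count tibble returned by [read_count_table()] or
#'   [simulate_counts()].
#' @return A tibble with columns `genus` and `phylum`.
#' @export
get_taxonomy <- function(counts) {
  tax <- attr(counts, "taxonomy")
  if (is.null(tax)) {
    ms_abort("no taxonomy attached to this count table", "ms_validation_error")
  }
  tax
}

#' Read and validate sample metadata
#'
#' @param path Path to a TSV with columns `sample_id`, `mouse_id`, `group`,
#'   `week`.
#' @param counts Optional count table; if given, the sample id sets must
#'   match exactly.
#' @return A validated metadata tibble.  Group labels are taken verbatim.
#' @export
read_metadata <- function(path, counts = NULL) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if ("week" %in% names(meta)) {
    wk <- suppressWarnings(as.integer(meta$week))
    if (any(is.na(wk) & !is.na(meta$week))) {
      ms_abort("non-integer values in metadata column 'week'",
               "ms_format_error")
    }
    meta$week <- wk
  }
  validate_metadata(meta, counts)
  meta
}

#' @rdname read_metadata
#' @param metadata Metadata tibble to validate.
#' @export
validate_metadata <- function(metadata, counts = NULL) {
  miss <- setdiff(c("sample_id", "mouse_id", "group", "week"), names(metadata))
  if (length(miss) > 0) {
    ms_abort(sprintf("metadata missing columns: %s",
                     paste(miss, collapse = ", ")), "ms_schema_error")
  }
  dup <- duplicated(metadata[c("mouse_id", "week")])
  if (any(dup)) {
    ms_abort(sprintf("duplicated (mouse_id, week) pairs: %s",
                     paste(unique(paste0(metadata$mouse_id[dup], "/w",
                                         metadata$week[dup])),
                           collapse = ", ")),
             "ms_validation_error")
  }
  if (!is.null(counts)) {
    ids <- counts$sample_id
    only_meta <- setdiff(metadata$sample_id, ids)
    only_counts <- setdiff(ids, metadata$sample_id)
    if (length(only_meta) > 0 || length(only_counts) > 0) {
      ms_abort(sprintf(
        "sample ids do not match count table; only in metadata: [%s]; only in counts: [%s]",
        paste(only_meta, collapse = ", "),
        paste(only_counts, collapse = ", ")),
        "ms_join_error")
    }
  }
  invisible(metadata)
}

#' Read a per-mouse phenotype series
#'
#' @param path TSV with columns `mouse_id`, `week`, `bw` (grams), `fbg`
#'   (mmol/L).
#' @return Validated tibble; `(mouse_id, week)` must be unique and values
#'   positive.
#' @export
read_phenotype <- function(path) {
  ph <- readr::read_tsv(path, col_types = readr::cols(
    mouse_id = readr::col_character(), week = readr::col_integer(),
    bw = readr::col_double(), fbg = readr::col_double()), progress = FALSE)
  validate_phenotype(ph)
  ph
}

#' @rdname read_phenotype
#' @param phenotype Phenotype tibble to validate.
#' @export
validate_phenotype <- function(phenotype) {
  miss <- setdiff(c("mouse_id", "week", "bw", "fbg"), names(phenotype))
  if (length(miss) > 0) {
    ms_abort(sprintf("phenotype table missing columns: %s",
                     paste(miss, collapse = ", ")), "ms_schema_error")
  }
  if (any(duplicated(phenotype[c("mouse_id", "week")]))) {
    ms_abort("duplicated (mouse_id, week) in phenotype table",
             "ms_validation_error")
  }
  if (any(phenotype$bw <= 0) || any(phenotype$fbg <= 0)) {
    ms_abort("bw and fbg must be positive", "ms_validation_error")
  }
  invisible(phenotype)
}

#' Read glucose-tolerance curves
#'
#' @param path TSV with columns `mouse_id`, `minutes`, `glucose` (mmol/L),
#'   one row per time point.
#' @return Validated tibble; per mouse, minutes are strictly increasing and
#'   start at 0.
#' @export
read_glucose <- function(path) {
  gl <- readr::read_tsv(path, col_types = readr::cols(
    mouse_id = readr::col_character(), minutes = readr::col_double(),
    glucose = readr::col_double()), progress = FALSE)
  validate_glucose(gl)
  gl
}

#' @rdname read_glucose
#' @param glucose Glucose-curve tibble to validate.
#' @export
validate_glucose <- function(glucose) {
  miss <- setdiff(c("mouse_id", "minutes", "glucose"), names(glucose))
  if (length(miss) > 0) {
    ms_abort(sprintf("glucose table missing columns: %s",
                     paste(miss, collapse = ", ")), "ms_schema_error")
  }
  by_mouse <- split(glucose, glucose$mouse_id)
  for (m in names(by_mouse)) {
    mins <- by_mouse[[m]]$minutes
    if (any(diff(mins) <= 0)) {
      ms_abort(sprintf("minutes not strictly increasing for mouse '%s'", m),
               "ms_validation_error")
    }
    if (mins[1] != 0) {
      ms_abort(sprintf("first time point must be 0 for mouse '%s'", m),
               "ms_validation_error")
    }
    if (any(mins < 0)) {
      ms_abort(sprintf("negative minutes for mouse '%s'", m),
               "ms_validation_error")
    }
  }
  invisible(glucose)
}

#' Write tables back to TSV
#'
#' Round-trip companions of the readers: `write_count_table()` also writes
#' the attached taxonomy when `taxonomy_path` is given.
#'
#' @param counts,metadata,phenotype,glucose Tibbles as produced by the
#'   corresponding readers or by the simulator.
#' @param path Output TSV path.
#' @param taxonomy_path Optional taxonomy output path.
#' @return The input, invisibly.
#' @export
write_count_table <- function(counts, path, taxonomy_path = NULL) {
  readr::write_tsv(counts, path, progress = FALSE)
  if (!is.null(taxonomy_path)) {
    readr::write_tsv(get_taxonomy(counts), taxonomy_path, progress = FALSE)
  }
  invisible(counts)
}

#' @rdname write_count_table
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(metadata)
}

#' @rdname write_count_table
#' @export
write_phenotype <- function(phenotype, path) {
  readr::write_tsv(phenotype, path, progress = FALSE)
  invisible(phenotype)
}

#' @rdname write_count_table
#' @export
write_glucose <- function(glucose, path) {
  readr::write_tsv(glucose, path, progress = FALSE)
  invisible(glucose)
}

#' Write a bundle of pipeline results to a directory
#'
#' Data frames are written as TSV (correlation networks as a
#' Cytoscape-compatible edge table), everything else as JSON.  File names
#' are deterministic (`<element name>.tsv`/`.json`) and a manifest listing
#' each file with an MD5 content checksum is returned.
#'
#' @param bundle Named list of results (tibbles, offset/ANOSIM objects,
#'   scalar summaries).  May be empty.
#' @param out_dir Output directory, created if needed.
#' @return A tibble manifest with columns `name`, `file`, `md5`.
#' @export
write_outputs <- function(bundle, out_dir) {
  stopifnot(is.list(bundle))
  if (length(bundle) > 0 &&
      (is.null(names(bundle)) || any(names(bundle) == ""))) {
    ms_abort("every bundle element must be named", "ms_validation_error")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    ms_abort(sprintf("cannot write to directory '%s'", out_dir), "ms_io_error")
  }
  files <- character(0)
  for (name in sort(names(bundle))) {
    x <- bundle[[name]]
    if (is.data.frame(x)) {
      file <- file.path(out_dir, paste0(name, ".tsv"))
      readr::write_tsv(as_tibble(x), file, progress = FALSE)
    } else {
      file <- file.path(out_dir, paste0(name, ".json"))
      jsonlite::write_json(as_report_list(x), file, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    files[name] <- file
  }
  tibble(name = names(files), file = unname(files),
         md5 = unname(tools::md5sum(files)))
}

# Plain-list rendering of result objects for JSON export.
as_report_list <- function(x) {
  if (inherits(x, "ms_offset_test")) {
    list(group_a = x$group_a, group_b = x$group_b, gm_offset = x$gm_offset,
         n_axes_used = x$n_axes_used, permutation_p = x$permutation_p,
         n_permutations = x$n_permutations,
         bootstrap_ci = x$bootstrap_ci, conf_level = x$conf_level,
         seed = x$seed)
  } else if (inherits(x, "ms_anosim")) {
    list(R = x$R, permutation_p = x$permutation_p,
         n_permutations = x$n_permutations, seed = x$seed)
  } else if (inherits(x, "ms_core_partition")) {
    list(per_group = x$per_group, core = x$core, specific = x$specific)
  } else if (is.list(x)) {
    lapply(x, as_report_list)
  } else {
    x
  }
}
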