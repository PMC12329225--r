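#' Write a labelled numeric matrix as TSV
#'
#' Tab-delimited, with row and column ids in the first column and header
#' row. Structural matrices use region ids on both axes; signal matrices
#' use region ids on rows and timepoint labels on columns.
#'
#' @param mat Numeric matrix.
#' @param path Output file.
#' @param row_ids,col_ids Identifier vectors (default: indices).
#' @export
write_matrix_tsv <- function(mat, path,
                             row_ids = seq_len(nrow(mat)),
                             col_ids = seq_len(ncol(mat))) {
  stopifnot(is.matrix(mat), length(row_ids) == nrow(mat),
            length(col_ids) == ncol(mat))
  header <- paste(c("id", col_ids), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(row_ids[i], format(mat[i, ], digits = 15, trim = TRUE,
                               scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' Parses the format written by [write_matrix_tsv()], with defensive
#' checks: ragged rows and non-numeric cells are reported with their line
#' number, row ids can be verified against an expected set, and matrices
#' declared structural must be square and symmetric.
#'
#' @param path Input file.
#' @param expected_row_ids Optional ids to verify the rows against (e.g.
#'   atlas region ids).
#' @param structural Declare the matrix structural: enforce square shape
#'   and symmetry (tolerance 1e-8).
#' @return List with `mat`, `row_ids`, `col_ids`.
#' @export
read_matrix_tsv <- function(path, expected_row_ids = NULL, structural = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop_invalid(path, ": no data rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != lens[1])) {
    stop_invalid(path, ": ragged row at line ", which(lens != lens[1])[1])
  }
  col_ids <- parts[[1]][-1]
  row_ids <- vapply(parts[-1], `[`, character(1), 1)
  vals <- suppressWarnings(
    lapply(parts[-1], function(p) as.numeric(p[-1])))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad)) {
    stop_invalid(path, ": non-numeric value at line ", bad[1] + 1L)
  }
  mat <- do.call(rbind, vals)
  if (!is.null(expected_row_ids) &&
      !identical(row_ids, as.character(expected_row_ids))) {
    stop_invalid(path, ": row ids do not match the atlas region ids")
  }
  if (structural) {
    if (nrow(mat) != ncol(mat)) stop_invalid(path, ": structural matrix not square")
    if (!identical(row_ids, col_ids)) {
      stop_invalid(path, ": structural matrix row/column ids differ")
    }
    if (!is_symmetric_num(mat)) stop_invalid(path, ": structural matrix not symmetric")
  }
  list(mat = mat, row_ids = row_ids, col_ids = col_ids)
}

#' Write a cohort to disk
#'
#' Emits the atlas TSV, the subject manifest CSV, per-subject matrices
#' (`<id>_streamlines.tsv`, `<id>_gmv.tsv`, `<id>_bold.tsv`), and
#' `ground_truth.json` with the planted generator parameters and the
#' realized per-subject SDI.
#'
#' @param cohort An `"sfc_cohort"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sfc_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$atlas, file.path(out_dir, "atlas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  ids <- cohort$manifest$subject_id
  rids <- cohort$atlas$region_id
  for (id in ids) {
    s <- cohort$subjects[[id]]
    write_matrix_tsv(s$streamline_counts,
                     file.path(out_dir, paste0(id, "_streamlines.tsv")),
                     row_ids = rids, col_ids = rids)
    write_matrix_tsv(matrix(s$gmv, ncol = 1),
                     file.path(out_dir, paste0(id, "_gmv.tsv")),
                     row_ids = rids, col_ids = "gmv")
    write_matrix_tsv(s$bold, file.path(out_dir, paste0(id, "_bold.tsv")),
                     row_ids = rids,
                     col_ids = paste0("t", seq_len(ncol(s$bold))))
  }
  gt <- list(
    config = unclass(cohort$config),
    realized_sdi = lapply(cohort$subjects, function(s) s$realized_sdi$sdi),
    realized_flags = lapply(cohort$subjects, function(s) s$realized_sdi$flag),
    cutoff_nominal = cohort$subjects[[1]]$cutoff_nominal
  )
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Load a cohort directory
#'
#' Reads the layout written by [write_cohort()] back into an
#' `"sfc_cohort"`, with validation: unique subject ids, flight hours only
#' for pilots (a control with hours gets a warning and the value dropped),
#' per-subject matrices dimension-checked against the atlas, and no
#' non-finite values.
#'
#' @param dir Cohort directory.
#' @return An `"sfc_cohort"` (bases are recomputed lazily downstream).
#' @export
load_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  atlas_path <- file.path(dir, "atlas.tsv")
  for (p in c(manifest_path, atlas_path)) {
    if (!file.exists(p)) stop_invalid("missing file: ", p)
  }
  atlas <- utils::read.delim(atlas_path, stringsAsFactors = FALSE)
  need <- c("region_id", "region_name", "hemisphere", "tissue_class", "system_label")
  if (!all(need %in% names(atlas))) stop_invalid("atlas is missing required columns")
  if (anyDuplicated(atlas$region_id) ||
      !identical(atlas$region_id, seq_len(nrow(atlas)))) {
    stop_invalid("atlas region_ids must be unique and contiguous from 1")
  }

  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need_m <- c("subject_id", "group", "age", "education", "tiv", "mfd", "flight_hours")
  if (!all(need_m %in% names(manifest))) {
    stop_invalid("manifest is missing required columns")
  }
  if (anyDuplicated(manifest$subject_id)) {
    stop_invalid("duplicated subject_id in manifest")
  }
  bad_ctl <- manifest$group == "control" & is.finite(manifest$flight_hours)
  if (any(bad_ctl)) {
    warning("control subject(s) with flight_hours present; value ignored: ",
            paste(manifest$subject_id[bad_ctl], collapse = ", "), call. = FALSE)
    manifest$flight_hours[bad_ctl] <- NA_real_
  }
  miss_fh <- manifest$group == "pilot" & !is.finite(manifest$flight_hours)
  if (any(miss_fh)) {
    stop_invalid("pilot(s) without flight_hours: ",
                 paste(manifest$subject_id[miss_fh], collapse = ", "))
  }
  for (col in c("age", "education", "tiv", "mfd")) {
    if (any(!is.finite(manifest[[col]]))) {
      stop_invalid("non-finite values in manifest column ", col)
    }
  }

  n_reg <- nrow(atlas)
  rids <- atlas$region_id
  subjects <- vector("list", nrow(manifest))
  names(subjects) <- manifest$subject_id
  for (id in manifest$subject_id) {
    paths <- file.path(dir, paste0(id, c("_streamlines.tsv", "_gmv.tsv", "_bold.tsv")))
    for (p in paths) if (!file.exists(p)) stop_invalid("missing file: ", p)
    sc <- read_matrix_tsv(paths[1], expected_row_ids = rids, structural = TRUE)
    gmv <- read_matrix_tsv(paths[2], expected_row_ids = rids)
    bold <- read_matrix_tsv(paths[3], expected_row_ids = rids)
    if (nrow(sc$mat) != n_reg || nrow(bold$mat) != n_reg) {
      stop_invalid(id, ": matrix dimensions do not match the atlas")
    }
    if (!all(is.finite(sc$mat)) || !all(is.finite(gmv$mat)) ||
        !all(is.finite(bold$mat))) {
      stop_invalid(id, ": non-finite values in subject matrices")
    }
    subjects[[id]] <- list(
      streamline_counts = sc$mat,
      gmv = drop(gmv$mat),
      bold = bold$mat
    )
  }

  config <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    config <- try(do.call(sfc_config, gt$config[setdiff(names(gt$config), NULL)]),
                  silent = TRUE)
    if (inherits(config, "try-error")) config <- NULL
  }
  if (is.null(config)) {
    # minimal config describing the on-disk data
    t_acq <- ncol(subjects[[1]]$bold)
    config <- sfc_config(
      n_regions_cortical = sum(atlas$tissue_class == "cortical"),
      n_regions_subcortical = sum(atlas$tissue_class == "subcortical"),
      n_timepoints_acquired = t_acq,
      n_discard = min(5L, t_acq - 2L),
      n_subjects_per_group = max(3L, min(table(manifest$group)))
    )
  }

  structure(list(atlas = atlas, manifest = manifest, subjects = subjects,
                 config = config),
            class = "sfc_cohort")
}
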