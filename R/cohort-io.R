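# Tabular cohort and NIfTI volume I/O, and assembly of the subjects x
# in-mask-voxels matrix that harmonization and VBM operate on.

COHORT_COLUMNS <- c("subject_id", "group", "site", "age", "sex", "tiv",
                    "res_grade", "noise_grade", "bias_grade",
                    "iqr_pct", "euler", "defect_pct")
COHORT_REQUIRED <- c("subject_id", "group", "iqr_pct", "euler", "defect_pct")
COHORT_NUMERIC <- c("age", "tiv", "res_grade", "noise_grade", "bias_grade",
                    "iqr_pct", "euler", "defect_pct")

#' Construct a cohort table
#'
#' A cohort table is a data frame of participants with a two-level group
#' label, scan site, demographics (age, sex, total intracranial volume) and
#' automated image-quality metrics: the overall image quality rating
#' (`iqr_pct`, percent, higher is better), the mean surface Euler number
#' (`euler`, higher is worse) and the topological defect size (`defect_pct`,
#' percent of the cortical surface, higher is worse). Optional percent-grade
#' columns (`res_grade`, `noise_grade`, `bias_grade`) may be `NA`. Row order
#' is stable and is the canonical subject order for every downstream module.
#'
#' @param df data frame with at least `subject_id`, `group`, `iqr_pct`,
#'   `euler`, `defect_pct`. Missing optional columns are added as `NA`
#'   (`site` defaults to `"site1"`).
#' @param treated_label,control_label the two group labels. If `NULL`, the
#'   smaller group is taken as treated (ties broken by first appearance),
#'   mirroring the convention of matching a patient group into a larger
#'   control pool.
#' @param name cohort name, used in reports.
#' @return a `cohort_table` (a validated data frame with attributes
#'   `treated_label`, `control_label`, `name`).
#' @export
cohort_table <- function(df, treated_label = NULL, control_label = NULL,
                         name = "cohort") {
  if (!is.data.frame(df)) qc_stop("qcmatch_validation_error", "df must be a data frame")
  missing_req <- setdiff(COHORT_REQUIRED, names(df))
  if (length(missing_req))
    qc_stop("qcmatch_schema_error", "missing required column(s): ",
            paste(missing_req, collapse = ", "))
  for (col in setdiff(COHORT_COLUMNS, names(df)))
    df[[col]] <- if (col == "site") "site1" else NA
  df <- df[, COHORT_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$site <- as.character(df$site)
  for (col in COHORT_NUMERIC) {
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "")
      if (length(bad))
        qc_stop("qcmatch_parse_error", "non-numeric value in column '", col,
                "' at row ", bad[1])
      v <- conv
    }
    df[[col]] <- as.numeric(v)
  }
  if (nrow(df) == 0L)
    qc_stop("qcmatch_validation_error", "cohort table has no records")
  if (anyDuplicated(df$subject_id))
    qc_stop("qcmatch_validation_error", "duplicate subject_id: ",
            df$subject_id[duplicated(df$subject_id)][1])
  labels <- unique(df$group)
  if (length(labels) != 2L)
    qc_stop("qcmatch_validation_error", "cohort must have exactly two group labels, found ",
            length(labels), ": ", paste(labels, collapse = ", "))
  if (is.null(treated_label)) {
    if (is.null(control_label)) {
      counts <- table(factor(df$group, levels = labels))
      treated_label <- labels[which.min(counts)]
      control_label <- setdiff(labels, treated_label)
    } else treated_label <- setdiff(labels, control_label)
  } else if (is.null(control_label)) {
    control_label <- setdiff(labels, treated_label)
  }
  if (!all(c(treated_label, control_label) %in% labels) ||
      treated_label == control_label)
    qc_stop("qcmatch_validation_error", "treated/control labels must be the two group labels")
  for (col in c("iqr_pct", "defect_pct")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100 | !is.finite(v))))
      qc_stop("qcmatch_validation_error", col, " must lie in [0, 100]")
  }
  if (any(!is.finite(df$euler)))
    qc_stop("qcmatch_validation_error", "euler must be finite")
  if (any(is.na(df$iqr_pct) | is.na(df$defect_pct)))
    qc_stop("qcmatch_validation_error", "iqr_pct and defect_pct are required for every record")
  if (any(!is.na(df$age) & df$age <= 0))
    qc_stop("qcmatch_validation_error", "age must be positive")
  if (any(!is.na(df$tiv) & df$tiv <= 0))
    qc_stop("qcmatch_validation_error", "tiv must be positive")
  if (any(!is.na(df$sex) & !df$sex %in% c("M", "F", "O")))
    qc_stop("qcmatch_validation_error", "sex must be one of M, F, O")
  structure(df, treated_label = treated_label, control_label = control_label,
            name = name, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table '", attr(x, "name"), "': ", nrow(x), " subjects (",
      sum(x$group == attr(x, "treated_label")), " ", attr(x, "treated_label"),
      " / ", sum(x$group == attr(x, "control_label")), " ",
      attr(x, "control_label"), "), ",
      length(unique(x$site)), " site(s)\n", sep = "")
  invisible(x)
}

#' @rdname cohort_table
#' @param x a `cohort_table`
#' @export
treated_label <- function(x) attr(x, "treated_label")

#' @rdname cohort_table
#' @export
control_label <- function(x) attr(x, "control_label")

#' @rdname cohort_table
#' @return `is_treated`: logical vector, `TRUE` for treated-group rows.
#' @export
is_treated <- function(x) x$group == attr(x, "treated_label")

#' Read a cohort table from TSV
#'
#' The on-disk dialect is UTF-8 tab-separated values with a header row;
#' missing optional grades are empty cells. Columns may be renamed through
#' `schema`, a named character vector mapping canonical names (see
#' [cohort_table()]) to the file's column names.
#'
#' @param path file path.
#' @param schema optional named character vector, e.g.
#'   `c(subject_id = "ID", iqr_pct = "IQR")`.
#' @inheritParams cohort_table
#' @return a `cohort_table` preserving file row order.
#' @export
read_cohort_table <- function(path, schema = NULL, treated_label = NULL,
                              control_label = NULL, name = NULL) {
  if (!file.exists(path)) qc_stop("qcmatch_io_error", "file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, comment.char = "#")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        qc_stop("qcmatch_schema_error", "schema column '", src,
                "' (for ", canon, ") not present in file")
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_req <- setdiff(COHORT_REQUIRED, names(raw))
  if (length(missing_req))
    qc_stop("qcmatch_schema_error", "missing required column(s): ",
            paste(missing_req, collapse = ", "))
  cohort_table(raw, treated_label = treated_label,
               control_label = control_label,
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a cohort table to TSV
#'
#' Numeric values are written with 17 significant digits so that
#' [read_cohort_table()] inverts the write exactly.
#'
#' @param table a `cohort_table`.
#' @param path output path.
#' @export
write_cohort_table <- function(table, path) {
  df <- as.data.frame(table)
  for (col in COHORT_NUMERIC)
    df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.17g", df[[col]]))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) qc_stop("qcmatch_io_error", "cannot write ", path,
                           ": ", conditionMessage(ok))
  invisible(NULL)
}

#' 3D volume with a world-coordinate affine
#'
#' @param grid 3D numeric array.
#' @param affine 4x4 invertible matrix mapping homogeneous 0-based voxel
#'   indices `(i, j, k, 1)` to world millimetre coordinates.
#' @param subject_id optional subject identifier.
#' @return a `volume_image`.
#' @export
volume_image <- function(grid, affine = diag(4), subject_id = NULL) {
  if (length(dim(grid)) != 3L || any(dim(grid) < 1L))
    qc_stop("qcmatch_validation_error", "grid must be a 3D array with positive dims")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) ||
      !is.finite(d <- det(affine)) || abs(d) < 1e-12)
    qc_stop("qcmatch_validation_error", "affine must be an invertible 4x4 matrix")
  structure(list(grid = grid, affine = affine,
                 subject_id = subject_id),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("volume_image", if (!is.null(x$subject_id)) paste0("'", x$subject_id, "'"),
      paste(dim(x$grid), collapse = "x"), "\n")
  invisible(x)
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param affine 4x4 affine.
#' @param ijk integer matrix (n x 3) or vector of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving grid values and the voxel-to-world
#' affine (sform) through a round trip.
#'
#' @param path `.nii` or `.nii.gz` path.
#' @param subject_id optional id attached to the returned volume.
#' @return `read_volume`: a [volume_image()].
#' @export
read_volume <- function(path, subject_id = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    qc_stop("qcmatch_format_error", "not a readable NIfTI file: ",
                            path, " (", conditionMessage(e), ")"))
  grid <- array(as.numeric(img), dim = dim(img)[1:3])
  volume_image(grid, unname(structure(RNifti::xform(img), code = NULL)),
               subject_id = subject_id)
}

#' @rdname read_volume
#' @param vol a `volume_image`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(NULL)
}

#' Assemble the subjects x in-mask-voxels matrix
#'
#' Rows follow the cohort's canonical subject order; columns are the nonzero
#' voxels of `mask` in R's native array scan order (first axis fastest,
#' i.e. the order returned by `which()` on the mask array). That order is
#' fixed and is reproduced by [scatter_voxel_dataset()].
#'
#' @param volumes list of [volume_image()], one per cohort subject.
#' @param mask a `volume_image` whose nonzero voxels define the analysis set.
#' @param cohort a [cohort_table()].
#' @return a `voxel_dataset`: list with `data` (n x V matrix), `mask`,
#'   `affine`, `subject_ids`, `voxel_index` (1-based linear indices into the
#'   grid array).
#' @export
assemble_voxel_dataset <- function(volumes, mask, cohort) {
  voxel_index <- which(mask$grid != 0)
  if (length(voxel_index) == 0L)
    qc_stop("qcmatch_validation_error", "mask has no nonzero voxels")
  ids <- vapply(volumes, function(v) v$subject_id %||% NA_character_, "")
  if (anyNA(ids) || anyDuplicated(ids))
    qc_stop("qcmatch_validation_error", "volumes must carry unique subject_ids")
  missing <- setdiff(cohort$subject_id, ids)
  if (length(missing))
    qc_stop("qcmatch_alignment_error", "no volume for subject(s): ",
            paste(utils::head(missing, 5), collapse = ", "))
  volumes <- volumes[match(cohort$subject_id, ids)]
  for (v in volumes) {
    if (!all(dim(v$grid) == dim(mask$grid)))
      qc_stop("qcmatch_alignment_error", "grid shape mismatch for subject ",
              v$subject_id)
    if (max(abs(v$affine - mask$affine)) > 1e-6)
      qc_stop("qcmatch_alignment_error", "affine mismatch for subject ",
              v$subject_id)
  }
  data <- do.call(rbind, lapply(volumes, function(v) v$grid[voxel_index]))
  rownames(data) <- cohort$subject_id
  new_voxel_dataset(data, mask, cohort$subject_id, voxel_index)
}

new_voxel_dataset <- function(data, mask, subject_ids, voxel_index) {
  structure(list(data = data, mask = mask, affine = mask$affine,
                 subject_ids = subject_ids, voxel_index = voxel_index),
            class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat("voxel_dataset:", nrow(x$data), "subjects x", ncol(x$data),
      "in-mask voxels (grid", paste(dim(x$mask$grid), collapse = "x"), ")\n")
  invisible(x)
}

#' Scatter dataset rows back into volumes
#'
#' Inverse of [assemble_voxel_dataset()] inside the mask; voxels outside the
#' mask are set to `fill`.
#'
#' @param dataset a `voxel_dataset`.
#' @param fill value outside the mask.
#' @return list of [volume_image()] in subject order.
#' @export
scatter_voxel_dataset <- function(dataset, fill = 0) {
  lapply(seq_along(dataset$subject_ids), function(i) {
    grid <- array(fill, dim = dim(dataset$mask$grid))
    grid[dataset$voxel_index] <- dataset$data[i, ]
    volume_image(grid, dataset$affine, subject_id = dataset$subject_ids[i])
  })
}

# 0-based (i, j, k) for each in-mask column of a voxel_dataset.
voxel_ijk0 <- function(dataset) {
  arrayInd(dataset$voxel_index, dim(dataset$mask$grid)) - 1L
}

#' Subset a voxel dataset to a set of subjects
#'
#' Rows are returned in the order of `ids` (e.g. the subject order of a
#' protocol-selected cohort).
#'
#' @param dataset a `voxel_dataset`.
#' @param ids subject ids, all present in the dataset.
#' @return a `voxel_dataset` with `length(ids)` rows.
#' @export
subset_voxel_dataset <- function(dataset, ids) {
  idx <- match(ids, dataset$subject_ids)
  if (anyNA(idx))
    qc_stop("qcmatch_alignment_error", "subject(s) absent from voxel dataset")
  new_voxel_dataset(dataset$data[idx, , drop = FALSE], dataset$mask,
                    dataset$subject_ids[idx], dataset$voxel_index)
}
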