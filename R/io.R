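#' Write / read a parcellation as NIfTI
#'
#' The label volume is stored as an integer NIfTI image; hemisphere and
#' volume maps are reconstructed from the labels on read (labels `1..N/2`
#' left, `N/2+1..N` right).
#'
#' @param p a `parcellation`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path` (write) or a `parcellation` (read), invisibly for write.
#' @export
write_parcellation_nifti <- function(p, path) {
  stopifnot(inherits(p, "parcellation"))
  RNifti::writeNifti(RNifti::asNifti(p$label_volume, pixdim = p$voxel_size),
                     path)
  invisible(path)
}

#' @param path NIfTI file path.
#' @rdname write_parcellation_nifti
#' @export
read_parcellation_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  parcellation(array(as.integer(round(img)), dim = dim(img)), voxel_size = vs)
}

#' Write / read a lesion mask as NIfTI
#'
#' @param m a `lesion_mask`.
#' @param path output path.
#' @return `path` (write) or a `lesion_mask` (read).
#' @export
write_lesion_nifti <- function(m, path) {
  stopifnot(inherits(m, "lesion_mask"))
  vol <- array(0L, dim = m$grid_shape)
  vol[m$linear] <- 1L
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname write_lesion_nifti
#' @export
read_lesion_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  lesion_mask(array(as.integer(round(img)) != 0L, dim = dim(img)))
}

#' Write / read streamlines as JSON-lines
#'
#' One streamline per line: a JSON array of `[x, y, z]` vertices in
#' continuous 0-based voxel coordinates.
#'
#' @param s a `streamline_set`.
#' @param path output `.jsonl` path.
#' @param subject_id subject id to attach on read.
#' @return `path` (write) or a `streamline_set` (read).
#' @export
write_streamlines_jsonl <- function(s, path) {
  stopifnot(inherits(s, "streamline_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in s$streamlines) {
    writeLines(jsonlite::toJSON(unname(p), digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_streamlines_jsonl
#' @export
read_streamlines_jsonl <- function(path, subject_id = basename(path)) {
  lines <- readLines(path)
  streamline_set(lapply(lines, function(l) {
    m <- jsonlite::fromJSON(l)
    matrix(as.numeric(m), ncol = 3L)
  }), subject_id = subject_id)
}

#' Write / read a connectome as CSV
#'
#' N rows by N comma-separated reals with a header row of region ids.
#'
#' @param c a `connectome`.
#' @param path output `.csv` path.
#' @return `path` (write) or a `connectome` (read).
#' @export
write_connectome_csv <- function(c, path) {
  w <- as_connectome_matrix(c)
  colnames(w) <- as.character(seq_len(ncol(w)))
  utils::write.csv(w, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  w <- as.matrix(utils::read.csv(path, check.names = FALSE))
  dimnames(w) <- NULL
  connectome(w)
}

#' Write / read a cohort table as CSV
#'
#' Header: `id,age,fma_2w,fma_3m,lesion_path,fa_h,fa_l`. When `lesion_dir`
#' is given, each patient's lesion mask is written as NIfTI next to the
#' table and referenced in `lesion_path`.
#'
#' @param cohort a `cohort`.
#' @param path output `.csv` path.
#' @param lesion_dir optional directory for lesion NIfTI files.
#' @return `path` (write) or a data.frame (read).
#' @export
write_cohort_csv <- function(cohort, path, lesion_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  df <- cohort$patients
  lesion_path <- rep(NA_character_, nrow(df))
  if (!is.null(lesion_dir)) {
    dir.create(lesion_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(df))) {
      lp <- file.path(lesion_dir, paste0(df$id[i], "_lesion.nii.gz"))
      write_lesion_nifti(cohort$lesions[[df$id[i]]], lp)
      # store the path relative to the table so the bundle is relocatable
      lesion_path[i] <- if (startsWith(normalizePath(lp, winslash = "/"),
                                       normalizePath(dirname(path),
                                                     winslash = "/"))) {
        substring(normalizePath(lp, winslash = "/"),
                  nchar(normalizePath(dirname(path), winslash = "/")) + 2L)
      } else {
        lp
      }
    }
  }
  out <- data.frame(id = df$id, age = df$age, fma_2w = df$fma_2w,
                    fma_3m = df$fma_3m, lesion_path = lesion_path,
                    fa_h = df$fa_h, fa_l = df$fa_l)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the per-patient measure table as CSV
#'
#' Rows are patients, columns the connectivity measures under their
#' human-readable labels.
#'
#' @param measures patients-by-measures matrix (rownames = patient ids).
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_measures_csv <- function(measures, path) {
  m <- as.matrix(measures)
  lab <- measure_labels()
  colnames(m) <- ifelse(colnames(m) %in% names(lab), lab[colnames(m)],
                        colnames(m))
  utils::write.csv(data.frame(id = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
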