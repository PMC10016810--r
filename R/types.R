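#' Construct a parcellation
#'
#' A parcellation is a labelled voxel grid: 0 marks background, labels
#' `1..N` mark regions. Labels `1..N/2` belong to the left hemisphere and
#' `N/2+1..N` to the right, mirroring atlas conventions that list all
#' left-hemisphere areas first.
#'
#' @param label_volume 3-D integer array of region labels (0 = background).
#' @param voxel_size length-3 numeric, physical size of a voxel along each
#'   axis (default 1, i.e. volumes are reported in voxel units).
#' @return An object of class `parcellation` with fields `label_volume`,
#'   `n_regions`, `hemisphere_of` (named character vector `"L"`/`"R"`),
#'   `region_volume` (named integer vector of voxel counts) and `voxel_size`.
#' @export
parcellation <- function(label_volume, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(label_volume)) == 3L, length(voxel_size) == 3L)
  labs <- as.integer(label_volume)
  n <- max(labs)
  if (n < 2L || n %% 2L != 0L) {
    stop("parcellation must contain an even number (>= 2) of region labels")
  }
  counts <- tabulate(labs, nbins = n)
  if (any(counts == 0L)) {
    stop("every region label 1..N must own at least one voxel")
  }
  hemi <- c(rep("L", n %/% 2L), rep("R", n - n %/% 2L))
  names(hemi) <- as.character(seq_len(n))
  names(counts) <- as.character(seq_len(n))
  structure(
    list(
      label_volume = array(labs, dim = dim(label_volume)),
      n_regions = n,
      hemisphere_of = hemi,
      region_volume = counts,
      voxel_size = as.numeric(voxel_size)
    ),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "<parcellation> %d regions (%d L / %d R), grid %s, voxel size %s\n",
    x$n_regions, sum(x$hemisphere_of == "L"), sum(x$hemisphere_of == "R"),
    paste(dim(x$label_volume), collapse = "x"),
    paste(x$voxel_size, collapse = "x")
  ))
  invisible(x)
}

#' Construct a streamline set
#'
#' @param streamlines list of numeric matrices, one polyline per streamline;
#'   each has >= 2 rows (vertices) and 3 columns (continuous voxel
#'   coordinates, 0-based: voxel (0,0,0) spans `[0,1)^3`).
#' @param subject_id character identifier of the (healthy) subject.
#' @return Object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, subject_id = "subject") {
  stopifnot(is.list(streamlines))
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L) {
      stop("each streamline must be a numeric matrix with >= 2 rows and 3 columns")
    }
  }
  structure(
    list(streamlines = streamlines, subject_id = as.character(subject_id)),
    class = "streamline_set"
  )
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf(
    "<streamline_set> subject '%s', %d streamlines\n",
    x$subject_id, length(x$streamlines)
  ))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Construct a lesion mask
#'
#' @param voxels integer matrix (n x 3) of 0-based voxel coordinates, or a
#'   3-D logical/numeric array which is converted to coordinates of nonzero
#'   voxels.
#' @param grid_shape length-3 integer grid dimensions (required when `voxels`
#'   is a coordinate matrix).
#' @return Object of class `lesion_mask` with a deduplicated, sorted voxel
#'   coordinate matrix and the grid shape.
#' @export
lesion_mask <- function(voxels, grid_shape = NULL) {
  if (is.array(voxels) && length(dim(voxels)) == 3L) {
    grid_shape <- dim(voxels)
    idx <- which(voxels != 0)
    vox <- linear_index_voxel(idx, grid_shape)
  } else {
    if (is.null(grid_shape)) stop("grid_shape required for coordinate input")
    vox <- matrix(as.integer(voxels), ncol = 3L)
  }
  grid_shape <- as.integer(grid_shape)
  if (nrow(vox) > 0L) {
    if (any(vox < 0L) || any(t(vox) >= grid_shape)) {
      stop("lesion voxels outside grid bounds")
    }
    lin <- sort(unique(voxel_linear_index(vox, grid_shape)))
    vox <- linear_index_voxel(lin, grid_shape)
  } else {
    lin <- integer(0)
    vox <- matrix(integer(0), ncol = 3L)
  }
  structure(
    list(voxels = vox, linear = lin, grid_shape = grid_shape),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask> %d voxels on grid %s\n",
    nrow(x$voxels), paste(x$grid_shape, collapse = "x")
  ))
  invisible(x)
}

#' Number of lesioned voxels
#' @param m a `lesion_mask`.
#' @return integer voxel count.
#' @export
lesion_size <- function(m) {
  stopifnot(inherits(m, "lesion_mask"))
  nrow(m$voxels)
}

#' Construct a connectome
#'
#' Symmetric nonnegative matrix of volume-normalized streamline counts:
#' entry (i, j) is the streamline count between regions i and j divided by
#' the summed voxel volumes of the two regions.
#'
#' @param weights symmetric N x N nonnegative matrix with zero diagonal.
#' @param n_streamlines_used streamlines contributing to off-diagonal counts.
#' @param n_excluded streamlines excluded (unassigned endpoints or self-pairs).
#' @return Object of class `connectome`.
#' @export
connectome <- function(weights, n_streamlines_used = NA_integer_,
                       n_excluded = NA_integer_) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 1e-12) stop("connectome must be symmetric")
  if (any(diag(weights) != 0)) stop("connectome diagonal must be zero")
  structure(
    list(
      weights = weights,
      n_streamlines_used = as.integer(n_streamlines_used),
      n_excluded = as.integer(n_excluded)
    ),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> %d regions, %s streamlines used, weighted density %.4f\n",
    nrow(x$weights),
    ifelse(is.na(x$n_streamlines_used), "?", x$n_streamlines_used),
    weighted_density(x)
  ))
  invisible(x)
}

as_connectome_matrix <- function(c) {
  if (inherits(c, "connectome")) c$weights else as.matrix(c)
}
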