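#' Rasterize a streamline onto the voxel grid
#'
#' Returns every voxel whose cube is entered by the polyline. Each segment is
#' supersampled at a step of at most `step` voxel units (default 0.5) and the
#' sampled points are floored to voxel coordinates; both endpoint voxels are
#' always included. Coordinates are continuous and 0-based: voxel (0,0,0)
#' spans the half-open cube `[0,1)^3`. Points on the upper grid boundary are
#' clamped into the last voxel.
#'
#' @param polyline numeric matrix (>= 2 rows, 3 cols) of vertex coordinates.
#' @param grid_shape length-3 integer grid dimensions.
#' @param step maximal supersampling step in voxel units.
#' @return integer matrix (n x 3) of distinct 0-based voxel coordinates, in
#'   increasing linear-index order.
#' @export
rasterize_streamline <- function(polyline, grid_shape, step = 0.5) {
  grid_shape <- as.integer(grid_shape)
  lin <- rasterize_linear(polyline, grid_shape, step)
  linear_index_voxel(lin, grid_shape)
}

# Internal: rasterized voxels as sorted unique 1-based linear indices.
rasterize_linear <- function(polyline, grid_shape, step = 0.5) {
  nv <- nrow(polyline)
  a <- polyline[-nv, , drop = FALSE]
  b <- polyline[-1L, , drop = FALSE]
  seg_len <- sqrt(rowSums((b - a)^2))
  nsteps <- pmax(1L, ceiling(seg_len / step))
  reps <- nsteps + 1L
  idx <- rep.int(seq_len(nv - 1L), reps)
  frac <- sequence(reps, from = 0L) / nsteps[idx]
  pts <- a[idx, , drop = FALSE] + frac * (b - a)[idx, , drop = FALSE]
  vox <- floor(pts)
  # clamp to grid (upper boundary points belong to the last voxel)
  for (k in 1:3) {
    vox[, k] <- pmin(pmax(vox[, k], 0), grid_shape[k] - 1L)
  }
  sort(unique(voxel_linear_index(vox, grid_shape)))
}

#' Delete streamlines passing through a lesion
#'
#' Virtual lesioning: removes from a healthy streamline set every streamline
#' whose rasterized voxel trace intersects the lesion mask, emulating the
#' deletion of all white-matter tracts passing through the lesioned area.
#' Streamline order is preserved and the input is not modified.
#'
#' @param s a `streamline_set`.
#' @param m a `lesion_mask` on the same grid.
#' @param grid_shape grid dimensions of `s` (defaults to the mask's grid).
#' @return a `streamline_set` containing only the surviving streamlines.
#' @export
apply_virtual_lesion <- function(s, m, grid_shape = NULL) {
  stopifnot(inherits(s, "streamline_set"), inherits(m, "lesion_mask"))
  grid_shape <- as.integer(grid_shape %||% m$grid_shape)
  if (!identical(grid_shape, as.integer(m$grid_shape))) {
    stop("streamline set and lesion mask are defined on different grids")
  }
  for (p in s$streamlines) {
    if (any(p < 0) || any(t(p) > grid_shape)) {
      stop("streamline coordinates fall outside the mask grid: ",
           "streamline set and lesion mask are defined on different grids")
    }
  }
  if (lesion_size(m) == 0L) {
    return(streamline_set(s$streamlines, s$subject_id))
  }
  lesioned <- logical(prod(grid_shape))
  lesioned[m$linear] <- TRUE
  keep <- vapply(s$streamlines, function(p) {
    !any(lesioned[rasterize_linear(p, grid_shape)])
  }, logical(1))
  streamline_set(s$streamlines[keep], s$subject_id)
}

#' Assign a streamline's endpoints to parcellation regions
#'
#' Each endpoint maps to the label of its containing voxel; when that voxel is
#' background, to the nearest labelled voxel within a Chebyshev radius
#' (default 2; ties broken by smaller Chebyshev distance, then lower linear
#' index). If either endpoint stays unassigned the streamline is unassignable.
#'
#' @param polyline numeric matrix of vertices (first and last row are used).
#' @param p a `parcellation`.
#' @param radius nonnegative integer Chebyshev search radius.
#' @return integer vector of two region labels, or `NULL` if unassignable.
#' @export
assign_endpoints <- function(polyline, p, radius = 2L) {
  stopifnot(inherits(p, "parcellation"), radius >= 0)
  dims <- dim(p$label_volume)
  ends <- polyline[c(1L, nrow(polyline)), , drop = FALSE]
  labs <- integer(2)
  for (k in 1:2) {
    vox <- pmin(pmax(floor(ends[k, ]), 0), dims - 1L)
    labs[k] <- lookup_label(vox, p$label_volume, radius)
    if (labs[k] == 0L) return(NULL)
  }
  labs
}

lookup_label <- function(vox, label_volume, radius) {
  dims <- dim(label_volume)
  lab <- label_volume[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L]
  if (lab > 0L || radius < 1L) return(lab)
  for (r in seq_len(radius)) {
    off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
    off <- off[pmax(abs(off[, 1]), pmax(abs(off[, 2]), abs(off[, 3]))) == r, ,
               drop = FALSE]
    cand <- sweep(off, 2L, vox, `+`)
    ok <- cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0 &
      cand[, 1] < dims[1] & cand[, 2] < dims[2] & cand[, 3] < dims[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    lin <- voxel_linear_index(cand, dims)
    labs <- label_volume[lin]
    hit <- labs > 0L
    if (any(hit)) {
      return(labs[hit][which.min(lin[hit])])
    }
  }
  0L
}

#' Build a volume-normalized connectome from a streamline set
#'
#' Counts streamlines whose two endpoints map to distinct regions i and j and
#' sets the edge weight to `count / (V_i + V_j)` where V are region voxel
#' volumes. Streamlines with unassignable endpoints or with both endpoints in
#' the same region are excluded (tracked in `n_excluded`).
#'
#' @param s a `streamline_set`.
#' @param p a `parcellation`.
#' @param radius endpoint Chebyshev search radius (see [assign_endpoints()]).
#' @return a `connectome`.
#' @export
build_connectome <- function(s, p, radius = 2L) {
  stopifnot(inherits(s, "streamline_set"), inherits(p, "parcellation"))
  n <- p$n_regions
  if (any(p$region_volume <= 0L)) stop("all region volumes must be positive")
  counts <- matrix(0, n, n)
  used <- 0L
  for (poly in s$streamlines) {
    ep <- assign_endpoints(poly, p, radius)
    if (is.null(ep) || ep[1] == ep[2]) next
    i <- min(ep); j <- max(ep)
    counts[i, j] <- counts[i, j] + 1
    used <- used + 1L
  }
  counts <- counts + t(counts)
  vsum <- outer(p$region_volume, p$region_volume, `+`)
  w <- counts / vsum
  diag(w) <- 0
  dimnames(w) <- NULL
  connectome(w, n_streamlines_used = used,
             n_excluded = length(s$streamlines) - used)
}

# ---- Fast indexed path used by the pipeline -------------------------------
#
# Rasterization and endpoint assignment do not depend on the lesion, so for a
# cohort they are computed once per healthy subject and reused across all
# patients.

#' Precompute rasterized voxels and endpoint regions for a streamline set
#'
#' Internal acceleration structure for cohort-scale virtual lesioning:
#' stores, for every streamline, its rasterized voxel trace (linear indices)
#' and its endpoint region pair, so that lesioning any mask reduces to a
#' vectorized lookup.
#'
#' @param s a `streamline_set`.
#' @param p a `parcellation`.
#' @param radius endpoint search radius.
#' @return an object of class `indexed_tractogram`.
#' @export
index_streamline_set <- function(s, p, radius = 2L, step = 0.5) {
  dims <- dim(p$label_volume)
  nsl <- length(s$streamlines)
  # one vectorized rasterization pass over all segments of all streamlines
  nv <- vapply(s$streamlines, nrow, integer(1))
  V <- do.call(rbind, s$streamlines)
  ends <- cumsum(nv)
  starts <- ends - nv + 1L
  seg_a <- setdiff(seq_len(sum(nv)), ends)       # segment start rows
  seg_sl <- rep.int(seq_len(nsl), nv - 1L)       # streamline of each segment
  A <- V[seg_a, , drop = FALSE]
  B <- V[seg_a + 1L, , drop = FALSE]
  seg_len <- sqrt(rowSums((B - A)^2))
  nsteps <- pmax(1L, ceiling(seg_len / step))
  reps <- nsteps + 1L
  idx <- rep.int(seq_along(seg_a), reps)
  frac <- sequence(reps, from = 0L) / nsteps[idx]
  pts <- A[idx, , drop = FALSE] + frac * (B - A)[idx, , drop = FALSE]
  vox <- floor(pts)
  for (k in 1:3) vox[, k] <- pmin(pmax(vox[, k], 0), dims[k] - 1L)
  lin <- voxel_linear_index(vox, dims)
  sl_of_pt <- seg_sl[idx]
  key <- (sl_of_pt - 1) * prod(dims) + lin
  keep <- !duplicated(key)
  lin <- lin[keep]
  sl_of_pt <- sl_of_pt[keep]
  nvox <- tabulate(sl_of_pt, nsl)
  ord <- order(sl_of_pt, lin)
  # endpoint assignment (vectorized containment, loop only for background)
  epts <- rbind(V[starts, , drop = FALSE], V[ends, , drop = FALSE])
  evox <- floor(epts)
  for (k in 1:3) evox[, k] <- pmin(pmax(evox[, k], 0), dims[k] - 1L)
  elab <- p$label_volume[voxel_linear_index(evox, dims)]
  miss <- which(elab == 0L)
  for (i in miss) {
    elab[i] <- lookup_label(evox[i, ], p$label_volume, radius)
  }
  ep <- cbind(pmin(elab[seq_len(nsl)], elab[nsl + seq_len(nsl)]),
              pmax(elab[seq_len(nsl)], elab[nsl + seq_len(nsl)]))
  ep[ep[, 1L] == 0L, ] <- NA_integer_
  structure(
    list(
      subject_id = s$subject_id,
      n_streamlines = nsl,
      voxel_id = lin[ord],
      sl_id = sl_of_pt[ord],
      endpoints = ep,
      n_regions = p$n_regions,
      region_volume = p$region_volume,
      grid_shape = dims
    ),
    class = "indexed_tractogram"
  )
}

#' Connectome of an indexed tractogram under a lesion mask
#'
#' Equivalent to `build_connectome(apply_virtual_lesion(s, m), p)` but using
#' the precomputed index; with `m = NULL` returns the healthy connectome.
#'
#' @param ix an `indexed_tractogram`.
#' @param m a `lesion_mask` or `NULL`.
#' @return a `connectome`.
#' @export
lesioned_connectome <- function(ix, m = NULL) {
  stopifnot(inherits(ix, "indexed_tractogram"))
  surviving <- rep(TRUE, ix$n_streamlines)
  if (!is.null(m) && lesion_size(m) > 0L) {
    if (!identical(as.integer(m$grid_shape), as.integer(ix$grid_shape))) {
      stop("lesion mask and tractogram are defined on different grids")
    }
    lesioned <- logical(prod(ix$grid_shape))
    lesioned[m$linear] <- TRUE
    hit_counts <- tabulate(ix$sl_id[lesioned[ix$voxel_id]], ix$n_streamlines)
    surviving <- hit_counts == 0L
  }
  n <- ix$n_regions
  ep <- ix$endpoints
  ok <- surviving & !is.na(ep[, 1]) & ep[, 1] != ep[, 2]
  # upper-triangle counts (ep[,1] <= ep[,2]) via column-major linear index
  pair <- ep[ok, 1] + (ep[ok, 2] - 1L) * n
  counts <- matrix(tabulate(pair, nbins = n * n), n, n)
  counts <- counts + t(counts)
  vsum <- outer(ix$region_volume, ix$region_volume, `+`)
  w <- counts / vsum
  diag(w) <- 0
  dimnames(w) <- NULL
  connectome(w, n_streamlines_used = sum(ok),
             n_excluded = ix$n_streamlines - sum(ok))
}

#' Streamline indices transected by a mask
#'
#' @param ix an `indexed_tractogram`.
#' @param m a `lesion_mask`.
#' @return integer vector of streamline indices hit by the mask.
#' @export
transected_streamlines <- function(ix, m) {
  stopifnot(inherits(ix, "indexed_tractogram"), inherits(m, "lesion_mask"))
  if (lesion_size(m) == 0L) return(integer(0))
  lesioned <- logical(prod(ix$grid_shape))
  lesioned[m$linear] <- TRUE
  which(tabulate(ix$sl_id[lesioned[ix$voxel_id]], ix$n_streamlines) > 0L)
}
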