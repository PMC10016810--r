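#' Configuration for the synthetic phantom study
#'
#' Defines the conditions of the synthetic study emulated by the generators:
#' a two-hemisphere parcellation, a template tractogram shared by all healthy
#' subjects up to seeded jitter, focal ellipsoidal lesions, and a patient
#' cohort whose recovery is a planted linear function of initial impairment,
#' CST asymmetry and lesion-induced network damage plus Gaussian noise.
#'
#' @param grid_shape length-3 positive integers (voxels).
#' @param n_regions even positive integer number of parcels (half per
#'   hemisphere).
#' @param n_healthy number of healthy tractograms.
#' @param n_streamlines streamlines per healthy subject.
#' @param n_patients cohort size.
#' @param hub_exponent preferential-attachment strength for region-pair
#'   sampling (0 = uniform endpoints, larger = stronger hubs).
#' @param noise_sd standard deviation of the recovery-score noise (% points).
#' @param planted_betas length-4 numeric: intercept, initial-FMA, asymmetry
#'   and network-damage coefficients of the planted recovery model.
#' @param fa_attenuation maximal relative FA loss of a fully transected CST.
#' @param jitter_sd per-subject Gaussian vertex jitter (voxel units).
#' @param seed integer master seed.
#' @return validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(24, 24, 16),
                           n_regions = 36,
                           n_healthy = 60,
                           n_streamlines = 5000,
                           n_patients = 40,
                           hub_exponent = 1,
                           noise_sd = 2,
                           planted_betas = c(5, 1.0, -60, -60),
                           fa_attenuation = 0.6,
                           jitter_sd = 0.3,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L || n_regions %% 2L != 0L) {
    stop("n_regions must be a positive even integer")
  }
  for (v in c(n_healthy, n_streamlines, n_patients)) {
    if (v < 1L) stop("all counts must be >= 1")
  }
  stopifnot(hub_exponent >= 0, noise_sd >= 0, length(planted_betas) == 4L,
            fa_attenuation >= 0, fa_attenuation <= 1)
  if (grid_shape[1L] < 2L || prod(grid_shape) < 2L * n_regions) {
    stop("grid too small to host n_regions non-empty parcels")
  }
  structure(
    list(grid_shape = grid_shape, n_regions = n_regions,
         n_healthy = as.integer(n_healthy),
         n_streamlines = as.integer(n_streamlines),
         n_patients = as.integer(n_patients),
         hub_exponent = hub_exponent, noise_sd = noise_sd,
         planted_betas = as.numeric(planted_betas),
         fa_attenuation = fa_attenuation, jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Split each hemisphere (x < nx/2 vs x >= nx/2) into n_regions/2 contiguous
# boxes by recursive halving of the box list along its longest axis.
phantom_parcellation <- function(config) {
  dims <- config$grid_shape
  half <- config$n_regions %/% 2L
  split_boxes <- function(box0, k) {
    boxes <- list(box0)
    while (length(boxes) < k) {
      sizes <- vapply(boxes, function(b) prod(b[, 2] - b[, 1] + 1), numeric(1))
      i <- which.max(sizes)
      b <- boxes[[i]]
      ext <- b[, 2] - b[, 1] + 1
      ax <- which.max(ext)
      if (ext[ax] < 2L) stop("grid too small to host n_regions non-empty parcels")
      mid <- b[ax, 1] + ext[ax] %/% 2L - 1L
      b1 <- b; b1[ax, 2] <- mid
      b2 <- b; b2[ax, 1] <- mid + 1L
      boxes <- c(boxes[-i], list(b1), list(b2))
    }
    boxes
  }
  # deterministic ordering: sort boxes by (z, y, x) of their lower corner
  order_boxes <- function(boxes) {
    key <- vapply(boxes, function(b) {
      b[3, 1] * 1e6 + b[2, 1] * 1e3 + b[1, 1]
    }, numeric(1))
    boxes[order(key)]
  }
  nx_l <- dims[1L] %/% 2L
  lab <- array(0L, dim = dims)
  fill <- function(lab, boxes, offset) {
    for (i in seq_along(boxes)) {
      b <- boxes[[i]]
      lab[(b[1, 1]:b[1, 2]) + 1L, (b[2, 1]:b[2, 2]) + 1L,
          (b[3, 1]:b[3, 2]) + 1L] <- offset + i
    }
    lab
  }
  box_l <- rbind(c(0L, nx_l - 1L), c(0L, dims[2L] - 1L), c(0L, dims[3L] - 1L))
  box_r <- rbind(c(nx_l, dims[1L] - 1L), c(0L, dims[2L] - 1L),
                 c(0L, dims[3L] - 1L))
  lab <- fill(lab, order_boxes(split_boxes(box_l, half)), 0L)
  lab <- fill(lab, order_boxes(split_boxes(box_r, half)), half)
  parcellation(lab)
}

# Sample a random point (continuous voxel coordinates) inside a region.
region_points <- function(parc, region, k) {
  idx <- which(parc$label_volume == region)
  pick <- idx[sample.int(length(idx), k, replace = TRUE)]
  linear_index_voxel(pick, dim(parc$label_volume)) + matrix(stats::runif(3 * k),
                                                            k, 3)
}

#' Generate the phantom brain: parcellation and healthy tractograms
#'
#' Builds a deterministic two-hemisphere box parcellation, a template
#' tractogram whose region pairs follow preferential attachment (probability
#' proportional to `(degree + 1)^hub_exponent`, so hubs emerge for positive
#' exponents and endpoint regions are uniform at exponent 0), and one
#' streamline set per healthy subject obtained by adding seeded Gaussian
#' vertex jitter (sd `jitter_sd` voxels) to the template. Two template
#' bundles, one per hemisphere, are designated as cortico-spinal tracts: all
#' streamlines incident to the most ventral region of each hemisphere.
#'
#' The returned parcellation carries attributes used downstream:
#' `hub_voxel` (0-based coordinates of the voxel with the highest template
#' streamline traversal density), `cst_centre_l` / `cst_centre_r` (corridor
#' centroids), `cst_streamlines_l` / `cst_streamlines_r` (template indices)
#' and `template` (the template `streamline_set`).
#'
#' @param config a `phantom_config`.
#' @return list with `parcellation` and `healthy` (list of `streamline_set`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  parc <- phantom_parcellation(config)
  n <- config$n_regions
  dims <- config$grid_shape
  out <- with_seed(config$seed, {
    deg <- rep(0, n)
    pairs <- matrix(0L, config$n_streamlines, 2L)
    for (s in seq_len(config$n_streamlines)) {
      wgt <- (deg + 1)^config$hub_exponent
      i <- sample.int(n, 1L, prob = wgt)
      wgt2 <- wgt; wgt2[i] <- 0
      j <- sample.int(n, 1L, prob = wgt2)
      pairs[s, ] <- c(i, j)
      deg[i] <- deg[i] + 1
      deg[j] <- deg[j] + 1
    }
    a <- do.call(rbind, lapply(seq_len(config$n_streamlines), function(s) {
      region_points(parc, pairs[s, 1L], 1L)
    }))
    b <- do.call(rbind, lapply(seq_len(config$n_streamlines), function(s) {
      region_points(parc, pairs[s, 2L], 1L)
    }))
    # polyline: straight chord with a mild random bow, 7 interior vertices
    n_iv <- 7L
    template <- vector("list", config$n_streamlines)
    for (s in seq_len(config$n_streamlines)) {
      t <- seq(0, 1, length.out = n_iv + 2L)
      chord <- outer(1 - t, a[s, ]) + outer(t, b[s, ])
      bow <- stats::rnorm(3, sd = 0.5)
      chord <- chord + outer(sin(pi * t), bow)
      template[[s]] <- clamp_to_grid(chord, dims)
    }
    jit <- lapply(seq_len(config$n_healthy), function(h) {
      lapply(template, function(p) {
        clamp_to_grid(p + matrix(stats::rnorm(length(p), sd = config$jitter_sd),
                                 nrow(p), 3L), dims)
      })
    })
    list(template = template, jit = jit, pairs = pairs)
  })
  template_set <- streamline_set(out$template, "template")
  healthy <- lapply(seq_len(config$n_healthy), function(h) {
    streamline_set(out$jit[[h]], sprintf("healthy%02d", h))
  })
  # traversal density of the template (for hub-centred lesions)
  dens <- integer(prod(dims))
  for (p in out$template) {
    lin <- rasterize_linear(p, dims)
    dens[lin] <- dens[lin] + 1L
  }
  hub_lin <- which.max(dens)
  attr(parc, "hub_voxel") <- as.integer(linear_index_voxel(hub_lin, dims))
  # CST designation: streamlines incident to the first region of each
  # hemisphere (a stand-in motor corridor)
  half <- n %/% 2L
  cst_l <- which(out$pairs[, 1L] == 1L | out$pairs[, 2L] == 1L)
  cst_r <- which(out$pairs[, 1L] == half + 1L | out$pairs[, 2L] == half + 1L)
  centre_of <- function(sl_idx) {
    if (length(sl_idx) == 0L) return(round(dims / 2))
    pts <- do.call(rbind, out$template[sl_idx])
    pmin(pmax(floor(colMeans(pts)), 0L), dims - 1L)
  }
  attr(parc, "cst_streamlines_l") <- cst_l
  attr(parc, "cst_streamlines_r") <- cst_r
  attr(parc, "cst_centre_l") <- as.integer(centre_of(cst_l))
  attr(parc, "cst_centre_r") <- as.integer(centre_of(cst_r))
  attr(parc, "template") <- template_set
  list(parcellation = parc, healthy = healthy)
}

clamp_to_grid <- function(p, dims, eps = 1e-6) {
  dimnames(p) <- NULL
  for (k in 1:3) {
    p[, k] <- pmin(pmax(p[, k], 0), dims[k] - eps)
  }
  p
}

#' Generate an ellipsoidal lesion
#'
#' Returns an ellipsoidal blob of lesioned voxels whose size grows
#' monotonically with `severity`: the semi-axes are
#' `severity * sqrt(3) * grid_shape`, so lesions at increasing severity with
#' the same seed are nested, `severity = 0` gives an empty mask, and
#' `severity = 1` covers the whole grid. `centre_bias` places the centre on
#' the voxel of highest streamline traversal density (`"hub"`), on the
#' designated cortico-spinal corridor (`"cst"`, with a small seeded jitter
#' and a seeded hemisphere choice), or uniformly at random (`"random"`).
#'
#' @param parc a `parcellation`; for `"hub"`/`"cst"` bias it must carry the
#'   attributes set by [generate_phantom()].
#' @param severity real in `[0, 1]`.
#' @param centre_bias `"hub"`, `"random"` or `"cst"`.
#' @param seed integer seed (fixes the centre, so severity only scales the
#'   blob).
#' @return a `lesion_mask`.
#' @export
generate_lesion <- function(parc, severity, centre_bias = c("random", "hub", "cst"),
                            seed = 1L) {
  centre_bias <- match.arg(centre_bias)
  assert_scalar_number(severity, "severity", 0, 1)
  dims <- dim(parc$label_volume)
  if (severity == 0) {
    return(lesion_mask(matrix(integer(0), ncol = 3L), grid_shape = dims))
  }
  centre <- with_seed(seed, {
    switch(centre_bias,
      hub = attr(parc, "hub_voxel") %||%
        stop("parcellation lacks hub annotation (run generate_phantom)"),
      cst = {
        side <- if (stats::runif(1) < 0.5) "l" else "r"
        base <- attr(parc, paste0("cst_centre_", side)) %||%
          stop("parcellation lacks CST annotation (run generate_phantom)")
        base + round(stats::rnorm(3, sd = 1.5))
      },
      random = floor(stats::runif(3) * dims)
    )
  })
  centre <- pmin(pmax(as.numeric(centre), 0), dims - 1L)
  semi <- severity * sqrt(3) * dims
  ax <- (seq_len(dims[1L]) - 1 - centre[1L]) / semi[1L]
  ay <- (seq_len(dims[2L]) - 1 - centre[2L]) / semi[2L]
  az <- (seq_len(dims[3L]) - 1 - centre[3L]) / semi[3L]
  d2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  lesion_mask(array(d2 <= 1, dim = dims))
}

#' Generate a synthetic patient cohort
#'
#' For each patient, draws a lesion severity, a lesion placed either on the
#' cortico-spinal corridor (60% of patients, emulating middle-cerebral-artery
#' territory strokes) or at a random location, an age (no planted effect on
#' recovery), and an initial FMA score decreasing in severity (clipped into
#' the inclusion range 0..55). The ipsilesional
#' CST mean FA is attenuated proportionally to the fraction of that
#' hemisphere's designated CST template streamlines transected by the lesion;
#' the contralateral FA is the subject's baseline. Network damage is the
#' relative drop in mean weighted global efficiency across the healthy
#' connectomes caused by virtually lesioning them with the patient's mask.
#' Recovery (% points) is then
#' `clip(b0 + b1 * fma_2w + b2 * asymmetry + b3 * damage + eps, 0, 100)` with
#' `eps ~ N(0, noise_sd^2)`, and the 3-month FMA is the rounded consequence
#' of that recovery. Noise is the only stochastic term in recovery given the
#' lesion.
#'
#' @param config a `phantom_config`.
#' @param parc the annotated `parcellation` from [generate_phantom()].
#' @param healthy list of healthy `streamline_set`s from [generate_phantom()].
#' @param indexed optional list of `indexed_tractogram`s (precomputed with
#'   [index_streamline_set()]); computed here when `NULL`.
#' @return object of class `cohort`: list with `patients` (data.frame
#'   `id, age, fma_2w, fma_3m, fa_h, fa_l, lesion_volume, severity, damage,
#'   recovery_true`), `lesions` (list of `lesion_mask`), `config`.
#' @export
generate_cohort <- function(config, parc, healthy, indexed = NULL) {
  stopifnot(inherits(config, "phantom_config"), inherits(parc, "parcellation"))
  if (is.null(indexed)) {
    indexed <- lapply(healthy, index_streamline_set, p = parc)
  }
  e_healthy <- mean(vapply(indexed, function(ix) {
    weighted_global_efficiency(lesioned_connectome(ix))
  }, numeric(1)))
  np <- config$n_patients
  betas <- config$planted_betas
  # per-patient seeds derived from the master seed keep each patient's lesion
  # reproducible in isolation
  draws <- with_seed(config$seed + 1L, {
    list(
      severity = stats::runif(np, 0.05, 0.25),
      age = round(stats::runif(np, 28, 85)),
      fma_noise = stats::rnorm(np, 0, 5),
      fa0 = stats::rnorm(np, 0.55, 0.02),
      eps = stats::rnorm(np, 0, config$noise_sd),
      centre_bias = ifelse(stats::runif(np) < 0.6, "cst", "random"),
      lesion_seed = sample.int(2^30, np)
    )
  })
  ids <- sprintf("P%03d", seq_len(np))
  lesions <- vector("list", np)
  rows <- vector("list", np)
  # template index for CST transection fractions
  template_ix <- index_streamline_set(attr(parc, "template"), parc)
  half <- config$n_regions %/% 2L
  for (i in seq_len(np)) {
    m <- generate_lesion(parc, draws$severity[i],
                         centre_bias = draws$centre_bias[i],
                         seed = draws$lesion_seed[i])
    lesions[[i]] <- m
    fma_2w <- round(min(55, max(0, 58 - 230 * draws$severity[i] +
                                  draws$fma_noise[i])))
    # which hemisphere holds the lesion centroid
    side <- if (nrow(m$voxels) && mean(m$voxels[, 1L]) <
               dim(parc$label_volume)[1L] / 2) "l" else "r"
    cst_idx <- attr(parc, paste0("cst_streamlines_", side))
    hit <- transected_streamlines(template_ix, m)
    frac <- if (length(cst_idx)) mean(cst_idx %in% hit) else 0
    fa_h <- draws$fa0[i]
    fa_l <- fa_h * (1 - config$fa_attenuation * frac)
    asym <- (fa_h - fa_l) / (fa_h + fa_l)
    e_les <- mean(vapply(indexed, function(ix) {
      weighted_global_efficiency(lesioned_connectome(ix, m))
    }, numeric(1)))
    damage <- if (e_healthy > 0) (e_healthy - e_les) / e_healthy else 0
    recovery <- betas[1L] + betas[2L] * fma_2w + betas[3L] * asym +
      betas[4L] * damage + draws$eps[i]
    recovery <- min(100, max(0, recovery))
    fma_3m <- round(fma_2w + recovery / 100 * (66 - fma_2w))
    fma_3m <- min(66L, max(0L, fma_3m))
    rows[[i]] <- data.frame(
      id = ids[i], age = draws$age[i], fma_2w = fma_2w, fma_3m = fma_3m,
      fa_h = fa_h, fa_l = fa_l,
      lesion_volume = lesion_volume(m, parc$voxel_size),
      severity = draws$severity[i], damage = damage, recovery_true = recovery
    )
  }
  patients <- do.call(rbind, rows)
  names(lesions) <- ids
  structure(
    list(patients = patients, lesions = lesions, config = config,
         provenance = "phantom"),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d patients (%s), median initial FMA %.0f\n",
    nrow(x$patients), x$provenance, stats::median(x$patients$fma_2w)
  ))
  invisible(x)
}
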