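test_that("rasterization follows the supersampled-floor contract", {
  grid <- c(8, 8, 8)
  # axis-aligned segment crosses four voxels
  vox <- rasterize_streamline(segment_sl(c(0.5, 0.5, 0.5), c(3.5, 0.5, 0.5)),
                              grid)
  expect_setequal(apply(vox, 1, paste, collapse = ","),
                  c("0,0,0", "1,0,0", "2,0,0", "3,0,0"))
  # degenerate polyline of two identical vertices occupies one voxel
  vox <- rasterize_streamline(rbind(c(2.2, 2.2, 2.2), c(2.2, 2.2, 2.2)), grid)
  expect_equal(vox, cbind(x = 2, y = 2, z = 2))
  # diagonal segment contains the three diagonal voxels
  vox <- rasterize_streamline(segment_sl(c(0.5, 0.5, 0.5), c(2.5, 2.5, 2.5)),
                              grid)
  keys <- apply(vox, 1, paste, collapse = ",")
  expect_true(all(c("0,0,0", "1,1,1", "2,2,2") %in% keys))
})

test_that("virtual lesioning removes exactly the transected streamlines", {
  grid <- c(8, 8, 8)
  sls <- streamline_set(list(
    segment_sl(c(0.5, 0.5, 0.5), c(3.5, 0.5, 0.5)),  # crosses (1,0,0)
    segment_sl(c(0.5, 4.5, 0.5), c(3.5, 4.5, 0.5)),
    segment_sl(c(0.5, 6.5, 6.5), c(3.5, 6.5, 6.5))
  ), "toy")
  m <- lesion_mask(matrix(c(1, 0, 0), 1), grid_shape = grid)
  out <- apply_virtual_lesion(sls, m)
  expect_length(out, 2)
  expect_identical(out$streamlines, sls$streamlines[2:3])
  # empty mask is a no-op; full mask deletes everything
  empty <- lesion_mask(matrix(integer(0), ncol = 3), grid_shape = grid)
  expect_identical(apply_virtual_lesion(sls, empty)$streamlines,
                   sls$streamlines)
  vol <- array(TRUE, grid)
  expect_length(apply_virtual_lesion(sls, lesion_mask(vol)), 0)
  # grid mismatch is an error
  bad <- lesion_mask(matrix(c(1, 0, 0), 1), grid_shape = c(4, 4, 4))
  expect_error(apply_virtual_lesion(sls, bad), "different grids")
})

test_that("endpoint assignment uses containment then radial search", {
  parc <- tiny_parcellation()
  # both endpoints inside labelled voxels
  expect_equal(assign_endpoints(segment_sl(c(1.5, 1.5, 1.5), c(5.5, 1.5, 1.5)),
                                parc),
               c(1, 3))
  # background voxel adjacent to a label is rescued within the radius
  lab <- array(0L, dim = c(8, 8, 8))
  lab[2:8, 1:4, ] <- 1L
  lab[2:8, 5:8, ] <- 2L
  p2 <- parcellation(lab)
  expect_equal(assign_endpoints(segment_sl(c(0.5, 2.5, 2.5), c(4.5, 6.5, 2.5)),
                                p2, radius = 1),
               c(1, 2))
  # no label within the radius -> unassignable
  lab2 <- array(0L, dim = c(8, 8, 8))
  lab2[5:8, 1:4, ] <- 1L
  lab2[5:8, 5:8, ] <- 2L
  p3 <- parcellation(lab2)
  expect_null(assign_endpoints(segment_sl(c(0.5, 0.5, 0.5), c(7.5, 7.5, 7.5)),
                               p3, radius = 2))
})

test_that("connectome weights are volume-normalized pair counts", {
  lab <- array(0L, dim = c(8, 8, 8))
  lab[1:4, 1:2, 1] <- 1L                 # region 1: 8 voxels
  lab[1:4, 3:8, 1] <- 2L                 # region 2: 24 voxels
  lab[5:8, 1:4, 1] <- 3L
  lab[5:8, 5:8, 1] <- 4L
  lab[, , 2:8] <- 0L
  lab[1, 1, 2] <- 1L; lab[1, 2, 2] <- 2L # pad so volumes stay positive
  p <- parcellation(lab)
  v1 <- p$region_volume[["1"]]; v2 <- p$region_volume[["2"]]
  sls <- replicate(4, segment_sl(c(0.5, 0.5, 0.5), c(0.5, 5.5, 0.5)),
                   simplify = FALSE)
  cn <- build_connectome(streamline_set(sls, "t"), p)
  expect_equal(cn$weights[1, 2], 4 / (v1 + v2))
  expect_equal(cn$weights[2, 1], cn$weights[1, 2])
  expect_equal(cn$n_streamlines_used, 4L)
  # streamline with both endpoints in one region contributes nothing
  self_sl <- streamline_set(list(segment_sl(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5))), "s")
  cn2 <- build_connectome(self_sl, p)
  expect_true(all(cn2$weights == 0))
  expect_equal(cn2$n_excluded, 1L)
  # empty set gives the zero matrix
  cn3 <- build_connectome(streamline_set(list(), "e"), p)
  expect_true(all(cn3$weights == 0))
})

test_that("indexed fast path reproduces the direct construction", {
  ph <- small_phantom(seed = 3)
  s <- ph$healthy[[1]]
  ix <- index_streamline_set(s, ph$parc)
  m <- generate_lesion(ph$parc, 0.15, centre_bias = "random", seed = 11)
  direct <- build_connectome(apply_virtual_lesion(s, m), ph$parc)
  fast <- lesioned_connectome(ix, m)
  expect_equal(fast$weights, direct$weights)
  expect_equal(fast$n_streamlines_used, direct$n_streamlines_used)
  healthy_direct <- build_connectome(s, ph$parc)
  expect_equal(lesioned_connectome(ix)$weights, healthy_direct$weights)
})

test_that("lesion invariants hold on randomized fixtures", {
  # spot-check of monotonicity, idempotence, conservation (the exhaustive
  # 200-fixture sweep lives in the acceptance suite)
  grid <- c(10, 10, 10)
  set.seed(99)
  parc_lab <- array(0L, dim = grid)
  parc_lab[1:5, , ] <- 1L
  parc_lab[6:10, , ] <- 2L
  p <- parcellation(parc_lab)
  for (rep in 1:25) {
    sls <- streamline_set(lapply(1:20, function(i) {
      a <- runif(3, 0.2, 9.8); b <- runif(3, 0.2, 9.8)
      segment_sl(a, b, n = 4)
    }), "r")
    vox_a <- matrix(sample(0:9, 3 * 15, replace = TRUE), ncol = 3)
    extra <- matrix(sample(0:9, 3 * 10, replace = TRUE), ncol = 3)
    m_a <- lesion_mask(vox_a, grid_shape = grid)
    m_b <- lesion_mask(rbind(vox_a, extra), grid_shape = grid)  # superset
    surv_a <- apply_virtual_lesion(sls, m_a)
    surv_b <- apply_virtual_lesion(sls, m_b)
    # monotonicity of survival and of connectome weights
    expect_true(all(vapply(surv_b$streamlines, function(x) {
      any(vapply(surv_a$streamlines, identical, logical(1), x))
    }, logical(1))))
    ca <- build_connectome(surv_a, p)$weights
    cb <- build_connectome(surv_b, p)$weights
    expect_true(all(cb <= ca + 1e-12))
    # idempotence
    expect_identical(apply_virtual_lesion(surv_a, m_a)$streamlines,
                     surv_a$streamlines)
    # conservation
    cn <- build_connectome(surv_a, p)
    expect_equal(cn$n_streamlines_used + cn$n_excluded,
                 length(surv_a$streamlines))
  }
})

test_that("connectome is invariant to streamline order", {
  ph <- small_phantom(seed = 5)
  s <- ph$healthy[[2]]
  perm <- sample(length(s$streamlines))
  shuffled <- streamline_set(s$streamlines[perm], s$subject_id)
  expect_equal(build_connectome(shuffled, ph$parc)$weights,
               build_connectome(s, ph$parc)$weights)
})
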