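test_that("Gaussian prefilter preserves constants and local mass", {
  const <- image_stack(array(7, c(8, 8, 8)))
  sm <- smooth_stack(const, 0.75)
  expect_equal(as.numeric(sm), rep(7, 512), tolerance = 1e-12)

  imp <- array(0, c(15, 15, 15))
  imp[8, 8, 8] <- 1
  sm2 <- smooth_stack(image_stack(imp), 0.75)
  expect_lt(sm2[8, 8, 8], 1)
  expect_equal(sum(sm2), 1, tolerance = 1e-9)  # kernel mass, interior impulse
})

test_that("separable smoothing equals dense 3D convolution", {
  set.seed(5)
  arr <- array(runif(6 * 7 * 8), c(6, 7, 8))
  mine <- smooth_stack(image_stack(arr), c(0.6, 0.8, 1.0))
  ref <- brute_gauss3d(arr, c(0.6, 0.8, 1.0))
  expect_equal(as.numeric(mine), as.numeric(ref), tolerance = 1e-10)
})

test_that("Li threshold separates modes and matches independent oracles", {
  expect_gt(li_threshold(c(rep(0, 100), rep(10, 100))), 0)
  expect_lt(li_threshold(c(rep(0, 100), rep(10, 100))), 10)
  expect_error(li_threshold(rep(3, 50)), "constant")

  vals <- li_fixture()
  thr <- li_threshold(vals)
  # frozen reference from scikit-image threshold_li on this exact fixture
  expect_equal(thr, 13.781162188466705, tolerance = 1e-9)
  # same binarization as direct minimization of the cross-entropy criterion
  scan <- brute_li_scan(vals)
  expect_identical(vals > thr, vals > scan)
})

test_that("network segmentation counts tube voxels and fragments", {
  set.seed(21)
  cell <- make_cell(50)
  net <- make_network(cell, 0.08, 0.175, seed = NULL)
  # sharp render: noise only (SNR ~ 10), no optical blur
  img <- render_cell(net, NULL, psf_sigma_um = c(0.02, 0.02, 0.02), seed = NULL)
  seg <- segment_network(img$mito, cell$mask)
  expect_equal(seg$volume_voxels, sum(net$mask), tolerance = 0.1)
  expect_equal(seg$volume_um3, seg$volume_voxels * prod(voxel_size(img$mito)))
  expect_equal(seg$fragments, 1L)

  # two disjoint tubes are two fragments
  net3 <- make_network(cell, 0.08, 0.175, fragments = 2L, seed = 99)
  img3 <- render_cell(net3, NULL, psf_sigma_um = c(0.02, 0.02, 0.02), seed = 99)
  seg3 <- segment_network(img3$mito, cell$mask)
  expect_equal(seg3$fragments, 2L)

  # an all-dark (constant) stack yields an empty mask with a warning
  dark <- image_stack(array(5, c(6, 6, 6)))
  expect_warning(s0 <- segment_network(dark), "constant")
  expect_equal(s0$volume_voxels, 0L)
  expect_equal(s0$fragments, 0L)
})

test_that("median normalization is exact, idempotent, and invertible", {
  set.seed(3)
  st <- image_stack(array(rlnorm(4 * 8 * 8, 1, 0.5), c(4, 8, 8)))
  mask <- array(runif(256) < 0.4, c(4, 8, 8))
  nz <- normalize_by_median(st, mask)
  expect_equal(median(nz[mask]), 1)
  expect_equal(as.numeric(normalize_by_median(nz, mask)), as.numeric(nz))
  expect_equal(as.numeric(nz) * median(st[mask]), as.numeric(st))
  expect_error(normalize_by_median(st, array(FALSE, c(4, 8, 8))), "empty")
})

test_that("local maxima detection equals the brute-force neighborhood scan", {
  set.seed(7)
  for (rep in 1:5) {
    st <- random_stack(c(16, 16, 16))
    mine <- detect_local_maxima(st)
    ref <- brute_local_maxima(unclass(st))
    expect_equal(nrow(mine), nrow(ref))
    key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
    expect_identical(key(as.matrix(mine[, c("z", "y", "x")])), key(ref))
  }
})

test_that("isolated spots are found exactly once each", {
  arr <- array(0, c(12, 24, 24))
  spots <- rbind(c(6, 6, 6), c(6, 18, 18))
  for (i in 1:2) {
    arr <- mitoscale:::.add_spot(arr, spots[i, ] * c(0.35, 0.1, 0.1), 10,
                                 c(0.3, 0.15, 0.15), c(0.35, 0.1, 0.1))
  }
  pk <- detect_local_maxima(image_stack(arr + 1e-9))
  # background plateau aside, the two brightest maxima are at the true spots
  top2 <- pk[1:2, ]
  expect_setequal(paste(top2$z, top2$y, top2$x),
                  paste(spots[, 1], spots[, 2], spots[, 3]))
})

test_that("resolution spheroid reproduces the Rayleigh radius", {
  sph <- resolution_spheroid(na = 1.4, lambda_nm = 509, rz_um = 1)
  expect_equal(round(sph$r_xy, 3), 0.222)
  expect_equal(sph$r_z, 1)
  expect_equal(resolution_spheroid(0.61, 1000, 1)$r_xy, 1.0)
  expect_error(resolution_spheroid(1.4, 0, 1), "positive")
})

test_that("deduplication keeps the brighter of conflicting peaks", {
  vox <- c(0.35, 0.1, 0.1)
  sph <- resolution_spheroid()
  # 0.10 um lateral separation: inside each other's spheroid, brighter wins
  pk <- data.frame(z = c(5, 5), y = c(10, 11), x = c(10, 10),
                   intensity = c(10, 8))
  kept <- dedup_peaks(pk, sph, vox)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$intensity, 10)
  # 0.50 um apart laterally (> 0.222): both kept
  pk2 <- data.frame(z = c(5, 5), y = c(10, 15), x = c(10, 10),
                    intensity = c(10, 8))
  expect_equal(nrow(dedup_peaks(pk2, sph, vox)), 2L)
  # pure axial offset (one z-plane, 0.35 um) inside the 1-um axial radius
  pk3 <- data.frame(z = c(5, 6), y = c(10, 10), x = c(10, 10),
                    intensity = c(8, 10))
  kept3 <- dedup_peaks(pk3, sph, vox)
  expect_equal(nrow(kept3), 1L)
  expect_equal(kept3$intensity, 10)
})

test_that("dedup output never contains a mutually conflicting pair", {
  set.seed(13)
  vox <- c(0.35, 0.1, 0.1)
  sph <- resolution_spheroid()
  for (rep in 1:5) {
    pk <- data.frame(z = sample(1:10, 40, TRUE), y = sample(1:40, 40, TRUE),
                     x = sample(1:40, 40, TRUE), intensity = runif(40))
    kept <- dedup_peaks(pk, sph, vox)
    if (nrow(kept) >= 2L) {
      um <- cbind(z = kept$z * vox[1], y = kept$y * vox[2], x = kept$x * vox[3])
      for (i in seq_len(nrow(kept) - 1L)) for (j in (i + 1L):nrow(kept)) {
        d2 <- ((um[i, "x"] - um[j, "x"])^2 + (um[i, "y"] - um[j, "y"])^2) /
          sph$r_xy^2 + (um[i, "z"] - um[j, "z"])^2 / sph$r_z^2
        expect_gt(d2, 1)
      }
    }
  }
})

test_that("Welch filter keeps bright nucleoids and drops mito-only peaks", {
  set.seed(31)
  d <- c(10, 30, 30)
  vox <- c(0.35, 0.1, 0.1)
  mask <- array(TRUE, d)
  # mito channel: flat normalized signal around 1
  mito <- image_stack(array(rnorm(prod(d), 1, 0.05), d), vox)
  # nucleoid channel: background 1 plus one strong spot at (5, 10, 10)
  nuc <- array(rnorm(prod(d), 1, 0.05), d)
  nuc <- mitoscale:::.add_spot(nuc, c(5, 10, 10) * vox, 5,
                               c(0.3, 0.12, 0.12), vox)
  nuc <- image_stack(nuc, vox)
  sph <- resolution_spheroid()
  cfg <- pipeline_config()
  pk <- data.frame(z = c(5, 5), y = c(10, 25), x = c(10, 25),
                   intensity = c(6, 1))
  out <- iterative_welch_filter(pk, nuc, mito, mask, sph, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$y, 10)
  expect_equal(attr(out, "rejected")$y, 25)

  # identical channels: nothing survives
  out2 <- iterative_welch_filter(pk, mito, mito, mask, sph, cfg)
  expect_equal(nrow(out2), 0L)

  # nucleoid signal below mito signal: negative t, discarded
  dim_nuc <- image_stack(unclass(mito) * 0.5, vox)
  out3 <- iterative_welch_filter(pk[1, ], dim_nuc, mito, mask, sph, cfg)
  expect_equal(nrow(out3), 0L)
})

test_that("peak count is non-increasing across the filtering cascade", {
  img <- make_synthetic_cell_image(volume_fl = 45, n_nucleoids = 14, seed = 77)
  cfg <- pipeline_config()
  nuc_s <- smooth_stack(img$nucleoid, cfg$sigma)
  mito_s <- smooth_stack(img$mito, cfg$sigma)
  seg <- segment_network(mito_s, img$cell_mask)
  mito_n <- normalize_by_median(mito_s, seg$mask)
  sph <- resolution_spheroid()
  cand <- detect_local_maxima(nuc_s, img$cell_mask)
  s5 <- filter_peaks_by_intensity(cand, nuc_s, img$cell_mask)
  s6 <- dedup_peaks(s5, sph, voxel_size(img$nucleoid))
  s7 <- iterative_welch_filter(s6, nuc_s, mito_n, seg$mask, sph, cfg)
  expect_lte(nrow(s5), nrow(cand))
  expect_lte(nrow(s6), nrow(s5))
  expect_lte(nrow(s7), nrow(s6))
  expect_lte(attr(s7, "iterations"), max(nrow(s6), 1L))
})

test_that("analyze_cell recovers well-separated planted nucleoids", {
  img <- make_synthetic_cell_image(volume_fl = 50, n_nucleoids = 12, seed = 5)
  res <- analyze_cell(img$nucleoid, img$mito, img$cell_mask)
  expect_equal(res$nucleoid_count, 12L)
  m <- match_peaks(img$truth$nucleoids_um, res$peaks[res$peaks$accepted, ],
                   voxel_size(img$nucleoid))
  expect_equal(m$tp, 12L)
  expect_equal(m$fp, 0L)
  expect_true(all(res$peaks$rejection_stage[!res$peaks$accepted] %in%
                    c("intensity", "dedup", "welch", "no_network")))
})

test_that("a cell without nucleoid spots keeps its network volume and sheds
           nearly all candidate peaks", {
  set.seed(15)
  cell <- make_cell(40)
  net <- make_network(cell, 0.08, 0.175, seed = NULL)
  img <- render_cell(net, NULL, seed = NULL)  # rho0-like: bleed-through only
  res <- suppressWarnings(analyze_cell(img$nucleoid, img$mito, cell$mask))
  expect_gt(res$network_volume_voxels, 0L)
  # the filter cascade rejects the overwhelming majority of spurious maxima;
  # a small residual survives the Welch stage on spot-free channels (see the
  # methods vignette on the normalization asymmetry)
  expect_lte(res$nucleoid_count, 0.1 * nrow(res$peaks))
  expect_error(analyze_cell(img$nucleoid, img$mito,
                            array(FALSE, dim(img$nucleoid))), "empty")
})
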