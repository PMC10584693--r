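#' Noise model for rendered microscopy stacks
#'
#' Shot noise is modelled by scaling the noise-free intensity to expected
#' photon counts, drawing Poisson counts, and scaling back; camera read
#' noise is additive Gaussian; a constant background offset is added before
#' the shot noise (real detectors see background photons too).
#'
#' @param photon_scale Photons per intensity unit (>= 0; 0 disables shot
#'   noise).
#' @param read_sd Additive Gaussian read-noise s.d. (>= 0).
#' @param offset Constant background offset (>= 0).
#' @return A `noise_model` object.
#' @export
noise_model <- function(photon_scale = 50, read_sd = 1, offset = 10) {
  stopifnot(photon_scale >= 0, read_sd >= 0, offset >= 0)
  structure(list(photon_scale = photon_scale, read_sd = read_sd,
                 offset = offset), class = "noise_model")
}

.apply_noise <- function(clean, noise) {
  out <- clean + noise$offset
  if (noise$photon_scale > 0) {
    out <- stats::rpois(length(out), lambda = out * noise$photon_scale) /
      noise$photon_scale
  }
  if (noise$read_sd > 0) {
    out <- out + stats::rnorm(length(out), sd = noise$read_sd)
  }
  array(out, dim(clean))
}

#' Ellipsoidal cell mask of a target volume
#'
#' Voxelizes a prolate ellipsoid (long axis along x, axis ratio 1.2 by
#' default) whose analytic volume equals the target; the voxelized volume is
#' required to land within 5% of the target. 1 fL = 1 um^3.
#'
#' @param volume_fl Target cell volume in fL (> 0, at least one voxel).
#' @param vox_size Voxel edge lengths (z, y, x) in um.
#' @param axis_ratio Long-to-short semi-axis ratio.
#' @param margin_um Empty margin around the cell, um.
#' @return List: `mask` (logical 3D array, dim (z, y, x)),
#'   `volume_fl` (achieved), `voxel_size`.
#' @export
make_cell <- function(volume_fl, vox_size = c(0.35, 0.1, 0.1),
                      axis_ratio = 1.2, margin_um = 0.6) {
  vox_size <- as.numeric(vox_size)
  stopifnot(length(vox_size) == 3L, all(vox_size > 0), axis_ratio >= 1)
  vv <- prod(vox_size)
  if (!is.finite(volume_fl) || volume_fl <= 0 || volume_fl < vv) {
    stop("make_cell: volume_fl must exceed one voxel volume")
  }
  b <- (3 * volume_fl / (4 * pi * axis_ratio))^(1 / 3)  # short semi-axis, um
  ax <- axis_ratio * b
  ext <- c(2 * b, 2 * b, 2 * ax) + 2 * margin_um        # (z, y, x) um
  d <- pmax(ceiling(ext / vox_size), 3L)
  ctr <- (d + 1) / 2 * vox_size
  zc <- (seq_len(d[1]) * vox_size[1] - ctr[1]) / b
  yc <- (seq_len(d[2]) * vox_size[2] - ctr[2]) / b
  xc <- (seq_len(d[3]) * vox_size[3] - ctr[3]) / ax
  mask <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`) <= 1
  achieved <- sum(mask) * vv
  if (abs(achieved - volume_fl) / volume_fl > 0.05) {
    stop("make_cell: voxelized volume misses the target by > 5%; ",
         "use finer voxels for this volume")
  }
  list(mask = mask, volume_fl = achieved, voxel_size = vox_size)
}

# voxel-offset ball of physical radius r_um under anisotropic voxel size
.sphere_offsets <- function(r_um, vox_size) {
  r <- pmax(floor(r_um / vox_size), 0L)
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz * vox_size[1])^2 + (g$dy * vox_size[2])^2 +
    (g$dx * vox_size[3])^2 <= r_um^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Tubular mitochondrial network inside a cell mask
#'
#' Grows the network as persistent random walks confined to the cell mask,
#' painting a tube of the given radius along each walk until the network
#' occupies the target fraction of the cell volume. A single walk yields one
#' connected component by construction; `fragments > 1` partitions the cell
#' into disjoint z-slabs (separated by more than the tube diameter) and
#' grows one walk per slab, so the component count is exact.
#'
#' @param cell A [make_cell()] result.
#' @param volume_fraction Target network fraction of cell volume (0, 0.5).
#' @param tube_radius_um Tube radius, um.
#' @param fragments Number of connected components (>= 1).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param step_um Centerline step length, um.
#' @return List: `mask` (logical array), `centerline_um` (matrix with
#'   columns z, y, x in um), `volume_fl`, `fragments`.
#' @export
make_network <- function(cell, volume_fraction = 0.08, tube_radius_um = 0.175,
                         fragments = 1L, seed = NULL, step_um = 0.2) {
  stopifnot(is.list(cell), !is.null(cell$mask))
  if (!is.null(seed)) set.seed(seed)
  if (volume_fraction <= 0 || volume_fraction >= 0.5) {
    stop("make_network: volume_fraction must be in (0, 0.5)")
  }
  vox_size <- cell$voxel_size
  d <- dim(cell$mask)
  ext_um <- d * vox_size
  if (2 * tube_radius_um >= min(ext_um) / 2) {
    stop("make_network: tube radius infeasible for this cell size")
  }
  vv <- prod(vox_size)
  target_total <- volume_fraction * sum(cell$mask)
  off <- .sphere_offsets(tube_radius_um, vox_size)
  net <- array(FALSE, d)
  centerline <- list()

  # z-slab partition when several components are requested; gap wide enough
  # that 26-connected dilated tubes cannot touch across slabs
  gap_z <- ceiling(2 * tube_radius_um / vox_size[1]) + 2L
  slab_ids <- if (fragments > 1L) {
    zs <- which(apply(cell$mask, 1, any))
    span <- length(zs)
    if (span < fragments * 3L + (fragments - 1L) * gap_z) {
      stop("make_network: too many fragments for this cell size")
    }
    width <- (span - (fragments - 1L) * gap_z) %/% fragments
    lapply(seq_len(fragments), function(f) {
      lo <- zs[1] + (f - 1L) * (width + gap_z)
      lo:(lo + width - 1L)
    })
  } else {
    list(seq_len(d[1]))
  }

  paint <- function(vox, allowed) {
    zz <- off[, 1] + vox[1]; yy <- off[, 2] + vox[2]; xx <- off[, 3] + vox[3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    idx <- cbind(zz[ok], yy[ok], xx[ok])
    idx <- idx[allowed[idx] & !net[idx], , drop = FALSE]
    if (nrow(idx) > 0L) net[idx] <<- TRUE
    nrow(idx)
  }

  for (f in seq_len(fragments)) {
    allowed <- array(FALSE, d)
    allowed[slab_ids[[f]], , ] <- TRUE
    allowed <- allowed & cell$mask
    if (!any(allowed)) stop("make_network: empty slab")
    target_f <- target_total / fragments
    start_idx <- which(allowed)
    start <- arrayInd(start_idx[sample.int(length(start_idx), 1L)], d)
    p <- as.numeric(start) * vox_size
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    trail <- list(p)
    painted <- paint(round(p / vox_size), allowed)
    guard <- 0L
    while (painted < target_f && guard < 200000L) {
      guard <- guard + 1L
      moved <- FALSE
      for (try in 1:25) {
        nd <- dir + 0.5 * stats::rnorm(3)
        nd <- nd / sqrt(sum(nd^2))
        p2 <- p + step_um * nd
        v2 <- round(p2 / vox_size)
        if (all(v2 >= 1) && all(v2 <= d) && allowed[v2[1], v2[2], v2[3]]) {
          p <- p2; dir <- nd; moved <- TRUE
          break
        }
      }
      if (!moved) {  # stuck at the membrane: branch from an earlier point
        p <- trail[[sample.int(length(trail), 1L)]]
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        next
      }
      trail[[length(trail) + 1L]] <- p
      painted <- painted + paint(round(p / vox_size), allowed)
    }
    if (painted < 0.9 * target_f) {
      stop("make_network: could not reach the target network volume")
    }
    centerline[[f]] <- do.call(rbind, trail)
  }

  cl <- do.call(rbind, centerline)
  colnames(cl) <- c("z", "y", "x")
  achieved <- sum(net)
  if (abs(achieved - target_total) / target_total > 0.10) {
    stop("make_network: network volume misses the target by > 10%")
  }
  list(mask = net, centerline_um = cl, volume_fl = achieved * vv,
       fragments = as.integer(fragments))
}

#' Place nucleoids on the network centerline
#'
#' Samples exactly `count` centerline points with pairwise separation at
#' least `min_separation_um`, by rejection with bounded restarts. By default
#' the separation is Euclidean. Because the optical resolution is strongly
#' anisotropic (the deduplication spheroid has a 1-um axial radius against a
#' 0.222-um lateral one), an axial exclusion radius `min_axial_um` can be
#' given: a pair is then admissible when it lies outside the exclusion
#' spheroid, i.e. `(d_xy / min_separation_um)^2 + (d_z / min_axial_um)^2 >= 1`,
#' which guarantees that planted spots stay mutually resolvable.
#'
#' @param centerline_um Matrix of centerline coordinates (columns z, y, x,
#'   um), e.g. from [make_network()].
#' @param count Number of nucleoids (>= 0).
#' @param min_separation_um Minimum pairwise separation (lateral radius of
#'   the exclusion spheroid when `min_axial_um` is given), um.
#' @param min_axial_um Optional axial exclusion radius, um; `NULL` for the
#'   isotropic Euclidean rule.
#' @param seed RNG seed (`NULL` = current state).
#' @param max_restarts Bounded retries before declaring the packing
#'   infeasible.
#' @return Matrix (count x 3) of coordinates in um, columns z, y, x.
#' @export
place_nucleoids <- function(centerline_um, count, min_separation_um = 0.5,
                            min_axial_um = NULL, seed = NULL,
                            max_restarts = 50L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.matrix(centerline_um), ncol(centerline_um) == 3L, count >= 0)
  out <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
  if (count == 0L) return(out)
  n <- nrow(centerline_um)
  if (n == 0L) stop("place_nucleoids: empty centerline")
  admissible <- function(have, cand) {
    dz <- have[, 1] - cand[1]
    dxy2 <- (have[, 2] - cand[2])^2 + (have[, 3] - cand[3])^2
    if (is.null(min_axial_um)) {
      all(dxy2 + dz^2 >= min_separation_um^2)
    } else {
      all(dxy2 / min_separation_um^2 + dz^2 / min_axial_um^2 >= 1)
    }
  }
  for (restart in seq_len(max_restarts)) {
    sel <- matrix(NA_real_, count, 3)
    got <- 0L
    for (draw in seq_len(200L * count)) {
      cand <- centerline_um[sample.int(n, 1L), ]
      if (got > 0L &&
          !admissible(sel[seq_len(got), , drop = FALSE], cand)) next
      got <- got + 1L
      sel[got, ] <- cand
      if (got == count) {
        colnames(sel) <- c("z", "y", "x")
        return(sel)
      }
    }
  }
  stop("place_nucleoids: packing ", count, " points at separation ",
       min_separation_um, " um is infeasible on this network")
}

# add an anisotropic Gaussian spot (sigma in um) analytically; equivalent to
# a point source convolved with the PSF
.add_spot <- function(arr, centre_um, amplitude, sigma_um, vox_size) {
  d <- dim(arr)
  r <- ceiling(4 * sigma_um / vox_size)
  c_vox <- centre_um / vox_size
  lo <- pmax(floor(c_vox - r), 1)
  hi <- pmin(ceiling(c_vox + r), d)
  if (any(lo > hi)) return(arr)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- exp(-0.5 * ((zi * vox_size[1] - centre_um[1]) / sigma_um[1])^2)
  gy <- exp(-0.5 * ((yi * vox_size[2] - centre_um[2]) / sigma_um[2])^2)
  gx <- exp(-0.5 * ((xi * vox_size[3] - centre_um[3]) / sigma_um[3])^2)
  arr[zi, yi, xi] <- arr[zi, yi, xi] +
    amplitude * (outer(outer(gz, gy), gx))
  arr
}

#' Render a two-channel stack from network + nucleoid ground truth
#'
#' The mitochondrial channel is the network mask scaled to `mito_amplitude`
#' and blurred by the PSF. The nucleoid channel is a fraction (`leak`) of
#' that blurred mitochondrial signal -- the matrix marker bleeds into the
#' nucleoid detection band and nucleoid-free network must not count as
#' nucleoids -- plus a diffraction-limited Gaussian spot of amplitude
#' `spot_amplitude` at each true coordinate. Both channels then receive
#' offset, shot noise, and read noise from the [noise_model()].
#'
#' @param network A [make_network()] result.
#' @param nucleoids_um Matrix of true nucleoid coordinates (um), possibly
#'   empty.
#' @param vox_size Voxel size (z, y, x), um.
#' @param psf_sigma_um PSF sigma (z, y, x), um.
#' @param spot_amplitude Peak intensity of one nucleoid above local
#'   background.
#' @param mito_amplitude In-network intensity of the mitochondrial channel.
#' @param leak Fraction of the mitochondrial signal bleeding into the
#'   nucleoid channel.
#' @param noise A [noise_model()].
#' @param seed RNG seed (`NULL` = current state).
#' @return List: `nucleoid`, `mito` ([image_stack()]s) and `truth`
#'   (coordinates, count, network mask/volume, seed, parameters).
#' @export
render_cell <- function(network, nucleoids_um, vox_size = c(0.35, 0.1, 0.1),
                        psf_sigma_um = c(0.5, 0.09, 0.09),
                        spot_amplitude = 30, mito_amplitude = 12, leak = 0.3,
                        noise = noise_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(psf_sigma_um > 0), spot_amplitude > 0, mito_amplitude > 0,
            inherits(noise, "noise_model"))
  vox_size <- as.numeric(vox_size)
  d <- dim(network$mask)
  sigma_vox <- psf_sigma_um / vox_size
  mito_clean <- array(cpp_gaussian_blur_3d(
    as.numeric(network$mask) * mito_amplitude, d, sigma_vox), d)
  nuc_clean <- leak * mito_clean
  if (!is.null(nucleoids_um) && nrow(nucleoids_um) > 0L) {
    for (i in seq_len(nrow(nucleoids_um))) {
      nuc_clean <- .add_spot(nuc_clean, nucleoids_um[i, ], spot_amplitude,
                             psf_sigma_um, vox_size)
    }
  }
  truth <- list(nucleoids_um = nucleoids_um,
                count = if (is.null(nucleoids_um)) 0L else nrow(nucleoids_um),
                network_mask = network$mask,
                network_volume_voxels = sum(network$mask),
                network_volume_fl = sum(network$mask) * prod(vox_size),
                seed = seed,
                params = list(psf_sigma_um = psf_sigma_um,
                              spot_amplitude = spot_amplitude,
                              mito_amplitude = mito_amplitude, leak = leak,
                              noise = noise))
  list(nucleoid = image_stack(.apply_noise(nuc_clean, noise), vox_size),
       mito = image_stack(.apply_noise(mito_clean, noise), vox_size),
       truth = truth)
}

#' One-call synthetic cell image with ground truth
#'
#' Builds a cell mask, grows a network, places nucleoids, and renders the
#' two channels. Convenience wrapper used for end-to-end validation of the
#' counting pipeline.
#'
#' @param volume_fl Cell volume, fL.
#' @param n_nucleoids Number of planted nucleoids.
#' @param seed RNG seed (drives every random stage).
#' @param min_separation_um Minimum lateral nucleoid separation (default
#'   0.5 um, beyond twice the 0.222-um lateral resolution radius).
#' @param min_axial_um Axial exclusion radius (default 2.2 um, beyond twice
#'   the 1-um axial deduplication radius), so planted spots remain mutually
#'   resolvable under the anisotropic optics.
#' @param fragments Network components.
#' @param ... Passed to [render_cell()].
#' @param vox_size,volume_fraction,tube_radius_um Geometry parameters.
#' @return List: `nucleoid`, `mito`, `cell_mask`, `truth`.
#' @export
make_synthetic_cell_image <- function(volume_fl = 50, n_nucleoids = 15,
                                      seed = 1, vox_size = c(0.35, 0.1, 0.1),
                                      volume_fraction = 0.08,
                                      tube_radius_um = 0.175,
                                      min_separation_um = 0.5,
                                      min_axial_um = 2.2,
                                      fragments = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  cell <- make_cell(volume_fl, vox_size)
  net <- make_network(cell, volume_fraction, tube_radius_um,
                      fragments = fragments, seed = NULL)
  pts <- place_nucleoids(net$centerline_um, n_nucleoids,
                         min_separation_um, min_axial_um, seed = NULL)
  img <- render_cell(net, pts, vox_size, seed = NULL, ...)
  img$cell_mask <- cell$mask
  img$truth$cell_volume_fl <- cell$volume_fl
  img$truth$seed <- seed
  img
}

#' Match detected peaks against ground-truth coordinates
#'
#' Greedy nearest matching: each true coordinate is matched to the closest
#' unmatched detection within `tol_um` (Euclidean, um). Reports precision
#' (matched / detected) and recall (matched / true).
#'
#' @param truth_um Matrix of true coordinates (z, y, x in um).
#' @param peaks Detected peak `data.frame` (voxel coordinates).
#' @param vox_size Voxel size (z, y, x), um.
#' @param tol_um Match radius, um.
#' @return List: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
match_peaks <- function(truth_um, peaks, vox_size, tol_um = 0.5) {
  det <- if (nrow(peaks) > 0L) {
    cbind(peaks$z * vox_size[1], peaks$y * vox_size[2], peaks$x * vox_size[3])
  } else matrix(numeric(0), 0, 3)
  nt <- if (is.null(truth_um)) 0L else nrow(truth_um)
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  for (i in seq_len(nt)) {
    if (nrow(det) == 0L) break
    dd <- sqrt(rowSums((det - matrix(truth_um[i, ], nrow(det), 3,
                                     byrow = TRUE))^2))
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) == 1L && dd[j] <= tol_um) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(det) - tp
  fn <- nt - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (nrow(det) > 0L) tp / nrow(det) else NA_real_,
       recall = if (nt > 0L) tp / nt else NA_real_)
}

#' Simulate a qPCR experiment from known copy numbers
#'
#' Inverts the quantification calculus: per-gene template concentrations are
#' derived from the true mtDNA copies per cell and the budding-index nuclear
#' genome count, converted to Cq through per-gene standard curves, and
#' jittered with Gaussian Cq noise. A matching standard-dilution series
#' (1e-4 to 1 pg/uL) and population table are emitted alongside the truth.
#'
#' @param mt_per_cell True mtDNA copies per cell, one per sample.
#' @param volumes_fl Mean cell volumes, fL.
#' @param budding_index %buds per sample (0-100).
#' @param ploidy `"haploid"` or `"diploid"` (recycled).
#' @param cq_noise_sd Gaussian Cq noise s.d. (cycles), applied to plate and
#'   standards wells alike.
#' @param replicates Technical replicates per well.
#' @param ndna_conc_pg_per_ul Nuclear template concentration per sample
#'   (recycled); mitochondrial templates scale with the true copy ratio.
#' @param curves Optional named list of `standard_curve`s per gene; defaults
#'   to near-ideal chemistry with gene-specific intercepts.
#' @param seed RNG seed.
#' @return List: `plate`, `standards`, `populations` (data.frames in the
#'   [quantify_plate()] dialects) and `truth`.
#' @export
simulate_qpcr <- function(mt_per_cell, volumes_fl, budding_index,
                          ploidy = "haploid", cq_noise_sd = 0.1,
                          replicates = 3L, ndna_conc_pg_per_ul = 0.01,
                          curves = NULL, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  ns <- length(mt_per_cell)
  stopifnot(length(volumes_fl) == ns, length(budding_index) == ns)
  ploidy <- rep_len(ploidy, ns)
  ndna_conc <- rep_len(ndna_conc_pg_per_ul, ns)
  genes <- names(default_gene_roles())
  if (is.null(curves)) {
    slopes <- c(ACT1 = -3.32, MIP1 = -3.41, MRX6 = -3.25,
                COX2 = -3.36, COX3 = -3.30)
    intercepts <- c(ACT1 = 15.2, MIP1 = 16.0, MRX6 = 15.6,
                    COX2 = 14.8, COX3 = 15.0)
    curves <- lapply(genes, function(g) {
      structure(list(gene = g, slope = slopes[[g]], intercept = intercepts[[g]],
                     efficiency = 10^(-1 / slopes[[g]]) - 1,
                     slope_se = NA_real_, intercept_se = NA_real_,
                     r_squared = 1),
                class = "standard_curve")
    })
    names(curves) <- genes
  }

  # the dilution series is measured with the same replication and noise as
  # the samples; all wells enter one least-squares fit per gene
  std_conc <- rep(10^seq(-4, 0), each = replicates)
  standards <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, concentration_pg_per_ul = std_conc,
               cq = concentration_to_cq(std_conc, curves[[g]]) +
                 stats::rnorm(length(std_conc), sd = cq_noise_sd))
  }))

  samples <- sprintf("s%02d", seq_len(ns))
  npc <- vapply(seq_len(ns), function(i) {
    ndna_per_cell(budding_index[i], ploidy[i])
  }, numeric(1))
  mt_ratio <- mt_per_cell / npc

  plate <- do.call(rbind, lapply(seq_len(ns), function(i) {
    do.call(rbind, lapply(genes, function(g) {
      conc <- if (default_gene_roles()[[g]] == "nuclear") {
        ndna_conc[i]
      } else {
        ndna_conc[i] * mt_ratio[i]
      }
      data.frame(sample = samples[i], gene = g,
                 replicate = seq_len(replicates),
                 cq = concentration_to_cq(conc, curves[[g]]) +
                   stats::rnorm(replicates, sd = cq_noise_sd))
    }))
  }))

  populations <- data.frame(sample = samples, mean_volume_fl = volumes_fl,
                            budding_index_pct = budding_index, ploidy = ploidy)
  list(plate = plate, standards = standards, populations = populations,
       truth = list(mt_per_cell = stats::setNames(mt_per_cell, samples),
                    mt_per_ndna = stats::setNames(mt_ratio, samples),
                    ndna_per_cell = stats::setNames(npc, samples),
                    curves = curves, seed = seed))
}

#' Simulate a cell population obeying a linear copy-number--volume law
#'
#' Draws cell volumes from a lognormal distribution, sets mtDNA copies to
#' `copies_per_fl * volume` and nucleoid counts to
#' `copies / copies_per_nucleoid`, each optionally jittered with
#' multiplicative Gaussian observation noise.
#'
#' @param n_cells Number of cells (>= 1).
#' @param mean_volume_fl Mean cell volume, fL.
#' @param cv_volume Coefficient of variation of the volume distribution.
#' @param copies_per_fl Scaling slope `c` in copies = c * V.
#' @param copies_per_nucleoid Planted copies-per-nucleoid ratio (default 2).
#' @param obs_noise_cv Fractional observation noise on copies and nucleoid
#'   counts (0 = noise-free).
#' @param seed RNG seed.
#' @return `data.frame` (`volume_fl`, `copies`, `nucleoids`) with attribute
#'   `truth` recording the generating parameters.
#' @export
simulate_population <- function(n_cells = 200, mean_volume_fl = 60,
                                cv_volume = 0.3, copies_per_fl = 1,
                                copies_per_nucleoid = 2, obs_noise_cv = 0,
                                seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cells >= 1, mean_volume_fl > 0, copies_per_fl > 0,
            copies_per_nucleoid > 0, obs_noise_cv >= 0)
  sdlog <- sqrt(log(1 + cv_volume^2))
  meanlog <- log(mean_volume_fl) - sdlog^2 / 2
  v <- stats::rlnorm(n_cells, meanlog, sdlog)
  copies <- copies_per_fl * v
  nucleoids <- copies / copies_per_nucleoid
  if (obs_noise_cv > 0) {
    copies <- copies * (1 + stats::rnorm(n_cells, sd = obs_noise_cv))
    nucleoids <- nucleoids * (1 + stats::rnorm(n_cells, sd = obs_noise_cv))
    copies <- pmax(copies, 0)
    nucleoids <- pmax(nucleoids, 0)
  }
  out <- data.frame(volume_fl = v, copies = copies, nucleoids = nucleoids)
  attr(out, "truth") <- list(copies_per_fl = copies_per_fl,
                             copies_per_nucleoid = copies_per_nucleoid,
                             mean_volume_fl = mean_volume_fl,
                             cv_volume = cv_volume,
                             obs_noise_cv = obs_noise_cv, seed = seed)
  out
}
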