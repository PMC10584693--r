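#' 3D image stack with physical voxel size
#'
#' A thin container for a confocal z-stack: a numeric 3D array with dimension
#' order (z, y, x) plus the anisotropic voxel edge lengths in micrometres.
#' The default voxel size matches a confocal acquisition with 0.35-um z
#' increments and 0.1-um lateral sampling.
#'
#' @param voxels Numeric 3D array, dimension order (z, y, x).
#' @param voxel_size Numeric length-3, (z, y, x) edge lengths in um, all > 0.
#' @return An `image_stack` object (the array with a `voxel_size` attribute).
#' @export
image_stack <- function(voxels, voxel_size = c(0.35, 0.1, 0.1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    stop("image_stack: voxels must be a non-empty 3D array")
  }
  if (!all(is.finite(voxels))) stop("image_stack: intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("image_stack: voxel_size must be three positive lengths (z, y, x) in um")
  }
  structure(voxels, voxel_size = voxel_size, class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size")
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @export
voxel_size <- function(x) attr(x, "voxel_size")

#' Volume of one voxel in femtolitres (um^3)
#' @param x An `image_stack` or a length-3 voxel size in um.
#' @return Scalar voxel volume in um^3 (1 um^3 = 1 fL).
#' @export
voxel_volume_um3 <- function(x) {
  vs <- if (inherits(x, "image_stack")) attr(x, "voxel_size") else as.numeric(x)
  prod(vs)
}

#' Configuration of the nucleoid-counting pipeline
#'
#' Defaults reproduce the analysis settings of the counting routine: a small
#' Gaussian prefilter (sigma 0.75 voxel), a resolution spheroid from a 1.4-NA
#' objective at the 509-nm mNeon emission with a 1-um axial radius, and a
#' Welch-test cut-off of p = 0.025 with discard when the t statistic is not
#' positive.
#'
#' @param sigma Gaussian prefilter sigma, voxels (> 0).
#' @param na Objective numerical aperture.
#' @param lambda_nm Emission wavelength, nm.
#' @param rz_um Axial radius of the deduplication spheroid, um.
#' @param p_threshold Welch-test p-value cut-off (0 < p < 1).
#' @param max_iter Cap on Welch-filter iterations.
#' @param p_side `"two.sided"` (default) or `"greater"`: sidedness of the
#'   Welch p-value. The discard rule is always `p > p_threshold || t <= 0`;
#'   the one-sided reading halves the p-value for positive t.
#' @param min_welch_voxels Minimum in-network voxels per nucleoid for the
#'   Welch test; smaller samples discard the peak (default 3).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sigma = 0.75, na = 1.4, lambda_nm = 509,
                            rz_um = 1, p_threshold = 0.025, max_iter = 50L,
                            p_side = c("two.sided", "greater"),
                            min_welch_voxels = 3L) {
  p_side <- match.arg(p_side)
  stopifnot(sigma > 0, na > 0, lambda_nm > 0, rz_um > 0,
            p_threshold > 0, p_threshold < 1, max_iter >= 1,
            min_welch_voxels >= 2)
  structure(list(sigma = sigma, na = na, lambda_nm = lambda_nm, rz_um = rz_um,
                 p_threshold = p_threshold, max_iter = as.integer(max_iter),
                 p_side = p_side,
                 min_welch_voxels = as.integer(min_welch_voxels)),
            class = "pipeline_config")
}

#' Resolution-limited spheroid
#'
#' The lateral radius is the Rayleigh resolution `0.61 * lambda / NA`
#' (converted to um); the axial radius is supplied directly (the axial
#' resolution of a confocal stack is dominated by the z-sampling and optics,
#' and is set to 1 um by default). With NA 1.4 and lambda 509 nm the lateral
#' radius is 0.222 um.
#'
#' @param na Numerical aperture (> 0).
#' @param lambda_nm Emission wavelength in nm (> 0).
#' @param rz_um Axial radius in um (> 0).
#' @return List of class `resolution_spheroid` with `r_xy` and `r_z` (um).
#' @export
resolution_spheroid <- function(na = 1.4, lambda_nm = 509, rz_um = 1) {
  if (!all(is.finite(c(na, lambda_nm, rz_um))) || na <= 0 || lambda_nm <= 0 ||
      rz_um <= 0) {
    stop("resolution_spheroid: na, lambda_nm and rz_um must be positive")
  }
  structure(list(r_xy = 0.61 * lambda_nm / na / 1000, r_z = rz_um),
            class = "resolution_spheroid")
}

#' Gaussian prefilter
#'
#' Separable 3D Gaussian convolution with replicate-edge padding (a constant
#' stack is therefore mapped to itself, and total intensity is conserved up
#' to boundary effects).
#'
#' @param stack An [image_stack()].
#' @param sigma Kernel sigma in voxels; either a scalar (isotropic in voxel
#'   units) or length-3 (z, y, x).
#' @return Smoothed `image_stack` of the same shape.
#' @export
smooth_stack <- function(stack, sigma = 0.75) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (any(sigma <= 0)) stop("smooth_stack: sigma must be > 0")
  out <- cpp_gaussian_blur_3d(as.numeric(stack), dim(stack), as.numeric(sigma))
  image_stack(array(out, dim(stack)), attr(stack, "voxel_size"))
}

#' Li minimum-cross-entropy threshold
#'
#' Fixed point of Li & Tam's iteration: after shifting the sample so its
#' minimum is zero, repeat
#' `t <- (mean_back - mean_fore) / (log(mean_back) - log(mean_fore))`
#' where `mean_back`/`mean_fore` are the means below/above the current
#' threshold, starting from the sample mean, until the change is below
#' `tol` (default: half the smallest gap between distinct values). The
#' returned threshold is shifted back to the original scale and lies strictly
#' between the sample minimum and maximum.
#'
#' @param values Numeric sample of intensities with at least two distinct
#'   finite values.
#' @param tol Convergence tolerance on the threshold; `NULL` for the default.
#' @param max_iter Iteration cap.
#' @return Scalar threshold.
#' @export
li_threshold <- function(values, tol = NULL, max_iter = 200L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("li_threshold: need at least 2 finite values")
  vmin <- min(values)
  vmax <- max(values)
  if (vmax == vmin) stop("li_threshold: constant sample, threshold undefined")
  v <- values - vmin
  if (is.null(tol)) {
    u <- sort(unique(v))
    tol <- min(diff(u)) / 2
  }
  t_next <- mean(v)
  t_curr <- -2 * tol - 1
  iter <- 0L
  while (abs(t_next - t_curr) > tol && iter < max_iter) {
    t_curr <- t_next
    fore <- v > t_curr
    mean_fore <- mean(v[fore])
    mean_back <- mean(v[!fore])
    if (!is.finite(mean_fore) || mean_back == 0) break
    t_next <- (mean_back - mean_fore) / (log(mean_back) - log(mean_fore))
    iter <- iter + 1L
  }
  t_next + vmin
}

#' Segment the mitochondrial network
#'
#' Applies Li thresholding to the (smoothed) mitochondrial-matrix channel;
#' voxels at or above the threshold are classified as network. When a cell
#' mask is given, both the threshold sample and the segmentation are
#' restricted to in-cell voxels. A constant channel yields an empty mask with
#' a warning (no threshold is defined), so cells without resolvable network
#' signal degrade gracefully rather than erroring.
#'
#' @param mito Smoothed mitochondrial-channel [image_stack()].
#' @param cell_mask Optional logical array, same shape; `NULL` = whole grid.
#' @return List of class `network_segmentation`: `mask` (logical array),
#'   `volume_voxels`, `volume_um3`, `fragments` (26-connected components),
#'   `threshold`.
#' @export
segment_network <- function(mito, cell_mask = NULL) {
  stopifnot(inherits(mito, "image_stack"))
  d <- dim(mito)
  if (is.null(cell_mask)) cell_mask <- array(TRUE, d)
  stopifnot(identical(dim(cell_mask), d))
  vals <- mito[cell_mask]
  empty <- function(thr) {
    structure(list(mask = array(FALSE, d), volume_voxels = 0L, volume_um3 = 0,
                   fragments = 0L, threshold = thr),
              class = "network_segmentation")
  }
  if (length(vals) == 0L) stop("segment_network: empty cell mask")
  if (diff(range(vals)) == 0) {
    warning("segment_network: constant channel, returning empty mask")
    return(empty(NA_real_))
  }
  thr <- li_threshold(vals)
  mask <- (mito >= thr) & cell_mask
  nv <- sum(mask)
  if (nv == 0L) return(empty(thr))
  lab <- cpp_label_components_3d(as.logical(mask), d)
  structure(list(mask = array(as.logical(mask), d),
                 volume_voxels = as.integer(nv),
                 volume_um3 = nv * voxel_volume_um3(mito),
                 fragments = attr(lab, "n_components"),
                 threshold = thr),
            class = "network_segmentation")
}

#' @export
print.network_segmentation <- function(x, ...) {
  cat(sprintf("network_segmentation: %d voxels (%.3g um^3), %d fragment(s)\n",
              x$volume_voxels, x$volume_um3, x$fragments))
  invisible(x)
}

#' Normalize a channel by the in-network median
#'
#' Divides every voxel by the median intensity over the network mask, so the
#' in-network median of the result is exactly 1. This puts the mitochondrial
#' signal of different cells on a common scale before the Welch comparison.
#'
#' @param stack An [image_stack()].
#' @param mask Logical array (network mask), same shape, non-empty.
#' @return Normalized `image_stack`.
#' @export
normalize_by_median <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"), identical(dim(mask), dim(stack)))
  if (!any(mask)) stop("normalize_by_median: empty mask")
  med <- stats::median(stack[mask])
  if (med == 0) stop("normalize_by_median: in-mask median is zero")
  image_stack(unclass(stack) / med, attr(stack, "voxel_size"))
}

#' Detect 3D local intensity maxima
#'
#' A voxel is a peak when its intensity is at least that of each of its 26
#' neighbors (grid borders compare only in-grid neighbors). Plateaus of equal
#' value are reduced to their lexicographically smallest (z, y, x) voxel.
#' When a mask is given, out-of-mask voxels are excluded both as peaks and as
#' competitors (they are treated as -Inf).
#'
#' @param stack An [image_stack()] (typically smoothed).
#' @param mask Optional logical array restricting the search.
#' @return A `data.frame` with columns `z`, `y`, `x` (1-based voxel indices)
#'   and `intensity`, ordered by decreasing intensity.
#' @export
detect_local_maxima <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  v <- unclass(stack)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(stack)))
    v[!mask] <- -Inf
  }
  pk <- cpp_local_maxima_3d(as.numeric(v), dim(stack))
  pk <- pk[order(-pk$intensity, pk$z, pk$y, pk$x), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Discard peaks below the Li intensity threshold
#'
#' The threshold is computed from the (smoothed) nucleoid channel, restricted
#' to the cell mask when one is given; peaks with intensity at or above the
#' threshold are retained.
#'
#' @param peaks Peak `data.frame` from [detect_local_maxima()].
#' @param nucleoid Smoothed nucleoid-channel [image_stack()].
#' @param cell_mask Optional logical array for the threshold sample.
#' @return Filtered peak `data.frame`.
#' @export
filter_peaks_by_intensity <- function(peaks, nucleoid, cell_mask = NULL) {
  stopifnot(inherits(nucleoid, "image_stack"))
  vals <- if (is.null(cell_mask)) as.numeric(nucleoid) else nucleoid[cell_mask]
  thr <- li_threshold(vals)
  out <- peaks[peaks$intensity >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# physical (um) coordinates of voxel centres for a peak table
.peak_um <- function(peaks, vs) {
  cbind(z = peaks$z * vs[1], y = peaks$y * vs[2], x = peaks$x * vs[3])
}

# squared spheroid metric between two um-coordinate matrices/vectors:
# ((dx^2 + dy^2)/r_xy^2) + dz^2/r_z^2; "inside" means <= 1
.spheroid_metric2 <- function(um, centre_um, sph) {
  ((um[, "x"] - centre_um[["x"]])^2 + (um[, "y"] - centre_um[["y"]])^2) / sph$r_xy^2 +
    (um[, "z"] - centre_um[["z"]])^2 / sph$r_z^2
}

#' Remove peaks closer than the optical resolution
#'
#' Greedy deduplication in descending intensity: a peak is accepted iff no
#' already-accepted peak lies within the resolution spheroid centred on it
#' (boundary inclusive), with physical distances computed from the
#' anisotropic voxel size. Ties in intensity are broken by lexicographic
#' (z, y, x) order, so the result is deterministic.
#'
#' @param peaks Peak `data.frame` (`z`, `y`, `x`, `intensity`).
#' @param sph A [resolution_spheroid()].
#' @param vox_size Length-3 voxel edge lengths (z, y, x) in um.
#' @return Accepted peaks, plus attribute `rejected` (the discarded rows).
#' @export
dedup_peaks <- function(peaks, sph, vox_size) {
  stopifnot(inherits(sph, "resolution_spheroid"), length(vox_size) == 3L)
  if (nrow(peaks) == 0L) {
    return(structure(peaks, rejected = peaks))
  }
  ord <- order(-peaks$intensity, peaks$z, peaks$y, peaks$x)
  peaks <- peaks[ord, , drop = FALSE]
  um <- .peak_um(peaks, as.numeric(vox_size))
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    acc <- which(keep)
    if (length(acc) == 0L) {
      keep[i] <- TRUE
      next
    }
    d2 <- .spheroid_metric2(um[acc, , drop = FALSE],
                            list(z = um[i, "z"], y = um[i, "y"], x = um[i, "x"]),
                            sph)
    keep[i] <- all(d2 > 1)
  }
  out <- peaks[keep, , drop = FALSE]
  rej <- peaks[!keep, , drop = FALSE]
  rownames(out) <- rownames(rej) <- NULL
  structure(out, rejected = rej)
}

#' Iterative Welch-test validation of nucleoid candidates
#'
#' A peak is a valid nucleoid only if its nucleoid-channel intensity is
#' significantly higher than the mitochondrial signal at the same voxels
#' (after normalization). Each pass (a) classifies in-network voxels as
#' inside a nucleoid iff they fall within the resolution spheroid of any
#' currently retained peak, (b) normalizes the nucleoid channel by the mean
#' over in-network voxels outside all nucleoids, (c) runs a Welch two-sample
#' t-test per peak of the normalized nucleoid intensities against the
#' median-normalized mitochondrial intensities over that peak's inside
#' voxels, discarding peaks with `p > p_threshold` or `t <= 0`, and (d)
#' repeats until the retained count stops changing (or `max_iter`). The
#' retained count is non-increasing across passes, so the loop terminates.
#'
#' @param peaks Peak `data.frame` after deduplication.
#' @param nucleoid Smoothed nucleoid-channel [image_stack()].
#' @param mito_norm Median-normalized mitochondrial [image_stack()].
#' @param network_mask Logical array: the segmented network.
#' @param sph A [resolution_spheroid()].
#' @param cfg A [pipeline_config()].
#' @return Retained peaks, plus attribute `rejected`; attribute `iterations`
#'   records the number of passes run.
#' @export
iterative_welch_filter <- function(peaks, nucleoid, mito_norm, network_mask,
                                   sph, cfg) {
  stopifnot(inherits(nucleoid, "image_stack"), inherits(mito_norm, "image_stack"),
            identical(dim(network_mask), dim(nucleoid)),
            inherits(sph, "resolution_spheroid"), inherits(cfg, "pipeline_config"))
  if (!any(network_mask)) stop("iterative_welch_filter: empty network mask")
  if (nrow(peaks) == 0L) {
    return(structure(peaks, rejected = peaks, iterations = 0L))
  }
  vs <- attr(nucleoid, "voxel_size")
  net_idx <- which(network_mask)
  d <- dim(nucleoid)
  coord <- arrayInd(net_idx, d)
  net_um <- cbind(z = coord[, 1] * vs[1], y = coord[, 2] * vs[2],
                  x = coord[, 3] * vs[3])
  nuc_net <- as.numeric(nucleoid)[net_idx]
  mito_net <- as.numeric(mito_norm)[net_idx]
  pk_um <- .peak_um(peaks, vs)

  # per-candidate in-network voxel sets are geometric, computed once
  inside_sets <- lapply(seq_len(nrow(peaks)), function(i) {
    which(.spheroid_metric2(net_um, list(z = pk_um[i, "z"], y = pk_um[i, "y"],
                                         x = pk_um[i, "x"]), sph) <= 1)
  })

  retained <- rep(TRUE, nrow(peaks))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    inside_any <- logical(length(net_idx))
    for (i in which(retained)) inside_any[inside_sets[[i]]] <- TRUE
    outside <- !inside_any
    if (!any(outside)) {
      stop("iterative_welch_filter: no in-network voxels outside nucleoids to normalize by")
    }
    norm_mean <- mean(nuc_net[outside])
    if (norm_mean <= 0) {
      stop("iterative_welch_filter: non-positive normalization mean")
    }
    nuc_norm <- nuc_net / norm_mean

    keep_now <- retained
    for (i in which(retained)) {
      vox <- inside_sets[[i]]
      if (length(vox) < cfg$min_welch_voxels) {
        warning("iterative_welch_filter: peak with < ", cfg$min_welch_voxels,
                " in-network voxels discarded")
        keep_now[i] <- FALSE
        next
      }
      tt <- tryCatch(stats::t.test(nuc_norm[vox], mito_net[vox],
                                   var.equal = FALSE),
                     error = function(e) NULL)
      if (is.null(tt)) {  # degenerate (constant) samples: no evidence, discard
        keep_now[i] <- FALSE
        next
      }
      tstat <- unname(tt$statistic)
      p <- tt$p.value
      if (cfg$p_side == "greater" && tstat > 0) p <- p / 2
      if (!is.finite(tstat) || tstat <= 0 || p > cfg$p_threshold) {
        keep_now[i] <- FALSE
      }
    }
    if (identical(keep_now, retained) || iterations >= cfg$max_iter) {
      retained <- keep_now
      break
    }
    retained <- keep_now
  }
  out <- peaks[retained, , drop = FALSE]
  rej <- peaks[!retained, , drop = FALSE]
  rownames(out) <- rownames(rej) <- NULL
  structure(out, rejected = rej, iterations = iterations)
}

#' Count nucleoids and measure the mitochondrial network of one cell
#'
#' Runs the full per-cell pipeline: Gaussian prefilter of both channels, Li
#' segmentation of the mitochondrial network (within the cell mask), median
#' normalization of the mitochondrial channel, 3D local-maxima detection in
#' the nucleoid channel, Li intensity filtering of the peaks, resolution-
#' spheroid deduplication, and the iterative Welch validation of the
#' survivors against the mitochondrial signal. A cell with no resolvable
#' network yields zero nucleoids and zero network volume rather than an
#' error.
#'
#' @param nucleoid Nucleoid-channel [image_stack()].
#' @param mito Mitochondrial-channel [image_stack()], same shape and voxel
#'   size.
#' @param cell_mask Logical array delimiting the cell; must be non-empty.
#' @param cfg A [pipeline_config()].
#' @return A list of class `cell_result`: `nucleoid_count`,
#'   `network_volume_voxels`, `network_volume_um3`, `fragments`,
#'   `peaks` (per-candidate table with `accepted` and `rejection_stage`
#'   in `none`/`intensity`/`dedup`/`welch`/`no_network`), and the
#'   intermediate `segmentation`.
#' @export
analyze_cell <- function(nucleoid, mito, cell_mask, cfg = pipeline_config()) {
  stopifnot(inherits(nucleoid, "image_stack"), inherits(mito, "image_stack"),
            identical(dim(nucleoid), dim(mito)),
            inherits(cfg, "pipeline_config"))
  stopifnot(identical(dim(cell_mask), dim(nucleoid)))
  if (!any(cell_mask)) stop("analyze_cell: empty cell mask")

  nuc_s <- smooth_stack(nucleoid, cfg$sigma)
  mito_s <- smooth_stack(mito, cfg$sigma)
  seg <- segment_network(mito_s, cell_mask)
  sph <- resolution_spheroid(cfg$na, cfg$lambda_nm, cfg$rz_um)
  vs <- attr(nucleoid, "voxel_size")

  stage_tbl <- function(kept, rejected_list) {
    tbl <- kept
    if (nrow(tbl) > 0L) {
      tbl$accepted <- TRUE
      tbl$rejection_stage <- "none"
    } else {
      tbl$accepted <- logical(0)
      tbl$rejection_stage <- character(0)
    }
    for (stage in names(rejected_list)) {
      r <- rejected_list[[stage]]
      if (nrow(r) > 0L) {
        r$accepted <- FALSE
        r$rejection_stage <- stage
        tbl <- rbind(tbl, r[, names(tbl), drop = FALSE])
      }
    }
    rownames(tbl) <- NULL
    tbl
  }

  candidates <- detect_local_maxima(nuc_s, cell_mask)

  if (seg$volume_voxels == 0L) {
    peaks_tbl <- stage_tbl(candidates[0, , drop = FALSE],
                           list(no_network = candidates))
    return(structure(list(nucleoid_count = 0L,
                          network_volume_voxels = 0L,
                          network_volume_um3 = 0,
                          fragments = 0L,
                          peaks = peaks_tbl,
                          segmentation = seg),
                     class = "cell_result"))
  }

  mito_norm <- normalize_by_median(mito_s, seg$mask)
  after_int <- filter_peaks_by_intensity(candidates, nuc_s, cell_mask)
  rej_int <- candidates[!do.call(paste, candidates[c("z", "y", "x")]) %in%
                          do.call(paste, after_int[c("z", "y", "x")]), , drop = FALSE]
  after_dedup <- dedup_peaks(after_int, sph, vs)
  rej_dedup <- attr(after_dedup, "rejected")
  final <- iterative_welch_filter(after_dedup, nuc_s, mito_norm, seg$mask,
                                  sph, cfg)
  rej_welch <- attr(final, "rejected")

  peaks_tbl <- stage_tbl(as.data.frame(final),
                         list(welch = rej_welch, dedup = rej_dedup,
                              intensity = rej_int))

  structure(list(nucleoid_count = nrow(final),
                 network_volume_voxels = seg$volume_voxels,
                 network_volume_um3 = seg$volume_um3,
                 fragments = seg$fragments,
                 peaks = peaks_tbl,
                 segmentation = seg),
            class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("cell_result: %d nucleoid(s); network %d voxels (%.3g um^3), %d fragment(s)\n",
              x$nucleoid_count, x$network_volume_voxels, x$network_volume_um3,
              x$fragments))
  invisible(x)
}
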