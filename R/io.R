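#' Read / write image stacks as multi-page TIFF
#'
#' Each z-slice is stored as one 32-bit float page in (y, x) orientation.
#' TIFF stores values in [0, 1], so intensities are divided by `scale` on
#' write and multiplied back on read; `write_stack_tiff()` returns the scale
#' it used so the round trip is exact to float precision.
#'
#' @param stack An [image_stack()].
#' @param path File path.
#' @param scale Intensity corresponding to 1.0 in the file; default the
#'   stack maximum (or 1 for an all-zero stack).
#' @return `write_stack_tiff()` invisibly returns `scale`;
#'   `read_stack_tiff()` returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("write_stack_tiff requires the 'tiff' package")
  }
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(scale)) {
    scale <- max(stack)
    if (scale <= 0) scale <- 1
  }
  pages <- lapply(seq_len(dim(stack)[1]), function(z) {
    unclass(stack)[z, , ] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_stack_tiff
#' @param voxel_size Voxel edge lengths (z, y, x) in um for the stack read
#'   back.
#' @export
read_stack_tiff <- function(path, voxel_size = c(0.35, 0.1, 0.1), scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("read_stack_tiff requires the 'tiff' package")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, d)
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * scale
  image_stack(arr, voxel_size)
}

#' Write per-cell results and per-peak tables as CSV
#'
#' @param results A list of `cell_result` objects (or a single one), named
#'   by cell id.
#' @param cells_csv,peaks_csv Output paths (`NULL` to skip one of them).
#' @return Invisibly, a list with the two assembled data.frames.
#' @export
write_cell_results <- function(results, cells_csv = NULL, peaks_csv = NULL) {
  if (inherits(results, "cell_result")) results <- list(cell1 = results)
  ids <- names(results)
  if (is.null(ids)) ids <- sprintf("cell%d", seq_along(results))
  cells <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(cell_id = ids[i], nucleoid_count = r$nucleoid_count,
               network_volume_voxels = r$network_volume_voxels,
               network_volume_um3 = r$network_volume_um3,
               fragments = r$fragments)
  }))
  peaks <- do.call(rbind, lapply(seq_along(results), function(i) {
    p <- results[[i]]$peaks
    if (nrow(p) == 0L) return(NULL)
    cbind(data.frame(cell_id = ids[i]), p)
  }))
  if (!is.null(cells_csv)) utils::write.csv(cells, cells_csv, row.names = FALSE)
  if (!is.null(peaks_csv) && !is.null(peaks)) {
    utils::write.csv(peaks, peaks_csv, row.names = FALSE)
  }
  invisible(list(cells = cells, peaks = peaks))
}
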