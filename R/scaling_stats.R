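#' Binned means with standard errors
#'
#' Groups `y` by bins of `x` and reports, per bin, the mean, standard error
#' (`sd / sqrt(count)`), and count, at the bin centre (midpoint of the
#' edges). Bins with fewer than `min_count` points are suppressed; bins with
#' a single point report `se = 0` and are flagged `se_defined = FALSE`.
#'
#' @param x Abscissa values (e.g. cell volume, fL).
#' @param y Ordinate values, same length.
#' @param edges Ascending bin boundaries (length >= 2). Default: equal-width
#'   bins between the 1st and 99th percentile of `x`.
#' @param n_bins Number of default bins when `edges` is `NULL`.
#' @param min_count Minimum points per reported bin (default 5; use 1 to keep
#'   all occupied bins).
#' @return `data.frame` of class `binned_series`: `center`, `mean`, `se`,
#'   `count`, `se_defined`.
#' @export
binned_means <- function(x, y, edges = NULL, n_bins = 8L, min_count = 5L) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(edges)) {
    lo <- stats::quantile(x, 0.01, names = FALSE)
    hi <- stats::quantile(x, 0.99, names = FALSE)
    if (hi <= lo) stop("binned_means: degenerate x range")
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  if (is.unsorted(edges, strictly = TRUE) || length(edges) < 2L) {
    stop("binned_means: edges must be strictly ascending, length >= 2")
  }
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= length(edges) - 1L
  rows <- lapply(seq_len(length(edges) - 1L), function(b) {
    yy <- y[inside & bin == b]
    n <- length(yy)
    if (n < min_count || n == 0L) return(NULL)
    s <- if (n > 1L) stats::sd(yy) / sqrt(n) else 0
    data.frame(center = (edges[b] + edges[b + 1L]) / 2,
               mean = mean(yy), se = s, count = n, se_defined = n > 1L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("binned_means: no bin reaches min_count")
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Ordinary least-squares line
#'
#' Linear fit of `y` on `x` (typically replicate means against volume),
#' returning estimates and their standard errors.
#'
#' @param x Abscissae (>= 2 distinct values).
#' @param y Ordinates, same length.
#' @return List of class `linear_fit`: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `r_squared`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L) stop("fit_linear: x is degenerate")
  fit <- stats::lm(y ~ x)
  # exact data fit perfectly; the perfect-fit warning is uninformative
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  # with 2 points the fit is exact and lm reports NaN standard errors
  se <- function(term) if (nrow(co) >= 2L && term %in% rownames(co))
    co[term, "Std. Error"] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[["x"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 slope_se = se("x"),
                 intercept_se = se("(Intercept)"),
                 r_squared = sm$r.squared),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear_fit: y = %.4g + %.4g x (R^2 = %.3f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Concentration ratio expected for a constant-amount species
#'
#' If a molecule is maintained at a constant amount per cell, its
#' concentration in big cells relative to small cells equals the inverse
#' volume ratio `v_small / v_big`. Used as the null expectation against
#' which measured big/small concentration ratios are compared.
#'
#' @param v_small Mean volume of the small population (> 0).
#' @param v_big Mean volume of the big population (> 0).
#' @return Expected big/small concentration ratio.
#' @export
constant_amount_ratio <- function(v_small, v_big) {
  if (any(!is.finite(c(v_small, v_big))) || any(c(v_small, v_big) <= 0)) {
    stop("constant_amount_ratio: volumes must be positive")
  }
  v_small / v_big
}

#' mtDNA copies per nucleoid across matched volume bins
#'
#' Bins the qPCR-derived copies per cell and the image-derived nucleoids per
#' cell on a shared volume axis and reports their per-bin ratio. Bins where
#' the mean nucleoid count is zero are flagged undefined (`NA` ratio) rather
#' than dropped.
#'
#' @param volume_copies,copies Volumes and copies per cell (qPCR side).
#' @param volume_nucleoids,nucleoids Volumes and nucleoid counts (imaging
#'   side).
#' @param edges Shared bin edges; default: equal-width bins over the overlap
#'   of the two volume ranges.
#' @param n_bins Number of default bins.
#' @param min_count Minimum points per bin on each side.
#' @return `data.frame`: `center`, `copies_mean`, `nucleoids_mean`, `ratio`,
#'   `defined`.
#' @export
mtdna_per_nucleoid <- function(volume_copies, copies, volume_nucleoids,
                               nucleoids, edges = NULL, n_bins = 5L,
                               min_count = 1L) {
  if (is.null(edges)) {
    lo <- max(min(volume_copies), min(volume_nucleoids))
    hi <- min(max(volume_copies), max(volume_nucleoids))
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
      stop("mtdna_per_nucleoid: volume ranges do not overlap")
    }
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  bc <- binned_means(volume_copies, copies, edges, min_count = min_count)
  bn <- binned_means(volume_nucleoids, nucleoids, edges, min_count = min_count)
  shared <- intersect(bc$center, bn$center)
  if (length(shared) == 0L) stop("mtdna_per_nucleoid: no shared occupied bin")
  bc <- bc[match(shared, bc$center), ]
  bn <- bn[match(shared, bn$center), ]
  ratio <- ifelse(bn$mean > 0, bc$mean / bn$mean, NA_real_)
  data.frame(center = shared, copies_mean = bc$mean,
             nucleoids_mean = bn$mean, ratio = ratio,
             defined = bn$mean > 0)
}

#' Background-subtract binned flow-cytometry signal
#'
#' For each scatter bin, subtracts the mean autofluorescence of a
#' non-fluorescent control from the mean signal of the fluorescent strain.
#' With measurements from two days, the point estimate is the mean of the
#' two background-corrected day signals and the error envelope runs from the
#' smaller day signal minus that day's standard error to the larger day
#' signal plus its standard error.
#'
#' @param sample_bins `data.frame` per day with columns `center`, `mean`,
#'   `se` (fluorescent strain); pass a list of one or two such frames.
#' @param control_bins Same structure for the autofluorescence control
#'   (matching `center`s per day).
#' @return `data.frame`: `center`, `signal` (day-mean corrected signal),
#'   `lower`, `upper` (envelope), `n_days`.
#' @export
flow_background_subtract <- function(sample_bins, control_bins) {
  if (is.data.frame(sample_bins)) sample_bins <- list(sample_bins)
  if (is.data.frame(control_bins)) control_bins <- list(control_bins)
  stopifnot(length(sample_bins) == length(control_bins),
            length(sample_bins) >= 1L, length(sample_bins) <= 2L)
  days <- lapply(seq_along(sample_bins), function(i) {
    s <- sample_bins[[i]]; ctl <- control_bins[[i]]
    stopifnot(all(c("center", "mean", "se") %in% names(s)),
              all(c("center", "mean") %in% names(ctl)))
    if (!isTRUE(all.equal(s$center, ctl$center))) {
      stop("flow_background_subtract: bin centres differ between strain and control")
    }
    data.frame(center = s$center, corrected = s$mean - ctl$mean, se = s$se)
  })
  centers <- days[[1]]$center
  for (d in days) {
    if (!isTRUE(all.equal(d$center, centers))) {
      stop("flow_background_subtract: bin centres differ between days")
    }
  }
  sig <- sapply(days, function(d) d$corrected)
  se <- sapply(days, function(d) d$se)
  if (is.null(dim(sig))) sig <- matrix(sig, ncol = length(days))
  if (is.null(dim(se))) se <- matrix(se, ncol = length(days))
  hi_day <- max.col(sig)
  lo_day <- max.col(-sig)
  n <- nrow(sig)
  data.frame(center = centers,
             signal = rowMeans(sig),
             lower = sig[cbind(seq_len(n), lo_day)] - se[cbind(seq_len(n), lo_day)],
             upper = sig[cbind(seq_len(n), hi_day)] + se[cbind(seq_len(n), hi_day)],
             n_days = length(days))
}

#' Two-sample comparison between strains
#'
#' Convenience wrapper applying a Shapiro-Wilk normality check (reported,
#' not enforced) and a two-tailed Welch two-sample t-test to replicate-level
#' values of two strains.
#'
#' @param x,y Replicate values of the two strains.
#' @return List: `p_value`, `t`, `shapiro_p_x`, `shapiro_p_y`.
#' @export
compare_strains <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  sw <- function(v) if (length(v) >= 3L) stats::shapiro.test(v)$p.value else NA_real_
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       shapiro_p_x = sw(x), shapiro_p_y = sw(y))
}
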