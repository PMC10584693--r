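#' Gene roles for mtDNA-per-nDNA quantification
#'
#' The quantification uses nuclear-genome amplicons (ACT1, MIP1, MRX6) and
#' mitochondrial-genome amplicons (COX2, COX3). In strains where MIP1 dosage
#' is manipulated, MIP1 is excluded from the nuclear pool.
#'
#' @param exclude Character vector of genes to drop (e.g. `"MIP1"`).
#' @return Named character vector mapping gene to `"nuclear"`/`"mito"`.
#' @export
default_gene_roles <- function(exclude = character()) {
  roles <- c(ACT1 = "nuclear", MIP1 = "nuclear", MRX6 = "nuclear",
             COX2 = "mito", COX3 = "mito")
  roles[!names(roles) %in% exclude]
}

#' Pool technical qPCR replicates
#'
#' Returns the mean Cq of the replicates. If their standard deviation exceeds
#' `sd_max` (default 0.5 cycles), the single replicate farthest from the
#' median is excluded and the criterion is retested; if the remaining
#' replicates still exceed `sd_max`, the well is flagged as failed
#' (`NA` with attribute `failed = TRUE`). With `iterate = TRUE` the
#' exclusion repeats (down to two replicates) instead of happening once.
#'
#' @param cqs Numeric replicate Cq values (>= 1).
#' @param sd_max Standard-deviation cut-off in cycles.
#' @param iterate Repeat the exclusion until the s.d. passes? Default FALSE
#'   (a single exclusion).
#' @return Mean Cq; `NA` with attribute `failed` when the well fails QC.
#'   Attribute `excluded` lists dropped replicate values.
#' @export
pool_technical_replicates <- function(cqs, sd_max = 0.5, iterate = FALSE) {
  cqs <- cqs[!is.na(cqs)]
  if (length(cqs) == 0L) {
    return(structure(NA_real_, failed = TRUE, excluded = numeric(0)))
  }
  stopifnot(all(is.finite(cqs)), all(cqs > 0))
  excluded <- numeric(0)
  repeat {
    if (length(cqs) == 1L || stats::sd(cqs) <= sd_max) {
      return(structure(mean(cqs), failed = FALSE, excluded = excluded))
    }
    if (length(cqs) == 2L) {
      return(structure(NA_real_, failed = TRUE, excluded = excluded))
    }
    drop <- which.max(abs(cqs - stats::median(cqs)))
    excluded <- c(excluded, cqs[drop])
    cqs <- cqs[-drop]
    if (!iterate) {
      if (stats::sd(cqs) <= sd_max || length(cqs) == 1L) {
        return(structure(mean(cqs), failed = FALSE, excluded = excluded))
      }
      return(structure(NA_real_, failed = TRUE, excluded = excluded))
    }
  }
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(template concentration) over a
#' dilution series of known input concentrations. The amplification
#' efficiency is `E = 10^(-1/slope) - 1`; ideal doubling chemistry gives a
#' slope of `-log2(10) = -3.3219` and `E = 1`.
#'
#' @param concentration Known template concentrations, pg/uL (> 0).
#' @param cq Measured Cq values, same length.
#' @param gene Optional gene label carried on the result.
#' @return A `standard_curve` object: `gene`, `slope`, `intercept` (Cq at
#'   1 pg/uL), `efficiency`, `slope_se`, `intercept_se`, `r_squared`.
#' @export
fit_standard_curve <- function(concentration, cq, gene = NA_character_) {
  stopifnot(length(concentration) == length(cq), length(cq) >= 2L)
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("fit_standard_curve: concentrations must be positive")
  }
  lc <- log10(concentration)
  if (length(unique(lc)) < 2L) {
    stop("fit_standard_curve: need at least 2 distinct concentrations")
  }
  fit <- stats::lm(cq ~ lc)
  # noise-free series fit exactly; the perfect-fit warning is uninformative
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope <- co["lc", "Estimate"]
  if (slope >= 0) {
    warning("fit_standard_curve: non-negative slope; more template should lower Cq")
  }
  structure(list(gene = gene,
                 slope = slope,
                 intercept = co["(Intercept)", "Estimate"],
                 efficiency = 10^(-1 / slope) - 1,
                 slope_se = co["lc", "Std. Error"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 r_squared = sm$r.squared),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve%s: Cq = %.4f + %.4f * log10(conc); efficiency %.3f\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$intercept, x$slope, x$efficiency))
  invisible(x)
}

#' Convert Cq to template concentration via a standard curve
#'
#' Inverts the calibration line: `conc = 10^((cq - intercept) / slope)`.
#' `concentration_to_cq()` is the forward map, used by the plate simulator.
#'
#' @param cq Cq value(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Concentration(s) in pg/uL.
#' @export
cq_to_concentration <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' @rdname cq_to_concentration
#' @param concentration Concentration(s) in pg/uL (> 0).
#' @export
concentration_to_cq <- function(concentration, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(concentration <= 0)) stop("concentration_to_cq: concentration must be > 0")
  curve$intercept + curve$slope * log10(concentration)
}

#' Pool per-gene concentrations into nuclear and mitochondrial means
#'
#' @param concentrations Named numeric vector of per-gene concentrations.
#' @param roles Named character vector (`"nuclear"`/`"mito"`), e.g.
#'   [default_gene_roles()]; genes absent from `roles` are ignored.
#' @return List with `ndna` and `mtdna` (arithmetic means over each group).
#' @export
pool_gene_groups <- function(concentrations, roles = default_gene_roles()) {
  stopifnot(!is.null(names(concentrations)), !is.null(names(roles)))
  use <- intersect(names(concentrations), names(roles))
  conc <- concentrations[use]
  conc <- conc[!is.na(conc)]
  nuc <- conc[names(conc) %in% names(roles)[roles == "nuclear"]]
  mito <- conc[names(conc) %in% names(roles)[roles == "mito"]]
  if (length(nuc) == 0L) stop("pool_gene_groups: no nuclear genes after exclusions")
  if (length(mito) == 0L) stop("pool_gene_groups: no mitochondrial genes after exclusions")
  list(ndna = mean(nuc), mtdna = mean(mito))
}

#' Average nuclear genome copies per cell from the budding index
#'
#' Budded cells have replicated their nuclear genome, so a population with
#' budding index %buds (percentage of budded cells, 0-100) carries on
#' average `(%buds * 2 + %no-buds * 1) / 100` nuclear genome copies per cell
#' if haploid, and `(%buds * 4 + %no-buds * 2) / 100` if diploid.
#'
#' @param budding_index %buds, on the 0-100 scale.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return Average nDNA copies per cell.
#' @export
ndna_per_cell <- function(budding_index, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (any(!is.finite(budding_index)) || any(budding_index < 0) ||
      any(budding_index > 100)) {
    stop("ndna_per_cell: budding_index must be within [0, 100]")
  }
  base <- if (ploidy == "haploid") c(2, 1) else c(4, 2)
  (budding_index * base[1] + (100 - budding_index) * base[2]) / 100
}

#' Population record
#'
#' @param sample Sample identifier.
#' @param mean_volume_fl Mean cell volume, fL (> 0).
#' @param budding_index %buds in [0, 100].
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return A `population_record` object.
#' @export
population_record <- function(sample, mean_volume_fl, budding_index,
                              ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.finite(mean_volume_fl), mean_volume_fl > 0,
            is.finite(budding_index), budding_index >= 0, budding_index <= 100)
  structure(list(sample = sample, mean_volume_fl = mean_volume_fl,
                 budding_index = budding_index, ploidy = ploidy),
            class = "population_record")
}

#' mtDNA copy number per cell and per fL
#'
#' Multiplies the mtDNA-per-nDNA ratio by the budding-index-derived average
#' nuclear genome copies per cell, and divides by mean cell volume for the
#' concentration.
#'
#' @param mt_per_ndna mtDNA copies per nuclear genome copy (>= 0).
#' @param pop A [population_record()].
#' @return List of class `copy_number_result`: `mt_per_ndna`,
#'   `ndna_per_cell`, `mt_per_cell`, `mt_per_fl`.
#' @export
copy_number <- function(mt_per_ndna, pop) {
  stopifnot(inherits(pop, "population_record"),
            is.finite(mt_per_ndna), mt_per_ndna >= 0)
  npc <- ndna_per_cell(pop$budding_index, pop$ploidy)
  mt_cell <- mt_per_ndna * npc
  structure(list(sample = pop$sample,
                 mt_per_ndna = mt_per_ndna,
                 ndna_per_cell = npc,
                 mt_per_cell = mt_cell,
                 mt_per_fl = mt_cell / pop$mean_volume_fl),
            class = "copy_number_result")
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat(sprintf("copy_number_result [%s]: %.3g mtDNA/nDNA, %.3g nDNA/cell, %.4g mtDNA/cell, %.3g mtDNA/fL\n",
              x$sample, x$mt_per_ndna, x$ndna_per_cell, x$mt_per_cell,
              x$mt_per_fl))
  invisible(x)
}

#' Normalize strain values to a reference strain
#'
#' Divides every value by the mean over the reference strain (e.g. wild
#' type), so the reference maps to 1.
#'
#' @param values Numeric vector of per-measurement values.
#' @param strain Character vector of strain ids, same length.
#' @param reference Reference strain id.
#' @return `values / mean(values[strain == reference])`.
#' @export
normalize_to_reference <- function(values, strain, reference) {
  stopifnot(length(values) == length(strain))
  ref <- values[strain == reference]
  ref <- ref[!is.na(ref)]
  if (length(ref) == 0L) stop("normalize_to_reference: reference strain missing")
  m <- mean(ref)
  if (m == 0) stop("normalize_to_reference: reference mean is zero")
  values / m
}

#' Quantify mtDNA copy numbers from plate, standards, and population tables
#'
#' End-to-end qPCR calculus: pools technical replicates per (sample, gene)
#' with the s.d. cut-off, fits one standard curve per gene, converts pooled
#' Cq values to concentrations, pools nuclear and mitochondrial gene groups,
#' and converts the mtDNA/nDNA ratio into copies per cell and per fL using
#' each sample's budding index, ploidy, and mean volume. Failed wells
#' propagate as `NA`, never as zero.
#'
#' @param plate `data.frame` with columns `sample`, `gene`, `replicate`, `cq`.
#' @param standards `data.frame` with columns `gene`,
#'   `concentration_pg_per_ul`, `cq`.
#' @param populations `data.frame` with columns `sample`, `mean_volume_fl`,
#'   `budding_index_pct`, `ploidy`.
#' @param roles Gene-role map, default [default_gene_roles()].
#' @param sd_max Replicate s.d. cut-off, default 0.5 cycles.
#' @return List with `results` (per-sample `data.frame`: `sample`,
#'   `mean_volume_fl`, `mt_per_ndna`, `ndna_per_cell`, `mt_per_cell`,
#'   `mt_per_fl`), `curves` (per-gene `standard_curve`s) and `qc`
#'   (per-well pooled Cq, failures, exclusions).
#' @export
quantify_plate <- function(plate, standards, populations,
                           roles = default_gene_roles(), sd_max = 0.5) {
  need <- function(df, cols, nm) {
    if (!all(cols %in% names(df))) {
      stop("quantify_plate: ", nm, " must have columns ",
           paste(cols, collapse = ", "))
    }
  }
  need(plate, c("sample", "gene", "replicate", "cq"), "plate")
  need(standards, c("gene", "concentration_pg_per_ul", "cq"), "standards")
  need(populations, c("sample", "mean_volume_fl", "budding_index_pct", "ploidy"),
       "populations")

  curves <- lapply(split(standards, standards$gene), function(s) {
    fit_standard_curve(s$concentration_pg_per_ul, s$cq, gene = s$gene[1])
  })

  wells <- split(plate, list(plate$sample, plate$gene), drop = TRUE)
  qc <- do.call(rbind, lapply(wells, function(w) {
    pooled <- pool_technical_replicates(w$cq, sd_max = sd_max)
    data.frame(sample = w$sample[1], gene = w$gene[1],
               cq_mean = as.numeric(pooled),
               failed = attr(pooled, "failed"),
               n_excluded = length(attr(pooled, "excluded")))
  }))
  rownames(qc) <- NULL

  results <- do.call(rbind, lapply(seq_len(nrow(populations)), function(i) {
    pop <- population_record(populations$sample[i],
                             populations$mean_volume_fl[i],
                             populations$budding_index_pct[i],
                             populations$ploidy[i])
    sub <- qc[qc$sample == pop$sample & !qc$failed & qc$gene %in% names(roles), ]
    conc <- vapply(seq_len(nrow(sub)), function(j) {
      cq_to_concentration(sub$cq_mean[j], curves[[sub$gene[j]]])
    }, numeric(1))
    names(conc) <- sub$gene
    pooled <- tryCatch(pool_gene_groups(conc, roles), error = function(e) NULL)
    if (is.null(pooled)) {
      return(data.frame(sample = pop$sample, mean_volume_fl = pop$mean_volume_fl,
                        mt_per_ndna = NA_real_, ndna_per_cell = NA_real_,
                        mt_per_cell = NA_real_, mt_per_fl = NA_real_))
    }
    res <- copy_number(pooled$mtdna / pooled$ndna, pop)
    data.frame(sample = pop$sample, mean_volume_fl = pop$mean_volume_fl,
               mt_per_ndna = res$mt_per_ndna, ndna_per_cell = res$ndna_per_cell,
               mt_per_cell = res$mt_per_cell, mt_per_fl = res$mt_per_fl)
  }))
  rownames(results) <- NULL
  list(results = results, curves = curves, qc = qc)
}
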