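#' Parameter set for the limiting-factor model of mtDNA homeostasis
#'
#' The model describes the concentration `n` of mitochondrial DNA in a growing
#' yeast cell as a balance of three processes: replication by the mtDNA
#' polymerase Mip1 (concentration `m`), degradation counteracted by the
#' packaging factor Abf2 (concentration `a`), and dilution by exponential
#' growth with population doubling time `T`:
#'
#' \deqn{dn/dt = k_R \frac{m}{K_1 + m/n} - k_D \frac{n}{K_2 + a/n} - \frac{n \ln 2}{T}}
#'
#' Replication saturates with the Mip1-per-mtDNA ratio (dissociation constant
#' `K1`); degradation is stoichiometrically inhibited by Abf2 bound to mtDNA
#' (saturation constant `K2`). All concentrations share one arbitrary unit and
#' all times another; the model makes relative, not absolute, predictions.
#'
#' @param kR Maximal replication rate constant (1/time).
#' @param kD Degradation rate constant (1/time).
#' @param K1 Mip1--mtDNA dissociation constant (concentration units).
#' @param K2 Degradation saturation constant (concentration units).
#' @param T Population doubling time (time units).
#' @param m Mip1 concentration.
#' @param a Abf2 concentration.
#'
#' @return An object of class `model_params` (a named list of the seven
#'   constants, all validated strictly positive).
#' @examples
#' p <- model_params(kR = 0.1, kD = 1, K1 = 5, K2 = 100, T = 150, m = 5, a = 100)
#' steady_state(p)
#' @export
model_params <- function(kR, kD, K1, K2, T, m, a) {
  p <- list(kR = kR, kD = kD, K1 = K1, K2 = K2, T = T, m = m, a = a)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model_params: '", nm, "' must be a single strictly positive number")
    }
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("mtDNA limiting-factor model parameters:\n")
  cat(sprintf("  kR = %g, kD = %g, K1 = %g, K2 = %g, T = %g, m = %g, a = %g\n",
              x$kR, x$kD, x$K1, x$K2, x$T, x$m, x$a))
  invisible(x)
}

#' Default wild-type parameter grid
#'
#' The four reference parameter sets used for gene-dosage predictions:
#' `m = 5`, `a = 100`, `T = 150`, `K1 = 5`, `K2 = 100`, with every combination
#' of `kR` in {0.01, 0.1} and `kD` in {1, 10}.
#'
#' @return A list of [model_params()] objects, named `kR<..>_kD<..>`.
#' @export
wild_type_grid <- function() {
  grid <- expand.grid(kR = c(0.01, 0.1), kD = c(1, 10))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    model_params(kR = grid$kR[i], kD = grid$kD[i],
                 K1 = 5, K2 = 100, T = 150, m = 5, a = 100)
  })
  names(out) <- sprintf("kR%g_kD%g", grid$kR, grid$kD)
  out
}

#' Net rate of change of the mtDNA concentration
#'
#' Evaluates the replication-degradation-dilution balance at concentration
#' `n`. At `n = 0` every term vanishes (the saturable terms by their limits,
#' dilution trivially), so 0 is always a fixed point.
#'
#' @param n mtDNA concentration (non-negative scalar or vector).
#' @param p A [model_params()] object.
#' @return `dn/dt`, same length as `n`.
#' @export
mtdna_rate <- function(n, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("mtdna_rate: n must be finite and non-negative")
  }
  out <- numeric(length(n))
  pos <- n > 0
  np <- n[pos]
  out[pos] <- p$kR * p$m / (p$K1 + p$m / np) -
    p$kD * np / (p$K2 + p$a / np) -
    np * log(2) / p$T
  out
}

#' Coefficients of the steady-state quadratic
#'
#' Setting `dn/dt = 0` and clearing denominators turns the balance into
#' `A n^2 + B n + C = 0` with
#' `A = K1 K2 ln2 + kD K1 T`,
#' `B = a K1 ln2 - K2 m kR T + K2 m ln2 + kD m T`,
#' `C = a m ln2 - a m kR T`.
#' `A` is always positive, and `C < 0` exactly when `kR T > ln 2`.
#'
#' @param p A [model_params()] object.
#' @return Named numeric vector `c(A =, B =, C =)`.
#' @export
steady_state_coefficients <- function(p) {
  stopifnot(inherits(p, "model_params"))
  L <- log(2)
  c(A = p$K1 * p$K2 * L + p$kD * p$K1 * p$T,
    B = p$a * p$K1 * L - p$K2 * p$m * p$kR * p$T + p$K2 * p$m * L + p$kD * p$m * p$T,
    C = p$a * p$m * L - p$a * p$m * p$kR * p$T)
}

#' Steady-state mtDNA concentration
#'
#' Solves the steady-state quadratic. A strictly positive root exists iff the
#' constant coefficient is negative, i.e. `kR * T > ln 2` (when `C >= 0` all
#' coefficients are non-negative and `n = 0` is the only non-negative fixed
#' point). When it exists the positive root is unique because the product of
#' the roots, `C/A`, is negative. The root is computed with the numerically
#' stable citardauq form.
#'
#' @param p A [model_params()] object.
#' @return A list of class `steady_state` with elements `n` (concentration,
#'   0 when no positive root exists) and `exists` (logical).
#' @export
steady_state <- function(p) {
  co <- steady_state_coefficients(p)
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]
  if (C >= 0) {
    return(structure(list(n = 0, exists = FALSE), class = "steady_state"))
  }
  disc <- B^2 - 4 * A * C
  # q-form avoids cancellation whichever sign B has
  q <- -(B + sign(B) * sqrt(disc)) / 2
  roots <- c(q / A, C / q)
  n <- roots[roots > 0][1]
  structure(list(n = n, exists = TRUE), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("steady-state mtDNA concentration n* = %g\n", x$n))
  } else {
    cat("no positive steady state (kR*T <= ln 2); n* = 0\n")
  }
  invisible(x)
}

#' Gene-dosage perturbation
#'
#' Multiplicative factors applied to the Mip1 (`fm`) and Abf2 (`fa`)
#' concentrations, e.g. `fm = 0.5` for a *MIP1* hemizygote, `fm = fa = 0.5`
#' for a double hemizygote, `fm = fa = 2` for double overexpression.
#'
#' @param fm Factor on `m` (> 0).
#' @param fa Factor on `a` (> 0).
#' @return A `dosage_perturbation` object.
#' @export
dosage_perturbation <- function(fm = 1, fa = 1) {
  stopifnot(is.numeric(fm), length(fm) == 1L, is.finite(fm), fm > 0,
            is.numeric(fa), length(fa) == 1L, is.finite(fa), fa > 0)
  structure(list(fm = fm, fa = fa), class = "dosage_perturbation")
}

#' Steady-state mtDNA of a perturbed strain relative to wild type
#'
#' Re-solves the steady state with `m * fm` and `a * fa` and divides by the
#' unperturbed steady state. When `fm == fa` the model family is homogeneous
#' (the balance has the form `n f(m/n) - n g(a/n) - n ln2/T`), so the ratio
#' equals the common factor exactly, independent of all other parameters.
#'
#' @param p Wild-type [model_params()]; must admit a positive steady state.
#' @param d A [dosage_perturbation()].
#' @return Dimensionless ratio (perturbed / wild type).
#' @export
relative_mtdna <- function(p, d) {
  stopifnot(inherits(p, "model_params"), inherits(d, "dosage_perturbation"))
  wt <- steady_state(p)
  if (!wt$exists) stop("relative_mtdna: wild-type steady state does not exist")
  pp <- model_params(kR = p$kR, kD = p$kD, K1 = p$K1, K2 = p$K2, T = p$T,
                     m = p$m * d$fm, a = p$a * d$fa)
  steady_state(pp)$n / wt$n
}

#' Integrate the mtDNA rate equation in time
#'
#' Numerical trajectory of `dn/dt` from an initial concentration, used as an
#' independent check on the quadratic steady-state solution: from any positive
#' start the trajectory approaches the positive root monotonically when one
#' exists, and decays to 0 otherwise.
#'
#' @param p A [model_params()] object.
#' @param n0 Initial concentration (>= 0).
#' @param t_end Integration horizon (> 0, model time units).
#' @param dt Output time step (> 0); the integrator itself is adaptive.
#' @return A data.frame with columns `time` and `n`.
#' @export
integrate_model <- function(p, n0, t_end, dt = t_end / 200) {
  stopifnot(inherits(p, "model_params"),
            is.numeric(n0), length(n0) == 1L, n0 >= 0,
            t_end > 0, dt > 0)
  rhs <- function(t, state, parms) {
    n <- max(state[[1L]], 0)  # clamp integrator excursions below 0
    list(mtdna_rate(n, p))
  }
  times <- unique(c(seq(0, t_end, by = dt), t_end))
  sol <- deSolve::ode(y = c(n = n0), times = times, func = rhs, parms = NULL,
                      atol = 1e-12, rtol = 1e-10)
  if (any(!is.finite(sol[, "n"]))) {
    stop("integrate_model: non-finite trajectory; try a smaller dt")
  }
  data.frame(time = sol[, "time"], n = pmax(sol[, "n"], 0))
}

#' Sweep dosage perturbations over a parameter grid
#'
#' @param p_grid A list of [model_params()] (e.g. [wild_type_grid()]).
#' @param perturbations A list of [dosage_perturbation()].
#' @return A data.frame with one row per (params, perturbation): columns
#'   `params_id`, `kR`, `kD`, `fm`, `fa`, `relative_mtdna`.
#' @export
sweep_dosage <- function(p_grid, perturbations) {
  stopifnot(is.list(p_grid), is.list(perturbations))
  if (length(p_grid) == 0L || length(perturbations) == 0L) {
    return(data.frame(params_id = character(), kR = numeric(), kD = numeric(),
                      fm = numeric(), fa = numeric(), relative_mtdna = numeric()))
  }
  ids <- names(p_grid)
  if (is.null(ids)) ids <- as.character(seq_along(p_grid))
  rows <- lapply(seq_along(p_grid), function(i) {
    p <- p_grid[[i]]
    do.call(rbind, lapply(perturbations, function(d) {
      data.frame(params_id = ids[i], kR = p$kR, kD = p$kD,
                 fm = d$fm, fa = d$fa,
                 relative_mtdna = relative_mtdna(p, d))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write model parameter sets as JSON
#'
#' JSON keys are the seven constant names (`kR`, `kD`, `K1`, `K2`, `T`, `m`,
#' `a`).
#'
#' @param path File path.
#' @return `read_model_params()` returns a [model_params()] object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, as.list(x[c("kR", "kD", "K1", "K2", "T", "m", "a")]))
}

#' @rdname read_model_params
#' @param p A [model_params()] object to write.
#' @export
write_model_params <- function(p, path) {
  stopifnot(inherits(p, "model_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
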