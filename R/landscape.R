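# Energy landscape over (A, R), constrained minimization and tension sweeps.
#
# At fixed R the total energy is quadratic in A:
#   E(A, R) = A * c1(R) + A^2 * gamma / (4 pi R^2),
# with c1(R) = (kappa_m/2)(2/R - 2/R_m)^2 + (kappa_c/2)(2/R - 2/R_c)^2 - a/A_c.
# That structure gives a closed-form inner minimization over A (the "profile")
# used by the default minimizer, and the boundary (A = 4 pi R^2) stationary
# radius in closed form.

.c1 <- function(R, p) {
  cm <- if (is.infinite(p$R_memb)) 0 else 2 / p$R_memb
  (p$kappa_memb / 2) * (2 / R - cm)^2 +
    (p$kappa_clath / 2) * (2 / R - 2 / p$R_clath)^2 - p$a / p$A_clath
}

# best energy over A in (0, 4 pi R^2] at fixed R, plus the minimizing A
.profile_at_R <- function(R, p) {
  cc <- .c1(R, p)
  Ab <- 4 * pi * R^2
  if (cc >= 0) return(list(E = 0, A = 0, branch = "empty"))
  Astar <- -2 * pi * R^2 * cc / p$gamma
  if (Astar <= Ab)
    list(E = -pi * R^2 * cc^2 / p$gamma, A = Astar, branch = "interior")
  else
    list(E = Ab * (cc + p$gamma), A = Ab, branch = "boundary")
}

#' Closed-form optimal radius on the closed-sphere boundary
#'
#' Along `A = 4*pi*R^2` the total energy is
#' `8*pi*kappa_memb + 4*pi*gamma*R^2 + 8*pi*kappa_clath*(1 - R/R_clath)^2 -
#'  4*pi*a*R^2/A_clath` (flat `R_memb`), whose stationary radius is
#' `R* = (4*kappa_clath/R_clath) / (2*gamma + 4*kappa_clath/R_clath^2 -
#'  2*a/A_clath)`. At default parameters `R* = 55.07` nm.
#'
#' @param p a [model_params()].
#' @return Radius in nm; `NA` if the boundary energy has no interior
#'   stationary point (denominator nonpositive, energy unbounded along the
#'   boundary).
#' @export
boundary_optimal_radius <- function(p = model_params()) {
  denom <- 2 * p$gamma + 4 * p$kappa_clath / p$R_clath^2 - 2 * p$a / p$A_clath
  if (denom <= 0) return(NA_real_)
  (4 * p$kappa_clath / p$R_clath) / denom
}

.is_unbounded <- function(p) {
  # large-R limit of the per-area density: if negative, E -> -Inf as the
  # interior profile minimum deepens with R^2
  cm <- if (is.infinite(p$R_memb)) 0 else 2 / p$R_memb
  dens_inf <- (p$kappa_memb / 2) * cm^2 +
    (p$kappa_clath / 2) * (2 / p$R_clath)^2 - p$a / p$A_clath
  dens_inf < 0
}

#' Minimize the CCP energy subject to A <= 4*pi*R^2
#'
#' Finds the lowest-energy spherical-cap state over area and radius of
#' curvature within the physically accessible region `A <= 4*pi*R^2` (the
#' closed-sphere locus). At the default parameters the minimum sits on the
#' boundary: a closed sphere of radius ~55 nm.
#'
#' @param p a [model_params()].
#' @param R_range search range for the radius (nm); default `c(5, 2000)`.
#' @param method `"profile"` (default) exploits the closed-form inner
#'   minimization over `A` at fixed `R` and refines over `R` with
#'   [stats::optimize()]; `"grid"` is an independent 2D grid search with
#'   iterative local refinement, used as a cross-check.
#' @param n_grid grid resolution per axis for `method = "grid"`.
#' @return List with `A` (nm^2), `R` (nm), `E` (kBT), `branch`
#'   (`"boundary"`, `"interior"` or `"empty"` when no coated state beats the
#'   bare flat membrane), and `unbounded` (logical; `TRUE` when the energy is
#'   unbounded below, in which case `A`, `R`, `E` are `NA`).
#' @examples
#' minimize_energy()            # boundary minimum near R = 55 nm
#' minimize_energy(model_params(gamma = 0.1))  # interior minimum
#' @export
minimize_energy <- function(p = model_params(), R_range = c(5, 2000),
                            method = c("profile", "grid"), n_grid = 200) {
  method <- match.arg(method)
  if (.is_unbounded(p))
    return(list(A = NA_real_, R = NA_real_, E = NA_real_,
                branch = "unbounded", unbounded = TRUE))
  if (method == "profile") {
    Rs <- exp(seq(log(R_range[1]), log(R_range[2]), length.out = 600))
    Es <- vapply(Rs, function(R) .profile_at_R(R, p)$E, numeric(1))
    i <- which.min(Es)
    lo <- Rs[max(1L, i - 2L)]; hi <- Rs[min(length(Rs), i + 2L)]
    opt <- stats::optimize(function(R) .profile_at_R(R, p)$E, c(lo, hi),
                           tol = 1e-10)
    best <- .profile_at_R(opt$minimum, p)
    if (best$branch == "empty" || best$E >= 0)
      return(list(A = 0, R = NA_real_, E = 0, branch = "empty",
                  unbounded = FALSE))
    return(list(A = best$A, R = opt$minimum, E = best$E, branch = best$branch,
                unbounded = FALSE))
  }
  # independent route: 2D grid with local refinement
  Rlo <- R_range[1]; Rhi <- R_range[2]
  Alo <- 1e-2; Ahi <- 4 * pi * Rhi^2
  best <- list(E = 0, A = 0, R = NA_real_, branch = "empty")
  for (round in 1:6) {
    Rs <- exp(seq(log(Rlo), log(Rhi), length.out = n_grid))
    As <- exp(seq(log(Alo), log(Ahi), length.out = n_grid))
    G <- outer(As, Rs, function(A, R) {
      E <- A * .c1(R, p) + p$gamma * A^2 / (4 * pi * R^2)
      E[A > 4 * pi * R^2] <- Inf
      E
    })
    ij <- arrayInd(which.min(G), dim(G))
    if (G[ij] < best$E) {
      A0 <- As[ij[1]]; R0 <- Rs[ij[2]]
      best <- list(E = G[ij], A = min(A0, 4 * pi * R0^2), R = R0,
                   branch = "interior")
    }
    # zoom
    fR <- exp(2 * log(Rhi / Rlo) / n_grid)
    fA <- exp(2 * log(Ahi / Alo) / n_grid)
    R0 <- if (is.na(best$R)) sqrt(Rlo * Rhi) else best$R
    A0 <- if (best$A <= 0) sqrt(Alo * Ahi) else best$A
    Rlo <- R0 / fR; Rhi <- R0 * fR
    Alo <- A0 / fA; Ahi <- A0 * fA
  }
  if (best$branch != "empty") {
    if (best$A > 0.995 * 4 * pi * best$R^2) {
      best$branch <- "boundary"
      best$A <- 4 * pi * best$R^2
    }
  }
  c(best[c("A", "R", "E", "branch")], list(unbounded = FALSE))
}

#' Energy landscape grid over area and radius of curvature
#'
#' Evaluates the total CCP energy (or one of its terms) on a log-spaced
#' `(A, R)` grid, masking the physically inaccessible region `A > 4*pi*R^2`.
#'
#' @param p a [model_params()].
#' @param A_range area range (nm^2); default `c(1e2, 1e5)`.
#' @param R_range radius range (nm); default `c(10, 400)`.
#' @param resolution grid cells per axis; default 400.
#' @param term one of `"total"`, `"memb_bend"`, `"memb_tension"`,
#'   `"clath_bend"`, `"clath_poly"`.
#' @return An object of class `energy_landscape`: list with `A` (axis,
#'   nm^2), `R` (axis, nm), `E` (matrix, rows = A, cols = R, kBT; `NA` where
#'   masked), `valid` (logical mask), `params`, `term`.
#' @export
energy_landscape <- function(p = model_params(), A_range = c(1e2, 1e5),
                             R_range = c(10, 400), resolution = 400,
                             term = c("total", "memb_bend", "memb_tension",
                                      "clath_bend", "clath_poly")) {
  term <- match.arg(term)
  if (length(A_range) != 2 || length(R_range) != 2 ||
      any(A_range <= 0) || any(R_range <= 0) ||
      diff(A_range) <= 0 || diff(R_range) <= 0)
    stop("A_range and R_range must be increasing positive ranges")
  As <- exp(seq(log(A_range[1]), log(A_range[2]), length.out = resolution))
  Rs <- exp(seq(log(R_range[1]), log(R_range[2]), length.out = resolution))
  f <- switch(term,
    total        = function(A, R) A * .c1(R, p) + p$gamma * A^2 / (4 * pi * R^2),
    memb_bend    = function(A, R) {
      cm <- if (is.infinite(p$R_memb)) 0 else 2 / p$R_memb
      A * (p$kappa_memb / 2) * (2 / R - cm)^2
    },
    memb_tension = function(A, R) p$gamma * A^2 / (4 * pi * R^2),
    clath_bend   = function(A, R) A * (p$kappa_clath / 2) * (2 / R - 2 / p$R_clath)^2,
    clath_poly   = function(A, R) -p$a * A / p$A_clath + 0 * R)
  E <- outer(As, Rs, f)
  valid <- outer(As, Rs, function(A, R) A <= 4 * pi * R^2)
  E[!valid] <- NA_real_
  structure(list(A = As, R = Rs, E = E, valid = valid, params = p,
                 term = term),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("energy landscape (%s): %d x %d cells, A in [%g, %g] nm^2, R in [%g, %g] nm\n",
              x$term, length(x$A), length(x$R), min(x$A), max(x$A),
              min(x$R), max(x$R)))
  cat(sprintf("  valid cells: %d; E range [%.4g, %.4g] kBT\n",
              sum(x$valid), min(x$E, na.rm = TRUE), max(x$E, na.rm = TRUE)))
  invisible(x)
}

#' Convert an energy landscape to a data frame
#'
#' @param x an [energy_landscape()].
#' @param ... unused.
#' @return Data frame with columns `A_nm2`, `R_nm`, `E_kBT` (NA where
#'   masked), `valid`.
#' @export
as.data.frame.energy_landscape <- function(x, ...) {
  data.frame(A_nm2 = rep(x$A, times = length(x$R)),
             R_nm = rep(x$R, each = length(x$A)),
             E_kBT = as.vector(x$E),
             valid = as.vector(x$valid))
}

#' Critical membrane tension for detachment from the closed-sphere locus
#'
#' Sweeps membrane tension over `gamma_grid` and returns the smallest tension
#' at which the constrained energy minimum lies strictly inside
#' `A < 4*pi*R^2` (an open cap) rather than on the closed-sphere boundary.
#' At default parameters and 0.005 kBT/nm^2 resolution the transition is at
#' ~0.06 kBT/nm^2: above it, closed-vesicle formation is no longer the
#' energy minimum and endocytosis is predicted to stall.
#'
#' @param p a [model_params()] (its `gamma` is ignored during the sweep).
#' @param gamma_grid increasing vector of tensions (kBT/nm^2); default
#'   `seq(0.005, 0.2, by = 0.005)`.
#' @return List with `gamma_critical` (kBT/nm^2; `NA` if not bracketed by the
#'   grid), `bracketed` (logical) and `sweep` (data frame of `gamma`,
#'   `branch`, `R`, `A`, `E`).
#' @export
critical_tension <- function(p = model_params(),
                             gamma_grid = seq(0.005, 0.2, by = 0.005)) {
  if (is.unsorted(gamma_grid, strictly = TRUE))
    stop("gamma_grid must be strictly increasing")
  rows <- lapply(gamma_grid, function(g) {
    pg <- p; pg$gamma <- g
    m <- minimize_energy(pg)
    data.frame(gamma = g, branch = m$branch, R = m$R, A = m$A, E = m$E)
  })
  sweep <- do.call(rbind, rows)
  interior <- sweep$branch == "interior"
  if (!any(interior) || all(interior))
    return(list(gamma_critical = NA_real_, bracketed = FALSE, sweep = sweep))
  gc <- min(sweep$gamma[interior])
  list(gamma_critical = gc, bracketed = TRUE, sweep = sweep)
}

#' Relax the radius of curvature at fixed coat area
#'
#' For a lattice fragment of fixed area `A` free of external constraints, the
#' energy-minimizing radius of curvature satisfies, in closed form,
#' `1/R = (4*kappa_clath/R_clath) / (4*kappa_memb + 4*kappa_clath +
#' gamma*A/(2*pi))`, clamped from below at the closed-sphere bound
#' `R >= sqrt(A/(4*pi))`. This is the end state of a nanodissected fragment
#' that curls up toward the intrinsic clathrin curvature.
#'
#' @param A coat area (nm^2), vectorized.
#' @param p a [model_params()].
#' @return Relaxed radius of curvature (nm).
#' @examples
#' relax_at_constant_area(10000)  # ~42 nm
#' @export
relax_at_constant_area <- function(A, p = model_params()) {
  if (any(A <= 0)) stop("A must be positive")
  num <- 4 * p$kappa_clath / p$R_clath +
    if (is.infinite(p$R_memb)) 0 else 4 * p$kappa_memb / p$R_memb
  Rstar <- (4 * p$kappa_memb + 4 * p$kappa_clath + p$gamma * A / (2 * pi)) / num
  pmax(Rstar, sqrt(A / (4 * pi)))
}
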