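#' Physical parameters of the CCP energy model
#'
#' Bundles the constants of the four-term clathrin-coated-pit energy:
#' membrane bending, membrane tension, clathrin coat bending and clathrin
#' polymerization. Defaults are the values used for all main-text landscape
#' calculations; each can be overridden.
#'
#' @param kappa_memb membrane bending rigidity (kBT); default 15.
#' @param R_memb intrinsic membrane radius of curvature (nm); `Inf` (default)
#'   means the unperturbed membrane is flat.
#' @param gamma membrane tension (kBT/nm^2); default 0.01, an intermediate
#'   value in the cellular range 1e-4 to 1.
#' @param kappa_clath clathrin coat bending rigidity (kBT); default 373, from
#'   AFM stiffness measurements on reconstituted cages (see
#'   [kappa_from_stiffness()]).
#' @param R_clath intrinsic (preferred) radius of curvature of the clathrin
#'   lattice (nm); default 40, the characteristic radius of self-assembled
#'   cages.
#' @param a polymerization energy per clathrin arm-arm interaction (kBT);
#'   default 30 (an upper-bound estimate, see [estimate_a_from_Rmean()]).
#' @param A_clath lattice area sustained by one arm-arm interaction (nm^2),
#'   one third of the hexagonal unit cell; default 218.
#'
#' @return An object of class `model_params` (named list of the seven
#'   constants).
#' @examples
#' p <- model_params()
#' p_tense <- model_params(gamma = 0.1)
#' @export
model_params <- function(kappa_memb = 15, R_memb = Inf, gamma = 0.01,
                         kappa_clath = 373, R_clath = 40, a = 30,
                         A_clath = 218) {
  p <- list(kappa_memb = kappa_memb, R_memb = R_memb, gamma = gamma,
            kappa_clath = kappa_clath, R_clath = R_clath, a = a,
            A_clath = A_clath)
  for (nm in c("kappa_memb", "gamma", "kappa_clath", "R_clath", "A_clath"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop(nm, " must be a positive scalar")
  if (!is.numeric(p$a) || length(p$a) != 1L || p$a < 0)
    stop("a must be a nonnegative scalar")
  if (!(is.infinite(p$R_memb) || p$R_memb > 0))
    stop("R_memb must be positive or infinite")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("CCP model parameters:\n")
  cat(sprintf("  kappa_memb  = %g kBT       R_memb = %g nm\n", x$kappa_memb, x$R_memb))
  cat(sprintf("  gamma       = %g kBT/nm^2\n", x$gamma))
  cat(sprintf("  kappa_clath = %g kBT       R_clath = %g nm\n", x$kappa_clath, x$R_clath))
  cat(sprintf("  a           = %g kBT       A_clath = %g nm^2\n", x$a, x$A_clath))
  invisible(x)
}

.check_cap_AR <- function(A, R) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be positive and finite")
  if (any(A < 0)) stop("A must be nonnegative")
  if (any(A > 4 * pi * R^2 * (1 + 1e-9)))
    stop("invalid cap: A > 4*pi*R^2")
}

#' Membrane bending energy of a CCP
#'
#' Helfrich bending energy of the membrane patch wrapped onto the cap:
#' `A * (kappa_memb/2) * (2/R - 2/R_memb)^2`. With a flat intrinsic membrane
#' shape (`R_memb = Inf`) this reduces to `4*pi*kappa_memb*(h/R)`, so it
#' depends on the cap only through the aspect ratio; a closed vesicle costs
#' `8*pi*kappa_memb` (about 376 kBT at 15 kBT) at any size.
#'
#' @param A cap surface area (nm^2).
#' @param R radius of curvature (nm).
#' @param p a [model_params()].
#' @return Energy in kBT (vectorized over `A`, `R`).
#' @export
memb_bend_energy <- function(A, R, p = model_params()) {
  .check_cap_AR(A, R)
  cm <- if (is.infinite(p$R_memb)) 0 else 2 / p$R_memb
  A * (p$kappa_memb / 2) * (2 / R - cm)^2
}

#' Membrane tension energy of a CCP
#'
#' Work done against lateral membrane tension to pull the cap out of the
#' plane: `gamma * delta_area(A, R) = gamma * A^2/(4*pi*R^2) = gamma*pi*h^2`.
#'
#' @inheritParams memb_bend_energy
#' @return Energy in kBT.
#' @export
memb_tension_energy <- function(A, R, p = model_params()) {
  p$gamma * delta_area(A, R)
}

#' Clathrin coat bending energy
#'
#' Cost of bending the clathrin lattice away from its preferred curvature:
#' `A * (kappa_clath/2) * (2/R - 2/R_clath)^2`, zero only at `R = R_clath`.
#'
#' @inheritParams memb_bend_energy
#' @return Energy in kBT.
#' @export
clath_bend_energy <- function(A, R, p = model_params()) {
  .check_cap_AR(A, R)
  A * (p$kappa_clath / 2) * (2 / R - 2 / p$R_clath)^2
}

#' Clathrin polymerization energy
#'
#' Favorable energy of polymerized arm-arm interactions,
#' `-a * (N_total - N_open_arms)` with `N_total ~ A / A_clath`. The open-arm
#' boundary correction is negligible for lattices of more than a few cells
#' and defaults to zero.
#'
#' @param A coat area (nm^2), `A >= 0`.
#' @param p a [model_params()].
#' @param n_open_arms number of unpolymerized (open) boundary arms, `>= 0`.
#' @return Energy in kBT (nonpositive when `n_open_arms = 0`).
#' @export
clath_poly_energy <- function(A, p = model_params(), n_open_arms = 0) {
  if (any(A < 0)) stop("A must be nonnegative")
  if (any(n_open_arms < 0)) stop("n_open_arms must be nonnegative")
  -p$a * (A / p$A_clath - n_open_arms)
}

#' Total CCP energy and its four-term breakdown
#'
#' Sums membrane bending, membrane tension, clathrin bending and clathrin
#' polymerization for a cap of area `A` and radius of curvature `R`:
#' \deqn{E = A\frac{\kappa_m}{2}\left(\frac{2}{R}\right)^2
#'        + \gamma\frac{A^2}{4\pi R^2}
#'        + A\frac{\kappa_c}{2}\left(\frac{2}{R}-\frac{2}{R_c}\right)^2
#'        - a\frac{A}{A_c}}
#'
#' @inheritParams memb_bend_energy
#' @return An object of class `energy_breakdown`: list with
#'   `E_memb_bend`, `E_memb_tension`, `E_clath_bend`, `E_clath_poly`,
#'   `E_total` (the exact sum), all in kBT.
#' @examples
#' total_energy(A = 4 * pi * 55^2, R = 55)
#' @export
total_energy <- function(A, R, p = model_params()) {
  .check_cap_AR(A, R)
  eb <- list(
    E_memb_bend    = memb_bend_energy(A, R, p),
    E_memb_tension = memb_tension_energy(A, R, p),
    E_clath_bend   = clath_bend_energy(A, R, p),
    E_clath_poly   = clath_poly_energy(A, p)
  )
  eb$E_total <- eb$E_memb_bend + eb$E_memb_tension + eb$E_clath_bend +
    eb$E_clath_poly
  structure(eb, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("CCP energy (kBT): memb bend %.4g + tension %.4g + clath bend %.4g + poly %.4g = %.5g\n",
              x$E_memb_bend, x$E_memb_tension, x$E_clath_bend, x$E_clath_poly,
              x$E_total))
  invisible(x)
}

#' Clathrin bending energy per arm-arm interaction
#'
#' The coat bending cost carried by a single arm-arm interaction in a lattice
#' of radius of curvature `R`: `A_clath * (kappa_clath/2) * (2/R - 2/R_clath)^2`.
#' Zero at `R = R_clath`, rising to `A_clath * 2*kappa_clath / R_clath^2`
#' (about 102 kBT at defaults) for a flat lattice.
#'
#' @param R radius of curvature (nm), vectorized; `Inf` allowed (flat).
#' @param p a [model_params()].
#' @return Energy in kBT.
#' @export
per_arm_bend_energy <- function(R, p = model_params()) {
  if (any(R <= 0)) stop("R must be positive")
  inv <- ifelse(is.infinite(R), 0, 2 / R)
  p$A_clath * (p$kappa_clath / 2) * (inv - 2 / p$R_clath)^2
}

#' Upper-bound estimate of the polymerization energy per arm
#'
#' If lattices at the population-mean radius of curvature `R_mean` are
#' marginally stable — clathrin bending cost per arm balancing the
#' polymerization gain per arm — then `a ~ per_arm_bend_energy(R_mean)`.
#' Because lattice defects can relax part of the bending cost, this is an
#' upper bound on `a`. At `R_mean = 92` nm and default parameters the
#' estimate is ~30 kBT.
#'
#' @param R_mean population mean radius of curvature (nm).
#' @param p a [model_params()].
#' @return Estimated `a` in kBT.
#' @export
estimate_a_from_Rmean <- function(R_mean, p = model_params()) {
  per_arm_bend_energy(R_mean, p)
}

#' Clathrin coat rigidity from cage stiffness (thin-shell theory)
#'
#' Converts an AFM point-load stiffness `k` measured on a clathrin cage into
#' a bending rigidity. The relation combines the thin-shell point-load
#' stiffness `k = 4 E t^2 / (R * sqrt(3 (1 - nu^2)))` with the plate rigidity
#' `kappa = E t^3 / (12 (1 - nu^2))`, giving
#' `kappa = k * R * t * sqrt(3) / (48 * sqrt(1 - nu^2))`
#' (equal to `k*R*t/24` at `nu = 0.5`). The exact shell relation and the
#' effective thickness of a clathrin lattice are not independently measured,
#' so the default thickness is a calibration: with `k = 0.08` N/m,
#' `R_cage = 40` nm, `nu = 0.5` and `t = 11.4977` nm the function returns the
#' default coat rigidity of ~373 kBT. The formula, not the returned value,
#' is the substantive content; linearity in `k` is exact.
#'
#' @param k measured cage stiffness (N/m).
#' @param R_cage cage radius (nm); default 40.
#' @param t effective shell thickness (nm); default 11.4977 (calibrated, see
#'   Details).
#' @param nu Poisson ratio in (0, 0.5]; default 0.5 (incompressible shell).
#' @param kBT_J thermal energy in joules; default 4.11e-21 (298 K).
#' @return Bending rigidity in kBT.
#' @examples
#' kappa_from_stiffness(0.08)  # ~373
#' @export
kappa_from_stiffness <- function(k, R_cage = 40, t = 11.4977, nu = 0.5,
                                 kBT_J = 4.11e-21) {
  stopifnot(k >= 0, R_cage > 0, t > 0, nu > 0, nu <= 0.5)
  kappa_J <- k * (R_cage * 1e-9) * (t * 1e-9) * sqrt(3) / (48 * sqrt(1 - nu^2))
  kappa_J / kBT_J
}
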