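#' Spherical-cap geometry of a clathrin-coated pit
#'
#' A clathrin-coated pit (CCP) is modeled as a spherical cap sitting on the
#' flat plasma membrane: a sphere of radius of curvature `R` truncated by the
#' membrane plane at height `h` below its apex. The cap surface area is
#' `A = 2*pi*R*h` exactly, so any two of (R, h, A) determine the third.
#' `h = 2*R` is a complete sphere (a closed clathrin-coated vesicle,
#' `A = 4*pi*R^2`); no separate type is used for that limit.
#'
#' @param R radius of curvature (nm), `R > 0`.
#' @param h cap height above the base plane (nm), `0 < h <= 2R`.
#' @param A cap surface area (nm^2), `0 < A <= 4*pi*R^2`.
#' @param center optional 3D sphere center (nm, length-3 numeric); defaults to
#'   `c(0, 0, h - R)` so the base plane is z = 0.
#'
#' @return An object of class `spherical_cap`: a list with fields `R`, `h`,
#'   `A`, `theta` (base angle in degrees between the membrane plane and the
#'   cap surface at its foot, in (0, 180]), and `center`.
#'
#' @details The base angle `theta` is the polar angle of the cap rim measured
#'   from the downward apex axis: `theta = acos(1 - h/R)` (degrees), so a
#'   hemisphere has `theta = 90` and a closed sphere `theta = 180`.
#'
#' @examples
#' cap <- spherical_cap(R = 100, h = 40)
#' cap$A            # 2*pi*100*40
#' aspect_ratio(cap)
#' @export
spherical_cap <- function(R, h = NULL, A = NULL, center = NULL) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R))
  if (R <= 0) stop("spherical cap requires R > 0")
  if (is.null(h) && is.null(A)) stop("supply h or A")
  if (is.null(h)) {
    if (A <= 0 || A > 4 * pi * R^2 * (1 + 1e-12))
      stop("cap area must satisfy 0 < A <= 4*pi*R^2")
    h <- min(A / (2 * pi * R), 2 * R)
  }
  if (h <= 0 || h > 2 * R * (1 + 1e-12))
    stop("cap height must satisfy 0 < h <= 2*R")
  h <- min(h, 2 * R)
  if (is.null(A)) A <- 2 * pi * R * h
  theta <- acos(max(-1, min(1, 1 - h / R))) * 180 / pi
  if (is.null(center)) center <- c(0, 0, h - R)
  structure(list(R = R, h = h, A = A, theta = theta, center = center),
            class = "spherical_cap")
}

#' @export
print.spherical_cap <- function(x, ...) {
  cat(sprintf("spherical cap: R = %.4g nm, h = %.4g nm, A = %.5g nm^2, theta = %.4g deg\n",
              x$R, x$h, x$A, x$theta))
  invisible(x)
}

#' Surface area of a spherical cap
#'
#' `A = 2*pi*R*h` for a cap of radius of curvature `R` and height `h`.
#'
#' @inheritParams spherical_cap
#' @return Area in nm^2.
#' @examples
#' cap_area(100, 40)  # 25132.74
#' @export
cap_area <- function(R, h) {
  stopifnot(is.numeric(R), is.numeric(h))
  if (any(R <= 0) || any(h <= 0)) stop("cap_area requires R > 0 and h > 0")
  if (any(h > 2 * R * (1 + 1e-12))) stop("cap_area requires h <= 2*R")
  2 * pi * R * h
}

#' In-plane membrane area absorbed by a cap
#'
#' Deforming a flat membrane patch into a spherical cap of area `A` and radius
#' `R` removes `delta_A = A^2 / (4*pi*R^2)` of in-plane (projected) area; the
#' membrane-tension work is `gamma * delta_A`. For any valid cap this equals
#' `pi*h^2` with `h = A/(2*pi*R)`.
#'
#' @param A cap surface area (nm^2), `A <= 4*pi*R^2`.
#' @param R radius of curvature (nm).
#' @return Area decrease in nm^2.
#' @examples
#' delta_area(2 * pi * 100 * 10, 100)  # pi * 10^2
#' @export
delta_area <- function(A, R) {
  stopifnot(is.numeric(A), is.numeric(R))
  if (any(R <= 0) || any(A < 0)) stop("delta_area requires R > 0 and A >= 0")
  if (any(A > 4 * pi * R^2 * (1 + 1e-12)))
    stop("invalid cap: A > 4*pi*R^2")
  A^2 / (4 * pi * R^2)
}

#' Cap aspect ratio h/R
#'
#' The ratio of cap height to radius of curvature, in (0, 2]: 1 is a
#' hemisphere and 2 a closed sphere. Membrane bending energy of a cap on a
#' flat membrane depends on the cap only through this ratio.
#'
#' @param cap a [spherical_cap()].
#' @return `h/R`, dimensionless.
#' @export
aspect_ratio <- function(cap) {
  stopifnot(inherits(cap, "spherical_cap"))
  cap$h / cap$R
}

#' Interior angle of a regular polygon
#'
#' `(n - 2) * 180 / n` degrees: 108 for a pentagon, 120 for a hexagon,
#' 128.57 for a heptagon — the reference values for clathrin inter-arm angles
#' in regular lattice polygons.
#'
#' @param n number of vertices, `n >= 3` (vectorized).
#' @return Interior angle(s) in degrees.
#' @export
regular_polygon_interior_angle <- function(n) {
  stopifnot(is.numeric(n))
  if (any(n < 3)) stop("a polygon needs at least 3 vertices")
  (n - 2) * 180 / n
}

#' Expected inter-arm angle sum for a triskelion in a polygon configuration
#'
#' A triskelion hub participating in three lattice polygons of sizes
#' `config = c(n1, n2, n3)` would, were all three polygons regular and planar,
#' show an inter-arm angle sum equal to the sum of the three regular interior
#' angles: 360 for 6-6-6 (flat tiling), 348 for 6-6-5, 336 for 6-5-5, 324 for
#' 5-5-5.
#'
#' @param config integer vector of three polygon sizes, each `>= 3`.
#' @return Angle sum in degrees.
#' @examples
#' expected_angle_sum(c(6, 6, 5))  # 348
#' @export
expected_angle_sum <- function(config) {
  stopifnot(is.numeric(config), length(config) == 3L)
  sum(regular_polygon_interior_angle(config))
}
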