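# Rendering AFM-like topographs from ground-truth geometry.

#' Ground truth for one synthetic topograph
#'
#' Bundles the geometry and imaging parameters of a synthetic AFM scene: an
#' optional spherical cap (a pit; `NULL` for a flat membrane), an optional
#' clathrin lattice mesh whose ridges decorate the surface, and the render
#' parameters. Defaults match the imaging geometry emulated throughout:
#' 300 x 300 pixel frames at 2 nm/pixel, 2 nm ridges, a 2 nm tip radius and
#' 0.1 nm pixel noise.
#'
#' @param cap a [spherical_cap()] or `NULL` (flat membrane).
#' @param mesh a [lattice_skeleton()] or `NULL` (no lattice texture); use
#'   [build_cap_lattice()] / [hex_patch_mesh()].
#' @param ridge_height lattice ridge height above the local surface (nm).
#' @param r_tip AFM tip radius for grayscale dilation (nm); 0 disables.
#' @param noise_sd additive Gaussian pixel noise (nm); 0 disables.
#' @param pixel_size nm per pixel.
#' @param n_pixels frame side length in pixels.
#' @param seed integer seed used for the noise draw.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(cap = NULL, mesh = NULL, ridge_height = 2,
                            r_tip = 2, noise_sd = 0.1, pixel_size = 2,
                            n_pixels = 300, seed = 1) {
  if (!is.null(cap)) stopifnot(inherits(cap, "spherical_cap"))
  if (!is.null(mesh)) stopifnot(inherits(mesh, "lattice_skeleton"))
  stopifnot(ridge_height >= 0, r_tip >= 0, noise_sd >= 0,
            pixel_size > 0, n_pixels >= 16)
  structure(list(cap = cap, mesh = mesh, ridge_height = ridge_height,
                 r_tip = r_tip, noise_sd = noise_sd,
                 pixel_size = pixel_size, n_pixels = n_pixels,
                 seed = as.integer(seed),
                 pentagon_count = if (!is.null(mesh))
                   attr(mesh, "pentagon_count") else NULL),
            class = "synthetic_truth")
}

#' Render a synthetic truth into an AFM-like topograph
#'
#' The height map is the pointwise maximum of a flat membrane at 0, the cap
#' surface, and lattice ridges raised `ridge_height` above the local
#' surface; the result is then grayscale-dilated with a spherical tip of
#' radius `r_tip` (the tip cannot descend into gaps narrower than itself,
#' which widens every protrusion) and Gaussian pixel noise is added. The cap
#' and mesh are placed at the frame center.
#'
#' @param truth a [synthetic_truth()].
#' @return A [topograph()] with `zero_level = 0`.
#' @export
render_topograph <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- truth$n_pixels; px <- truth$pixel_size
  cx <- floor((n - 1) / 2) * px; cy <- floor((n - 1) / 2) * px  # a pixel center
  xs <- (seq_len(n) - 1) * px
  ys <- (seq_len(n) - 1) * px
  h <- matrix(0, n, n)          # rows = y, cols = x
  cap <- truth$cap
  surf_at <- function(X, Y) {
    if (is.null(cap)) return(0 * X)
    d2 <- (X - cx)^2 + (Y - cy)^2
    z <- (cap$h - cap$R) + sqrt(pmax(cap$R^2 - d2, 0))
    z[d2 > cap$R^2] <- 0
    pmax(z, 0)
  }
  if (!is.null(cap)) {
    foot <- if (cap$h < cap$R) sqrt(cap$h * (2 * cap$R - cap$h)) else cap$R
    if (2 * (foot + truth$r_tip) > (n - 1) * px)
      stop("cap footprint exceeds the frame")
    X <- matrix(xs, n, n, byrow = TRUE)
    Y <- matrix(ys, n, n)
    h <- pmax(h, surf_at(X, Y))
  }
  mesh <- truth$mesh
  if (!is.null(mesh) && nrow(mesh$edges) > 0) {
    v <- mesh$vertices
    v[, 1] <- v[, 1] + cx; v[, 2] <- v[, 2] + cy
    step <- px / 3
    for (e in seq_len(nrow(mesh$edges))) {
      a <- v[mesh$edges[e, 1], ]; b <- v[mesh$edges[e, 2], ]
      len <- sqrt(sum((b - a)^2))
      if (len == 0) next
      ts <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      sx <- a[1] + (b[1] - a[1]) * ts
      sy <- a[2] + (b[2] - a[2]) * ts
      ci <- round(sx / px) + 1
      ri <- round(sy / px) + 1
      ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
      if (!any(ok)) next
      ri <- ri[ok]; ci <- ci[ok]; sx <- sx[ok]; sy <- sy[ok]
      zs <- surf_at(sx, sy) + truth$ridge_height
      ii <- cbind(ri, ci)
      h[ii] <- pmax(h[ii], zs)
    }
  }
  if (truth$r_tip > 0) h <- .tip_dilate(h, truth$r_tip, px)
  if (truth$noise_sd > 0)
    h <- h + .with_seed(truth$seed,
                        matrix(stats::rnorm(n * n, sd = truth$noise_sd), n, n))
  topograph(h, px, zero_level = 0)
}

# grayscale dilation with a spherical tip: out(x) = max_u h(x+u) - b(u),
# b(u) = r - sqrt(r^2 - |u|^2) (tip sagitta)
.tip_dilate <- function(h, r_tip, px) {
  kmax <- floor(r_tip / px)
  out <- h
  for (du in -kmax:kmax) for (dv in -kmax:kmax) {
    if (du == 0 && dv == 0) next
    d2 <- (du^2 + dv^2) * px^2
    if (d2 > r_tip^2) next
    sag <- r_tip - sqrt(r_tip^2 - d2)
    out <- pmax(out, .shift_matrix(h, du, dv, fill = -Inf) - sag)
  }
  out
}

#' Sample a CCP population from the energy landscape
#'
#' Draws `(A, R)` states with probability proportional to
#' `exp(-E_total / T_eff)` over the valid (`A <= 4*pi*R^2`) cells of a
#' landscape grid, then jitters each draw uniformly within its (log-spaced)
#' cell. `T_eff` is an effective sampling temperature controlling the spread
#' of the cloud around the energy minimum — a device for generating
#' plausible synthetic populations, not a physical claim; as `T_eff -> 0`
#' all samples collapse onto the global minimum.
#'
#' @param p a [model_params()].
#' @param n number of pits to draw.
#' @param T_eff effective temperature (kBT); default 300.
#' @param seed integer seed.
#' @param A_range,R_range,resolution forwarded to [energy_landscape()];
#'   resolution defaults to 200.
#' @return List of `n` [spherical_cap()]s.
#' @export
sample_population <- function(p = model_params(), n, T_eff = 300, seed = 1,
                              A_range = c(1e2, 1e5), R_range = c(10, 400),
                              resolution = 200) {
  stopifnot(n >= 1)
  if (T_eff <= 0) stop("T_eff must be positive")
  ls <- energy_landscape(p, A_range, R_range, resolution = resolution)
  ok <- which(ls$valid & is.finite(ls$E))
  E <- ls$E[ok]
  w <- exp(-(E - min(E)) / T_eff)
  dlA <- diff(log(ls$A))[1]; dlR <- diff(log(ls$R))[1]
  .with_seed(seed, {
    pick <- sample(seq_along(ok), n, replace = TRUE, prob = w)
    ij <- arrayInd(ok[pick], dim(ls$E))
    A <- ls$A[ij[, 1]] * exp(stats::runif(n, -dlA / 2, dlA / 2))
    R <- ls$R[ij[, 2]] * exp(stats::runif(n, -dlR / 2, dlR / 2))
    A <- pmin(A, 4 * pi * R^2)
    lapply(seq_len(n), function(i) spherical_cap(R = R[i], A = A[i]))
  })
}

#' Simulate nanodissection of a lattice mesh
#'
#' Removes the given arm-arm interactions (edges) from the mesh, finds the
#' resulting connected components, assigns each component a coat area from
#' its face count (three arm-arm interactions of area `A_clath` per unit
#' cell), and relaxes each component's radius of curvature at constant area
#' via [relax_at_constant_area()]. Components untouched by the cut (same
#' face count as the intact mesh) keep their original radius: severing a
#' terminal open arm releases no constraint.
#'
#' @param truth a [synthetic_truth()] whose `mesh` is set; `truth$cap` gives
#'   the pre-cut radius of curvature (`Inf`, flat, when `cap` is `NULL`).
#' @param cut_edges integer vector of edge row indices of `truth$mesh$edges`
#'   to sever.
#' @param p a [model_params()].
#' @return Data frame, one row per post-cut component: `component`,
#'   `n_faces`, `A_nm2`, `R_before_nm`, `R_after_nm`, `E_elastic_before_kBT`,
#'   `E_elastic_after_kBT`, `dE_elastic_kBT`.
#' @export
simulate_nanodissection <- function(truth, cut_edges, p = model_params()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mesh <- truth$mesh
  if (is.null(mesh)) stop("truth has no lattice mesh")
  m <- nrow(mesh$edges)
  cut_edges <- as.integer(cut_edges)
  if (length(cut_edges) && (any(cut_edges < 1) || any(cut_edges > m)))
    stop("cut of nonexistent edge")
  keep <- setdiff(seq_len(m), cut_edges)
  g <- igraph::graph_from_edgelist(mesh$edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) -
                                     igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # assign each face to the component holding most of its vertices
  face_comp <- vapply(mesh$faces, function(fa) {
    tab <- table(memb[fa])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  comps <- sort(unique(face_comp))
  R_before <- if (is.null(truth$cap)) Inf else truth$cap$R
  elastic <- function(A, R) {
    inv <- if (is.infinite(R)) 0 else 1 / R
    A * (p$kappa_memb / 2) *
      (2 * inv - if (is.infinite(p$R_memb)) 0 else 2 / p$R_memb)^2 +
      p$gamma * A^2 * inv^2 / (4 * pi) +
      A * (p$kappa_clath / 2) * (2 * inv - 2 / p$R_clath)^2
  }
  n_faces_total <- length(mesh$faces)
  rows <- lapply(seq_along(comps), function(k) {
    nf <- sum(face_comp == comps[k])
    A <- nf * 3 * p$A_clath
    untouched <- length(comps) == 1L && nf == n_faces_total
    R_after <- if (untouched) R_before else relax_at_constant_area(A, p)
    Eb <- elastic(A, R_before)
    Ea <- elastic(A, R_after)
    data.frame(component = k, n_faces = nf, A_nm2 = A,
               R_before_nm = R_before, R_after_nm = R_after,
               E_elastic_before_kBT = Eb, E_elastic_after_kBT = Ea,
               dE_elastic_kBT = Ea - Eb)
  })
  do.call(rbind, rows)
}
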