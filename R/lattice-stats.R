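# Triskelion inter-arm angle statistics and population distributions.

#' Inter-arm angles at a triskelion hub
#'
#' For a degree-3 vertex of a lattice skeleton, computes the three inter-arm
#' angles `alpha`, `beta`, `gamma_angle` between the 3D chord vectors to its
#' neighbor hubs (pairwise arc-cosines of normalized dot products), their
#' sum, and the conformation class: a flat triskelion has angle sum 360
#' degrees, a convex (pyramidal, pointing out of the lattice plane) one
#' less, a concave one more.
#'
#' @param skel a [lattice_skeleton()].
#' @param vertex vertex index; must have degree 3.
#' @param tolerance flat-class half-width in degrees for
#'   [classify_conformation()]; default 5.
#' @return An object of class `triskelion_hub`: list with `vertex`,
#'   `position`, `arms` (3 x 3 matrix of chord vectors), `alpha`, `beta`,
#'   `gamma_angle`, `angle_sum` (degrees), `class`, and `adjacent_faces`
#'   (sizes of the skeleton faces meeting at the hub, possibly fewer than 3
#'   at the lattice boundary). Degree != 3 returns `NULL` with a warning.
#' @export
hub_angles <- function(skel, vertex, tolerance = 5) {
  stopifnot(inherits(skel, "lattice_skeleton"))
  nbrs <- c(skel$edges[skel$edges[, 1] == vertex, 2],
            skel$edges[skel$edges[, 2] == vertex, 1])
  if (length(nbrs) != 3L) {
    warning("vertex ", vertex, " has degree ", length(nbrs), ", not 3; skipped")
    return(NULL)
  }
  pos <- skel$vertices[vertex, ]
  arms <- skel$vertices[nbrs, , drop = FALSE] -
    matrix(pos, 3, 3, byrow = TRUE)
  ang <- function(u, v)
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  a12 <- ang(arms[1, ], arms[2, ])
  a13 <- ang(arms[1, ], arms[3, ])
  a23 <- ang(arms[2, ], arms[3, ])
  s <- a12 + a13 + a23
  adj <- lengths(Filter(function(f) vertex %in% f, skel$faces))
  structure(list(vertex = vertex, position = pos, arms = arms,
                 alpha = a12, beta = a13, gamma_angle = a23,
                 angle_sum = s,
                 class = classify_conformation(s, tolerance),
                 adjacent_faces = adj),
            class = "triskelion_hub")
}

#' Classify a triskelion conformation from its angle sum
#'
#' `convex` if the inter-arm angle sum is below `360 - tolerance`, `concave`
#' above `360 + tolerance`, `flat` in between. The default 5-degree band
#' absorbs AFM angular noise.
#'
#' @param angle_sum inter-arm angle sum in degrees (vectorized).
#' @param tolerance half-width of the flat band (degrees); default 5.
#' @return Character vector: `"convex"`, `"flat"` or `"concave"`.
#' @export
classify_conformation <- function(angle_sum, tolerance = 5) {
  stopifnot(all(angle_sum > 0))
  ifelse(angle_sum < 360 - tolerance, "convex",
         ifelse(angle_sum > 360 + tolerance, "concave", "flat"))
}

#' All hub angle statistics of a skeleton
#'
#' Runs [hub_angles()] over every degree-3 vertex.
#'
#' @param skel a [lattice_skeleton()].
#' @param tolerance passed to [hub_angles()].
#' @return Data frame with columns `vertex`, `alpha`, `beta`, `gamma_angle`,
#'   `angle_sum`, `class`.
#' @export
skeleton_hub_table <- function(skel, tolerance = 5) {
  hubs <- which(skel$is_hub)
  rows <- lapply(hubs, function(v) {
    h <- suppressWarnings(hub_angles(skel, v, tolerance))
    if (is.null(h)) return(NULL)
    data.frame(vertex = v, alpha = h$alpha, beta = h$beta,
               gamma_angle = h$gamma_angle, angle_sum = h$angle_sum,
               class = h$class)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(vertex = integer(0), alpha = numeric(0),
                      beta = numeric(0), gamma_angle = numeric(0),
                      angle_sum = numeric(0), class = character(0))
  out
}

#' Interior-angle distribution of one polygon class
#'
#' Collects, across skeletons, the interior angle at every vertex of every
#' face with `size` edges (the inter-arm angle between the two arms bounding
#' the face at that vertex, measured between 3D chords) and fits a normal
#' distribution by maximum likelihood (sample mean and standard deviation).
#' For regular flat polygons the distribution collapses onto
#' `(size - 2) * 180 / size` degrees.
#'
#' @param skels a [lattice_skeleton()] or list of them.
#' @param size polygon class: 5, 6 or 7 for the canonical clathrin fits.
#' @param bin_width histogram bin width in degrees; default 2.
#' @param min_n minimum number of angles for a fit; default 10.
#' @return An object of class `angle_fit`: list with `size`, `n`, `mean`,
#'   `sd` (degrees; `NA` if `n < min_n`), `angles`, and `histogram` (data
#'   frame of bin mids and counts).
#' @export
polygon_angle_histogram <- function(skels, size, bin_width = 2, min_n = 10) {
  if (inherits(skels, "lattice_skeleton")) skels <- list(skels)
  angles <- unlist(lapply(skels, function(sk) {
    fs <- Filter(function(f) length(f) == size, sk$faces)
    unlist(lapply(fs, function(f) .face_interior_angles(sk$vertices, f)))
  }))
  n <- length(angles)
  fit_ok <- n >= min_n
  brk <- seq(floor(min(c(angles, 0)) / bin_width) * bin_width,
             ceiling(max(c(angles, 1)) / bin_width) * bin_width, by = bin_width)
  hist <- if (n > 0) {
    hh <- graphics::hist(angles, breaks = brk, plot = FALSE)
    data.frame(angle_deg = hh$mids, count = hh$counts)
  } else data.frame(angle_deg = numeric(0), count = integer(0))
  structure(list(size = size, n = n,
                 mean = if (fit_ok) mean(angles) else NA_real_,
                 sd = if (fit_ok) stats::sd(angles) else NA_real_,
                 angles = angles, histogram = hist),
            class = "angle_fit")
}

#' @export
print.angle_fit <- function(x, ...) {
  if (is.na(x$mean))
    cat(sprintf("%d-gon interior angles: n = %d (insufficient for a fit)\n",
                x$size, x$n))
  else
    cat(sprintf("%d-gon interior angles: n = %d, normal fit mean %.2f deg, sd %.2f deg\n",
                x$size, x$n, x$mean, x$sd))
  invisible(x)
}

.face_interior_angles <- function(verts, face) {
  k <- length(face)
  vapply(seq_len(k), function(i) {
    v0 <- verts[face[i], ]
    vp <- verts[face[if (i == 1) k else i - 1], ]
    vn <- verts[face[if (i == k) 1 else i + 1], ]
    u <- vp - v0; w <- vn - v0
    acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
  }, numeric(1))
}

#' Angle sum versus radius of curvature
#'
#' Bins per-hub inter-arm angle sums by the radius of curvature of the pit
#' each hub belongs to, and reports per-bin means and a Spearman rank
#' correlation. Lattices on more highly curved pits (smaller R) have more
#' convex triskelia (smaller angle sums), so the correlation is positive.
#'
#' @param data data frame with columns `R_nm` and `angle_sum_deg` (one row
#'   per hub).
#' @param n_bins number of quantile bins over `R_nm`; default 4.
#' @return List with `bins` (data frame: `R_mid_nm`, `n`, `mean_sum_deg`,
#'   `sd_sum_deg`) and `spearman_rho` (rank correlation of `R_nm` and
#'   `angle_sum_deg` across hubs).
#' @export
anglesum_vs_radius <- function(data, n_bins = 4) {
  stopifnot(all(c("R_nm", "angle_sum_deg") %in% names(data)))
  if (length(unique(data$R_nm)) < 2) stop("need at least 2 distinct radii")
  if (length(unique(data$R_nm)) <= n_bins) {
    bins <- factor(data$R_nm)
  } else {
    qs <- unique(stats::quantile(data$R_nm, seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(data$R_nm, qs, include.lowest = TRUE)
  }
  agg <- lapply(split(data, bins), function(d)
    data.frame(R_mid_nm = mean(d$R_nm), n = nrow(d),
               mean_sum_deg = mean(d$angle_sum_deg),
               sd_sum_deg = stats::sd(d$angle_sum_deg)))
  bins_df <- do.call(rbind, agg)
  rownames(bins_df) <- NULL
  rho <- stats::cor(data$R_nm, data$angle_sum_deg, method = "spearman")
  list(bins = bins_df, spearman_rho = rho)
}

#' Area-radius distribution of a CCP population
#'
#' Summarizes a set of fitted pits in the area versus radius-of-curvature
#' plane: the scatter table, a kernel density on log-log axes, the mean-area
#' (constant-area model) and mean-radius (constant-curvature model)
#' reference lines, and the closed-sphere locus `A = 4*pi*R^2`. Optionally
#' records the density mode for comparison with [minimize_energy()].
#'
#' @param records list of `ccp_record`s, list of [spherical_cap()]s, or a
#'   data frame with columns `A_nm2`, `R_nm`; at least 3 entries.
#' @param grid_n kernel density grid size per axis; default 100.
#' @return An object of class `area_radius_dist`: list with `table`
#'   (`A_nm2`, `R_nm`), `mean_A`, `mean_R`, `density` (list `x` = log10 R,
#'   `y` = log10 A, `z`), `mode` (`A_nm2`, `R_nm` at the density maximum).
#' @export
area_radius_distribution <- function(records, grid_n = 100) {
  tab <- if (is.data.frame(records)) {
    records[, c("A_nm2", "R_nm")]
  } else {
    records <- Filter(function(r)
      inherits(r, "spherical_cap") || isTRUE(r$ok), records)
    caps <- lapply(records, function(r)
      if (inherits(r, "spherical_cap")) r else r$cap)
    data.frame(A_nm2 = vapply(caps, `[[`, numeric(1), "A"),
               R_nm = vapply(caps, `[[`, numeric(1), "R"))
  }
  if (nrow(tab) < 3) stop("need at least 3 records")
  dens <- MASS::kde2d(log10(tab$R_nm), log10(tab$A_nm2), n = grid_n)
  ij <- arrayInd(which.max(dens$z), dim(dens$z))
  structure(list(table = tab, mean_A = mean(tab$A_nm2),
                 mean_R = mean(tab$R_nm), density = dens,
                 mode = c(A_nm2 = 10^dens$y[ij[2]],
                          R_nm = 10^dens$x[ij[1]])),
            class = "area_radius_dist")
}

#' @export
print.area_radius_dist <- function(x, ...) {
  cat(sprintf("area-radius distribution: n = %d; mean A = %.4g nm^2, mean R = %.4g nm\n",
              nrow(x$table), x$mean_A, x$mean_R))
  cat(sprintf("  density mode near A = %.4g nm^2, R = %.4g nm\n",
              x$mode["A_nm2"], x$mode["R_nm"]))
  invisible(x)
}

#' Plot an area-radius distribution
#'
#' Scatter of pits on log-log axes with the mean-area and mean-radius
#' reference lines and the closed-sphere locus `A = 4*pi*R^2`.
#'
#' @param x an [area_radius_distribution()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.area_radius_dist <- function(x, ...) {
  Rline <- exp(seq(log(min(x$table$R_nm) / 2), log(max(x$table$R_nm) * 2),
                   length.out = 200))
  sphere <- data.frame(R_nm = Rline, A_nm2 = 4 * pi * Rline^2)
  ggplot2::ggplot(x$table, ggplot2::aes(x = R_nm, y = A_nm2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = sphere, color = "black") +
    ggplot2::geom_hline(yintercept = x$mean_A, color = "red") +
    ggplot2::geom_vline(xintercept = x$mean_R, color = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "radius of curvature R (nm)",
                  y = expression(area ~ A ~ (nm^2)))
}
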