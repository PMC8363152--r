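# Spherical-cap fitting to topographic data.

#' Fit a spherical cap to a pit in a topograph
#'
#' Two-stage linear least-squares sphere fit. Stage 1 fits the algebraic
#' sphere equation `x^2 + y^2 + z^2 + D x + E y + F z + G = 0` to all pixels
#' of the protrusion containing `seed` (the connected region above
#' `zero_level + height_thresh`). Stage 2 refits using only points whose
#' polar angle from the fitted apex is at most `apex_angle` degrees, iterated
#' `iterations` times: the apex region is where the AFM tip tracks the true
#' surface, while the steep flanks are widened by tip dilation and would bias
#' the fit.
#'
#' Cap height is read from the fitted sphere, `h = center_z + R` above the
#' zero level, and the cap area is `A = 2*pi*R*h` (area above the zero
#' level).
#'
#' @param t a leveled [topograph()].
#' @param seed `(x, y)` position in nm inside the protrusion.
#' @param p [model_params()] used to attach an energy breakdown to the
#'   record.
#' @param height_thresh protrusion threshold above `zero_level` (nm);
#'   default 0.5.
#' @param apex_angle polar-angle cutoff from the apex (degrees); default 45.
#' @param iterations apex-restriction refits; default 2.
#' @param R_limits admissible fitted radius range (nm); default
#'   `c(5, 2000)`.
#' @return An object of class `ccp_record`: list with `ok` (logical), `cap`
#'   ([spherical_cap()]), `center` (3D, nm, z relative to zero level),
#'   `residual` (RMS radial misfit, nm), `n_points`, `energies`
#'   ([total_energy()] breakdown), `seed`, and on failure `reason`.
#' @export
fit_sphere <- function(t, seed, p = model_params(), height_thresh = 0.5,
                       apex_angle = 45, iterations = 2,
                       R_limits = c(5, 2000)) {
  stopifnot(inherits(t, "topograph"), length(seed) == 2)
  fail <- function(reason)
    structure(list(ok = FALSE, reason = reason, seed = seed),
              class = "ccp_record")
  d <- dim(t$heights)
  sr <- round(seed[2] / t$pixel_size) + 1
  sc <- round(seed[1] / t$pixel_size) + 1
  if (sr < 1 || sr > d[1] || sc < 1 || sc > d[2]) return(fail("seed out of bounds"))
  mask <- t$heights > t$zero_level + height_thresh
  if (!mask[sr, sc]) return(fail("seed not inside a protrusion"))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), d[1], d[2]))
  id <- lab[sr, sc]
  px <- which(lab == id)
  if (length(px) < 12) return(fail("fewer than 12 usable points"))
  rc <- arrayInd(px, d)
  x <- (rc[, 2] - 1) * t$pixel_size
  y <- (rc[, 1] - 1) * t$pixel_size
  z <- t$heights[px] - t$zero_level
  fit <- .algebraic_sphere(x, y, z)
  if (is.null(fit)) return(fail("degenerate sphere fit"))
  for (it in seq_len(iterations)) {
    dx <- x - fit$cx; dy <- y - fit$cy; dz <- z - fit$cz
    rho <- sqrt(dx^2 + dy^2 + dz^2)
    polar <- acos(pmax(-1, pmin(1, dz / rho))) * 180 / pi
    sel <- polar <= apex_angle
    if (sum(sel) < 12) break
    fit2 <- .algebraic_sphere(x[sel], y[sel], z[sel])
    if (is.null(fit2)) break
    fit <- fit2
    fit$n <- sum(sel)
  }
  R <- fit$R
  if (!is.finite(R) || R < R_limits[1] || R > R_limits[2])
    return(fail("fitted radius outside admissible range"))
  h <- fit$cz + R
  if (h <= 0) return(fail("apex below zero level"))
  h <- min(h, 2 * R)
  cap <- spherical_cap(R = R, h = h,
                       center = c(fit$cx, fit$cy, fit$cz))
  structure(list(ok = TRUE, cap = cap,
                 center = c(fit$cx, fit$cy, fit$cz),
                 residual = fit$residual, n_points = fit$n,
                 energies = total_energy(cap$A, cap$R, p),
                 seed = seed),
            class = "ccp_record")
}

#' @export
print.ccp_record <- function(x, ...) {
  if (!x$ok) {
    cat("CCP fit failed:", x$reason, "\n")
  } else {
    cat(sprintf("CCP: R = %.4g nm, h = %.4g nm, A = %.5g nm^2, theta = %.4g deg (residual %.3g nm, %d pts)\n",
                x$cap$R, x$cap$h, x$cap$A, x$cap$theta, x$residual, x$n_points))
    cat(sprintf("  E_total = %.5g kBT\n", x$energies$E_total))
  }
  invisible(x)
}

# linear least-squares sphere: x^2+y^2+z^2 + Dx + Ey + Fz + G = 0
.algebraic_sphere <- function(x, y, z) {
  M <- cbind(x, y, z, 1)
  b <- -(x^2 + y^2 + z^2)
  coef <- tryCatch(unname(qr.solve(M, b)), error = function(e) NULL)
  if (is.null(coef)) return(NULL)
  cx <- -coef[1] / 2; cy <- -coef[2] / 2; cz <- -coef[3] / 2
  R2 <- cx^2 + cy^2 + cz^2 - coef[4]
  if (!is.finite(R2) || R2 <= 0) return(NULL)
  R <- sqrt(R2)
  rho <- sqrt((x - cx)^2 + (y - cy)^2 + (z - cz)^2)
  list(cx = cx, cy = cy, cz = cz, R = R,
       residual = sqrt(mean((rho - R)^2)), n = length(x))
}

#' Detect and fit all pits in a topograph
#'
#' Batch driver: labels connected protrusions above
#' `zero_level + height_thresh`, seeds each blob at its highest pixel, and
#' runs [fit_sphere()] on every seed. Blobs smaller than `min_px` pixels are
#' skipped.
#'
#' @inheritParams fit_sphere
#' @param min_px minimum blob size in pixels; default 50.
#' @return List of `ccp_record`s (successful and failed).
#' @export
detect_ccps <- function(t, p = model_params(), height_thresh = 0.5,
                        min_px = 50, ...) {
  stopifnot(inherits(t, "topograph"))
  d <- dim(t$heights)
  mask <- t$heights > t$zero_level + height_thresh
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), d[1], d[2]))
  n <- max(lab)
  recs <- list()
  for (id in seq_len(n)) {
    px <- which(lab == id)
    if (length(px) < min_px) next
    top <- px[which.max(t$heights[px])]
    rc <- arrayInd(top, d)
    seed <- c((rc[1, 2] - 1) * t$pixel_size, (rc[1, 1] - 1) * t$pixel_size)
    recs[[length(recs) + 1L]] <-
      fit_sphere(t, seed, p, height_thresh = height_thresh, ...)
  }
  recs
}

#' Tabulate CCP records
#'
#' @param records list of `ccp_record`s (failed fits are dropped).
#' @return Data frame with columns `id`, `R_nm`, `h_nm`, `A_nm2`,
#'   `theta_deg`, `residual_nm`, `E_total_kBT`.
#' @export
records_table <- function(records) {
  records <- Filter(function(r) isTRUE(r$ok), records)
  if (length(records) == 0)
    return(data.frame(id = integer(0), R_nm = numeric(0), h_nm = numeric(0),
                      A_nm2 = numeric(0), theta_deg = numeric(0),
                      residual_nm = numeric(0), E_total_kBT = numeric(0)))
  data.frame(
    id = seq_along(records),
    R_nm = vapply(records, function(r) r$cap$R, numeric(1)),
    h_nm = vapply(records, function(r) r$cap$h, numeric(1)),
    A_nm2 = vapply(records, function(r) r$cap$A, numeric(1)),
    theta_deg = vapply(records, function(r) r$cap$theta, numeric(1)),
    residual_nm = vapply(records, function(r) r$residual, numeric(1)),
    E_total_kBT = vapply(records, function(r) r$energies$E_total, numeric(1))
  )
}
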