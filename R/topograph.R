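#' AFM topograph: a height map with physical pixel size
#'
#' Container for one HS-AFM height image. Heights are in nm; `zero_level` is
#' the background membrane height defining the base plane for cap heights and
#' areas (set by [level_background()]).
#'
#' @param heights numeric matrix of heights (nm), rows = y, cols = x; at
#'   least 16 x 16, all finite.
#' @param pixel_size physical pixel size (nm/pixel), > 0.
#' @param zero_level background height (nm); default 0.
#' @return An object of class `topograph`.
#' @export
topograph <- function(heights, pixel_size, zero_level = 0) {
  stopifnot(is.matrix(heights), is.numeric(heights))
  if (any(!is.finite(heights))) stop("heights must be finite")
  if (nrow(heights) < 16 || ncol(heights) < 16)
    stop("topograph must be at least 16 x 16 pixels")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  structure(list(heights = heights, pixel_size = pixel_size,
                 zero_level = zero_level),
            class = "topograph")
}

#' @export
print.topograph <- function(x, ...) {
  cat(sprintf("topograph: %d x %d px at %.3g nm/px (%.3g x %.3g nm), zero level %.3g nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              nrow(x$heights) * x$pixel_size, ncol(x$heights) * x$pixel_size,
              x$zero_level))
  cat(sprintf("  height range [%.3g, %.3g] nm\n", min(x$heights), max(x$heights)))
  invisible(x)
}

#' Read / write topographs
#'
#' A topograph is stored as either a 32-bit float TIFF plus a JSON sidecar
#' (`<file>.json`) or a plain CSV grid plus the same sidecar. The sidecar
#' holds `pixel_size_nm` and `zero_level_nm`; for TIFF it additionally holds
#' `height_offset_nm` and `height_scale_nm`, because float TIFF samples are
#' stored normalized to `[0, 1]` (`height = offset + scale * sample`). CSV
#' stores raw nm values.
#'
#' @param t a [topograph()].
#' @param path file path ending in `.tif`/`.tiff` or `.csv`.
#' @return `write_topograph` returns `path` invisibly; `read_topograph`
#'   returns a [topograph()].
#' @export
write_topograph <- function(t, path) {
  stopifnot(inherits(t, "topograph"))
  side <- list(pixel_size_nm = t$pixel_size, zero_level_nm = t$zero_level)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    off <- min(t$heights)
    sc <- max(t$heights) - off
    if (sc == 0) sc <- 1
    side$height_offset_nm <- off
    side$height_scale_nm <- sc
    tiff::writeTIFF((t$heights - off) / sc, path, bits.per.sample = 32,
                    reduce = FALSE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.table(t$heights, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported topograph format: ", path)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topograph
#' @export
read_topograph <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    h <- side$height_offset_nm + side$height_scale_nm * m
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    h <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(h) <- NULL
  } else stop("unsupported topograph format: ", path)
  topograph(h, side$pixel_size_nm, side$zero_level_nm)
}

#' Set the zero level from the background membrane
#'
#' Estimates the background membrane height as the median of the lowest
#' quartile of pixel heights — robust against the protruding pits, which
#' occupy the upper part of the height distribution — and stores it as the
#' topograph's `zero_level`. Heights themselves are unchanged.
#'
#' @param t a [topograph()].
#' @return The topograph with `zero_level` updated.
#' @export
level_background <- function(t) {
  stopifnot(inherits(t, "topograph"))
  q <- stats::quantile(t$heights, 0.25)
  low <- t$heights[t$heights <= q]
  t$zero_level <- stats::median(low)
  t
}

#' Align frames by integer-pixel translation
#'
#' Registers a sequence of topographs to the first frame by the integer
#' translation maximizing the cross-correlation of mean-subtracted heights
#' (computed via FFT). Shifted-in regions are filled with the frame's median
#' height. Intended for slow scanner drift between frames; sub-pixel and
#' affine motion are out of scope.
#'
#' @param frames list of [topograph()]s of identical dimensions.
#' @return List of aligned topographs, with attribute `shifts`: an n x 2
#'   integer matrix of applied (row, col) shifts.
#' @export
register_frames <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  lapply(frames, function(f) stopifnot(inherits(f, "topograph")))
  ref <- frames[[1]]$heights
  d <- dim(ref)
  Fref <- stats::fft(ref - mean(ref))
  shifts <- matrix(0L, length(frames), 2)
  out <- frames
  for (i in seq_along(frames)) {
    if (i == 1L) next
    cur <- frames[[i]]$heights
    if (!all(dim(cur) == d)) stop("all frames must share dimensions")
    cc <- Re(stats::fft(Fref * Conj(stats::fft(cur - mean(cur))),
                        inverse = TRUE))
    if (max(cc) - min(cc) < 1e-9 * max(abs(cc), 1)) {
      warning("featureless frame ", i, ": identity shift assumed")
      next
    }
    ij <- arrayInd(which.max(cc), d)
    sh <- ij - 1L
    sh <- ifelse(sh > d / 2, sh - d, sh)           # wrap to signed shift
    shifts[i, ] <- sh
    out[[i]]$heights <- .shift_matrix(cur, sh[1], sh[2],
                                      fill = stats::median(cur))
  }
  attr(out, "shifts") <- shifts
  out
}

.shift_matrix <- function(m, dr, dc, fill = 0) {
  d <- dim(m)
  res <- matrix(fill, d[1], d[2])
  src_r <- seq_len(d[1]) - dr
  src_c <- seq_len(d[2]) - dc
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  res[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  res
}

#' Height profile along a line section
#'
#' Samples the topograph along a straight segment at 1-pixel spacing using
#' bilinear interpolation, and attaches a local curvature estimate from
#' least-squares circle fits over a sliding window — the section analysis
#' used to read out pit curvature along a scan line.
#'
#' @param t a [topograph()].
#' @param from,to segment endpoints as `(x, y)` in nm (pixel-center
#'   convention: pixel `[i, j]` is at `x = (j-1)*pixel_size`,
#'   `y = (i-1)*pixel_size`).
#' @param window circle-fit window in samples (odd, >= 5); default 15.
#' @return Data frame with columns `s_nm` (arclength), `x_nm`, `y_nm`,
#'   `height_nm`, `radius_nm` (local fitted circle radius, signed: positive
#'   for a crest curving downwards on both sides, `Inf` where flat within
#'   tolerance), `curvature_inm` (= 1/radius).
#' @export
section_profile <- function(t, from, to, window = 15) {
  stopifnot(inherits(t, "topograph"), length(from) == 2, length(to) == 2)
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) stop("zero-length section")
  n <- max(2L, ceiling(len / t$pixel_size) + 1L)
  s <- seq(0, len, length.out = n)
  xs <- from[1] + (to[1] - from[1]) * s / len
  ys <- from[2] + (to[2] - from[2]) * s / len
  z <- .bilinear(t$heights, ys / t$pixel_size + 1, xs / t$pixel_size + 1)
  half <- max(2L, (as.integer(window) - 1L) %/% 2L)
  rad <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    if (hi - lo + 1 < 5) next
    rad[i] <- .circle_fit_radius(s[lo:hi], z[lo:hi])
  }
  data.frame(s_nm = s, x_nm = xs, y_nm = ys, height_nm = z,
             radius_nm = rad, curvature_inm = 1 / rad)
}

.bilinear <- function(m, r, c) {
  d <- dim(m)
  r <- pmin(pmax(r, 1), d[1]); c <- pmin(pmax(c, 1), d[2])
  r0 <- pmin(floor(r), d[1] - 1); c0 <- pmin(floor(c), d[2] - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# signed circle-fit radius of a 2D profile (s, z); positive = dome (concave
# down), Inf when essentially straight
.circle_fit_radius <- function(s, z) {
  s0 <- s - mean(s); z0 <- z - mean(z)
  # algebraic (Kasa) fit: s^2 + z^2 + D s + E z + G = 0
  M <- cbind(s0, z0, 1)
  b <- -(s0^2 + z0^2)
  sol <- tryCatch(qr.solve(M, b), error = function(e) NULL)
  if (is.null(sol)) return(Inf)
  cs <- -sol[1] / 2; cz <- -sol[2] / 2
  R2 <- cs^2 + cz^2 - sol[3]
  if (!is.finite(R2) || R2 <= 0) return(Inf)
  R <- sqrt(R2)
  if (R > 1e6) return(Inf)
  # dome if the circle center sits below the profile
  if (cz < 0) R else -R
}
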