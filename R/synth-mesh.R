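# Synthetic clathrin lattice meshes with known ground truth.
#
# Cap lattices are built by icosahedral geodesic subdivision of the sphere
# followed by polyhedral dualization: the dual is a hexagon-dominant mesh
# with exactly 12 pentagons on the closed sphere (Euler's formula), the
# canonical hexagon+pentagon architecture of clathrin cages. A seeded random
# rotation decorrelates pentagon placement from the cap axis, so partial
# caps carry on average 12 * (cap solid angle / 4pi) pentagons.

#' Build a hexagon-dominant clathrin lattice on a spherical cap
#'
#' Subdivides an icosahedron at the frequency matching the requested arm
#' (edge) length, projects to the sphere of the cap's radius, dualizes to a
#' hexagon/pentagon mesh (triskelion hubs are the degree-3 dual vertices),
#' applies a seeded random rotation, and keeps the faces whose centers lie on
#' the cap. The mesh is positioned like the cap: base plane z = 0, apex at
#' `z = h`.
#'
#' @param cap a [spherical_cap()].
#' @param edge_length target hub-hub arm length (nm), in `[10, 30]`
#'   (clathrin scale; `A_clath ~ 218 nm^2` implies roughly 18 nm); default
#'   18.
#' @param seed integer seed for the random orientation; default 1.
#' @return A [lattice_skeleton()] with extra attributes: `pentagon_count`,
#'   `cap`, `edge_length` (mean realized arm length, nm).
#' @examples
#' full <- spherical_cap(R = 40, h = 80)   # closed cage
#' mesh <- build_cap_lattice(full)
#' attr(mesh, "pentagon_count")            # exactly 12
#' @export
build_cap_lattice <- function(cap, edge_length = 18, seed = 1) {
  stopifnot(inherits(cap, "spherical_cap"))
  if (edge_length < 10 || edge_length > 30)
    stop("edge_length must be in [10, 30] nm (clathrin arm scale)")
  R <- cap$R
  # icosahedron edge = R * 4 / sqrt(10 + 2*sqrt(5)); triangulation edge
  # = icosa_edge / f; dual (hub-hub) edge = triangulation edge / sqrt(3)
  icosa_edge <- R * 4 / sqrt(10 + 2 * sqrt(5))
  f <- max(2L, as.integer(round(icosa_edge / (edge_length * sqrt(3)))))
  geo <- .geodesic_sphere(f)
  dual <- .dual_mesh(geo)
  rot <- .random_rotation(seed)
  dv <- dual$vertices %*% t(rot)
  fc <- dual$face_centers %*% t(rot)
  # cap region: polar angle from +z apex with cos >= 1 - h/R
  cos_cut <- 1 - cap$h / R
  keep_face <- fc[, 3] >= cos_cut * (1 - 1e-12)
  if (!any(keep_face)) stop("cap too small for a single lattice cell")
  faces <- dual$faces[keep_face]
  used <- sort(unique(unlist(faces)))
  remap <- integer(nrow(dv)); remap[used] <- seq_along(used)
  faces <- lapply(faces, function(fa) remap[fa])
  verts <- dv[used, , drop = FALSE] * R
  verts[, 3] <- verts[, 3] + (cap$h - R)       # sphere center at z = h - R
  edges <- unique(t(apply(do.call(rbind, lapply(faces, function(fa)
    cbind(fa, c(fa[-1], fa[1])))), 1, sort)))
  skel <- lattice_skeleton(verts, edges, faces)
  el <- sqrt(rowSums((verts[edges[, 1], , drop = FALSE] -
                      verts[edges[, 2], , drop = FALSE])^2))
  attr(skel, "pentagon_count") <- sum(lengths(faces) == 5L)
  attr(skel, "cap") <- cap
  attr(skel, "edge_length") <- mean(el)
  skel
}

# subdivided icosahedron on the unit sphere: vertices + triangles
.geodesic_sphere <- function(f) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (f == 1L) return(list(vertices = v, triangles = tri))
  verts <- list(); tris <- list()
  key_env <- new.env(hash = TRUE)
  get_idx <- function(p) {
    p <- round(p, 9)
    p[p == 0] <- 0                       # normalize -0
    key <- paste(sprintf("%.9f", p), collapse = ",")
    i <- key_env[[key]]
    if (is.null(i)) {
      verts[[length(verts) + 1L]] <<- p
      i <- length(verts)
      key_env[[key]] <- i
    }
    i
  }
  for (tr in seq_len(nrow(tri))) {
    a <- v[tri[tr, 1], ]; b <- v[tri[tr, 2], ]; c3 <- v[tri[tr, 3], ]
    # barycentric grid of (f+1)(f+2)/2 points, each projected to the sphere
    idx <- matrix(NA_integer_, f + 1, f + 1)
    for (i in 0:f) for (j in 0:(f - i)) {
      p <- (a * (f - i - j) + b * i + c3 * j) / f
      p <- p / sqrt(sum(p^2))
      idx[i + 1, j + 1] <- get_idx(p)
    }
    for (i in 0:(f - 1)) for (j in 0:(f - 1 - i)) {
      tris[[length(tris) + 1L]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 1],
                                     idx[i + 1, j + 2])
      if (j < f - 1 - i)
        tris[[length(tris) + 1L]] <- c(idx[i + 2, j + 1], idx[i + 2, j + 2],
                                       idx[i + 1, j + 2])
    }
  }
  list(vertices = do.call(rbind, verts), triangles = do.call(rbind, tris))
}

# polyhedral dual: one vertex per triangle (normalized centroid), one face
# per original vertex (adjacent triangles ordered around it)
.dual_mesh <- function(geo) {
  v <- geo$vertices; tri <- geo$triangles
  cent <- (v[tri[, 1], ] + v[tri[, 2], ] + v[tri[, 3], ]) / 3
  cent <- cent / sqrt(rowSums(cent^2))
  n <- nrow(v)
  inc <- vector("list", n)
  for (tr in seq_len(nrow(tri)))
    for (vv in tri[tr, ]) inc[[vv]] <- c(inc[[vv]], tr)
  faces <- vector("list", n)
  for (vv in seq_len(n)) {
    tl <- inc[[vv]]
    p <- v[vv, ]
    # order adjacent triangles by angle in the tangent plane at p
    ref <- if (abs(p[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * p) * p; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(p[2] * e1[3] - p[3] * e1[2],
            p[3] * e1[1] - p[1] * e1[3],
            p[1] * e1[2] - p[2] * e1[1])
    rel <- cent[tl, , drop = FALSE] - matrix(p, length(tl), 3, byrow = TRUE)
    ang <- atan2(rel %*% e2, rel %*% e1)
    faces[[vv]] <- tl[order(ang)]
  }
  list(vertices = cent, faces = faces, face_centers = v)
}

# deterministic uniform random rotation matrix from a seed
.random_rotation <- function(seed) {
  u <- .with_seed(seed, stats::runif(3))
  # Shoemake's method: uniform quaternion from three uniforms
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Flat honeycomb lattice patch
#'
#' A planar patch of regular hexagons (`rings` rings around a central
#' hexagon: 1, 7, 19, ... hexagons) with the given edge length, at z = 0.
#' Used as ground truth for flat-lattice fixtures.
#'
#' @param rings number of rings around the central hexagon; default 2
#'   (19 hexagons).
#' @param edge hexagon edge length (nm); default 18.
#' @return A [lattice_skeleton()] whose faces are all hexagons.
#' @export
hex_patch_mesh <- function(rings = 2, edge = 18) {
  centers <- list()
  for (q in -rings:rings) for (r in -rings:rings) {
    if (abs(q + r) > rings) next
    centers[[length(centers) + 1L]] <-
      c(edge * sqrt(3) * (q + r / 2), edge * 1.5 * r)
  }
  ang <- pi / 6 + (0:5) * pi / 3      # pointy-top hexagon corners
  verts <- list(); faces <- list()
  key_env <- new.env(hash = TRUE)
  get_idx <- function(p) {
    p <- round(p, 6)
    p[p == 0] <- 0                       # normalize -0
    key <- paste(sprintf("%.6f", p), collapse = ",")
    i <- key_env[[key]]
    if (is.null(i)) {
      verts[[length(verts) + 1L]] <<- p
      i <- length(verts)
      key_env[[key]] <- i
    }
    i
  }
  for (ce in centers) {
    fa <- vapply(ang, function(a)
      get_idx(c(ce[1] + edge * cos(a), ce[2] + edge * sin(a))), integer(1))
    faces[[length(faces) + 1L]] <- fa
  }
  v <- do.call(rbind, verts)
  v <- cbind(v, 0)
  edges <- unique(t(apply(do.call(rbind, lapply(faces, function(fa)
    cbind(fa, c(fa[-1], fa[1])))), 1, sort)))
  lattice_skeleton(v, edges, faces)
}
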