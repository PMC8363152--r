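# Clathrin-lattice ridge detection and 3D skeletonization.

#' Detect clathrin-lattice ridges in a topograph
#'
#' Produces a binary mask of lattice ridges: the topograph is high-pass
#' filtered (subtracting a Gaussian-smoothed copy) to remove the overall pit
#' topography, then pixels that are strict 1D local maxima of the high-pass
#' image along either image axis are selected. The peak test runs at three
#' samplings (1, 0.5, 0.25 by block-mean down-sampling) to also catch the
#' tops of flat, wide ridges, and the up-sampled masks are OR-combined.
#' Finally a morphological closing (`rounds` rounds of 3x3 dilation followed
#' by the same number of erosions) bridges single-pixel gaps left by missed
#' detections.
#'
#' @param t a leveled [topograph()].
#' @param sigma Gaussian high-pass scale in pixels (at each sampling);
#'   default 4.
#' @param samplings down-sampling factors; default `c(1, 0.5, 0.25)`.
#' @param rounds closing rounds; default 2.
#' @param min_prominence minimum high-pass height (nm) a peak must rise above
#'   its lower neighbors' mean to count; default 0.5, well above the pixel
#'   noise floor but a fraction of the ridge corrugation.
#' @return Integer matrix (0/1) of the topograph's dimensions.
#' @export
detect_lattice <- function(t, sigma = 4, samplings = c(1, 0.5, 0.25),
                           rounds = 2, min_prominence = 0.5) {
  stopifnot(inherits(t, "topograph"))
  h <- t$heights
  d <- dim(h)
  mask <- matrix(FALSE, d[1], d[2])
  for (s in samplings) {
    k <- as.integer(round(1 / s))
    hs <- if (k == 1L) h else .block_mean(h, k)
    if (min(dim(hs)) < 4 * sigma) next
    hp <- hs - EBImage::gblur(hs, sigma = sigma)
    pk <- .axis_peaks(hp, min_prominence)
    if (k > 1L) {
      pk_up <- matrix(FALSE, d[1], d[2])
      pk_big <- pk[rep(seq_len(nrow(pk)), each = k)[seq_len(min(d[1], nrow(pk) * k))],
                   rep(seq_len(ncol(pk)), each = k)[seq_len(min(d[2], ncol(pk) * k))],
                   drop = FALSE]
      pk_up[seq_len(nrow(pk_big)), seq_len(ncol(pk_big))] <- pk_big
      pk <- pk_up
    }
    mask <- mask | pk
  }
  m <- matrix(as.numeric(mask), d[1], d[2])
  if (rounds > 0) {
    br <- EBImage::makeBrush(3, shape = "box")
    for (i in seq_len(rounds)) m <- EBImage::dilate(m, br)
    for (i in seq_len(rounds)) m <- EBImage::erode(m, br)
  }
  matrix(as.integer(m > 0.5), d[1], d[2])
}

# strict 1D local maxima along rows or columns, with minimum prominence
.axis_peaks <- function(m, prom) {
  d <- dim(m)
  up <- rbind(m[-1, , drop = FALSE], rep(Inf, d[2]))   # border pixels are
  dn <- rbind(rep(Inf, d[2]), m[-d[1], , drop = FALSE]) # never peaks
  lf <- cbind(m[, -1, drop = FALSE], rep(Inf, d[1]))
  rt <- cbind(rep(Inf, d[1]), m[, -d[2], drop = FALSE])
  py <- (m > up) & (m > dn) & (m - (up + dn) / 2 > prom)
  px <- (m > lf) & (m > rt) & (m - (lf + rt) / 2 > prom)
  px | py
}

.block_mean <- function(m, k) {
  nr <- (nrow(m) %/% k) * k; nc <- (ncol(m) %/% k) * k
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  rr <- matrix(colMeans(matrix(m, nrow = k)), nrow = nr / k, byrow = FALSE)
  # rr has dim (nr/k, nc); now average columns in blocks of k
  t(matrix(colMeans(matrix(t(rr), nrow = k)), nrow = nc / k, byrow = FALSE))
}

# Zhang-Suen thinning of a binary matrix to a 1-pixel skeleton
.thin_mask <- function(mask) {
  img <- mask > 0
  pad <- function(x) {
    d <- dim(x)
    y <- matrix(FALSE, d[1] + 2, d[2] + 2)
    y[2:(d[1] + 1), 2:(d[2] + 1)] <- x
    y
  }
  p <- pad(img)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      d <- dim(p)
      i <- 2:(d[1] - 1); j <- 2:(d[2] - 1)
      P1 <- p[i, j]
      P2 <- p[i - 1, j];     P3 <- p[i - 1, j + 1]; P4 <- p[i, j + 1]
      P5 <- p[i + 1, j + 1]; P6 <- p[i + 1, j];     P7 <- p[i + 1, j - 1]
      P8 <- p[i, j - 1];     P9 <- p[i - 1, j - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (step == 1) {
        cond <- P1 & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- P1 & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        q <- p[i, j]; q[cond] <- FALSE; p[i, j] <- q
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- p[2:(nrow(p) - 1), 2:(ncol(p) - 1)]
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' Lattice skeleton: triskelion hubs, arms and polygon faces in 3D
#'
#' Container for the skeletonized clathrin lattice: `vertices` are 3D points
#' (nm) at triskelion hubs and arm endpoints, `edges` are hub-hub arms and
#' `faces` are the minimal polygon cycles (lattice polygons). Arm counts
#' follow the polymerization bookkeeping: `N_total` arms, of which
#' `N_open_arms` have a free (degree-1) end and
#' `N_poly_arms = N_total - N_open_arms` are polymerized.
#'
#' @param vertices numeric n x 3 matrix (nm).
#' @param edges integer m x 2 matrix of vertex indices.
#' @param faces list of integer vectors (cycles of length >= 3), may be
#'   empty.
#' @return An object of class `lattice_skeleton` with fields `vertices`,
#'   `edges`, `faces`, `degree`, `is_hub` (degree-3 vertices), `N_total`,
#'   `N_open_arms`, `N_poly_arms`.
#' @export
lattice_skeleton <- function(vertices, edges, faces = list()) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0)
    stopifnot(max(edges) <= nrow(vertices), min(edges) >= 1)
  for (f in faces) if (length(f) < 3) stop("faces must be cycles of length >= 3")
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(vertices))
  open_arm <- if (nrow(edges) > 0)
    deg[edges[, 1]] == 1L | deg[edges[, 2]] == 1L else logical(0)
  structure(list(vertices = vertices, edges = edges, faces = faces,
                 degree = deg, is_hub = deg == 3L,
                 N_total = nrow(edges),
                 N_open_arms = sum(open_arm),
                 N_poly_arms = nrow(edges) - sum(open_arm)),
            class = "lattice_skeleton")
}

#' @export
print.lattice_skeleton <- function(x, ...) {
  sizes <- lengths(x$faces)
  cat(sprintf("lattice skeleton: %d vertices (%d hubs), %d arms (%d open), %d faces\n",
              nrow(x$vertices), sum(x$is_hub), x$N_total, x$N_open_arms,
              length(x$faces)))
  if (length(sizes))
    cat("  face sizes:", paste(sprintf("%d-gon x %d", sort(unique(sizes)),
        tabulate(sizes)[sort(unique(sizes))]), collapse = ", "), "\n")
  invisible(x)
}

#' Skeleton JSON I/O
#'
#' Skeletons are serialized as JSON with fields `vertices` (n x 3, nm),
#' `edges` (m x 2, 1-based indices) and `faces` (list of index cycles).
#'
#' @param skel a [lattice_skeleton()].
#' @param path output path.
#' @return `write_skeleton` returns `path` invisibly; `read_skeleton` a
#'   [lattice_skeleton()].
#' @export
write_skeleton <- function(skel, path) {
  jsonlite::write_json(
    list(vertices = unname(as.matrix(skel$vertices)),
         edges = unname(as.matrix(skel$edges)),
         faces = lapply(skel$faces, as.integer)),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  faces <- j$faces
  if (is.matrix(faces)) faces <- lapply(seq_len(nrow(faces)), function(i) faces[i, ])
  lattice_skeleton(j$vertices, j$edges, as.list(faces))
}

#' Build a 3D lattice skeleton from a ridge mask
#'
#' Thins the ridge mask to a 1-pixel skeleton, identifies junction pixels
#' (>= 3 skeleton neighbors) and merges junctions closer than `merge_radius`
#' pixels into single nodes (AFM hub blobs span more than one pixel), traces
#' arms between nodes, and lifts nodes to 3D using the local height maximum
#' of the topograph. Faces are the minimal cycles of the planar-embedded
#' graph (the lattice polygons); the unbounded outer face is dropped.
#'
#' @param mask binary ridge mask from [detect_lattice()].
#' @param t the corresponding [topograph()] (for pixel size and heights).
#' @param merge_radius junction merge radius in pixels; default 2.
#' @param min_arm_px drop traced arms shorter than this many pixels (spur
#'   pruning); default 3.
#' @return A [lattice_skeleton()].
#' @export
build_skeleton <- function(mask, t, merge_radius = 2, min_arm_px = 3) {
  stopifnot(inherits(t, "topograph"))
  sk <- .thin_mask(mask)
  # pixel-level spur suppression: peel endpoint pixels so short noise
  # branches do not spawn spurious junctions (real arm tips shorten by up to
  # min_arm_px pixels)
  for (i in seq_len(min_arm_px)) {
    nbp <- .neighbor_count(sk)
    sk[sk == 1L & nbp <= 1L] <- 0L
  }
  d <- dim(sk)
  on <- which(sk == 1L)
  if (length(on) == 0)
    return(lattice_skeleton(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 2)))
  if (length(on) == 0)
    return(lattice_skeleton(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 2)))
  nb <- .neighbor_count(sk)
  # junctions by crossing number (number of distinct neighbor arcs), which
  # ignores staircase pixels of digitized diagonal lines
  tc <- .transition_count(sk)
  node_px <- which(sk == 1L & (tc >= 3L | nb == 1L))
  # a pure closed loop (e.g. an isolated polygon ridge) has neither
  # junctions nor endpoints: seed one node arbitrarily; corner splitting
  # recovers its vertices
  if (length(node_px) == 0) node_px <- on[1]
  # cluster junction/end pixels within merge_radius
  rc <- arrayInd(node_px, d)
  clus <- .cluster_points(rc, merge_radius)
  n_nodes <- max(clus)
  node_rc <- t(vapply(seq_len(n_nodes), function(k)
    colMeans(rc[clus == k, , drop = FALSE]), numeric(2)))
  # map each node pixel to its cluster id
  px2node <- integer(prod(d))
  px2node[node_px] <- clus
  paths <- .branch_paths(sk, px2node, d)
  if (length(paths) == 0)
    return(lattice_skeleton(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 2)))
  sc <- .split_corners(paths, node_rc, d)
  paths <- sc$paths
  node_rc <- sc$node_rc
  n_nodes <- nrow(node_rc)
  em <- do.call(rbind, lapply(paths, function(p)
    c(p$a, p$b, length(p$px) - 1L)))
  # deduplicate parallel arms and drop self-loops for the graph/face analysis
  key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  keep <- !duplicated(key) & em[, 1] != em[, 2]
  em <- em[keep, , drop = FALSE]
  # prune short spurs: arms shorter than min_arm_px ending at a free node
  repeat {
    if (nrow(em) == 0) break
    deg <- tabulate(c(em[, 1], em[, 2]), nbins = n_nodes)
    spur <- (deg[em[, 1]] == 1L | deg[em[, 2]] == 1L) & em[, 3] < 2 * min_arm_px
    if (!any(spur)) break
    em <- em[!spur, , drop = FALSE]
  }
  if (nrow(em) == 0)
    return(lattice_skeleton(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 2)))
  em <- em[, 1:2, drop = FALSE]
  # splice out degree-2 pass-through nodes (arms continuing nearly straight,
  # an artifact of junction detection) so arm cycles equal true polygon
  # sizes; genuine lattice corners (arm-arm angle near 120 deg) are kept
  repeat {
    deg <- tabulate(c(em[, 1], em[, 2]), nbins = n_nodes)
    v2 <- which(deg == 2L)
    changed <- FALSE
    for (v in v2) {
      ei <- which(em[, 1] == v | em[, 2] == v)
      if (length(ei) != 2L) next
      nb <- setdiff(as.vector(em[ei, ]), v)
      if (length(nb) != 2L) next                      # self-loop-ish; skip
      u1 <- node_rc[nb[1], ] - node_rc[v, ]
      u2 <- node_rc[nb[2], ] - node_rc[v, ]
      ang <- acos(max(-1, min(1, sum(u1 * u2) /
                                sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
      if (ang < 150) next                             # a real lattice corner
      if (any((em[, 1] == nb[1] & em[, 2] == nb[2]) |
              (em[, 1] == nb[2] & em[, 2] == nb[1]))) next
      em <- em[-ei, , drop = FALSE]
      em <- rbind(em, nb)
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  used <- sort(unique(as.vector(em)))
  remap <- integer(n_nodes); remap[used] <- seq_along(used)
  em <- cbind(remap[em[, 1]], remap[em[, 2]])
  node_rc <- node_rc[used, , drop = FALSE]
  # 3D positions: x = (col-1)*px, y = (row-1)*px, z = local height max
  z <- vapply(seq_len(nrow(node_rc)), function(i) {
    r <- round(node_rc[i, 1]); c <- round(node_rc[i, 2])
    rs <- max(1, r - 1):min(d[1], r + 1)
    cs <- max(1, c - 1):min(d[2], c + 1)
    max(t$heights[rs, cs]) - t$zero_level
  }, numeric(1))
  verts <- cbind((node_rc[, 2] - 1) * t$pixel_size,
                 (node_rc[, 1] - 1) * t$pixel_size, z)
  faces <- .planar_faces(verts[, 1:2, drop = FALSE], em)
  lattice_skeleton(verts, em, faces)
}

# number of 0->1 transitions in the circular 8-neighborhood sequence
.transition_count <- function(sk) {
  d <- dim(sk)
  p <- matrix(0L, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- sk
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1)
  ring <- list(
    p[i - 1, j], p[i - 1, j + 1], p[i, j + 1], p[i + 1, j + 1],
    p[i + 1, j], p[i + 1, j - 1], p[i, j - 1], p[i - 1, j - 1])
  s <- matrix(0L, d[1], d[2])
  for (k in 1:8) {
    a <- ring[[k]]; b <- ring[[if (k == 8) 1 else k + 1]]
    s <- s + ((a == 0L) & (b == 1L))
  }
  s
}

.neighbor_count <- function(sk) {
  d <- dim(sk)
  p <- matrix(0L, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- sk
  s <- matrix(0L, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + p[(2 + dr):(d[1] + 1 + dr), (2 + dc):(d[2] + 1 + dc)]
  }
  s
}

# single-linkage clustering of pixel coordinates within radius r
.cluster_points <- function(rc, r) {
  n <- nrow(rc)
  if (n == 1) return(1L)
  dm <- as.matrix(stats::dist(rc))
  adj <- dm <= r
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

# arm extraction via branch components: non-node skeleton pixels are
# labeled into 8-connected components; each component is one arm joining
# the node clusters adjacent to its two ends. Returns list of
# (a, b, px = ordered pixel index sequence).
.branch_paths <- function(sk, px2node, d) {
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  branch <- which(sk == 1L & px2node == 0L)
  if (length(branch) == 0) return(list())
  bset <- logical(prod(d)); bset[branch] <- TRUE
  nset <- px2node > 0L
  # 8-adjacency edges among branch pixels; adjacency is severed when the
  # two pixels flank a common node pixel (arms must break at junctions even
  # though their end pixels touch diagonally around the junction pixel)
  rc <- arrayInd(branch, d)
  pos <- integer(prod(d)); pos[branch] <- seq_along(branch)
  common_offsets <- function(a, b) {
    if (a != 0 && b != 0) list(c(a, 0), c(0, b))
    else if (a == 0) list(c(1, 0), c(-1, 0), c(1, b), c(-1, b))
    else list(c(0, 1), c(0, -1), c(a, 1), c(a, -1))
  }
  pe <- list()
  for (k in 1:8) {
    r2 <- rc[, 1] + offs[k, 1]; c2 <- rc[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= d[1] & c2 >= 1 & c2 <= d[2]
    nb_idx <- (c2[ok] - 1L) * d[1] + r2[ok]
    sel <- bset[nb_idx]
    i1 <- which(ok)[sel]
    if (length(i1) == 0) next
    blocked <- logical(length(i1))
    for (co in common_offsets(offs[k, 1], offs[k, 2])) {
      r3 <- rc[i1, 1] + co[1]; c3 <- rc[i1, 2] + co[2]
      inb <- r3 >= 1 & r3 <= d[1] & c3 >= 1 & c3 <= d[2]
      q <- (c3[inb] - 1L) * d[1] + r3[inb]
      bl <- logical(length(i1)); bl[inb] <- nset[q]
      blocked <- blocked | bl
    }
    keep2 <- !blocked
    pe[[length(pe) + 1L]] <- cbind(i1[keep2], pos[nb_idx[sel]][keep2])
  }
  pe <- do.call(rbind, pe)
  g <- igraph::make_empty_graph(n = length(branch), directed = FALSE)
  if (nrow(pe) > 0) g <- igraph::add_edges(g, t(pe[pe[, 1] < pe[, 2], ,
                                                   drop = FALSE]))
  memb <- igraph::components(g)$membership
  node_neighbors <- function(px) {
    r0 <- (px - 1L) %% d[1] + 1L; c0 <- (px - 1L) %/% d[1] + 1L
    out <- integer(0)
    for (k in 1:8) {
      r2 <- r0 + offs[k, 1]; c2 <- c0 + offs[k, 2]
      if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
      q <- (c2 - 1L) * d[1] + r2
      if (px2node[q] > 0L) out <- c(out, q)
    }
    out
  }
  paths <- list()
  for (comp in seq_len(max(memb))) {
    px <- branch[memb == comp]
    ordered <- .order_branch(px, d)
    a_px <- node_neighbors(ordered[1])
    b_px <- node_neighbors(ordered[length(ordered)])
    if (length(a_px) == 0 && length(b_px) == 0) next  # floating loop: handled upstream
    if (length(a_px) == 0 || length(b_px) == 0) next  # dangling nub
    paths[[length(paths) + 1L]] <-
      list(a = px2node[a_px[1]], b = px2node[b_px[1]],
           px = c(a_px[1], ordered, b_px[1]))
  }
  paths
}

# order a branch component's pixels along the path by greedy nearest
# unvisited walking from an end pixel (fewest in-component neighbors)
.order_branch <- function(px, d) {
  n <- length(px)
  if (n <= 2) return(px)
  rc <- arrayInd(px, d)
  dm <- as.matrix(stats::dist(rc))
  adj <- dm <= sqrt(2) + 1e-9
  diag(adj) <- FALSE
  start <- which.min(rowSums(adj))
  visited <- logical(n)
  ord <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    ord[i] <- cur
    visited[cur] <- TRUE
    cand <- which(adj[cur, ] & !visited)
    if (length(cand) == 0) {
      rest <- which(!visited)
      if (length(rest) == 0) break
      cand <- rest[which.min(dm[cur, rest])]
    }
    cur <- cand[which.min(dm[cur, cand])[1]]
  }
  px[ord[ord > 0]]
}

# split arm paths at strong corners: a lattice vertex whose third arm is
# missing (patch boundary) leaves only a bend in the traced path; a new node
# is inserted at the point of maximal perpendicular deviation from the chord
.split_corners <- function(paths, node_rc, d, dev_thresh = 2.2) {
  queue <- paths
  out <- list()
  while (length(queue) > 0) {
    pth <- queue[[1]]; queue <- queue[-1]
    rc <- arrayInd(pth$px, d)
    n <- nrow(rc)
    if (n < 7) { out[[length(out) + 1L]] <- pth; next }
    a <- rc[1, ]; b <- rc[n, ]
    ch <- b - a
    L <- sqrt(sum(ch^2))
    inner <- 3:(n - 2)
    dev <- if (L < 1e-9) {
      sqrt(rowSums((rc[inner, , drop = FALSE] -
                      matrix(a, length(inner), 2, byrow = TRUE))^2))
    } else {
      abs((rc[inner, 1] - a[1]) * ch[2] - (rc[inner, 2] - a[2]) * ch[1]) / L
    }
    if (max(dev) <= dev_thresh) { out[[length(out) + 1L]] <- pth; next }
    k <- inner[which.max(dev)]
    new_id <- nrow(node_rc) + 1L
    node_rc <- rbind(node_rc, rc[k, ])
    queue <- c(queue,
               list(list(a = pth$a, b = new_id, px = pth$px[1:k]),
                    list(a = new_id, b = pth$b, px = pth$px[k:n])))
  }
  list(paths = out, node_rc = node_rc)
}

# faces of a planar straight-line graph via the rotation system; drops the
# outer face (largest absolute signed area)
.planar_faces <- function(xy, edges) {
  n <- nrow(xy)
  if (nrow(edges) == 0) return(list())
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb)) {
      ang <- atan2(xy[nb, 2] - xy[v, 2], xy[nb, 1] - xy[v, 1])
      adj[[v]] <- nb[order(ang)]
    }
  }
  visited <- new.env(hash = TRUE)
  faces <- list()
  for (i in seq_len(nrow(edges))) for (dir in 1:2) {
    u <- edges[i, dir]; v <- edges[i, 3 - dir]
    if (!is.null(visited[[paste(u, v)]])) next
    cyc <- integer(0); cu <- u; cv <- v
    repeat {
      visited[[paste(cu, cv)]] <- TRUE
      cyc <- c(cyc, cu)
      nb <- adj[[cv]]
      pos <- match(cu, nb)
      nxt <- nb[(pos %% length(nb)) + 1L]   # next neighbor ccw after cu
      cu <- cv; cv <- nxt
      if (cu == u && cv == v) break
      if (length(cyc) > 10 * nrow(edges)) break
    }
    if (length(cyc) >= 3 && !anyDuplicated(cyc))
      faces[[length(faces) + 1L]] <- cyc
  }
  if (length(faces) == 0) return(list())
  sarea <- vapply(faces, function(f) {
    x <- xy[f, 1]; y <- xy[f, 2]
    0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  }, numeric(1))
  # interior faces share one orientation; the outer face has the opposite
  # orientation (and, when both orientations occur, the largest magnitude)
  pos <- sum(sarea > 0); neg <- sum(sarea < 0)
  if (pos > 0 && neg > 0) {
    minority <- if (pos < neg) sarea > 0 else if (neg < pos) sarea < 0 else
      seq_along(sarea) == which.max(abs(sarea))
    faces <- faces[!minority]
  } else if (length(faces) > 1) {
    faces <- faces[-which.max(abs(sarea))]
  }
  faces
}
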