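#' Build a hemisphere object from NSC coordinates
#'
#' Represents the discrete support of the analysis: the positions of all
#' neural stem cells (NSCs) on the ventricular surface, a Delaunay
#' triangulation over them, and the surface area obtained as the sum of all
#' triangle areas. Events (cells in S-phase) can only occur at these
#' positions, which is what makes the Ripley's K statistics "discrete".
#'
#' Coordinates are projected onto the best-fitting plane (principal
#' components) before triangulation; triangle areas are computed from the
#' original 3D positions, so a curved cell sheet is measured along the
#' surface. Exactly planar inputs reduce to the ordinary planar Delaunay
#' triangulation of the points.
#'
#' @param coords numeric matrix with one row per NSC and 2 or 3 columns
#'   (x, y\[, z\] positions in micrometres). At least 3 non-collinear points.
#' @param id character identifier for the hemisphere.
#' @return An object of class `"hemisphere"`: a list with elements `id`,
#'   `coords` (N x 3 matrix), `tri` (triangle vertex indices, M x 3),
#'   `area` (sum of triangle areas, square micrometres), `flat` (logical),
#'   `proj` (N x 2 planar projection), `hull` (indices of the convex hull of
#'   the projection, counter-clockwise) and `boundary_edges` (B x 2 indices).
#' @examples
#' sq <- hemisphere(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' sq$area  # 10000
#' @export
hemisphere <- function(coords, id = "hemisphere") {
  coords <- as.matrix(coords)
  if (ncol(coords) == 2) coords <- cbind(coords, 0)
  dimnames(coords) <- NULL
  .assert(ncol(coords) == 3, "coords must have 2 or 3 columns")
  .assert(nrow(coords) >= 3, "at least 3 points are required")
  .assert(all(is.finite(coords)), "all coordinates must be finite")
  if (anyDuplicated(coords) > 0)
    stop("duplicate coordinates at rows: ",
         paste(which(duplicated(coords)), collapse = ", "), call. = FALSE)
  n <- nrow(coords)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  sv <- svd(cc)
  scale0 <- max(sv$d[1], 1e-12)
  if (sv$d[2] / scale0 < 1e-9)
    stop("points are collinear; a surface cannot be triangulated",
         call. = FALSE)
  flat <- sv$d[3] / scale0 < 1e-7
  basis <- sv$v[, 1:2, drop = FALSE]
  normal <- sv$v[, 3]
  proj <- cc %*% basis

  dd <- deldir::deldir(proj[, 1], proj[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  tri <- t(vapply(tl, function(t) as.integer(t$ptNum), integer(3)))
  .assert(all(seq_len(n) %in% tri),
          "triangulation does not cover every cell")

  a <- coords[tri[, 1], , drop = FALSE]
  b <- coords[tri[, 2], , drop = FALSE]
  cpt <- coords[tri[, 3], , drop = FALSE]
  u <- b - a
  v <- cpt - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  tri_areas <- 0.5 * sqrt(rowSums(cr^2))
  area <- sum(tri_areas)
  .assert(area > 0, "degenerate triangulation: zero area")

  hull <- grDevices::chull(proj)
  # normalize hull orientation to counter-clockwise
  hx <- proj[hull, 1]; hy <- proj[hull, 2]
  signed <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (signed < 0) hull <- rev(hull)

  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  key <- paste(edges[, 1], edges[, 2])
  cnt <- table(key)
  uniq <- !duplicated(key)
  uedges <- edges[uniq, , drop = FALSE]
  boundary <- uedges[cnt[key[uniq]] == 1L, , drop = FALSE]

  structure(list(id = id, coords = coords, tri = tri, area = area,
                 flat = flat, proj = proj, basis = basis, normal = normal,
                 center = ctr, hull = hull, edges = uedges,
                 boundary_edges = boundary, tri_areas = tri_areas),
            class = "hemisphere")
}

#' @export
print.hemisphere <- function(x, ...) {
  cat(sprintf("hemisphere '%s': %d NSCs, %d triangles, area %.1f um^2%s\n",
              x$id, nrow(x$coords), nrow(x$tri), x$area,
              if (x$flat) " (flat)" else ""))
  invisible(x)
}

#' Number of NSCs in a hemisphere
#' @param h a `hemisphere`.
#' @return integer cell count.
#' @export
n_cells <- function(h) nrow(h$coords)

#' Pairwise distances between NSCs
#'
#' Geodesic distances are shortest paths restricted to the edges of the
#' triangulated mesh, with each edge weighted by its straight-line 3D
#' length; this accounts for the bending of the hemisphere surface. For
#' flat inputs the mesh lies in a plane and geodesic distances reduce to
#' planar Euclidean distances, which are returned directly.
#'
#' @param h a `hemisphere`.
#' @param metric `"geodesic"` (along the mesh) or `"euclidean"`
#'   (straight-line 3D distance).
#' @return Object of class `"nsc_distmat"`: list with `entries` (N x N
#'   symmetric matrix, micrometres) and `metric`.
#' @export
distance_matrix <- function(h, metric = c("geodesic", "euclidean")) {
  metric <- match.arg(metric)
  .assert(inherits(h, "hemisphere"), "h must be a hemisphere")
  n <- n_cells(h)
  if (metric == "euclidean" || h$flat) {
    entries <- as.matrix(stats::dist(h$coords))
  } else {
    e <- h$edges
    w <- sqrt(rowSums((h$coords[e[, 1], , drop = FALSE] -
                         h$coords[e[, 2], , drop = FALSE])^2))
    g <- igraph::make_graph(t(e), n = n, directed = FALSE)
    comp <- igraph::components(g)
    if (comp$no > 1) {
      sizes <- paste(comp$csize, collapse = ", ")
      stop("mesh is disconnected (", comp$no,
           " components with sizes ", sizes, ")", call. = FALSE)
    }
    entries <- igraph::distances(g, weights = w)
  }
  dimnames(entries) <- NULL
  diag(entries) <- 0
  structure(list(entries = entries, metric = metric), class = "nsc_distmat")
}

#' @export
print.nsc_distmat <- function(x, ...) {
  cat(sprintf("%s distance matrix for %d cells\n", x$metric,
              nrow(x$entries)))
  invisible(x)
}

# accept either an nsc_distmat or a plain matrix
.dist_entries <- function(d) {
  if (inherits(d, "nsc_distmat")) d$entries else as.matrix(d)
}

# straight-line distances from rows of a (m x 3) to rows of b (n x 3)
.cross_dist <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    out[i, ] <- sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 +
                       (b[, 3] - a[i, 3])^2)
  }
  out
}

# ---- edge correction ------------------------------------------------------

# squared distance from points P (m x k) to segment [a, b]
.point_seg_dist2 <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  Pa <- sweep(P, 2, a)
  t <- if (len2 > 0) pmin(1, pmax(0, drop(Pa %*% ab) / len2)) else 0
  d <- Pa - outer(t, ab)
  rowSums(d^2)
}

# distance from points P (m x 2/3) to a polyline given as segment index pairs
.boundary_dist <- function(P, coords, segs) {
  best <- rep(Inf, nrow(P))
  for (k in seq_len(nrow(segs))) {
    d2 <- .point_seg_dist2(P, coords[segs[k, 1], ], coords[segs[k, 2], ])
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# are points (m x 2) inside the convex polygon poly (h x 2, CCW)?
.in_convex <- function(P, poly) {
  h <- nrow(poly)
  ok <- rep(TRUE, nrow(P))
  for (k in seq_len(h)) {
    a <- poly[k, ]
    b <- poly[if (k == h) 1L else k + 1L, ]
    cr <- (b[1] - a[1]) * (P[, 2] - a[2]) - (b[2] - a[2]) * (P[, 1] - a[1])
    ok <- ok & (cr >= -1e-9)
    if (!any(ok)) break
  }
  ok
}

# distance from points P (m x 3) to triangle (a, b, c), vectorized over P
.point_tri_dist <- function(P, a, b, c) {
  # project onto triangle plane, clamp into triangle via barycentric regions;
  # fall back to edge distances outside
  n <- pracma_cross(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) { # degenerate triangle: use longest edge
    return(sqrt(.point_seg_dist2(P, a, b)))
  }
  n <- n / nn
  Pa <- sweep(P, 2, a)
  dist_plane <- drop(Pa %*% n)
  Q <- P - outer(dist_plane, n) # projections onto the plane
  # barycentric coordinates of Q
  v0 <- b - a; v1 <- c - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  Qa <- sweep(Q, 2, a)
  d20 <- drop(Qa %*% v0); d21 <- drop(Qa %*% v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  inside <- v >= 0 & w >= 0 & (v + w) <= 1
  out <- abs(dist_plane)
  if (!all(inside)) {
    Pe <- P[!inside, , drop = FALSE]
    e2 <- pmin(.point_seg_dist2(Pe, a, b),
               .point_seg_dist2(Pe, b, c),
               .point_seg_dist2(Pe, c, a))
    out[!inside] <- sqrt(e2)
  }
  out
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# outward-consistent vertex normal from incident triangles
.vertex_normal <- function(h, i) {
  inc <- which(h$tri[, 1] == i | h$tri[, 2] == i | h$tri[, 3] == i)
  acc <- c(0, 0, 0)
  for (t in inc) {
    a <- h$coords[h$tri[t, 1], ]
    b <- h$coords[h$tri[t, 2], ]
    cc <- h$coords[h$tri[t, 3], ]
    nrm <- pracma_cross(b - a, cc - a)
    if (sum(nrm * h$normal) < 0) nrm <- -nrm
    acc <- acc + nrm
  }
  acc / sqrt(sum(acc^2))
}

#' Disc edge-correction weight
#'
#' Fraction of the disc of radius `r` around a cell that lies inside the
#' hemisphere. Cells whose disc does not cut the hemisphere edge get weight
#' 1; for boundary cells the inside fraction is estimated from a
#' deterministic low-discrepancy set of sample points on the disc
#' (a golden-angle spiral), classified inside/outside against the mesh.
#' For planar hemispheres the classification is an exact point-in-convex-hull
#' test; for curved meshes the disc is placed on the tangent plane and a
#' sample point counts as outside when its nearest point on the mesh lies on
#' the mesh boundary.
#'
#' @param h a `hemisphere`.
#' @param cell cell index.
#' @param r disc radius in micrometres (> 0).
#' @param n_points number of disc sample points.
#' @return weight in (0, 1].
#' @export
edge_correction <- function(h, cell, r, n_points = 256L) {
  .assert(length(r) == 1 && is.finite(r) && r > 0, "r must be positive")
  .assert(cell >= 1 && cell <= n_cells(h), "invalid cell index")
  drop(edge_weights(h, cell, r, n_points))
}

#' Edge-correction weights for several cells and radii
#'
#' Batch version of [edge_correction()]; weights depend only on the cell
#' and the radius, so they can be computed once per hemisphere and reused
#' across resampling envelopes.
#'
#' @inheritParams edge_correction
#' @param cells integer vector of cell indices.
#' @param radii numeric vector of radii (micrometres).
#' @return matrix `length(cells)` x `length(radii)` of weights in (0, 1].
#' @export
edge_weights <- function(h, cells, radii, n_points = 256L) {
  .assert(all(radii > 0), "r must be positive")
  disc <- .disc_points(n_points)
  w <- matrix(1, length(cells), length(radii))
  if (h$flat) {
    poly <- h$proj[h$hull, , drop = FALSE]
    segs <- cbind(seq_along(h$hull),
                  c(seq_along(h$hull)[-1], 1L))
    bdist <- .boundary_dist(h$proj[cells, , drop = FALSE],
                            poly, segs)
    for (ci in seq_along(cells)) {
      need <- which(radii > bdist[ci])
      if (!length(need)) next
      ctr <- h$proj[cells[ci], ]
      pts <- do.call(rbind, lapply(radii[need], function(r)
        cbind(ctr[1] + r * disc[, 1], ctr[2] + r * disc[, 2])))
      ins <- .in_convex(pts, poly)
      w[ci, need] <- colMeans(matrix(ins, nrow = n_points))
    }
    return(w)
  }
  # curved mesh: tangent-plane disc, classified by nearest mesh feature
  maxedge <- max(sqrt(rowSums((h$coords[h$edges[, 1], , drop = FALSE] -
                                 h$coords[h$edges[, 2], , drop = FALSE])^2)))
  bsegs <- h$boundary_edges
  for (ci in seq_along(cells)) {
    i <- cells[ci]
    nrm <- .vertex_normal(h, i)
    e1 <- pracma_cross(nrm, if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- pracma_cross(nrm, e1)
    euc <- sqrt(colSums((t(h$coords) - h$coords[i, ])^2))
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      pts <- matrix(h$coords[i, ], n_points, 3, byrow = TRUE) +
        r * (disc[, 1] %o% e1 + disc[, 2] %o% e2)
      db <- .boundary_dist(pts, h$coords, bsegs)
      near <- which(euc <= r + 2 * maxedge)
      keep <- h$tri[h$tri[, 1] %in% near | h$tri[, 2] %in% near |
                      h$tri[, 3] %in% near, , drop = FALSE]
      dm <- rep(Inf, n_points)
      for (t in seq_len(nrow(keep))) {
        dm <- pmin(dm, .point_tri_dist(pts,
                                       h$coords[keep[t, 1], ],
                                       h$coords[keep[t, 2], ],
                                       h$coords[keep[t, 3], ]))
      }
      inside <- db > dm + 1e-9 * max(1, r)
      w[ci, ri] <- max(mean(inside), 1 / n_points)
    }
  }
  w
}
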