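# 3D Delaunay triangulation (incremental Bowyer-Watson), alpha-shape
# surface extraction, Loop subdivision and surface sampling. Written in
# plain R; intended for point clouds of a few hundred to a few thousand
# aligned spots, where an O(n * tets) incremental insertion is fast enough.

# Circumsphere (centre, squared radius) of a tetrahedron. Returns NULL for
# degenerate (near-coplanar) tetrahedra.
circumsphere <- function(P) {
  A <- 2 * rbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ])
  if (abs(det(A)) < 1e-12 * max(abs(A))^3) return(NULL)
  b <- c(sum(P[2, ]^2) - sum(P[1, ]^2),
         sum(P[3, ]^2) - sum(P[1, ]^2),
         sum(P[4, ]^2) - sum(P[1, ]^2))
  ctr <- solve(A, b)
  list(center = ctr, r2 = sum((P[1, ] - ctr)^2))
}

# Deterministic sub-micron jitter to break cospherical degeneracies
# (e.g. grid-arranged spots); amplitude relative to the cloud extent.
symmetry_jitter <- function(pts, rel = 1e-6) {
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  n <- nrow(pts)
  h <- outer(seq_len(n), 1:3, function(i, d)
    sin(i * 12.9898 + d * 78.233) * 43758.5453)
  pts + (h - floor(h) - 0.5) * rel * scale
}

# Incremental 3D Delaunay. Returns a matrix of tetrahedra (rows of 4 point
# indices) and their squared circumradii.
delaunay3d <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 4)
  ctr <- colMeans(pts)
  span <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) * 50 + 1
  super <- rbind(ctr + c(0, 0, 3 * span),
                 ctr + c(-2 * span, -span, -span),
                 ctr + c(2 * span, -span, -span),
                 ctr + c(0, 2 * span, -span))
  P <- rbind(super, pts)
  tets <- matrix(1:4, 1, 4)
  cs <- circumsphere(P[1:4, ])
  centers <- matrix(cs$center, 1, 3)
  r2s <- cs$r2
  for (ip in 5:(n + 4)) {
    p <- P[ip, ]
    d2 <- rowSums(sweep(centers, 2, p)^2)
    bad <- which(d2 < r2s * (1 + 1e-10))
    if (length(bad) == 0) bad <- which.min(d2 - r2s)  # numeric fallback
    faces <- do.call(rbind, lapply(bad, function(t) {
      v <- tets[t, ]
      rbind(v[-1], v[-2], v[-3], v[-4])
    }))
    key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
    keep_face <- key %in% names(which(table(key) == 1))
    faces <- faces[keep_face, , drop = FALSE]
    tets <- tets[-bad, , drop = FALSE]
    centers <- centers[-bad, , drop = FALSE]
    r2s <- r2s[-bad]
    for (fi in seq_len(nrow(faces))) {
      tet <- c(faces[fi, ], ip)
      cs <- circumsphere(P[tet, ])
      if (is.null(cs)) next
      tets <- rbind(tets, tet)
      centers <- rbind(centers, cs$center)
      r2s <- c(r2s, cs$r2)
    }
  }
  keep <- rowSums(tets <= 4) == 0
  list(tets = tets[keep, , drop = FALSE] - 4L, r2 = r2s[keep],
       points = pts)
}

#' Alpha-shape surface mesh of a 3D point cloud
#'
#' Computes the Delaunay tetrahedralization of the (deterministically
#' micro-jittered) points, keeps tetrahedra whose circumradius is below
#' `alpha`, and extracts the boundary triangles (faces incident to exactly
#' one kept tetrahedron). In the large-`alpha` limit this is the convex
#' hull. The surface is then smoothed by `subdivisions` rounds of Loop
#' subdivision, each of which quadruples the face count.
#'
#' @param coords3d n x 3 point matrix (micrometres), n >= 4, not coplanar.
#' @param alpha circumradius threshold in the coordinate units; `Inf` gives
#'   the convex hull.
#' @param subdivisions Loop subdivision rounds (0 leaves the mesh as
#'   extracted).
#' @return Object of class `mesh3d_manifold`: `vertices` (m x 3), `faces`
#'   (f x 3 vertex indices), `watertight` (TRUE when every edge borders
#'   exactly two faces).
#' @export
build_mesh <- function(coords3d, alpha = Inf, subdivisions = 0) {
  coords3d <- as.matrix(coords3d)
  if (nrow(coords3d) < 4) stop("need at least 4 points")
  sv <- svd(sweep(coords3d, 2, colMeans(coords3d)))$d
  if (sv[3] < 1e-9 * sv[1]) {
    stop("degenerate (coplanar) point cloud; consider a 2.5D treatment")
  }
  pts <- symmetry_jitter(coords3d)
  dt <- delaunay3d(pts)
  keep <- sqrt(dt$r2) < alpha
  if (!any(keep)) stop("alpha too small: no tetrahedra retained")
  tets <- dt$tets[keep, , drop = FALSE]
  faces <- do.call(rbind, lapply(seq_len(nrow(tets)), function(t) {
    v <- tets[t, ]
    rbind(sort(v[-1]), sort(v[-2]), sort(v[-3]), sort(v[-4]))
  }))
  key <- apply(faces, 1, paste, collapse = "-")
  boundary <- faces[key %in% names(which(table(key) == 1)), , drop = FALSE]
  used <- sort(unique(as.vector(boundary)))
  remap <- match(boundary, used)
  mesh <- structure(list(vertices = coords3d[used, , drop = FALSE],
                         faces = matrix(remap, ncol = 3)),
                    class = "mesh3d_manifold")
  mesh$watertight <- is_watertight(mesh)
  if (subdivisions > 0) {
    for (i in seq_len(subdivisions)) mesh <- loop_subdivide(mesh)
  }
  mesh
}

is_watertight <- function(mesh) {
  ek <- edge_keys(mesh$faces)
  all(table(ek) == 2)
}

edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
}

#' @exportS3Method base::print
print.mesh3d_manifold <- function(x, ...) {
  cat(sprintf("<mesh3d_manifold> %d vertices, %d faces, %swatertight\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$watertight)) "" else "NOT "))
  invisible(x)
}

#' One round of Loop subdivision
#'
#' Each triangle is split into four; new edge vertices use the 3/8-1/8
#' interior stencil (midpoint on boundary edges) and original vertices are
#' relaxed with the Loop valence weights (boundary vertices with the
#' 3/4-1/8 curve rule). Face count exactly quadruples.
#'
#' @param mesh a `mesh3d_manifold`.
#' @return The subdivided `mesh3d_manifold`.
#' @export
loop_subdivide <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  nv <- nrow(V)
  e_all <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(1, 3)])
  e_opp <- c(F[, 3], F[, 1], F[, 2])
  ekey <- paste(pmin(e_all[, 1], e_all[, 2]),
                pmax(e_all[, 1], e_all[, 2]), sep = "-")
  edges <- unique(ekey)
  eid <- match(ekey, edges)
  n_e <- length(edges)
  # endpoints and opposite vertices per unique edge
  ep <- matrix(0L, n_e, 2)
  opp <- vector("list", n_e)
  for (i in seq_along(eid)) {
    id <- eid[i]
    ep[id, ] <- c(min(e_all[i, ]), max(e_all[i, ]))
    opp[[id]] <- c(opp[[id]], e_opp[i])
  }
  boundary_edge <- lengths(opp) == 1
  newV <- matrix(0, n_e, 3)
  for (id in seq_len(n_e)) {
    a <- V[ep[id, 1], ]; b <- V[ep[id, 2], ]
    if (boundary_edge[id]) {
      newV[id, ] <- (a + b) / 2
    } else {
      cd <- colSums(V[opp[[id]][1:2], , drop = FALSE])
      newV[id, ] <- 3 / 8 * (a + b) + 1 / 8 * cd
    }
  }
  # even (original) vertex update
  nbr <- vector("list", nv)
  for (id in seq_len(n_e)) {
    nbr[[ep[id, 1]]] <- c(nbr[[ep[id, 1]]], ep[id, 2])
    nbr[[ep[id, 2]]] <- c(nbr[[ep[id, 2]]], ep[id, 1])
  }
  bnd_vert <- unique(as.vector(ep[boundary_edge, , drop = FALSE]))
  V2 <- V
  for (v in seq_len(nv)) {
    nb <- unique(nbr[[v]])
    nn <- length(nb)
    if (nn == 0) next
    if (v %in% bnd_vert) {
      bn <- intersect(nb, unique(as.vector(
        ep[boundary_edge & (ep[, 1] == v | ep[, 2] == v), , drop = FALSE])))
      bn <- setdiff(bn, v)
      if (length(bn) >= 2) {
        V2[v, ] <- 3 / 4 * V[v, ] + 1 / 8 * colSums(V[bn[1:2], , drop = FALSE])
      }
    } else {
      beta <- if (nn == 3) 3 / 16 else
        (1 / nn) * (5 / 8 - (3 / 8 + 1 / 4 * cos(2 * pi / nn))^2)
      V2[v, ] <- (1 - nn * beta) * V[v, ] +
        beta * colSums(V[nb, , drop = FALSE])
    }
  }
  # new connectivity: 4 faces per old face
  nf <- nrow(F)
  m12 <- nv + eid[seq_len(nf)]
  m23 <- nv + eid[nf + seq_len(nf)]
  m13 <- nv + eid[2 * nf + seq_len(nf)]
  F2 <- rbind(cbind(F[, 1], m12, m13),
              cbind(m12, F[, 2], m23),
              cbind(m13, m23, F[, 3]),
              cbind(m12, m23, m13))
  out <- structure(list(vertices = rbind(V2, newV), faces = F2),
                   class = "mesh3d_manifold")
  out$watertight <- mesh$watertight
  out
}

#' Uniform surface sampling of a mesh
#'
#' Area-weighted triangle selection with uniform barycentric coordinates.
#'
#' @param mesh a `mesh3d_manifold`.
#' @param n number of points (the production default budget of 500,000 is a
#'   knob; predictions are pointwise, so results at any budget agree on
#'   shared points).
#' @param seed integer seed.
#' @return n x 3 matrix of surface points.
#' @export
sample_mesh <- function(mesh, n = 10000, seed = 1L) {
  set.seed(derive_seed(seed, 30L))
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], ] - V[F[, 1], ]
  b <- V[F[, 3], ] - V[F[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  tri <- sample.int(nrow(F), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  V[F[tri, 1], ] * w1 + V[F[tri, 2], ] * w2 + V[F[tri, 3], ] * w3
}
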