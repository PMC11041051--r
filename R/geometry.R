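# Geometric primitives: density clustering, smallest enclosing circle,
# 3D convex hull volume, angle conventions. All lengths in cm.

#' Density-based clustering (DBSCAN) of a small point set
#'
#' Exact DBSCAN over a dense distance matrix. Points with at least
#' `min_samples` neighbours within `eps` (the point itself included) are core
#' points; clusters are the connected components of core points under the
#' eps-neighbour relation, plus any border points they reach. Remaining
#' points are noise.
#'
#' @param points Numeric matrix (n x d).
#' @param eps Neighbourhood radius.
#' @param min_samples Minimum neighbourhood size for a core point.
#' @return Integer vector of cluster labels, 0 for noise; clusters numbered
#'   from 1 in order of first appearance (deterministic).
#' @export
dbscan_points <- function(points, eps, min_samples) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(points))
  nb <- d <= eps
  deg <- rowSums(nb)
  core <- deg >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      if (!core[p]) next
      reach <- which(nb[p, ] & labels == 0L)
      labels[reach] <- cl
      queue <- c(queue, reach[core[reach]])
    }
  }
  labels
}

circle_2pt <- function(a, b) {
  list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
}

circle_3pt <- function(a, b, c) {
  # circumcircle; NULL when the points are (near-)collinear
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale <- max(abs(c(a, b, c)), 1)
  if (abs(d) < 1e-12 * scale^2) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

trivial_circle <- function(R) {
  nr <- nrow(R)
  if (nr == 0L) return(list(center = c(0, 0), radius = -1))
  if (nr == 1L) return(list(center = R[1, ], radius = 0))
  if (nr == 2L) return(circle_2pt(R[1, ], R[2, ]))
  cc <- circle_3pt(R[1, ], R[2, ], R[3, ])
  if (!is.null(cc)) return(cc)
  # collinear support set: widest pair
  best <- NULL
  for (i in 1:2) for (j in (i + 1):3) {
    c2 <- circle_2pt(R[i, ], R[j, ])
    if (is.null(best) || c2$radius > best$radius) best <- c2
  }
  best
}

in_circle <- function(circ, p, tol) {
  circ$radius >= 0 && sqrt(sum((p - circ$center)^2)) <= circ$radius + tol
}

welzl <- function(P, R, tol) {
  if (nrow(P) == 0L || nrow(R) == 3L) return(trivial_circle(R))
  p <- P[1L, ]
  D <- welzl(P[-1L, , drop = FALSE], R, tol)
  if (in_circle(D, p, tol)) return(D)
  welzl(P[-1L, , drop = FALSE], rbind(R, p), tol)
}

#' Smallest enclosing circle of 2D points (Welzl's algorithm)
#'
#' @param points Numeric matrix (n x 2).
#' @return List with `center` (length-2), `radius` and `diameter`.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' min_enclosing_circle(sq)$diameter  # 10 * sqrt(2)
#' @export
min_enclosing_circle <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 1L)
  points <- unique(points)
  scale <- max(abs(points), 1)
  tol <- 1e-10 * scale
  circ <- welzl(points, points[0, , drop = FALSE], tol)
  circ$diameter <- 2 * circ$radius
  circ
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' 3D convex hull with divergence-theorem volume
#'
#' Incremental convex hull: an initial extreme tetrahedron is grown point by
#' point; for each point outside the current hull the visible faces are
#' replaced by a fan of new faces over the horizon edges. The enclosed volume
#' is the sum of signed tetrahedron volumes of the outward-oriented faces
#' against an interior reference point.
#'
#' @param points Numeric matrix (n x 3), n >= 4.
#' @return List with `faces` (m x 3 matrix of point indices, outward
#'   orientation) and `volume` (cm^3). Degenerate (collinear/coplanar) input
#'   gives `volume = 0`, no faces, and a warning.
#' @export
convex_hull_3d <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  n <- nrow(points)
  scale <- max(apply(points, 2, function(v) diff(range(v))), 1e-12)
  eps <- 1e-9 * scale
  degenerate <- function(msg) {
    warning("degenerate point set (", msg, "): hull volume is 0")
    list(faces = matrix(integer(0), 0, 3), volume = 0)
  }
  if (n < 4L) return(degenerate("fewer than 4 points"))

  i1 <- which.min(points[, 1])
  d1 <- rowSums(sweep(points, 2, points[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < eps^2) return(degenerate("coincident points"))
  u <- points[i2, ] - points[i1, ]
  rel <- sweep(points, 2, points[i1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  d2 <- rowSums(cr^2)
  i3 <- which.max(d2)
  if (sqrt(d2[i3]) < eps * sqrt(sum(u^2))) return(degenerate("collinear points"))
  nrm <- cross3(u, points[i3, ] - points[i1, ])
  d3 <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(d3)
  if (d3[i4] < eps) return(degenerate("coplanar points"))

  interior <- colMeans(points[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- points[f[1], ]
    nn <- cross3(points[f[2], ] - a, points[f[3], ] - a)
    if (sum(nn * (a - interior)) < 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  face_plane <- function(f) {
    a <- points[f[1], ]
    nn <- cross3(points[f[2], ] - a, points[f[3], ] - a)
    len <- sqrt(sum(nn^2))
    if (len > 0) nn <- nn / len
    c(nn, sum(nn * a))
  }
  planes <- t(apply(faces, 1, face_plane))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    pt <- points[p, ]
    vis <- which(planes[, 1:3, drop = FALSE] %*% pt - planes[, 4] > eps)
    if (!length(vis)) next
    vf <- faces[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    fwd <- paste(edges[, 1], edges[, 2])
    rev <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(fwd %in% rev), , drop = FALSE]
    if (!nrow(horizon)) next  # numerically inside
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient))
    faces <- rbind(faces[-vis, , drop = FALSE], newf)
    planes <- rbind(planes[-vis, , drop = FALSE],
                    t(apply(newf, 1, face_plane)))
  }

  a <- points[faces[, 1], , drop = FALSE]
  b <- points[faces[, 2], , drop = FALSE]
  cc <- points[faces[, 3], , drop = FALSE]
  a <- sweep(a, 2, interior); b <- sweep(b, 2, interior)
  cc <- sweep(cc, 2, interior)
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- sum(rowSums(a * cr)) / 6
  list(faces = faces, volume = abs(vol))
}

#' Volume of the convex hull of a 3D point set
#' @param points Numeric matrix (n x 3).
#' @return Hull volume in cm^3 (0, with a warning, for degenerate input).
#' @export
convex_hull_volume <- function(points) convex_hull_3d(points)$volume

# unsigned angle between two 3D vectors, degrees, in [0, 180]
angle_between_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("angle undefined for zero-length vector")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# azimuth of a vector's xy-projection, degrees counterclockwise from +x,
# in [0, 360); NA for a (numerically) vertical vector, whose horizontal
# projection has no direction
azimuth_deg <- function(v) {
  if (sqrt(v[1]^2 + v[2]^2) < 1e-9 * max(1, abs(v[3])))
    return(NA_real_)
  (atan2(v[2], v[1]) * 180 / pi) %% 360
}
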