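# Tiller repair and skeleton tracing: 2-cm height slabs, per-slab DBSCAN,
# cylinder repair, and a scored top-down search that assigns slice-cluster
# centres to tiller chains.

#' Slice the tiller cloud into 2-cm height slabs
#'
#' Partitions the tiller-labelled points into horizontal slabs of fixed
#' height, anchored at the tiller cloud's minimum z. Slabs are half-open
#' `[z_lo, z_hi)`; the top slab also includes the maximum.
#'
#' @param cloud A [labeled_cloud()] containing tiller points.
#' @param slab_height_cm Slab height in cm (default 2).
#' @return List of slabs, each `list(index, z_lo, z_hi, idx)` where `idx`
#'   are point indices into `cloud`, ordered bottom to top. Empty slabs are
#'   kept (with empty `idx`) so slab indices are arithmetic in height.
#' @export
slice_tiller_cloud <- function(cloud, slab_height_cm = 2) {
  stopifnot(slab_height_cm > 0)
  sel <- which(cloud$semantic == "tiller")
  if (!length(sel)) stop("cloud contains no tiller-labelled points")
  z <- cloud$points[sel, 3]
  z0 <- min(z)
  bin <- floor((z - z0) / slab_height_cm) + 1L
  nb <- max(bin)
  lapply(seq_len(nb), function(b) {
    list(index = b,
         z_lo = z0 + (b - 1L) * slab_height_cm,
         z_hi = z0 + b * slab_height_cm,
         idx = sel[bin == b])
  })
}

#' Cluster each slab with DBSCAN and extract cluster centres
#'
#' Runs DBSCAN on the xy-projection of every slab's points (the slab is
#' thin, and the purpose of the clustering is to separate tiller
#' cross-sections in the horizontal plane; projecting also keeps one tiller
#' in one cluster when dropout empties a vertical band inside the slab).
#' Noise points are discarded and each cluster is summarised by its 3D
#' centroid, the candidate tiller skeleton point for that slab.
#'
#' @param cloud The cloud the slabs index into.
#' @param slabs Output of [slice_tiller_cloud()].
#' @param eps_cm DBSCAN neighbourhood radius (cm).
#' @param min_samples DBSCAN core-point threshold.
#' @return A data.frame with one row per slice cluster: centre `x,y,z`,
#'   `slab` index, within-slab `cluster` index, member count `size`, and a
#'   `members` list-column of point indices into `cloud`.
#' @export
cluster_slabs <- function(cloud, slabs, eps_cm = 1.0, min_samples = 5L) {
  if (!length(slabs)) stop("no slabs to cluster")
  rows <- list()
  for (sl in slabs) {
    if (!length(sl$idx)) next
    P <- cloud$points[sl$idx, 1:2, drop = FALSE]
    lab <- dbscan_points(P, eps_cm, min_samples)
    for (m in seq_len(max(lab, 0L))) {
      mem <- sl$idx[lab == m]
      ctr <- colMeans(cloud$points[mem, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        x = ctr[1], y = ctr[2], z = ctr[3],
        slab = sl$index, cluster = m, size = length(mem))
      rows[[length(rows)]]$members <- I(list(mem))
    }
  }
  if (!length(rows))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      slab = integer(0), cluster = integer(0),
                      size = integer(0)))
  do.call(rbind, rows)
}

#' Replace slice clusters with sampled repair cylinders
#'
#' For each cluster centre a vertical cylinder (lateral surface, regular
#' grid) of the given height and radius is generated, producing a regular
#' repaired tiller cloud in place of the sparse original.
#'
#' @param clusters Data.frame from [cluster_slabs()].
#' @param height_cm Cylinder height (default 2 cm).
#' @param radius_cm Cylinder radius (default 0.5 cm).
#' @param density Surface density, points per cm^2.
#' @return A tiller-labelled [labeled_cloud()] (empty for no clusters).
#' @export
repair_with_cylinders <- function(clusters, height_cm = 2, radius_cm = 0.5,
                                  density = 30) {
  if (!nrow(clusters))
    return(labeled_cloud(matrix(numeric(0), 0, 3), character(0)))
  n_per <- max(8L, round(density * 2 * pi * radius_cm * height_cm))
  n_th <- max(4L, round(sqrt(n_per * 2 * pi * radius_cm / height_cm)))
  n_z <- max(2L, ceiling(n_per / n_th))
  th <- seq(0, 2 * pi, length.out = n_th + 1L)[-1L]
  zz <- seq(-height_cm / 2, height_cm / 2, length.out = n_z)
  grid <- expand.grid(th = th, dz = zz)
  out <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    out[[i]] <- cbind(clusters$x[i] + radius_cm * cos(grid$th),
                      clusters$y[i] + radius_cm * sin(grid$th),
                      clusters$z[i] + grid$dz)
  }
  P <- do.call(rbind, out)
  labeled_cloud(P, rep("tiller", nrow(P)))
}

#' Pairwise score table over slice-cluster centres
#'
#' Scores every pair of candidate skeleton points as a weighted sum of their
#' horizontal (xy) and vertical (|dz|) distances: `score = alpha*h + beta*v`.
#' Lower scores mean the pair is more likely to belong to the same tiller.
#'
#' @param centers Data.frame from [cluster_slabs()] (>= 2 rows).
#' @param alpha,beta Non-negative weights for the horizontal and vertical
#'   distance (not both zero). Horizontal drift is penalised more by default
#'   because tillers are near-vertical.
#' @return A `score_table`: list with `centers` (sorted by decreasing
#'   height, the search order), matrices `h`, `v`, `score`, and the weights.
#' @export
build_score_table <- function(centers, alpha = 2, beta = 1) {
  if (nrow(centers) < 2L)
    stop("need at least two cluster centres to build a score table")
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0))
    stop("weights must be non-negative and not both zero")
  ord <- order(-centers$z, centers$x, centers$y)
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- NULL
  h <- as.matrix(stats::dist(centers[, c("x", "y")]))
  v <- abs(outer(centers$z, centers$z, `-`))
  structure(list(centers = centers, h = h, v = v,
                 score = alpha * h + beta * v,
                 alpha = alpha, beta = beta),
            class = "score_table")
}

#' Search constraints for tiller tracing
#'
#' Concretises the morphological limits on linking two skeleton points into
#' one tiller: a cap on the link score, on each link's slope away from
#' vertical (tillers grow upward, so a near-horizontal link joins two
#' different stems, not two points of one stem), on the bend between
#' consecutive skeleton segments, and on how many empty slabs a link may
#' span.
#'
#' @param max_score Maximum admissible link score (cm-scaled units).
#' @param max_slope_deg Maximum angle of a link from the vertical (degrees).
#' @param max_bend_deg Maximum angle between consecutive segments (degrees).
#' @param max_gap_slabs Maximum number of skipped slabs per link.
#' @return A `search_constraints` list.
#' @export
search_constraints <- function(max_score = 12, max_slope_deg = 60,
                               max_bend_deg = 35, max_gap_slabs = 2L) {
  stopifnot(max_score > 0, max_slope_deg > 0, max_bend_deg > 0,
            max_gap_slabs >= 0)
  structure(list(max_score = max_score, max_slope_deg = max_slope_deg,
                 max_bend_deg = max_bend_deg,
                 max_gap_slabs = as.integer(max_gap_slabs)),
            class = "search_constraints")
}

new_tiller_skeleton <- function(id, points, slabs = NULL,
                                centers_idx = NULL) {
  structure(list(id = id, points = points, slabs = slabs,
                 centers_idx = centers_idx,
                 base_extended = FALSE,
                 H_base_original = points[1, 3], H0 = NA_real_),
            class = "tiller_skeleton")
}

#' @export
print.tiller_skeleton <- function(x, ...) {
  cat(sprintf("Tiller skeleton %d: %d points, z [%.1f, %.1f] cm%s\n",
              x$id, nrow(x$points), x$points[1, 3],
              x$points[nrow(x$points), 3],
              if (x$base_extended) " (base-extended)" else ""))
  invisible(x)
}

#' Top-down greedy tracing of tiller chains
#'
#' Processes the cluster centres in decreasing height; each centre either
#' extends the existing chain whose head gives the lowest admissible score
#' (admissible: score within `max_score`, link slope within
#' `max_slope_deg` of vertical, bend within `max_bend_deg`, slab gap within
#' `max_gap_slabs`) or seeds a new chain. Ties on score break to
#' the smaller bend, then the lower chain id, so the trace is deterministic.
#'
#' @param table A [build_score_table()] result.
#' @param constraints A [search_constraints()] object.
#' @return List of `tiller_skeleton` objects, each ordered bottom to top;
#'   every centre belongs to exactly one chain. `centers_idx` maps skeleton
#'   points back to row numbers of `table$centers`.
#' @export
trace_tillers <- function(table, constraints = search_constraints()) {
  ctr <- table$centers
  n <- nrow(ctr)
  P <- as.matrix(ctr[, c("x", "y", "z")])
  chains <- list()          # vectors of centre indices, head = last added
  for (i in seq_len(n)) {
    best <- NULL; best_score <- Inf; best_bend <- Inf
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      head_i <- ch[length(ch)]
      sc <- table$score[i, head_i]
      if (sc > constraints$max_score) next
      gap <- ctr$slab[head_i] - ctr$slab[i] - 1L
      if (gap > constraints$max_gap_slabs) next
      link <- P[head_i, ] - P[i, ]
      if (angle_between_deg(link, c(0, 0, 1)) > constraints$max_slope_deg)
        next
      bend <- 0
      if (length(ch) >= 2L) {
        prev_i <- ch[length(ch) - 1L]
        bend <- angle_between_deg(P[head_i, ] - P[prev_i, ],
                                  P[i, ] - P[head_i, ])
        if (bend > constraints$max_bend_deg) next
      }
      if (sc < best_score - 1e-12 ||
          (abs(sc - best_score) <= 1e-12 && bend < best_bend - 1e-12)) {
        best <- ci; best_score <- sc; best_bend <- bend
      }
    }
    if (is.null(best)) chains[[length(chains) + 1L]] <- i
    else chains[[best]] <- c(chains[[best]], i)
  }
  lapply(seq_along(chains), function(t) {
    idx <- chains[[t]]
    ord <- order(ctr$z[idx])     # bottom -> top
    idx <- idx[ord]
    new_tiller_skeleton(t, P[idx, , drop = FALSE], ctr$slab[idx], idx)
  })
}

#' Drop skeleton chains with too few points
#'
#' Noise and classification errors produce short chains; chains with fewer
#' than `min_points` skeleton points are excluded (the boundary count is
#' kept). Remaining tiller ids are reassigned contiguously.
#'
#' @param skeletons List of `tiller_skeleton` objects.
#' @param min_points Minimum chain size retained (default 4).
#' @return Filtered list (warning when nothing survives).
#' @export
filter_skeletons <- function(skeletons, min_points = 4L) {
  keep <- vapply(skeletons, function(s) nrow(s$points) >= min_points,
                 logical(1))
  out <- skeletons[keep]
  if (!length(out) && length(skeletons))
    warning("all skeleton chains were filtered out; plant has no valid tiller")
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Extend each tiller skeleton down to the plant base
#'
#' Reconstructed tiller bottoms are often missing; each skeleton is extended
#' vertically from its original base height down to `H_0`, the lowest height
#' among the plant's tiller points, and the pre-extension base height is
#' recorded for the length correction.
#'
#' @param skeletons List of `tiller_skeleton` objects.
#' @param H_0 Plant base height (cm): the minimum z of the tiller points.
#' @return The skeletons, base-extended where needed, with `H_base_original`
#'   and `H0` recorded.
#' @export
extend_to_base <- function(skeletons, H_0) {
  lapply(skeletons, function(s) {
    s$H_base_original <- s$points[1, 3]
    s$H0 <- H_0
    if (s$points[1, 3] > H_0 + 1e-9) {
      base <- matrix(c(s$points[1, 1], s$points[1, 2], H_0), 1L)
      s$points <- rbind(base, s$points)
      dimnames(s$points) <- list(NULL, c("x", "y", "z"))
      if (!is.null(s$slabs)) s$slabs <- c(NA_integer_, s$slabs)
      if (!is.null(s$centers_idx)) s$centers_idx <- c(NA_integer_, s$centers_idx)
      s$base_extended <- TRUE
    }
    s
  })
}

#' Full tiller-skeleton stage
#'
#' Convenience wrapper running slicing, per-slab clustering, score-table
#' construction, top-down tracing, short-chain filtering and base extension
#' on the tiller points of a labelled cloud.
#'
#' @param cloud A [labeled_cloud()] with tiller points.
#' @param control A [recon_control()] parameter list.
#' @return List with `skeletons` (base-extended `tiller_skeleton`s),
#'   `clusters` (the slice-cluster table) and `H0`.
#' @export
trace_tiller_skeletons <- function(cloud, control = recon_control()) {
  slabs <- slice_tiller_cloud(cloud, control$slab_height_cm)
  clusters <- cluster_slabs(cloud, slabs, control$eps_cm, control$min_samples)
  if (nrow(clusters) < 2L)
    stop("tiller stage: fewer than two slice clusters; cannot trace")
  tab <- build_score_table(clusters, control$alpha, control$beta)
  sk <- trace_tillers(tab, search_constraints(control$max_score,
                                              control$max_slope_deg,
                                              control$max_bend_deg,
                                              control$max_gap_slabs))
  sk <- filter_skeletons(sk, control$min_skeleton_points)
  H0 <- min(cloud$points[cloud$semantic == "tiller", 3])
  sk <- extend_to_base(sk, H0)
  list(skeletons = sk, clusters = tab$centers, H0 = H0)
}
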