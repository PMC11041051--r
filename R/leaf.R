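# Leaf skeletonization: k-means segmentation along the blade, endpoint
# extraction, nearest-neighbour chaining, base identification with the
# minD/avgD correction, and phytomer assembly.

#' Segment one leaf into ordered point-cloud segments
#'
#' k-means segmentation along the leaf axis: k = 4 for leaves with fewer
#' than 1000 points, k = 7 otherwise (small leaves do not support more
#' segments; large ones benefit from a finer skeleton). Segments are ordered
#' by the projection of their centroids onto the leaf's first principal
#' axis. The k-means seed is derived from the leaf id, so segmentation is
#' reproducible.
#'
#' @param points Numeric matrix (n x 3) of one leaf instance.
#' @param leaf_id Integer leaf id (seeds the clustering).
#' @param threshold Point count at which k switches from 4 to 7.
#' @return A `leaf_segments` object: list with `leaf_id`, `k`, `assignment`
#'   (per-point segment, ordered), `segments` (list of row-index vectors),
#'   `centroids` (k x 3, ordered along the axis) and `axis` (unit PC1).
#' @export
segment_leaf <- function(points, leaf_id = 1L, threshold = 1000L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("degenerate leaf: fewer than 2 points")
  k <- if (n < threshold) 4L else 7L
  if (n < k) {
    warning("leaf ", leaf_id, " has fewer points than k; falling back to k = 2")
    k <- 2L
  }
  km <- with_seed(97561L + leaf_id, {
    stats::kmeans(points, centers = k, nstart = 5L, iter.max = 100L)
  })
  pc1 <- stats::prcomp(points, center = TRUE, scale. = FALSE)$rotation[, 1]
  proj <- as.numeric(km$centers %*% pc1)
  ord <- order(proj)
  relabel <- match(seq_len(k), ord)
  assignment <- relabel[km$cluster]
  structure(list(leaf_id = leaf_id, k = k,
                 assignment = assignment,
                 segments = split(seq_len(n), assignment),
                 centroids = km$centers[ord, , drop = FALSE],
                 axis = pc1),
            class = "leaf_segments")
}

#' Extract the two leaf endpoints
#'
#' For each edge segment, the endpoint is the segment point farthest from
#' the centroid of the neighbouring segment, which lands on the physical
#' extremity of the blade rather than on an interior maximal chord.
#'
#' @param points The leaf's point matrix (as passed to [segment_leaf()]).
#' @param segments A [segment_leaf()] result (k >= 2).
#' @return A 2 x 3 matrix: rows `e_first`, `e_last`, in segment order.
#' @export
extract_endpoints <- function(points, segments) {
  stopifnot(segments$k >= 2L)
  points <- as.matrix(points)
  endpoint_of <- function(edge, neighbour) {
    ref <- colMeans(points[segments$segments[[neighbour]], , drop = FALSE])
    cand <- segments$segments[[edge]]
    d2 <- rowSums(sweep(points[cand, , drop = FALSE], 2, ref)^2)
    points[cand[which.max(d2)], ]
  }
  out <- rbind(e_first = endpoint_of(1L, 2L),
               e_last = endpoint_of(segments$k, segments$k - 1L))
  out
}

#' Chain centroids and endpoints into a leaf skeleton polyline
#'
#' Builds the skeleton by repeated nearest-neighbour linking: starting from
#' one endpoint, the closest unvisited centroid is appended until all are
#' used, then the other endpoint closes the polyline.
#'
#' @param centroids k x 3 matrix of segment centroids.
#' @param endpoints 2 x 3 matrix from [extract_endpoints()].
#' @param leaf_id Integer id carried on the skeleton.
#' @return A `leaf_skeleton`: list with `leaf_id`, `polyline`
#'   ((k+2) x 3), `base` (`NA` until [identify_base()]), and bookkeeping.
#' @export
chain_skeleton <- function(centroids, endpoints, leaf_id = 1L) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  cur <- endpoints[1L, ]
  left <- seq_len(k)
  ord <- integer(0)
  while (length(left)) {
    d2 <- rowSums(sweep(centroids[left, , drop = FALSE], 2, cur)^2)
    nxt <- left[which.min(d2)]
    ord <- c(ord, nxt)
    cur <- centroids[nxt, ]
    left <- setdiff(left, nxt)
  }
  poly <- rbind(endpoints[1L, ], centroids[ord, , drop = FALSE],
                endpoints[2L, ])
  rownames(poly) <- NULL
  structure(list(leaf_id = leaf_id, polyline = poly, k = k,
                 base = NA_character_),
            class = "leaf_skeleton")
}

#' @export
print.leaf_skeleton <- function(x, ...) {
  cat(sprintf("Leaf skeleton %d: %d vertices%s\n", x$leaf_id,
              nrow(x$polyline),
              if (!is.na(x$base)) " (base set)" else ""))
  invisible(x)
}

#' Decide which leaf endpoint is the base
#'
#' Wheat morphology heuristic: leaves low on the plant splay outward, so the
#' base endpoint is the one closer (in xy) to the centre of the whole plant
#' cloud; leaves high on the plant grow near-vertically, so the base is the
#' lower endpoint. The zone is chosen by the leaf's mean height relative to
#' the plant's z-extent.
#'
#' @param skeleton A [chain_skeleton()] result.
#' @param plant_center_xy Length-2 xy centroid of the full plant cloud.
#' @param plant_zrange Length-2 `c(min, max)` z of the plant cloud.
#' @param z_split Relative height splitting the bottom and top zones.
#' @return The skeleton with `base` set (`"first"`/`"last"`) and the
#'   polyline oriented base-first.
#' @export
identify_base <- function(skeleton, plant_center_xy, plant_zrange,
                          z_split = 0.5) {
  poly <- skeleton$polyline
  e1 <- poly[1L, ]; e2 <- poly[nrow(poly), ]
  rel <- (mean(poly[, 3]) - plant_zrange[1]) / max(diff(plant_zrange), 1e-12)
  if (rel < z_split) {
    d1 <- sum((e1[1:2] - plant_center_xy)^2)
    d2 <- sum((e2[1:2] - plant_center_xy)^2)
    base_first <- d1 <= d2
  } else {
    base_first <- e1[3] <= e2[3]
  }
  if (!base_first)
    skeleton$polyline <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  skeleton$base <- "first"
  skeleton$zone <- if (rel < z_split) "bottom" else "top"
  skeleton
}

tiller_point_stack <- function(tillers) {
  pts <- do.call(rbind, lapply(tillers, `[[`, "points"))
  ids <- rep(vapply(tillers, `[[`, integer(1), "id"),
             vapply(tillers, function(s) nrow(s$points), integer(1)))
  list(points = pts, tiller = ids)
}

min_dist_to_stack <- function(p, stack) {
  d2 <- rowSums(sweep(stack$points, 2, p)^2)
  i <- which.min(d2)
  list(dist = sqrt(d2[i]), idx = i)
}

#' Correct one leaf's base by the minD/avgD rule
#'
#' `minD` is the distance from the current base endpoint to the nearest
#' tiller skeleton point. When `minD` exceeds `factor` times `avgD` (the
#' plant-wide mean of `minD` over all leaves), the base is suspect: the
#' other endpoint's distance `minD2` is computed, and if `minD2 < minD` the
#' endpoints are swapped. The attachment point is the nearest tiller
#' skeleton point to the final base, and the host tiller is that point's
#' tiller.
#'
#' @param skeleton A base-identified [leaf_skeleton].
#' @param tillers List of `tiller_skeleton`s (>= 1).
#' @param avgD Plant-wide mean base-to-skeleton distance (computed over all
#'   leaves before any correction).
#' @param factor Correction trigger multiplier (default 1.75).
#' @return List `(skeleton, record)` where `record` is the attachment
#'   record: `leaf_id`, `base`, `minD`, `avgD`, `minD2`, `corrected`,
#'   `attachment`, `host_tiller`.
#' @export
correct_attachment <- function(skeleton, tillers, avgD, factor = 1.75) {
  if (!length(tillers)) stop("attachment impossible: no tiller skeletons")
  stack <- tiller_point_stack(tillers)
  poly <- skeleton$polyline
  base <- poly[1L, ]
  other <- poly[nrow(poly), ]
  hit <- min_dist_to_stack(base, stack)
  minD <- hit$dist
  minD2 <- NA_real_
  corrected <- FALSE
  if (minD > factor * avgD) {
    hit2 <- min_dist_to_stack(other, stack)
    minD2 <- hit2$dist
    if (minD2 < minD) {
      skeleton$polyline <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
      hit <- hit2
      corrected <- TRUE
    }
  }
  record <- list(leaf_id = skeleton$leaf_id,
                 base = skeleton$polyline[1L, ],
                 minD = minD, avgD = avgD, minD2 = minD2,
                 corrected = corrected,
                 attachment = stack$points[hit$idx, ],
                 host_tiller = stack$tiller[hit$idx],
                 attach_dist = hit$dist,
                 unattached = FALSE)
  list(skeleton = skeleton, record = record)
}

#' Locate and correct attachments for all leaves of a plant
#'
#' First pass computes every leaf's `minD` and the plant-wide `avgD`; second
#' pass applies [correct_attachment()] leaf by leaf.
#'
#' @param skeletons List of base-identified [leaf_skeleton]s.
#' @param tillers List of `tiller_skeleton`s.
#' @param factor Correction trigger multiplier.
#' @return List with updated `skeletons` and `records`.
#' @export
locate_attachments <- function(skeletons, tillers, factor = 1.75) {
  if (!length(tillers)) stop("attachment impossible: no tiller skeletons")
  stack <- tiller_point_stack(tillers)
  minDs <- vapply(skeletons, function(s)
    min_dist_to_stack(s$polyline[1L, ], stack)$dist, numeric(1))
  avgD <- mean(minDs)
  out <- lapply(skeletons, correct_attachment, tillers = tillers,
                avgD = avgD, factor = factor)
  list(skeletons = lapply(out, `[[`, "skeleton"),
       records = lapply(out, `[[`, "record"))
}

#' Assemble the phytomer model of one plant
#'
#' Leaves are translated so the base endpoint coincides with its attachment
#' point (when the snap distance is within `snap_max_cm`; farther leaves are
#' left in place and flagged), and tillers, leaves and ears are collected
#' into a single plant model.
#'
#' @param tillers List of `tiller_skeleton`s.
#' @param leaves List of [leaf_skeleton]s.
#' @param records Attachment records matching `leaves`.
#' @param ears List of per-ear point matrices (named by instance id), may be
#'   empty.
#' @param leaf_segments Optional list of [segment_leaf()] results (kept for
#'   width extraction).
#' @param cloud Optional source cloud (kept for plant-level extents).
#' @param snap_max_cm Maximum base-to-attachment snap distance.
#' @return A `plant_model` object.
#' @export
assemble_plant <- function(tillers, leaves, records, ears = list(),
                           leaf_segments = NULL, cloud = NULL,
                           snap_max_cm = 3) {
  tiller_ids <- vapply(tillers, `[[`, integer(1), "id")
  for (i in seq_along(leaves)) {
    rec <- records[[i]]
    if (isTRUE(rec$unattached)) next
    if (!rec$host_tiller %in% tiller_ids)
      stop("leaf ", rec$leaf_id, " references missing tiller ",
           rec$host_tiller)
    shift <- rec$attachment - leaves[[i]]$polyline[1L, ]
    if (sqrt(sum(shift^2)) <= snap_max_cm) {
      leaves[[i]]$polyline <- sweep(leaves[[i]]$polyline, 2, shift, `+`)
      records[[i]]$snapped <- TRUE
    } else {
      warning("leaf ", rec$leaf_id, " base is ", round(sqrt(sum(shift^2)), 2),
              " cm from its attachment; left in place")
      records[[i]]$snapped <- FALSE
    }
  }
  extents <- if (!is.null(cloud) && n_points(cloud))
    apply(cloud$points, 2, range)
  structure(list(tillers = tillers, leaves = leaves, records = records,
                 ears = ears, leaf_segments = leaf_segments,
                 extents = extents, cloud = cloud),
            class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  cat("Assembled wheat plant model\n")
  cat("  tillers:", length(x$tillers),
      " leaves:", length(x$leaves),
      " ears:", length(x$ears), "\n")
  nsnap <- sum(vapply(x$records, function(r) isTRUE(r$snapped), logical(1)))
  if (length(x$records))
    cat("  leaves snapped to attachment:", nsnap, "/", length(x$records), "\n")
  invisible(x)
}

#' Leaf-skeleton stage for a whole cloud
#'
#' Runs segmentation, endpoint extraction, chaining and base identification
#' for every leaf instance of a labelled cloud.
#'
#' @param cloud An instance-segmented [labeled_cloud()].
#' @param control A [recon_control()].
#' @return List with `skeletons` and `segments` (both keyed by 1-based leaf
#'   number; leaf k corresponds to cloud instance id k-1).
#' @export
extract_leaf_skeletons <- function(cloud, control = recon_control()) {
  sel <- cloud$semantic == "leaf"
  ids <- sort(unique(cloud$instance[sel]))
  center_xy <- colMeans(cloud$points[, 1:2, drop = FALSE])
  zr <- range(cloud$points[, 3])
  skeletons <- list(); segments <- list()
  for (id in ids) {
    pts <- cloud$points[sel & cloud$instance == id, , drop = FALSE]
    seg <- segment_leaf(pts, leaf_id = id + 1L,
                        threshold = control$kmeans_threshold)
    ep <- extract_endpoints(pts, seg)
    sk <- chain_skeleton(seg$centroids, ep, leaf_id = id + 1L)
    sk <- identify_base(sk, center_xy, zr, control$z_split)
    skeletons[[length(skeletons) + 1L]] <- sk
    segments[[length(segments) + 1L]] <- seg
  }
  list(skeletons = skeletons, segments = segments)
}
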