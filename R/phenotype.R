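# Extraction of the 18 plant-morphology parameters from an assembled plant
# model: counts, tiller lengths/angles, plant height, girth, leaf
# length/width/angles/attachment/venule, ear length/attachment/volume.

polyline_length <- function(P) sum(sqrt(rowSums(diff(P)^2)))

#' Tiller length with base-extension correction
#'
#' Sum of the distances between consecutive skeleton points of the traced
#' (pre-extension) chain, plus the height gap between the chain's original
#' base and the plant base, which accounts for the missing reconstructed
#' bottom.
#'
#' @param sk A `tiller_skeleton` (>= 2 points).
#' @return Length in cm.
#' @export
tiller_length <- function(sk) {
  P <- sk$points
  if (sk$base_extended) P <- P[-1L, , drop = FALSE]
  if (nrow(P) < 2L) stop("tiller length undefined for a single-point skeleton")
  corr <- if (!is.na(sk$H0)) sk$H_base_original - sk$H0 else 0
  unname(polyline_length(P) + corr)
}

skeleton_height_vector <- function(sk) {
  z <- sk$points[, 3]
  zr <- range(z)
  p1 <- sk$points[which.min(abs(z - (zr[1] + diff(zr) / 3))), ]
  p2 <- sk$points[which.min(abs(z - (zr[1] + 2 * diff(zr) / 3))), ]
  v <- p2 - p1
  if (sqrt(sum(v^2)) < 1e-12)
    stop("tiller direction undefined: 1/3- and 2/3-height points coincide")
  v
}

#' Tiller inclination and azimuth
#'
#' The tiller vector joins the skeleton points nearest 1/3 and 2/3 of the
#' tiller's own z-extent; the main-stem vector is built the same way. The
#' inclination is the unsigned angle between the two vectors; the azimuth is
#' the angle of the tiller vector's xy-projection counterclockwise from +x.
#'
#' @param sk,main `tiller_skeleton`s (the tiller and the main stem).
#' @return `c(angle_deg, azimuth_deg)`: angle in [0, 180], azimuth in
#'   [0, 360).
#' @export
tiller_angles <- function(sk, main) {
  v <- skeleton_height_vector(sk)
  vm <- skeleton_height_vector(main)
  c(angle_deg = angle_between_deg(v, vm), azimuth_deg = azimuth_deg(v))
}

#' Plant height
#'
#' Height difference between the highest and lowest point of the plant
#' cloud.
#'
#' @param cloud A non-empty [labeled_cloud()].
#' @return Height in cm.
#' @export
plant_height <- function(cloud) {
  if (n_points(cloud) == 0L) stop("empty cloud has no height")
  diff(range(cloud$points[, 3]))
}

#' Plant girth from the tillers' mid-height cross-section
#'
#' Takes each tiller's skeleton point nearest half the plant height, forms
#' the xy convex hull of these points, and returns the diameter of the
#' smallest enclosing circle (Welzl) of the hull vertices. Reflects how
#' loosely the tillers spread.
#'
#' @param tillers List of `tiller_skeleton`s (>= 1).
#' @param plant_height_cm Plant height in cm.
#' @return Girth (circle diameter) in cm; 0 for a single tiller.
#' @export
girth <- function(tillers, plant_height_cm) {
  stopifnot(length(tillers) >= 1L)
  z_base <- min(vapply(tillers, function(s) min(s$points[, 3]), numeric(1)))
  target <- z_base + plant_height_cm / 2
  tops <- vapply(tillers, function(s) max(s$points[, 3]), numeric(1))
  if (all(tops < target))
    warning("no tiller reaches half the plant height; using tiller tops")
  pts <- t(vapply(tillers, function(s) {
    s$points[which.min(abs(s$points[, 3] - target)), 1:2]
  }, numeric(2)))
  if (nrow(pts) < 2L) return(0)
  hull <- grDevices::chull(pts)
  min_enclosing_circle(pts[hull, , drop = FALSE])$diameter
}

#' Select the main stem among the traced tillers
#'
#' The main stem is the tiller that is both long and central: tillers are
#' ranked by length (descending) and by the xy-distance of their mean axis
#' position from the plant centre (ascending), and the lowest rank sum wins;
#' ties break to the lower tiller id. The mean axis position, rather than
#' the base, carries the centrality signal: near the crown all tillers
#' converge (and traced bases may sit on the shared crown column), while the
#' main stem is the one that stays central over its whole height.
#'
#' @param tillers List of `tiller_skeleton`s.
#' @return The selected tiller's id.
#' @export
select_main_stem <- function(tillers) {
  stopifnot(length(tillers) >= 1L)
  if (length(tillers) == 1L) return(tillers[[1L]]$id)
  lens <- vapply(tillers, tiller_length, numeric(1))
  all_pts <- do.call(rbind, lapply(tillers, `[[`, "points"))
  ctr <- colMeans(all_pts[, 1:2, drop = FALSE])
  cen <- vapply(tillers, function(s)
    sqrt(sum((colMeans(s$points[, 1:2, drop = FALSE]) - ctr)^2)), numeric(1))
  score <- rank(-lens, ties.method = "min") + rank(cen, ties.method = "min")
  ids <- vapply(tillers, `[[`, integer(1), "id")
  ids[order(score, ids)][1L]
}

#' Leaf length along the skeleton polyline
#'
#' Sum of the distances between adjacent leaf-skeleton vertices (both
#' endpoints included); the skeleton is dense and of low curvature, so the
#' chain length approximates the blade's midrib length.
#'
#' @param sk A [chain_skeleton()] result.
#' @return Length in cm.
#' @export
leaf_length <- function(sk) polyline_length(sk$polyline)

#' Leaf width from the mid-blade segments
#'
#' Pools the two middle leaf segments, runs PCA on the pooled points (whose
#' principal axes align with the blade's length, width and thickness), and
#' reports the extent of the projections onto the second principal axis.
#'
#' @param points The leaf's point matrix.
#' @param segments A [segment_leaf()] result.
#' @return Width in cm.
#' @export
leaf_width <- function(points, segments) {
  points <- as.matrix(points)
  k <- segments$k
  if (k < 4L) {
    warning("fewer than 4 segments; width taken from the middle segment")
    mid <- segments$segments[[ceiling(k / 2)]]
  } else {
    lo <- floor(k / 2)
    mid <- c(segments$segments[[lo]], segments$segments[[lo + 1L]])
  }
  pts <- points[mid, , drop = FALSE]
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  diff(range(pc$x[, 2]))
}

#' Stem-leaf angle and leaf azimuth
#'
#' The stem-leaf angle is the angle between the leaf-base growth direction
#' (base endpoint to first skeleton centroid) and the local growth direction
#' of the host tiller (the skeleton points bracketing the attachment point).
#' The azimuth is the angle from +x of the xy-projection of the vector from
#' the base to the leaf's highest skeleton vertex.
#'
#' @param sk An attached [leaf_skeleton].
#' @param host The host `tiller_skeleton`.
#' @param attachment The attachment point (a skeleton point of `host`).
#' @return `c(angle_deg, azimuth_deg)`.
#' @export
leaf_angles <- function(sk, host, attachment) {
  poly <- sk$polyline
  base_dir <- poly[2L, ] - poly[1L, ]
  d2 <- rowSums(sweep(host$points, 2, attachment)^2)
  j <- which.min(d2)
  lo <- max(1L, j - 1L); hi <- min(nrow(host$points), j + 1L)
  tiller_dir <- host$points[hi, ] - host$points[lo, ]
  hi_v <- poly[which.max(poly[, 3]), ]
  c(angle_deg = angle_between_deg(base_dir, tiller_dir),
    azimuth_deg = azimuth_deg(hi_v - poly[1L, ]))
}

#' Ear length by principal-axis projection
#'
#' @param points Point matrix of one ear instance (>= 3 points).
#' @return Extent of the projections onto the first principal axis, cm.
#' @export
ear_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("degenerate ear: fewer than 3 points")
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  diff(range(pc$x[, 1]))
}

#' Ear volume from the convex hull
#'
#' Signed sum of tetrahedron volumes over the outward-oriented faces of the
#' ear's 3D convex hull (divergence-theorem form).
#'
#' @param points Point matrix of one ear instance.
#' @return Volume in cm^3 (0, with a warning, for coplanar input).
#' @export
ear_volume <- function(points) convex_hull_volume(as.matrix(points))

#' Ear attachment point
#'
#' The ear point with the lowest height; ties break to the lowest point
#' index, so the choice is deterministic.
#'
#' @param points Point matrix of one ear instance.
#' @return The attachment point `c(x, y, z)`.
#' @export
ear_attachment <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1L)
  points[which.min(points[, 3]), ]
}

na_on_error <- function(expr, what) {
  tryCatch(expr, error = function(e) {
    warning(what, ": ", conditionMessage(e), call. = FALSE)
    NA_real_
  })
}

#' Compile the full phenotype report of a plant
#'
#' Populates all 18 morphological parameters from an assembled plant model:
#' counts, main stem, per-tiller length and angles, plant height and girth,
#' per-leaf length, width, angles, attachment point and venule nodes, and
#' per-ear length, attachment and volume. Per-organ failures degrade to
#' `NA` fields with a warning; the report is always produced.
#'
#' @param model A [assemble_plant()] result.
#' @return A `phenotype_report` object (see `as.data.frame` /
#'   [write_report()] for flat export).
#' @export
compile_report <- function(model) {
  tillers <- model$tillers
  main_id <- select_main_stem(tillers)
  main <- tillers[[which(vapply(tillers, `[[`, integer(1), "id") == main_id)]]
  t_df <- do.call(rbind, lapply(tillers, function(s) {
    ang <- c(angle_deg = NA_real_, azimuth_deg = NA_real_)
    ang_try <- tryCatch(tiller_angles(s, main), error = function(e) ang)
    data.frame(id = s$id,
               length_cm = na_on_error(tiller_length(s), "tiller length"),
               angle_main_deg = unname(ang_try[1]),
               azimuth_deg = unname(ang_try[2]))
  }))

  h <- if (!is.null(model$cloud)) plant_height(model$cloud)
       else diff(range(do.call(rbind,
                               lapply(tillers, `[[`, "points"))[, 3]))
  g <- na_on_error(girth(tillers, h), "girth")

  l_df <- NULL
  venules <- list()
  if (length(model$leaves)) {
    l_rows <- lapply(seq_along(model$leaves), function(i) {
      sk <- model$leaves[[i]]
      rec <- model$records[[i]]
      seg <- if (!is.null(model$leaf_segments)) model$leaf_segments[[i]]
      len <- na_on_error(leaf_length(sk), "leaf length")
      wid <- if (!is.null(seg) && !is.null(model$cloud)) {
        pts <- model$cloud$points[model$cloud$semantic == "leaf" &
                                    model$cloud$instance == sk$leaf_id - 1L,
                                  , drop = FALSE]
        na_on_error(leaf_width(pts, seg), "leaf width")
      } else NA_real_
      if (isTRUE(rec$unattached)) {
        ang <- c(NA_real_, NA_real_)
        att <- c(NA_real_, NA_real_, NA_real_)
        host <- NA_integer_
      } else {
        host <- rec$host_tiller
        hsk <- model$tillers[[which(vapply(model$tillers, `[[`, integer(1),
                                           "id") == host)]]
        ang <- tryCatch(leaf_angles(sk, hsk, rec$attachment),
                        error = function(e) c(NA_real_, NA_real_))
        att <- rec$attachment
      }
      venules[[i]] <<- sk$polyline
      data.frame(id = sk$leaf_id, length_cm = len, width_cm = wid,
                 angle_deg = unname(ang[1]), azimuth_deg = unname(ang[2]),
                 attach_x = att[1], attach_y = att[2], attach_z = att[3],
                 host_tiller = host,
                 corrected = isTRUE(rec$corrected))
    })
    l_df <- do.call(rbind, l_rows)
  }

  e_df <- NULL
  if (length(model$ears)) {
    e_rows <- lapply(seq_along(model$ears), function(i) {
      pts <- model$ears[[i]]
      att <- ear_attachment(pts)
      data.frame(id = i,
                 length_cm = na_on_error(ear_length(pts), "ear length"),
                 attach_x = att[1], attach_y = att[2], attach_z = att[3],
                 volume_cm3 = na_on_error(
                   suppressWarnings(ear_volume(pts)), "ear volume"))
    })
    e_df <- do.call(rbind, e_rows)
  }

  structure(list(
    n_tillers = length(tillers),
    main_stem_id = main_id,
    tillers = t_df,
    plant_height_cm = h,
    girth_cm = g,
    n_leaves = length(model$leaves),
    leaves = l_df,
    venules = venules,
    n_ears = length(model$ears),
    ears = e_df), class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("Wheat plant phenotype report\n")
  cat(sprintf("  tillers: %d (main stem: %d)   leaves: %d   ears: %d\n",
              x$n_tillers, x$main_stem_id, x$n_leaves, x$n_ears))
  cat(sprintf("  plant height: %.1f cm   girth: %.1f cm\n",
              x$plant_height_cm, x$girth_cm))
  if (!is.null(x$tillers)) {
    cat("  tiller lengths (cm):",
        paste(sprintf("%.1f", x$tillers$length_cm), collapse = ", "), "\n")
  }
  if (!is.null(x$leaves)) {
    cat(sprintf("  leaf length (cm): mean %.1f [%.1f, %.1f]\n",
                mean(x$leaves$length_cm, na.rm = TRUE),
                min(x$leaves$length_cm, na.rm = TRUE),
                max(x$leaves$length_cm, na.rm = TRUE)))
  }
  invisible(x)
}

#' Flatten a phenotype report to one row per organ
#'
#' @param x A `phenotype_report`.
#' @param row.names,optional,... Unused, for S3 compatibility.
#' @return A data.frame with columns `organ`, `id` and the parameter
#'   columns; plant-level values appear on a `plant` row.
#' @export
as.data.frame.phenotype_report <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  plant <- data.frame(organ = "plant", id = NA_integer_,
                      n_tillers = x$n_tillers, main_stem = x$main_stem_id,
                      n_leaves = x$n_leaves, n_ears = x$n_ears,
                      height_cm = x$plant_height_cm, girth_cm = x$girth_cm)
  pad <- function(df, organ) {
    if (is.null(df)) return(NULL)
    cbind(data.frame(organ = organ), df)
  }
  out <- list(plant = plant, tiller = pad(x$tillers, "tiller"),
              leaf = pad(x$leaves, "leaf"), ear = pad(x$ears, "ear"))
  out <- out[!vapply(out, is.null, logical(1))]
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(df) {
    for (m in setdiff(nm, names(df))) df[[m]] <- NA
    df[, nm]
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write a phenotype report to disk
#'
#' @param report A `phenotype_report`.
#' @param path Output path; `.json` writes the nested report, anything else
#'   the flat one-row-per-organ CSV.
#' @return Invisibly `path`.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    x <- unclass(report)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
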