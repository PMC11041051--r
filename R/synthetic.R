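# Procedural wheat-plant generator with exact ground truth. Organs are
# sampled as surfaces around analytic axis curves; multi-view-stereo
# artifacts (jitter, dropout holes, missing stem bottoms) are applied after
# labelling, so the emitted cloud plus ground truth form a recovery oracle
# for the reconstruction pipeline.

TUBE_RADIUS_CM <- 0.25  # tiller tube radius; repair cylinders use 2x this

#' Specify a synthetic wheat plant
#'
#' Any per-organ field left `NULL` is drawn (deterministically, from
#' `rng_seed`) inside [generate_plant()] from field-realistic ranges: tiller
#' heights U(40, 90) cm with the main stem tallest, leans U(2, 15) degrees
#' from vertical (main stem U(0, 4)), azimuths evenly spaced around the crown
#' with +/-25 degree jitter, leaf lengths U(8, 25) cm, maximum widths
#' U(0.6, 2.0) cm, insertion height fractions U(0.15, 0.85), insertion angles
#' U(15, 45) degrees, ear lengths U(5, 10) cm.
#'
#' @param n_tillers Number of tillers (>= 1); tiller 1 is grown as the main
#'   stem (tallest, base at the crown centre, smallest lean).
#' @param tiller_heights,tiller_lean_deg,tiller_azimuth_deg,tiller_curvature
#'   Optional per-tiller axis length (cm), inclination from vertical (deg),
#'   azimuth (deg) and outward bow amplitude (cm).
#' @param leaves_per_tiller Leaves grown on each tiller (>= 0).
#' @param leaf_params Optional data.frame with columns `tiller`, `length`,
#'   `width`, `insert_frac`, `insert_angle`, `azimuth`, `arch` (one row per
#'   leaf; lengths/widths/arch in cm, angles in degrees, `insert_frac` in
#'   [0, 1)).
#' @param has_ear Logical, recycled over tillers: cap the tiller with an ear?
#' @param ear_length_cm,ear_radius_cm Optional per-ear axis length and radius.
#' @param sampling Surface sampling density, points per cm^2.
#' @param noise_sd_cm Isotropic Gaussian jitter applied to every point.
#' @param dropout_fraction Fraction of points removed (half uniformly, half
#'   as spherical dropout holes).
#' @param base_missing_cm Height below which tiller points are truncated,
#'   emulating missing stem bottoms.
#' @param rng_seed Integer seed; everything the generator draws flows from it.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_tillers = 3L,
                       tiller_heights = NULL,
                       tiller_lean_deg = NULL,
                       tiller_azimuth_deg = NULL,
                       tiller_curvature = NULL,
                       leaves_per_tiller = 3L,
                       leaf_params = NULL,
                       has_ear = TRUE,
                       ear_length_cm = NULL,
                       ear_radius_cm = NULL,
                       sampling = 30,
                       noise_sd_cm = 0.05,
                       dropout_fraction = 0.10,
                       base_missing_cm = 2,
                       rng_seed = 1L) {
  spec <- list(n_tillers = as.integer(n_tillers),
               tiller_heights = tiller_heights,
               tiller_lean_deg = tiller_lean_deg,
               tiller_azimuth_deg = tiller_azimuth_deg,
               tiller_curvature = tiller_curvature,
               leaves_per_tiller = as.integer(leaves_per_tiller),
               leaf_params = leaf_params,
               has_ear = has_ear,
               ear_length_cm = ear_length_cm,
               ear_radius_cm = ear_radius_cm,
               sampling = sampling,
               noise_sd_cm = noise_sd_cm,
               dropout_fraction = dropout_fraction,
               base_missing_cm = base_missing_cm,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "plant_spec"
  validate_plant_spec(spec)
  spec
}

validate_plant_spec <- function(spec) {
  if (spec$n_tillers < 1L) stop("n_tillers must be >= 1")
  if (spec$leaves_per_tiller < 0L) stop("leaves_per_tiller must be >= 0")
  if (!is.null(spec$tiller_heights) && any(spec$tiller_heights <= 0))
    stop("tiller heights must be positive")
  if (spec$sampling <= 0) stop("sampling density must be positive")
  if (spec$noise_sd_cm < 0) stop("noise_sd_cm must be non-negative")
  if (spec$dropout_fraction < 0 || spec$dropout_fraction > 1)
    stop("dropout_fraction must lie in [0, 1]")
  if (spec$base_missing_cm < 0) stop("base_missing_cm must be non-negative")
  lp <- spec$leaf_params
  if (!is.null(lp)) {
    if (any(lp$length <= 0) || any(lp$width <= 0))
      stop("leaf lengths and widths must be positive")
    if (any(lp$insert_frac < 0 | lp$insert_frac >= 1))
      stop("leaf insertion height fraction must lie in [0, 1)")
    if (any(lp$insert_angle <= 0 | lp$insert_angle >= 120))
      stop("leaf insertion angle must lie in (0, 120) degrees")
  }
  invisible(TRUE)
}

# dense polyline -> arc-length lookup table with position/tangent queries
curve_table <- function(P) {
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  list(P = P, s = s, length = s[length(s)])
}

curve_pos <- function(ct, sq) {
  sq <- pmin(pmax(sq, 0), ct$length)
  i <- pmin(findInterval(sq, ct$s, rightmost.closed = TRUE),
            nrow(ct$P) - 1L)
  w <- (sq - ct$s[i]) / pmax(ct$s[i + 1L] - ct$s[i], 1e-300)
  ct$P[i, , drop = FALSE] * (1 - w) + ct$P[i + 1L, , drop = FALSE] * w
}

curve_tan <- function(ct, sq) {
  sq <- pmin(pmax(sq, 0), ct$length)
  i <- pmin(findInterval(sq, ct$s, rightmost.closed = TRUE),
            nrow(ct$P) - 1L)
  d <- ct$P[i + 1L, , drop = FALSE] - ct$P[i, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

unitv <- function(v) v / sqrt(sum(v^2))

# orthonormal frame perpendicular to unit vector d
perp_frame <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- unitv(cross3(d, ref))
  n2 <- cross3(d, n1)
  list(n1 = n1, n2 = n2)
}

# sample a tube of given radius around an axis curve
sample_tube <- function(ct, radius, density) {
  n <- max(20L, round(density * 2 * pi * radius * ct$length))
  sq <- stats::runif(n, 0, ct$length)
  th <- stats::runif(n, 0, 2 * pi)
  pos <- curve_pos(ct, sq)
  tan <- curve_tan(ct, sq)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    fr <- perp_frame(tan[i, ])
    out[i, ] <- pos[i, ] + radius * (cos(th[i]) * fr$n1 + sin(th[i]) * fr$n2)
  }
  out
}

resolve_spec <- function(spec) {
  nt <- spec$n_tillers
  H <- spec$tiller_heights
  if (is.null(H)) {
    H <- stats::runif(nt, 40, 90)
    H[1] <- max(H) + stats::runif(1, 1, 5)  # main stem tallest
  }
  lean <- spec$tiller_lean_deg
  if (is.null(lean)) {
    lean <- stats::runif(nt, 2, 15)
    lean[1] <- stats::runif(1, 0, 4)
  }
  az <- spec$tiller_azimuth_deg
  if (is.null(az))
    az <- (stats::runif(1, 0, 360) + (seq_len(nt) - 1) * 360 / nt +
             stats::runif(nt, -25, 25)) %% 360
  bow <- spec$tiller_curvature
  if (is.null(bow)) bow <- stats::runif(nt, 0, 4)
  base_r <- c(0, stats::runif(max(0, nt - 1), 0.3, 1.0))
  bases <- cbind(base_r * cos(az * pi / 180), base_r * sin(az * pi / 180), 0)

  lp <- spec$leaf_params
  if (is.null(lp) && spec$leaves_per_tiller > 0L) {
    nl <- nt * spec$leaves_per_tiller
    lp <- data.frame(
      tiller = rep(seq_len(nt), each = spec$leaves_per_tiller),
      length = stats::runif(nl, 8, 25),
      width = stats::runif(nl, 0.6, 2.0),
      insert_frac = as.vector(vapply(seq_len(nt), function(t)
        sort(stats::runif(spec$leaves_per_tiller, 0.15, 0.85)),
        numeric(spec$leaves_per_tiller))),
      insert_angle = stats::runif(nl, 15, 45),
      azimuth = stats::runif(nl, 0, 360),
      arch = stats::runif(nl, 0.5, 3))
  }
  ear <- rep_len(as.logical(spec$has_ear), nt)
  elen <- spec$ear_length_cm
  erad <- spec$ear_radius_cm
  if (is.null(elen)) elen <- stats::runif(nt, 5, 10)
  if (is.null(erad)) erad <- stats::runif(nt, 0.5, 0.9)
  list(n_tillers = nt, heights = H, lean = lean, azimuth = az, bow = bow,
       bases = bases, leaf_params = lp, has_ear = ear,
       ear_length = rep_len(elen, nt), ear_radius = rep_len(erad, nt))
}

tiller_curve <- function(base, H, lean_deg, az_deg, bow, m = 400L) {
  u <- seq(0, 1, length.out = m)
  lean <- lean_deg * pi / 180
  azr <- az_deg * pi / 180
  d <- c(sin(lean) * cos(azr), sin(lean) * sin(azr), cos(lean))
  h_out <- c(cos(azr), sin(azr), 0)
  P <- outer(u * H, d) + outer(bow * u^2, h_out)
  sweep(P, 2, base, `+`)
}

leaf_curve <- function(A, t_local, angle_deg, az_deg, L, arch, m = 300L) {
  e1 <- unitv(t_local)
  hpsi <- c(cos(az_deg * pi / 180), sin(az_deg * pi / 180), 0)
  e2 <- hpsi - sum(hpsi * e1) * e1
  if (sqrt(sum(e2^2)) < 1e-8) e2 <- perp_frame(e1)$n1 else e2 <- unitv(e2)
  a <- angle_deg * pi / 180
  d0 <- cos(a) * e1 + sin(a) * e2
  g <- c(0, 0, -1)
  nd <- g - sum(g * d0) * d0
  if (sqrt(sum(nd^2)) < 1e-6) nd <- e2 else nd <- unitv(nd)
  u <- seq(0, 1, length.out = m)
  P <- sweep(outer(u * L, d0) + outer(arch * u^2, nd), 2, A, `+`)
  list(P = P, d0 = d0, droop = nd, lateral = unitv(cross3(d0, nd)))
}

ue <- 0.7  # lanceolate blade-shape exponents: widest ~1/3 from the base,
we <- 0.6  # blunt at the sheath end, acute at the apex

# width at relative midrib position u, peak width W
blade_width <- function(u, W) W * sin(pi * u^ue)^we

sample_leaf_strip <- function(lc, W, density) {
  ct <- curve_table(lc$P)
  mean_rel <- stats::integrate(function(u) sin(pi * u^ue)^we, 0, 1)$value
  area <- ct$length * W * mean_rel
  n <- max(40L, round(density * area))
  # draw arc positions with probability proportional to local width
  uu <- stats::runif(3L * n)
  keep <- stats::runif(3L * n) < sin(pi * uu^ue)^we
  uu <- uu[keep][seq_len(n)]
  uu[is.na(uu)] <- stats::runif(sum(is.na(uu)))
  sq <- uu * ct$length
  off <- stats::runif(n, -0.5, 0.5) * blade_width(uu, W)
  pos <- curve_pos(ct, sq)
  pos + outer(off, lc$lateral)
}

sample_ear <- function(center, axis, a, c_semi, density) {
  fr <- perp_frame(axis)
  area <- 4 * pi * ((a^1.6 * a^1.6 + 2 * (a^1.6 * c_semi^1.6)) / 3)^(1 / 1.6)
  n <- max(60L, round(density * area))
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  pts <- outer(v[, 1] * a, fr$n1) + outer(v[, 2] * a, fr$n2) +
    outer(v[, 3] * c_semi, axis)
  sweep(pts, 2, center, `+`)
}

#' Generate a synthetic wheat plant with ground truth
#'
#' Builds the plant described by a [plant_spec()]: tillers are point tubes
#' (radius 0.25 cm) around bowed axis curves, leaves are strips around arched
#' midribs whose width peaks mid-leaf, ears are ellipsoidal tufts capping
#' flagged tillers. Labels and instance ids are assigned from the generating
#' organs, then the MVS artifacts (jitter, dropout, base truncation) are
#' applied. Deterministic for a fixed `rng_seed`.
#'
#' @param spec A [plant_spec()].
#' @return List with `cloud` (a [labeled_cloud()]) and `truth`, a
#'   `wheat_truth` list holding per-tiller polylines/lengths/angles, per-leaf
#'   polylines/lengths/widths/base points/host tillers/insertion angles,
#'   per-ear lengths/volumes/attachment points, and plant height/girth.
#'   Ground-truth organ k (1-based) corresponds to cloud instance id k-1.
#' @export
generate_plant <- function(spec = plant_spec()) {
  validate_plant_spec(spec)
  with_seed(spec$rng_seed, {
    rs <- resolve_spec(spec)
    nt <- rs$n_tillers
    pts <- list(); sem <- list(); inst <- list(); col <- list()
    truth <- list(tillers = list(), leaves = list(), ears = list(),
                  main_stem = 1L)

    tiller_cts <- vector("list", nt)
    for (t in seq_len(nt)) {
      P <- tiller_curve(rs$bases[t, ], rs$heights[t], rs$lean[t],
                        rs$azimuth[t], rs$bow[t])
      ct <- curve_table(P)
      tiller_cts[[t]] <- ct
      tp <- sample_tube(ct, TUBE_RADIUS_CM, spec$sampling)
      pts <- c(pts, list(tp))
      sem <- c(sem, list(rep("tiller", nrow(tp))))
      inst <- c(inst, list(rep(t - 1L, nrow(tp))))
      col <- c(col, list(matrix(rep(c(120, 180, 80), each = nrow(tp)),
                                ncol = 3)))
      truth$tillers[[t]] <- list(
        id = t, polyline = P,
        length = ct$length, lean_deg = rs$lean[t],
        azimuth_deg = rs$azimuth[t], base = rs$bases[t, ],
        top = P[nrow(P), ])
    }

    lp <- rs$leaf_params
    if (!is.null(lp)) for (i in seq_len(nrow(lp))) {
      t <- lp$tiller[i]
      ct <- tiller_cts[[t]]
      s0 <- lp$insert_frac[i] * ct$length
      A <- as.numeric(curve_pos(ct, s0))
      tl <- as.numeric(curve_tan(ct, s0))
      lc <- leaf_curve(A, tl, lp$insert_angle[i], lp$azimuth[i],
                       lp$length[i], lp$arch[i])
      sp <- sample_leaf_strip(lc, lp$width[i], spec$sampling)
      lct <- curve_table(lc$P)
      pts <- c(pts, list(sp))
      sem <- c(sem, list(rep("leaf", nrow(sp))))
      inst <- c(inst, list(rep(i - 1L, nrow(sp))))
      col <- c(col, list(matrix(rep(c(60, 160, 60), each = nrow(sp)),
                                ncol = 3)))
      truth$leaves[[i]] <- list(
        id = i, host_tiller = t,
        polyline = lc$P,
        length = lct$length, width = lp$width[i],
        base = A, tip = lc$P[nrow(lc$P), ],
        angle_deg = lp$insert_angle[i], azimuth_deg = lp$azimuth[i],
        insert_frac = lp$insert_frac[i], attach_z = A[3])
    }

    e_id <- 0L
    for (t in seq_len(nt)) {
      if (!rs$has_ear[t]) next
      e_id <- e_id + 1L
      ct <- tiller_cts[[t]]
      top <- ct$P[nrow(ct$P), ]
      axis <- as.numeric(curve_tan(ct, ct$length))
      c_semi <- rs$ear_length[t] / 2
      center <- top + c_semi * axis
      ep <- sample_ear(center, axis, rs$ear_radius[t], c_semi, spec$sampling)
      pts <- c(pts, list(ep))
      sem <- c(sem, list(rep("ear", nrow(ep))))
      inst <- c(inst, list(rep(e_id - 1L, nrow(ep))))
      col <- c(col, list(matrix(rep(c(200, 190, 120), each = nrow(ep)),
                                ncol = 3)))
      truth$ears[[e_id]] <- list(
        id = e_id, host_tiller = t, length = rs$ear_length[t],
        volume = 4 / 3 * pi * rs$ear_radius[t]^2 * c_semi,
        attachment = top)
    }

    P <- do.call(rbind, pts)
    semantic <- unlist(sem)
    instance <- unlist(inst)
    colors <- do.call(rbind, col)
    truth$plant <- list(height = max(P[, 3]) - min(P[, 3]),
                        n_tillers = nt,
                        n_leaves = if (is.null(lp)) 0L else nrow(lp),
                        n_ears = e_id)
    truth$spec <- spec
    truth$resolved <- rs
    class(truth) <- "wheat_truth"

    # --- MVS artifacts, applied after labelling ---
    n <- nrow(P)
    if (spec$noise_sd_cm > 0)
      P <- P + matrix(stats::rnorm(3 * n, 0, spec$noise_sd_cm), n, 3)
    keep <- rep(TRUE, n)
    target <- round(spec$dropout_fraction * n)
    if (target > 0) {
      uni <- sample.int(n, ceiling(target / 2))
      keep[uni] <- FALSE
      removed <- sum(!keep)
      tries <- 0L
      while (removed < target && tries < 40L) {
        ctr <- P[sample(which(keep), 1L), ]
        hole <- keep & (rowSums(sweep(P, 2, ctr)^2) < 0.8^2)
        keep[hole] <- FALSE
        removed <- sum(!keep)
        tries <- tries + 1L
      }
    }
    if (spec$base_missing_cm > 0)
      keep <- keep & !(semantic == "tiller" & P[, 3] < spec$base_missing_cm)
    cloud <- labeled_cloud(P[keep, , drop = FALSE], semantic[keep],
                           instance[keep], colors[keep, , drop = FALSE])
    list(cloud = cloud, truth = truth)
  })
}

#' Two-tiller fixture with controllable overlap
#'
#' Builds two leafless tillers whose axes approach each other at a given
#' height fraction, the regime used to probe tiller tracing under organ
#' overlap: well-separated bases trace cleanly, close approaches force the
#' slice clusters to merge locally, and (near-)coincident tillers are the
#' documented merge-failure mode.
#'
#' @param separation_cm Distance between the two tiller bases (>= 0).
#' @param crossing_height_fraction Height fraction (0-1) of closest approach.
#' @param seed Integer RNG seed for the surface sampling.
#' @param height_cm Tiller height (both tillers).
#' @param sampling,noise_sd_cm Sampling density and jitter, as in
#'   [plant_spec()].
#' @return List with `cloud` (tiller points only; instance id = tiller - 1,
#'   giving per-point membership ground truth) and `truth` with the two axis
#'   polylines, the minimum inter-axis distance, and `degenerate = TRUE` when
#'   the tillers mostly coincide and tracing is expected to merge them.
#' @export
make_crossing_tillers <- function(separation_cm, crossing_height_fraction = 0.5,
                                  seed = 1L, height_cm = 60,
                                  sampling = 30, noise_sd_cm = 0.05) {
  stopifnot(separation_cm >= 0)
  hf <- crossing_height_fraction
  stopifnot(hf > 0, hf < 1)
  with_seed(seed, {
    H <- height_cm
    # each tiller swerves smoothly across (a kink would make the *straight*
    # continuation the other tiller); the tanh scale gives a peak slope of
    # ~45 degrees at the crossing, so the two axes stay within
    # clustering-merge distance only over a couple of slabs
    D <- min(separation_cm, 8)
    lam <- 4
    yoff <- min(0.5, separation_cm / 10)
    z <- seq(0, H, length.out = 400L)
    swerve <- D * (1 + tanh((z - hf * H) / lam)) / 2
    PA <- cbind(-separation_cm / 2 + swerve, rep(-yoff / 2, 400L), z)
    PB <- cbind(separation_cm / 2 - swerve, rep(yoff / 2, 400L), z)
    ctA <- curve_table(PA); ctB <- curve_table(PB)
    tA <- sample_tube(ctA, TUBE_RADIUS_CM, sampling)
    tB <- sample_tube(ctB, TUBE_RADIUS_CM, sampling)
    P <- rbind(tA, tB)
    if (noise_sd_cm > 0)
      P <- P + matrix(stats::rnorm(3 * nrow(P), 0, noise_sd_cm), ncol = 3)
    cloud <- labeled_cloud(P, rep("tiller", nrow(P)),
                           c(rep(0L, nrow(tA)), rep(1L, nrow(tB))))
    min_gap <- min(sqrt(rowSums((PA - PB)^2)))
    truth <- structure(list(
      tillers = list(
        list(id = 1L, polyline = PA, length = ctA$length),
        list(id = 2L, polyline = PB, length = ctB$length)),
      min_axis_gap = min_gap,
      degenerate = separation_cm <= 2 * TUBE_RADIUS_CM,
      plant = list(height = H, n_tillers = 2L)), class = "wheat_truth")
    list(cloud = cloud, truth = truth)
  })
}

#' @export
print.wheat_truth <- function(x, ...) {
  cat("Synthetic wheat plant ground truth\n")
  cat("  tillers:", length(x$tillers),
      " leaves:", length(x$leaves),
      " ears:", length(x$ears), "\n")
  if (!is.null(x$plant$height))
    cat(sprintf("  plant height: %.1f cm\n", x$plant$height))
  if (isTRUE(x$degenerate))
    cat("  flagged degenerate: overlapping tillers, tracing expected to merge\n")
  invisible(x)
}

#' Serialize ground truth to JSON
#' @param truth A `wheat_truth` object.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$spec <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
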