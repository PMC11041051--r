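# Pipeline orchestration and the user-facing model object.

#' Reconstruction parameters
#'
#' All tunable parameters of the reconstruction pipeline, with the defaults
#' used throughout: 2-cm slabs, DBSCAN eps 1 cm (twice the repair-cylinder
#' radius) with 5-point cores, score weights alpha = 2 / beta = 1
#' (horizontal drift is penalised more because tillers are near-vertical),
#' link caps of 12 score units / 35 degrees bend / 2 skipped slabs (a link
#' spanning g empty slabs carries an unavoidable vertical distance of about
#' 2*(g+1) cm, so the score cap leaves room for beta*6 plus an alpha*3
#' lateral allowance; a tighter cap would silently forbid the slab gaps the
#' gap cap is meant to permit), 4-point
#' minimum chains, the 1000-point k-means switch, the 1.75 x avgD attachment
#' correction, a 0.5 bottom/top zone split, and a 3-cm snap cap.
#'
#' @param slab_height_cm Tiller slab height.
#' @param eps_cm,min_samples Per-slab DBSCAN parameters.
#' @param alpha,beta Score-table weights (horizontal, vertical).
#' @param max_score,max_slope_deg,max_bend_deg,max_gap_slabs Link
#'   admissibility caps (score, link slope from vertical, inter-segment
#'   bend, skipped slabs).
#' @param min_skeleton_points Minimum chain size kept.
#' @param kmeans_threshold Leaf point count switching k from 4 to 7.
#' @param attach_factor Attachment-correction trigger multiplier.
#' @param z_split Relative height splitting bottom/top base heuristics.
#' @param snap_max_cm Maximum leaf-to-attachment snap distance.
#' @param cylinder_height_cm,cylinder_radius_cm Repair cylinder shape.
#' @return A `recon_control` list.
#' @export
recon_control <- function(slab_height_cm = 2, eps_cm = 1.0, min_samples = 5L,
                          alpha = 2, beta = 1, max_score = 12,
                          max_slope_deg = 60, max_bend_deg = 35,
                          max_gap_slabs = 2L,
                          min_skeleton_points = 4L,
                          kmeans_threshold = 1000L,
                          attach_factor = 1.75, z_split = 0.5,
                          snap_max_cm = 3,
                          cylinder_height_cm = 2, cylinder_radius_cm = 0.5) {
  structure(list(slab_height_cm = slab_height_cm, eps_cm = eps_cm,
                 min_samples = as.integer(min_samples), alpha = alpha,
                 beta = beta, max_score = max_score,
                 max_slope_deg = max_slope_deg,
                 max_bend_deg = max_bend_deg,
                 max_gap_slabs = as.integer(max_gap_slabs),
                 min_skeleton_points = as.integer(min_skeleton_points),
                 kmeans_threshold = as.integer(kmeans_threshold),
                 attach_factor = attach_factor, z_split = z_split,
                 snap_max_cm = snap_max_cm,
                 cylinder_height_cm = cylinder_height_cm,
                 cylinder_radius_cm = cylinder_radius_cm),
            class = "recon_control")
}

ear_clouds_of <- function(cloud) {
  sel <- cloud$semantic == "ear"
  ids <- sort(unique(cloud$instance[sel]))
  stats::setNames(
    lapply(ids, function(id)
      cloud$points[sel & cloud$instance == id, , drop = FALSE]),
    as.character(ids))
}

#' Reconstruct a wheat plant from a labelled point cloud
#'
#' The full reconstruction: tiller slab slicing, per-slab density
#' clustering, scored top-down skeleton tracing, short-chain filtering and
#' base extension; per-leaf k-means skeletonization, endpoint extraction,
#' base identification and minD/avgD attachment correction; phytomer
#' assembly; and extraction of the 18 morphological parameters.
#'
#' @param cloud An instance-segmented [labeled_cloud()].
#' @param control A [recon_control()] parameter list.
#' @return A `wheat_plant` object with elements `model` (the assembled
#'   [assemble_plant()] result), `report` (the [compile_report()] phenotype
#'   report) and `control`. Methods: `print`, `summary`, `coef` (plant-level
#'   parameters as a named vector), `plot`.
#' @examples
#' \donttest{
#' pl <- generate_plant(plant_spec(rng_seed = 7))
#' fit <- reconstruct_plant(pl$cloud)
#' coef(fit)
#' }
#' @export
reconstruct_plant <- function(cloud, control = recon_control()) {
  validate_cloud(cloud, instance_segmented = TRUE)
  tstage <- trace_tiller_skeletons(cloud, control)
  lstage <- extract_leaf_skeletons(cloud, control)
  att <- if (length(lstage$skeletons))
    locate_attachments(lstage$skeletons, tstage$skeletons,
                       control$attach_factor)
  else list(skeletons = list(), records = list())
  model <- assemble_plant(tstage$skeletons, att$skeletons, att$records,
                          ears = ear_clouds_of(cloud),
                          leaf_segments = lstage$segments,
                          cloud = cloud,
                          snap_max_cm = control$snap_max_cm)
  report <- compile_report(model)
  structure(list(model = model, report = report, control = control,
                 clusters = tstage$clusters),
            class = "wheat_plant")
}

#' @export
print.wheat_plant <- function(x, ...) {
  cat("Reconstructed wheat plant\n")
  print(x$report)
  invisible(x)
}

#' @export
summary.wheat_plant <- function(object, ...) {
  print(object)
  cat("\nPer-tiller parameters:\n")
  print(object$report$tillers, row.names = FALSE)
  if (!is.null(object$report$leaves)) {
    cat("\nPer-leaf parameters:\n")
    print(object$report$leaves, row.names = FALSE)
  }
  if (!is.null(object$report$ears)) {
    cat("\nPer-ear parameters:\n")
    print(object$report$ears, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.wheat_plant <- function(object, ...) {
  r <- object$report
  c(n_tillers = r$n_tillers, main_stem = r$main_stem_id,
    plant_height_cm = r$plant_height_cm, girth_cm = r$girth_cm,
    n_leaves = r$n_leaves, n_ears = r$n_ears)
}

#' Plot a reconstructed plant
#'
#' Side (x-z) projection of the traced tiller skeletons (solid), leaf
#' skeleton polylines (coloured), ear points (grey) and, optionally, the
#' underlying cloud.
#'
#' @param x A `wheat_plant`.
#' @param show_cloud Draw the source cloud points behind the skeletons?
#' @param ... Passed to `plot.default`.
#' @export
plot.wheat_plant <- function(x, show_cloud = TRUE, ...) {
  m <- x$model
  allp <- do.call(rbind, c(lapply(m$tillers, `[[`, "points"),
                           lapply(m$leaves, `[[`, "polyline")))
  plot(allp[, 1], allp[, 3], type = "n", xlab = "x (cm)", ylab = "z (cm)",
       asp = 1, ...)
  if (show_cloud && !is.null(m$cloud))
    graphics::points(m$cloud$points[, 1], m$cloud$points[, 3],
                     pch = ".", col = "grey80")
  for (e in m$ears)
    graphics::points(e[, 1], e[, 3], pch = ".", col = "grey50")
  for (t in m$tillers)
    graphics::lines(t$points[, 1], t$points[, 3], lwd = 2)
  cols <- grDevices::hcl.colors(max(1L, length(m$leaves)), "Dark 3")
  for (i in seq_along(m$leaves))
    graphics::lines(m$leaves[[i]]$polyline[, 1], m$leaves[[i]]$polyline[, 3],
                    col = cols[i], lwd = 1.5)
  invisible(x)
}

#' Run the full pipeline, optionally against ground truth
#'
#' Orchestrates generation (or ingestion), reconstruction and phenotyping;
#' when ground truth is available the per-parameter recovery comparison is
#' appended. Stage failures are re-raised with the stage name.
#'
#' @param cloud A labelled cloud, or `NULL` to generate one from `spec`.
#' @param spec A [plant_spec()] used when `cloud` is `NULL`.
#' @param truth Optional `wheat_truth`; filled automatically when the cloud
#'   is generated here.
#' @param control A [recon_control()].
#' @return List with `plant` (the `wheat_plant`), `report`, `truth` and,
#'   when truth is present, `recovery` (see [evaluate_plant_recovery()]).
#' @export
run_pipeline <- function(cloud = NULL, spec = NULL, truth = NULL,
                         control = recon_control()) {
  if (is.null(cloud)) {
    if (is.null(spec)) stop("pipeline: supply a cloud or a plant spec")
    gen <- generate_plant(spec)
    cloud <- gen$cloud
    truth <- gen$truth
  }
  plant <- withCallingHandlers(
    tryCatch(reconstruct_plant(cloud, control),
             error = function(e)
               stop("reconstruction stage failed: ", conditionMessage(e),
                    call. = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"))
  out <- list(plant = plant, report = plant$report, truth = truth)
  if (!is.null(truth))
    out$recovery <- evaluate_plant_recovery(plant, truth)
  out
}

# match traced skeletons to ground-truth tiller axes by mean point-to-axis
# distance (greedy, best first)
match_tillers_to_truth <- function(tillers, truth) {
  nt <- length(truth$tillers)
  d <- matrix(Inf, length(tillers), nt)
  for (i in seq_along(tillers)) {
    P <- tillers[[i]]$points
    for (j in seq_len(nt)) {
      G <- truth$tillers[[j]]$polyline
      d[i, j] <- mean(apply(P, 1, function(p)
        sqrt(min(rowSums(sweep(G, 2, p)^2)))))
    }
  }
  map <- rep(NA_integer_, length(tillers))
  dd <- d
  for (k in seq_len(min(dim(d)))) {
    ij <- arrayInd(which.min(dd), dim(dd))
    if (!is.finite(dd[ij])) break
    map[ij[1]] <- ij[2]
    dd[ij[1], ] <- Inf; dd[, ij[2]] <- Inf
  }
  map
}

#' Compare a reconstruction with its generating ground truth
#'
#' Matches traced tillers to true axes and leaves by instance id, and
#' tabulates extracted-vs-true values for tiller length, leaf length, leaf
#' width, attachment height, stem-leaf angle, plus base-endpoint and
#' host-tiller correctness.
#'
#' @param plant A `wheat_plant`.
#' @param truth The generating `wheat_truth`.
#' @return List of data.frames `tillers`, `leaves`, and scalar
#'   `n_tillers_traced` / `n_tillers_true`.
#' @export
evaluate_plant_recovery <- function(plant, truth) {
  m <- plant$model
  map <- match_tillers_to_truth(m$tillers, truth)
  t_df <- do.call(rbind, lapply(seq_along(m$tillers), function(i) {
    if (is.na(map[i])) return(NULL)
    data.frame(traced = i, true = map[i],
               length_true = truth$tillers[[map[i]]]$length,
               length_hat = tiller_length(m$tillers[[i]]))
  }))
  l_df <- NULL
  if (length(m$leaves)) {
    l_df <- do.call(rbind, lapply(seq_along(m$leaves), function(i) {
      sk <- m$leaves[[i]]
      rec <- m$records[[i]]
      tr <- truth$leaves[[sk$leaf_id]]
      base_hat <- sk$polyline[1L, ]
      d_base <- sqrt(sum((base_hat - tr$base)^2))
      d_tip <- sqrt(sum((base_hat - tr$tip)^2))
      host_true <- NA_integer_
      if (!isTRUE(rec$unattached) && !is.na(rec$host_tiller)) {
        tix <- which(vapply(m$tillers, `[[`, integer(1), "id") ==
                       rec$host_tiller)
        if (length(tix) && !is.na(map[tix])) host_true <- map[tix]
      }
      row <- plant$report$leaves[plant$report$leaves$id == sk$leaf_id, ]
      data.frame(leaf = sk$leaf_id,
                 length_true = tr$length, length_hat = leaf_length(sk),
                 width_true = tr$width, width_hat = row$width_cm,
                 attach_z_true = tr$attach_z, attach_z_hat = row$attach_z,
                 angle_true = tr$angle_deg, angle_hat = row$angle_deg,
                 base_correct = d_base < d_tip,
                 host_correct = !is.na(host_true) &&
                   host_true == tr$host_tiller)
    }))
  }
  list(tillers = t_df, leaves = l_df,
       n_tillers_traced = length(m$tillers),
       n_tillers_true = truth$plant$n_tillers)
}

#' Multi-plant recovery study
#'
#' Generates `n` synthetic plants under the default study conditions (2-4
#' tillers, 3 leaves per tiller, default noise/dropout/base truncation),
#' reconstructs each, and pools the recovery comparisons.
#'
#' @param n Number of plants.
#' @param seed Base seed; plant i uses `seed * 1000 + i`.
#' @param n_tillers_range Inclusive range tiller counts are drawn from.
#' @param control A [recon_control()].
#' @return List with pooled data.frames `tillers` and `leaves`, the
#'   per-plant tiller-count table `counts`, and `metrics`: R^2/RMSE for
#'   tiller length, leaf length, leaf width and attachment height, mean
#'   absolute stem-leaf angle error, and base/host accuracies.
#' @export
recovery_study <- function(n = 50L, seed = 1L, n_tillers_range = c(2L, 4L),
                           control = recon_control()) {
  tl <- list(); ll <- list(); cnt <- list()
  for (i in seq_len(n)) {
    si <- seed * 1000L + i
    nt <- with_seed(si, sample(seq(n_tillers_range[1], n_tillers_range[2]),
                               1L))
    res <- run_pipeline(spec = plant_spec(n_tillers = nt, rng_seed = si),
                        control = control)
    rec <- res$recovery
    tl[[i]] <- rec$tillers
    ll[[i]] <- rec$leaves
    cnt[[i]] <- data.frame(plant = i, traced = rec$n_tillers_traced,
                           true = rec$n_tillers_true)
  }
  tillers <- do.call(rbind, tl)
  leaves <- do.call(rbind, ll)
  counts <- do.call(rbind, cnt)
  metrics <- list(
    tiller_length = recovery_metrics(tillers$length_true, tillers$length_hat),
    leaf_length = recovery_metrics(leaves$length_true, leaves$length_hat),
    leaf_width = recovery_metrics(leaves$width_true, leaves$width_hat),
    attach_height = recovery_metrics(leaves$attach_z_true,
                                     leaves$attach_z_hat),
    angle_mae = mean(abs(leaves$angle_true - leaves$angle_hat), na.rm = TRUE),
    base_accuracy = mean(leaves$base_correct),
    host_accuracy = mean(leaves$host_correct),
    count_accuracy = mean(counts$traced == counts$true))
  list(tillers = tillers, leaves = leaves, counts = counts,
       metrics = metrics)
}
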