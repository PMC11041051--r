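#' Semantic classes recognised by the pipeline
#'
#' Organ classes carried by every labelled cloud, in their canonical order.
#' The order defines the label ordinal used to break majority-vote ties when
#' downsampling.
#'
#' @format Character vector of length 4.
#' @export
SEMANTIC_LEVELS <- c("leaf", "tiller", "ear", "unknown")

#' Construct a labelled point cloud
#'
#' The pipeline's universal input: a set of 3D points (cm, z-up) with a
#' semantic organ label per point and, for leaf and ear points, an organ
#' instance id. Instance ids are per-class contiguous integers starting at 0;
#' -1 marks an unassigned point.
#'
#' @param points Numeric matrix with 3 columns (x, y, z) in cm.
#' @param semantic Character vector, one of [SEMANTIC_LEVELS] per point.
#' @param instance Integer vector of per-point instance ids (-1 =
#'   unassigned). Defaults to all -1.
#' @param colors Optional numeric matrix with 3 columns (r, g, b) in 0-255.
#' @return An object of class `wheat_cloud`: a list with elements `points`,
#'   `semantic`, `instance` and (optionally NULL) `colors`.
#' @examples
#' pts <- cbind(runif(10), runif(10), runif(10))
#' cl <- labeled_cloud(pts, rep("tiller", 10), rep(0L, 10))
#' cl
#' @export
labeled_cloud <- function(points, semantic, instance = NULL, colors = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have three columns (x, y, z)")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  n <- nrow(points)
  semantic <- as.character(semantic)
  if (length(semantic) != n)
    stop("`semantic` must have one label per point")
  bad <- setdiff(unique(semantic), SEMANTIC_LEVELS)
  if (length(bad))
    stop("unknown semantic label(s): ", paste(bad, collapse = ", "))
  if (is.null(instance)) instance <- rep(-1L, n)
  instance <- as.integer(instance)
  if (length(instance) != n)
    stop("`instance` must have one id per point")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (nrow(colors) != n || ncol(colors) != 3L)
      stop("`colors` must be an n x 3 matrix")
    colnames(colors) <- c("r", "g", "b")
  }
  structure(
    list(points = points, semantic = semantic,
         instance = instance, colors = colors),
    class = "wheat_cloud"
  )
}

#' Number of points in a labelled cloud
#' @param cloud A `wheat_cloud`.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Validate labelled-cloud invariants
#'
#' Checks the structural invariants of a labelled cloud: equal field lengths,
#' known semantic labels, and (when `instance_segmented = TRUE`) that every
#' leaf- and ear-labelled point carries an instance id >= 0 and that no
#' instance id spans two semantic classes.
#'
#' @param cloud A `wheat_cloud`.
#' @param instance_segmented Require instance ids on leaf/ear points?
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_cloud <- function(cloud, instance_segmented = FALSE) {
  stopifnot(inherits(cloud, "wheat_cloud"))
  n <- nrow(cloud$points)
  if (length(cloud$semantic) != n || length(cloud$instance) != n)
    stop("cloud fields have unequal lengths")
  if (!is.null(cloud$colors) && nrow(cloud$colors) != n)
    stop("cloud colors length differs from points")
  if (instance_segmented) {
    need <- cloud$semantic %in% c("leaf", "ear")
    if (any(cloud$instance[need] < 0L))
      stop("instance-segmented cloud has leaf/ear points without instance id")
  }
  invisible(TRUE)
}

#' Subset a labelled cloud by point index
#' @param cloud A `wheat_cloud`.
#' @param idx Integer or logical index into the points.
#' @return A `wheat_cloud` holding the selected points.
#' @export
cloud_subset <- function(cloud, idx) {
  labeled_cloud(cloud$points[idx, , drop = FALSE],
                cloud$semantic[idx],
                cloud$instance[idx],
                if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE])
}

#' Concatenate labelled clouds
#' @param ... `wheat_cloud` objects. Colors are kept only if present on all.
#' @return A single `wheat_cloud`.
#' @export
cloud_bind <- function(...) {
  cls <- list(...)
  cls <- cls[vapply(cls, function(x) n_points(x) > 0L, logical(1))]
  if (!length(cls)) stop("nothing to bind")
  cols <- NULL
  if (all(vapply(cls, function(x) !is.null(x$colors), logical(1))))
    cols <- do.call(rbind, lapply(cls, `[[`, "colors"))
  labeled_cloud(do.call(rbind, lapply(cls, `[[`, "points")),
                unlist(lapply(cls, `[[`, "semantic")),
                unlist(lapply(cls, `[[`, "instance")),
                cols)
}

#' @export
print.wheat_cloud <- function(x, ...) {
  n <- n_points(x)
  cat("Labelled wheat point cloud:", n, "points\n")
  if (n) {
    tab <- table(factor(x$semantic, levels = SEMANTIC_LEVELS))
    cat("  semantic:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent:  x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] cm\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
    for (cl in c("leaf", "ear")) {
      ids <- unique(x$instance[x$semantic == cl & x$instance >= 0L])
      if (length(ids)) cat("  ", cl, " instances: ", length(ids), "\n", sep = "")
    }
  }
  invisible(x)
}

# run code with a temporarily-seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
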