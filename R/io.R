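#' Describe an on-disk labelled-cloud layout
#'
#' Two layouts are supported: a single ASCII PLY file carrying `semantic`
#' (uint8 ordinal) and `instance` (int32) vertex properties, and an
#' S3DIS-style directory holding one `<class>_<id>.txt` file per organ
#' instance with whitespace-separated `x y z r g b` rows.
#'
#' @param layout `"ply"` or `"s3dis_dir"`.
#' @param semantic_names Named character vector mapping the canonical class
#'   names ([SEMANTIC_LEVELS]) to the strings used on disk.
#' @return A `cloud_format` specification list. Units are cm throughout.
#' @export
cloud_format <- function(layout = c("ply", "s3dis_dir"),
                         semantic_names = NULL) {
  layout <- match.arg(layout)
  if (is.null(semantic_names))
    semantic_names <- stats::setNames(SEMANTIC_LEVELS, SEMANTIC_LEVELS)
  structure(list(layout = layout, semantic_names = semantic_names,
                 units = "cm"),
            class = "cloud_format")
}

s3dis_class_of <- function(fname, spec) {
  stem <- sub("_[0-9]+\\.txt$", "", basename(fname))
  hit <- names(spec$semantic_names)[match(stem, spec$semantic_names)]
  if (is.na(hit))
    stop("unknown semantic name '", stem, "' in file ", basename(fname))
  hit
}

read_s3dis_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty instance file: ", basename(path))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop("malformed row in ", basename(path), " line ", bad,
         ": expected 6 fields 'x y z r g b', got ", nf[bad])
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad <- which(vapply(fields, function(f)
      anyNA(suppressWarnings(as.numeric(f))), logical(1)))[1L]
    stop("malformed row in ", basename(path), " line ", bad,
         ": non-numeric field")
  }
  m <- matrix(vals, ncol = 6L, byrow = TRUE)
  list(points = m[, 1:3, drop = FALSE], colors = m[, 4:6, drop = FALSE])
}

#' Read a labelled plant point cloud
#'
#' @param path A PLY file or an S3DIS-style directory, per `spec$layout`.
#' @param spec A [cloud_format()] specification.
#' @return A [labeled_cloud()]. For the directory layout, instance ids are
#'   assigned per class as contiguous integers from 0 in sorted-filename
#'   order, so re-reads are deterministic.
#' @export
read_labeled_cloud <- function(path, spec = cloud_format("ply")) {
  if (spec$layout == "ply") return(read_ply_cloud(path, spec))
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- sort(list.files(path, pattern = "_[0-9]+\\.txt$", full.names = TRUE))
  if (!length(files)) stop("empty input: no instance files under ", path)
  parts <- lapply(files, read_s3dis_file)
  classes <- vapply(files, s3dis_class_of, character(1), spec = spec)
  next_id <- stats::setNames(integer(length(SEMANTIC_LEVELS)), SEMANTIC_LEVELS)
  pts <- list(); cols <- list(); sem <- list(); inst <- list()
  for (i in seq_along(files)) {
    n <- nrow(parts[[i]]$points)
    cl <- classes[i]
    pts[[i]] <- parts[[i]]$points
    cols[[i]] <- parts[[i]]$colors
    sem[[i]] <- rep(cl, n)
    inst[[i]] <- rep(next_id[[cl]], n)
    next_id[[cl]] <- next_id[[cl]] + 1L
  }
  labeled_cloud(do.call(rbind, pts), unlist(sem), unlist(inst),
                do.call(rbind, cols))
}

#' Write a labelled plant point cloud
#'
#' @param cloud A [labeled_cloud()] with at least one point.
#' @param path Destination PLY file or directory.
#' @param spec A [cloud_format()] specification.
#' @return Invisibly `path`. The artifact round-trips through
#'   [read_labeled_cloud()] with identical points, semantic labels and
#'   instance ids. The directory layout requires colours on disk; clouds
#'   without colours are written with r = g = b = 0. Points the directory
#'   layout cannot key (instance -1) are grouped into a single per-class
#'   instance file.
#' @export
write_labeled_cloud <- function(cloud, path, spec = cloud_format("ply")) {
  validate_cloud(cloud)
  if (n_points(cloud) == 0L) stop("refusing to write an empty plant cloud")
  if (spec$layout == "ply") return(write_ply_cloud(cloud, path, spec))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cols <- cloud$colors
  if (is.null(cols)) cols <- matrix(0, n_points(cloud), 3L)
  for (cl in unique(cloud$semantic)) {
    sel <- which(cloud$semantic == cl)
    ids <- cloud$instance[sel]
    ids[ids < 0L] <- if (any(ids >= 0L)) max(ids) + 1L else 0L
    for (id in sort(unique(ids))) {
      rows <- sel[ids == id]
      m <- cbind(cloud$points[rows, , drop = FALSE],
                 cols[rows, , drop = FALSE])
      f <- file.path(path, sprintf("%s_%03d.txt",
                                   spec$semantic_names[[cl]], id))
      utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                         f, quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

read_ply_cloud <- function(path, spec) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", lines)
  if (is.na(end) || lines[1] != "ply")
    stop("not an ASCII PLY file: ", path)
  fmt <- grep("^format ", lines[seq_len(end)], value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stop("only ASCII PLY is supported: ", path)
  el <- grep("^element vertex ", lines[seq_len(end)], value = TRUE)
  nv <- as.integer(sub("^element vertex ", "", el[1]))
  props <- sub("^property [a-z0-9]+ ", "",
               grep("^property ", lines[seq_len(end)], value = TRUE))
  body <- lines[(end + 1L):(end + nv)]
  fields <- strsplit(trimws(body), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != length(props))) {
    bad <- which(nf != length(props))[1L]
    stop("malformed PLY row at vertex line ", bad)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = length(props), byrow = TRUE)
  colnames(m) <- props
  need <- c("x", "y", "z", "semantic", "instance")
  if (!all(need %in% props)) stop("PLY is missing labelled-cloud properties")
  sem <- SEMANTIC_LEVELS[m[, "semantic"] + 1L]
  cols <- NULL
  if (all(c("red", "green", "blue") %in% props))
    cols <- m[, c("red", "green", "blue"), drop = FALSE]
  labeled_cloud(m[, c("x", "y", "z"), drop = FALSE], sem,
                as.integer(m[, "instance"]), cols)
}

write_ply_cloud <- function(cloud, path, spec) {
  n <- n_points(cloud)
  has_col <- !is.null(cloud$colors)
  hdr <- c("ply", "format ascii 1.0",
           "comment labelled wheat plant point cloud (cm, z-up)",
           paste("element vertex", n),
           "property double x", "property double y", "property double z")
  if (has_col)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, "property uchar semantic", "property int instance",
           "end_header")
  sem_ord <- match(cloud$semantic, SEMANTIC_LEVELS) - 1L
  cols <- if (has_col)
    paste(as.integer(cloud$colors[, 1]), as.integer(cloud$colors[, 2]),
          as.integer(cloud$colors[, 3]))
  xyz <- apply(cloud$points, 1, function(p)
    paste(sprintf("%.17g", p), collapse = " "))
  body <- if (has_col) paste(xyz, cols, sem_ord, cloud$instance)
          else paste(xyz, sem_ord, cloud$instance)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Voxel-grid downsampling of a labelled cloud
#'
#' Density normalisation: the cloud's bounding box is tiled with half-open
#' cubic voxels `[min + k*v, min + (k+1)*v)` anchored at the axis-aligned
#' minimum corner, and each occupied voxel is replaced by the centroid of its
#' points. Semantic and instance labels are decided by majority vote within
#' the voxel; ties go to the lowest label ordinal (semantic) or the lowest id
#' (instance).
#'
#' @param cloud A [labeled_cloud()].
#' @param voxel_cm Positive voxel edge length in cm.
#' @return A downsampled `wheat_cloud` (empty cloud in, empty cloud out).
#' @export
voxel_downsample <- function(cloud, voxel_cm = 0.1) {
  stopifnot(voxel_cm > 0)
  n <- n_points(cloud)
  if (n == 0L) return(cloud)
  lo <- apply(cloud$points, 2, min)
  key <- floor(sweep(sweep(cloud$points, 2, lo), 2, voxel_cm, `/`))
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  grp <- match(kstr, unique(kstr))
  ng <- max(grp)
  pts <- rowsum(cloud$points, grp) / as.vector(table(grp))
  sem_ord <- match(cloud$semantic, SEMANTIC_LEVELS)
  maj <- function(v) {
    tab <- table(v)
    vals <- as.integer(names(tab))
    vals[order(-as.integer(tab), vals)][1L]  # ties: lowest ordinal / id
  }
  sem <- SEMANTIC_LEVELS[vapply(split(sem_ord, grp), maj, integer(1))]
  inst <- vapply(split(cloud$instance, grp), maj, integer(1))
  cols <- if (!is.null(cloud$colors))
    round(rowsum(cloud$colors, grp) / as.vector(table(grp)))
  labeled_cloud(pts, sem, inst, cols)
}
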