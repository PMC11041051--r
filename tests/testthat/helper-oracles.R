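# Independent oracles and small fixture builders shared across the suite.
# These deliberately use brute force / closed forms, never the package's own
# code paths, so they can vouch for the implementations they check.

# exhaustive smallest enclosing circle: minimum over all circles through
# 2 or 3 of the points that contain all points
brute_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  tol <- 1e-9 * max(1, abs(pts))
  contains_all <- function(ctr, r) all(sqrt(rowSums(sweep(pts, 2, ctr)^2)) <= r + tol)
  best_r <- Inf; best_ctr <- NULL
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best_r && contains_all(ctr, r)) { best_r <- r; best_ctr <- ctr }
  }
  if (n >= 3L) for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
             sum(cc^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
             sum(cc^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    r <- sqrt(sum((a - ctr)^2))
    if (r < best_r && contains_all(ctr, r)) { best_r <- r; best_ctr <- ctr }
  }
  list(center = best_ctr, radius = best_r)
}

# exhaustive minimum-total-link-score partition of the score table's centres
# into two height-descending chains
brute_best_two_chains <- function(tab) {
  n <- nrow(tab$centers)
  stopifnot(n <= 14L)
  cost_of <- function(assign) {
    total <- 0
    for (ch in 1:2) {
      idx <- which(assign == ch)  # already in descending-height order
      if (length(idx) >= 2L)
        for (q in seq_len(length(idx) - 1L))
          total <- total + tab$score[idx[q], idx[q + 1L]]
    }
    total
  }
  best <- Inf; best_assign <- NULL
  for (mask in 0:(2^n - 1L)) {
    assign <- as.integer(intToBits(mask))[seq_len(n)] + 1L
    cst <- cost_of(assign)
    if (cst < best) { best <- cst; best_assign <- assign }
  }
  list(cost = best, assign = best_assign)
}

# total link score actually used by a set of traced chains
chains_link_score <- function(skeletons, tab) {
  total <- 0
  for (s in skeletons) {
    idx <- rev(s$centers_idx[!is.na(s$centers_idx)])  # top-down order
    if (length(idx) >= 2L)
      for (q in seq_len(length(idx) - 1L))
        total <- total + tab$score[idx[q], idx[q + 1L]]
  }
  total
}

# AP via exhaustive prefix matching: for every prediction prefix (confidence
# order) the maximum number of threshold-feasible matches is found by
# enumerating injective assignments, giving the precision-recall curve
brute_instance_ap <- function(preds, truths, thr) {
  nt <- length(truths)
  if (!length(preds)) return(list(AP = 0, recall = if (nt) 0 else NA_real_))
  conf <- vapply(preds, `[[`, numeric(1), "confidence")
  preds <- preds[order(-conf)]
  iou <- outer(seq_along(preds), seq_len(max(nt, 1L)),
               Vectorize(function(i, j)
                 if (nt) length(intersect(preds[[i]]$points, truths[[j]]$points)) /
                   length(union(preds[[i]]$points, truths[[j]]$points)) else 0))
  max_match <- function(k) {
    if (!nt) return(0L)
    best <- 0L
    rec <- function(i, used, cnt) {
      if (cnt + (k - i + 1L) <= best || i > k) {
        best <<- max(best, cnt); return(invisible())
      }
      rec(i + 1L, used, cnt)  # leave pred i unmatched
      for (j in seq_len(nt))
        if (!used[j] && iou[i, j] >= thr) {
          used[j] <- TRUE; rec(i + 1L, used, cnt + 1L); used[j] <- FALSE
        }
    }
    rec(1L, rep(FALSE, nt), 0L)
    best
  }
  tp <- vapply(seq_along(preds), max_match, integer(1))
  rec <- if (nt) tp / nt else rep(0, length(tp))
  prec <- tp / seq_along(preds)
  mrec <- c(0, rec, 1); mpre <- c(0, prec, 0)
  for (i in rev(seq_len(length(mpre) - 1L))) mpre[i] <- max(mpre[i], mpre[i + 1L])
  idx <- which(diff(mrec) > 0)
  list(AP = sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L]),
       recall = if (nt) max(rec) else NA_real_)
}

# numeric arc length of a dense polyline (independent re-integration)
num_arc_length <- function(P) sum(sqrt(rowSums(diff(P)^2)))

# a flat rectangular strip sampled on a grid, length along x, width along y
strip_points <- function(length_cm = 10, width_cm = 2, n_long = 60, n_wide = 12) {
  g <- expand.grid(x = seq(0, length_cm, length.out = n_long),
                   y = seq(-width_cm / 2, width_cm / 2, length.out = n_wide))
  cbind(g$x, g$y, 0)
}

# a semicircular midrib strip of radius r in the xz-plane
arc_strip_points <- function(r = 6, width_cm = 1, n = 900, seed = 5) {
  wheatrecon:::with_seed(seed, {
    th <- runif(n, 0, pi)
    off <- runif(n, -width_cm / 2, width_cm / 2)
    cbind(r * cos(th), off, r * sin(th))
  })
}

# straight vertical tiller cloud: a thin sampled line
line_cloud <- function(z_max = 10, n = 400, x = 0, y = 0, jitter = 0.05,
                       seed = 2) {
  wheatrecon:::with_seed(seed, {
    z <- seq(0, z_max, length.out = n)
    labeled_cloud(cbind(x + rnorm(n, 0, jitter), y + rnorm(n, 0, jitter), z),
                  rep("tiller", n))
  })
}

# membership accuracy of traced chains against per-point instance truth
crossing_membership_accuracy <- function(cx) {
  ctr <- cluster_slabs(cx$cloud, slice_tiller_cloud(cx$cloud))
  tab <- build_score_table(ctr)
  sk <- filter_skeletons(trace_tillers(tab))
  gt <- vapply(tab$centers$members, function(m) {
    t <- table(cx$cloud$instance[m])
    as.integer(names(t)[which.max(t)])
  }, integer(1))
  if (length(sk) != 2L) return(list(n_chains = length(sk), accuracy = NA_real_))
  assign <- rep(NA_integer_, nrow(tab$centers))
  for (s in sk) assign[s$centers_idx[!is.na(s$centers_idx)]] <- s$id
  acc <- max(mean((assign - 1L) == gt), mean((2L - assign) == gt))
  list(n_chains = 2L, accuracy = acc)
}
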