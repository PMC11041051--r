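test_that("slab slicing follows the half-open 2-cm convention", {
  z <- seq(0, 5, by = 0.5)
  cl <- labeled_cloud(cbind(0, 0, z), rep("tiller", length(z)))
  slabs <- slice_tiller_cloud(cl)
  expect_length(slabs, 3L)
  expect_equal(slabs[[1]]$z_lo, 0); expect_equal(slabs[[1]]$z_hi, 2)
  # z = 2 sits in the second slab: intervals are [lo, hi)
  expect_true(which(z == 2) %in% (slabs[[2]]$idx))
  expect_false(which(z == 2) %in% (slabs[[1]]$idx))
  # the maximum belongs to the top slab
  expect_true(which.max(z) %in% slabs[[3]]$idx)
  # every tiller point lands in exactly one slab
  all_idx <- unlist(lapply(slabs, `[[`, "idx"))
  expect_setequal(all_idx, seq_along(z))
  expect_identical(anyDuplicated(all_idx), 0L)

  flat <- labeled_cloud(cbind(0, 0, runif(20, 0, 1.5)), rep("tiller", 20))
  expect_length(slice_tiller_cloud(flat), 1L)
  expect_error(slice_tiller_cloud(
    labeled_cloud(cbind(1, 1, 1), "leaf", 0L)), "no tiller")
})

test_that("per-slab clustering separates cross-sections and drops noise", {
  z <- rep(seq(0.1, 1.9, length.out = 30), 2)
  pts <- rbind(cbind(0, 0, z[1:30]), cbind(10, 0, z[31:60]))
  cl <- labeled_cloud(pts, rep("tiller", 60))
  ctr <- cluster_slabs(cl, slice_tiller_cloud(cl), eps_cm = 1, min_samples = 5)
  expect_identical(nrow(ctr), 2L)
  expect_setequal(round(ctr$x), c(0, 10))

  # an isolated point below min_samples is noise
  one <- labeled_cloud(rbind(cbind(0, 0, seq(0.1, 1.9, length.out = 10)),
                             c(8, 0, 1)), rep("tiller", 11))
  ctr2 <- cluster_slabs(one, slice_tiller_cloud(one), 1, 4)
  expect_identical(nrow(ctr2), 1L)
  expect_equal(ctr2$x, 0, tolerance = 1e-9)

  # a dense tube segment yields one cluster centred on the axis
  cx <- line_cloud(z_max = 1.9, n = 120, x = 3, jitter = 0.1)
  ctr3 <- cluster_slabs(cx, slice_tiller_cloud(cx), 1, 5)
  expect_identical(nrow(ctr3), 1L)
  expect_equal(ctr3$x, 3, tolerance = 0.1)
})

test_that("repair cylinders have the prescribed shape", {
  ctr <- data.frame(x = 0, y = 0, z = 1, slab = 1L, cluster = 1L, size = 10L)
  rep1 <- repair_with_cylinders(ctr, height_cm = 2, radius_cm = 0.5)
  r_xy <- sqrt(rep1$points[, 1]^2 + rep1$points[, 2]^2)
  expect_true(all(abs(r_xy - 0.5) < 1e-9))
  expect_gte(min(rep1$points[, 3]), 0)
  expect_lte(max(rep1$points[, 3]), 2)
  expect_true(all(rep1$semantic == "tiller"))

  ctr3 <- rbind(ctr, transform(ctr, z = 3), transform(ctr, z = 5))
  rep3 <- repair_with_cylinders(ctr3)
  expect_identical(n_points(rep3), 3L * n_points(rep1))
  expect_identical(n_points(repair_with_cylinders(ctr[0, ])), 0L)
})

test_that("the score table implements the weighted distance formula", {
  ctr <- data.frame(x = c(0, 0.5), y = c(0, 0), z = c(10, 8),
                    slab = c(5L, 4L), cluster = c(1L, 1L), size = c(9L, 9L))
  tab <- build_score_table(ctr, alpha = 1, beta = 1)
  expect_equal(tab$h[1, 2], 0.5)
  expect_equal(tab$v[1, 2], 2)
  expect_equal(tab$score[1, 2], 2.5)

  same <- data.frame(x = c(1, 1), y = c(2, 2), z = c(3, 3),
                     slab = c(2L, 2L), cluster = 1:2, size = c(5L, 5L))
  expect_equal(build_score_table(same, 2, 1)$score[1, 2], 0)

  vert <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 7),
                     slab = c(1L, 4L), cluster = c(1L, 1L), size = c(5L, 5L))
  expect_equal(build_score_table(vert, alpha = 2, beta = 0)$score[1, 2], 0)

  expect_error(build_score_table(ctr[1, ]), "two cluster centres")
  expect_error(build_score_table(ctr, 0, 0), "not both zero")
})

test_that("score tables are symmetric, non-negative and monotone", {
  wheatrecon:::with_seed(42, {
    for (rep in 1:5) {
      n <- sample(5:12, 1)
      ctr <- data.frame(x = runif(n, -5, 5), y = runif(n, -5, 5),
                        z = runif(n, 0, 30), slab = sample(1:5, n, TRUE),
                        cluster = seq_len(n), size = rep(5L, n))
      tab <- build_score_table(ctr, alpha = runif(1, 0.5, 3),
                               beta = runif(1, 0.5, 3))
      expect_true(all(tab$score >= 0))
      expect_equal(tab$score, t(tab$score))
      expect_true(all((tab$score == 0) ==
                        (tab$h == 0 & tab$v == 0)))
      # increasing h or v never decreases the score
      i <- sample(n, 1); j <- sample(setdiff(seq_len(n), i), 1)
      expect_gte(tab$alpha * (tab$h[i, j] + 1) + tab$beta * tab$v[i, j],
                 tab$score[i, j])
    }
  })
})

test_that("a single vertical line traces to one chain holding every centre", {
  cl <- line_cloud(z_max = 20, n = 900)
  ctr <- cluster_slabs(cl, slice_tiller_cloud(cl))
  tab <- build_score_table(ctr)
  sk <- trace_tillers(tab)
  expect_length(sk, 1L)
  expect_identical(nrow(sk[[1]]$points), nrow(ctr))
  expect_true(all(diff(sk[[1]]$points[, 3]) > 0))  # bottom-to-top ordering
})

test_that("chains never share a centre and cover all centres", {
  cx <- make_crossing_tillers(8, 0.5, seed = 2)
  ctr <- cluster_slabs(cx$cloud, slice_tiller_cloud(cx$cloud))
  tab <- build_score_table(ctr)
  sk <- trace_tillers(tab)
  used <- unlist(lapply(sk, function(s) s$centers_idx[!is.na(s$centers_idx)]))
  expect_identical(anyDuplicated(used), 0L)
  expect_setequal(used, seq_len(nrow(ctr)))
})

test_that("crossing tillers are traced to the ground-truth membership", {
  res <- crossing_membership_accuracy(make_crossing_tillers(8, 0.5, seed = 1))
  expect_identical(res$n_chains, 2L)
  expect_identical(res$accuracy, 1)
})

test_that("greedy tracing matches the exhaustive two-chain optimum", {
  # two clean parallel stacks, 6 centres each: enumerate all 2^12 partitions
  wheatrecon:::with_seed(9, {
    z <- seq(1, 11, by = 2)
    ctr <- data.frame(x = c(rnorm(6, 0, 0.1), rnorm(6, 8, 0.1)),
                      y = rnorm(12, 0, 0.1), z = rep(z, 2),
                      slab = rep(seq_along(z), 2), cluster = rep(1:2, each = 6),
                      size = rep(9L, 12))
  })
  tab <- build_score_table(ctr)
  sk <- trace_tillers(tab)
  expect_length(sk, 2L)
  oracle <- brute_best_two_chains(tab)
  expect_equal(chains_link_score(sk, tab), oracle$cost, tolerance = 1e-9)
})

test_that("far-apart stacks separated by a large gap are never merged", {
  z1 <- seq(0.2, 7.8, length.out = 60)
  z2 <- seq(20.2, 27.8, length.out = 60)
  cl <- labeled_cloud(cbind(0.01 * rnorm(120), 0.01 * rnorm(120), c(z1, z2)),
                      rep("tiller", 120))
  ctr <- cluster_slabs(cl, slice_tiller_cloud(cl))
  sk <- trace_tillers(build_score_table(ctr),
                      search_constraints(max_gap_slabs = 2L))
  expect_length(sk, 2L)
})

test_that("the chain filter keeps exactly the chains with enough points", {
  mk <- function(n, id) wheatrecon:::new_tiller_skeleton(
    id, cbind(0, 0, seq_len(n)))
  sks <- list(mk(5, 1L), mk(3, 2L), mk(6, 3L))
  kept <- filter_skeletons(sks, 4L)
  expect_length(kept, 2L)
  expect_identical(vapply(kept, `[[`, integer(1), "id"), 1:2)  # contiguous
  expect_identical(vapply(kept, function(s) nrow(s$points), integer(1)),
                   c(5L, 6L))
  expect_length(filter_skeletons(list(mk(4, 1L)), 4L), 1L)  # boundary kept
  expect_length(filter_skeletons(list(), 4L), 0L)
  expect_warning(out <- filter_skeletons(list(mk(2, 1L)), 4L), "no valid")
  expect_length(out, 0L)
})

test_that("base extension drops each chain to the plant base height", {
  mk <- function(z0) wheatrecon:::new_tiller_skeleton(
    1L, cbind(1, 2, z0 + c(0, 2, 4, 6)))
  ext <- extend_to_base(list(mk(0), mk(4), mk(6)), H_0 = 0)
  expect_false(ext[[1]]$base_extended)
  expect_equal(ext[[1]]$H_base_original - ext[[1]]$H0, 0)
  for (k in 2:3) {
    s <- ext[[k]]
    expect_true(s$base_extended)
    expect_equal(unname(s$points[1, 3]), 0)
    expect_equal(s$points[1, 1:2], s$points[2, 1:2],
                 ignore_attr = TRUE)  # vertical extension
    expect_equal(s$H_base_original - s$H0, c(4, 6)[k - 1])
  }
})
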