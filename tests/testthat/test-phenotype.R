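mk_sk <- function(P, H0 = NA_real_, Hb = NULL) {
  s <- wheatrecon:::new_tiller_skeleton(1L, as.matrix(P))
  if (!is.na(H0)) { s$H0 <- H0; s$H_base_original <- if (is.null(Hb)) P[1, 3] else Hb }
  s
}

test_that("tiller length sums the chain and adds the base correction", {
  sk <- mk_sk(cbind(0, 0, c(2, 4, 6, 8)), H0 = 0)
  expect_equal(tiller_length(sk), 8)            # 6 cm chain + 2 cm correction
  sk0 <- mk_sk(cbind(0, 0, c(0, 2, 4)), H0 = 0)
  expect_equal(tiller_length(sk0), 4)           # already at the base
  expect_error(tiller_length(mk_sk(cbind(0, 0, 5), H0 = 0)), "single-point")
})

test_that("traced bowed tillers recover the true axis length", {
  spec <- plant_spec(n_tillers = 1L, tiller_heights = 60, tiller_lean_deg = 8,
                     tiller_azimuth_deg = 45, tiller_curvature = 4,
                     leaves_per_tiller = 0L, has_ear = FALSE,
                     noise_sd_cm = 0.05, dropout_fraction = 0.05,
                     base_missing_cm = 0, rng_seed = 13)
  gen <- generate_plant(spec)
  st <- trace_tiller_skeletons(gen$cloud)
  expect_length(st$skeletons, 1L)
  expect_equal(tiller_length(st$skeletons[[1]]),
               gen$truth$tillers[[1]]$length, tolerance = 0.03)
})

test_that("tiller angles follow the 1/3-2/3 height vector convention", {
  main <- mk_sk(cbind(0, 0, seq(0, 30, 2)))
  expect_equal(unname(tiller_angles(main, main)[1]), 0)
  lean30 <- mk_sk(cbind(seq(0, 30, 2) * tan(30 * pi / 180), 0, seq(0, 30, 2)))
  a <- tiller_angles(lean30, main)
  expect_equal(unname(a[1]), 30, tolerance = 1e-6)
  expect_equal(unname(a[2]), 0, tolerance = 1e-6)
  lean_y <- mk_sk(cbind(0, seq(0, 30, 2) * tan(0.3), seq(0, 30, 2)))
  expect_equal(unname(tiller_angles(lean_y, main)[2]), 90, tolerance = 1e-6)
  flat <- mk_sk(cbind(0, 0, c(0, 0, 0)))
  expect_error(tiller_angles(flat, main), "undefined")
})

test_that("plant height is the z-extent of the cloud", {
  cl <- labeled_cloud(cbind(runif(10), runif(10), seq(0, 82.5, length.out = 10)),
                      rep("tiller", 10))
  expect_equal(plant_height(cl), 82.5)
  expect_equal(plant_height(labeled_cloud(cbind(1, 1, 5), "leaf", 0L)), 0)
  expect_error(plant_height(labeled_cloud(matrix(numeric(0), 0, 3),
                                          character(0))), "empty")
})

test_that("girth is the smallest enclosing circle of mid-height points", {
  sq <- lapply(1:4, function(i) {
    xy <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))[i, ]
    wheatrecon:::new_tiller_skeleton(i, cbind(xy[1], xy[2], seq(0, 40, 2)))
  })
  expect_equal(girth(sq, 40), 10 * sqrt(2), tolerance = 1e-9)
  one <- sq[1]
  expect_equal(girth(one, 40), 0)
  short <- lapply(sq, function(s) { s$points <- s$points[1:3, ]; s })
  expect_warning(g <- girth(short, 40), "tiller tops")
  expect_equal(g, 10 * sqrt(2), tolerance = 1e-9)
})

test_that("smallest enclosing circles match the exhaustive oracle", {
  wheatrecon:::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(2:15, 1)
      pts <- matrix(runif(2 * n, -10, 10), ncol = 2)
      mec <- min_enclosing_circle(pts)
      oracle <- brute_enclosing_circle(pts)
      expect_equal(mec$radius, oracle$radius, tolerance = 1e-9)
      d <- sqrt(rowSums(sweep(pts, 2, mec$center)^2))
      expect_lte(max(d), mec$radius + 1e-9)
    }
  })
})

test_that("the main stem is the long central tiller", {
  one <- mk_sk(cbind(0, 0, seq(0, 30, 2)), H0 = 0)
  expect_identical(select_main_stem(list(one)), 1L)
  mk_id <- function(id, x, top) {
    s <- wheatrecon:::new_tiller_skeleton(id, cbind(x, 0, seq(0, top, 2)))
    s$H0 <- 0; s
  }
  sks <- list(mk_id(1L, 8, 30), mk_id(2L, 0.3, 60), mk_id(3L, -8, 28))
  expect_identical(select_main_stem(sks), 2L)
})

test_that("generator-marked main stems are recovered", {
  hits <- 0L
  for (i in 1:20) {
    gen <- generate_plant(plant_spec(n_tillers = 3L, leaves_per_tiller = 0L,
                                     has_ear = FALSE, rng_seed = 400L + i))
    fit <- trace_tiller_skeletons(gen$cloud)
    main <- select_main_stem(fit$skeletons)
    map <- wheatrecon:::match_tillers_to_truth(fit$skeletons, gen$truth)
    if (map[main] == gen$truth$main_stem) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("leaf length is the polyline sum and never below the chord", {
  ctr <- cbind(seq(2, 8, 2), 0, 0)
  ep <- rbind(c(0, 0, 0), c(10, 0, 0))
  sk <- chain_skeleton(ctr, ep, 1L)
  expect_equal(leaf_length(sk), 10)
  wheatrecon:::with_seed(33, {
    for (rep in 1:1000) {
      k <- sample(2:7, 1)
      poly <- matrix(rnorm(3 * (k + 2)), ncol = 3)
      sk2 <- structure(list(leaf_id = 1L, polyline = poly, k = k,
                            base = "first"), class = "leaf_skeleton")
      chord <- sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2))
      expect_gte(leaf_length(sk2), chord - 1e-12)
    }
  })
})

test_that("leaf width reads the second principal extent of the mid-blade", {
  pts <- strip_points(10, 2, n_long = 80, n_wide = 16)
  seg <- segment_leaf(pts, 1L)
  expect_equal(leaf_width(pts, seg), 2, tolerance = 0.15)
  # rotation invariance
  th <- 0.7; ph <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  rot <- pts %*% t(R)
  segr <- segment_leaf(rot, 1L)
  expect_equal(leaf_width(rot, segr), leaf_width(pts, seg), tolerance = 1e-6)
  # fewer than 4 segments: middle-segment fallback with a warning
  segk2 <- suppressWarnings(segment_leaf(pts[1:3, ], 9L))
  expect_warning(leaf_width(pts[1:3, ], segk2), "middle segment")
})

test_that("curled blades report a width no larger than the unrolled width", {
  # arch the strip across its width direction (curl): the unrolled (flat)
  # width is the arc length of the curled cross-section
  wheatrecon:::with_seed(8, {
    x <- runif(800, 0, 10)
    v <- runif(800, -1, 1)
    pts <- cbind(x, v, 0.4 * (1 - v^2))
  })
  unrolled <- stats::integrate(function(v) sqrt(1 + (0.8 * v)^2), -1, 1)$value
  seg <- segment_leaf(pts, 1L)
  w <- leaf_width(pts, seg)
  expect_lte(w, unrolled)
  expect_gte(w, 1.8)  # still close to the projected chord
})

test_that("leaf angles measure base direction against the local tiller", {
  host <- wheatrecon:::new_tiller_skeleton(1L, cbind(0, 0, seq(0, 40, 2)))
  mk_leaf <- function(dirv) {
    base <- c(0, 0, 20)
    chain_skeleton(rbind(base + 2 * dirv, base + 4 * dirv),
                   rbind(base, base + 6 * dirv), 1L)
  }
  up <- leaf_angles(mk_leaf(c(0, 0, 1)), host, c(0, 0, 20))
  expect_equal(unname(up[1]), 0, tolerance = 1e-9)
  horiz <- leaf_angles(mk_leaf(c(1, 0, 0.001)), host, c(0, 0, 20))
  expect_equal(unname(horiz[1]), 90, tolerance = 0.1)
  expect_equal(unname(horiz[2]), 0, tolerance = 0.1)
})

test_that("ear length and attachment follow the principal axis and lowest point", {
  seg8 <- cbind(seq(0, 8, length.out = 50), 0, 0)
  expect_equal(ear_length(seg8 + rnorm(150, 0, 1e-8)), 8, tolerance = 1e-3)
  wheatrecon:::with_seed(4, {
    dirs <- matrix(rnorm(3 * 4000), ncol = 3)
    sphere <- dirs / sqrt(rowSums(dirs^2))
  })
  expect_equal(ear_length(sphere), 2, tolerance = 0.02)
  expect_error(ear_length(seg8[1:2, ]), "fewer than 3")

  ear <- cbind(runif(30), runif(30), seq(60, 68, length.out = 30))
  expect_equal(unname(ear_attachment(ear)[3]), 60)
  tie <- rbind(c(1, 0, 5), c(2, 0, 5), c(0, 0, 9))
  expect_equal(unname(ear_attachment(tie)), c(1, 0, 5))  # first lowest index
})

test_that("hull volumes match closed forms and bound the sphere", {
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(convex_hull_volume(cube), 8, tolerance = 1e-9)
  a <- 2
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (a / (2 * sqrt(2)))
  expect_equal(convex_hull_volume(tetra), a^3 / (6 * sqrt(2)),
               tolerance = 1e-9)
  # interior points change nothing
  expect_equal(convex_hull_volume(rbind(cube, c(1, 1, 1), c(0.5, 1.2, 0.3))),
               8, tolerance = 1e-9)
  wheatrecon:::with_seed(14, {
    dirs <- matrix(rnorm(600), ncol = 3)
    pts <- dirs / sqrt(rowSums(dirs^2)) * runif(200)^(1 / 3)
  })
  v200 <- convex_hull_volume(pts)
  expect_lte(v200, 4 * pi / 3)
  wheatrecon:::with_seed(15, {
    dirs <- matrix(rnorm(9000), ncol = 3)
    big <- dirs / sqrt(rowSums(dirs^2)) * runif(3000)^(1 / 3)
  })
  vbig <- convex_hull_volume(big)
  expect_gt(vbig, v200)                # converging to the ball volume
  expect_gt(vbig, 0.9 * 4 * pi / 3)
  expect_warning(v0 <- convex_hull_volume(cbind(runif(10), runif(10), 0)),
                 "degenerate")
  expect_equal(v0, 0)
})

test_that("the compiled report carries all 18 parameters and degrades gently", {
  gen <- generate_plant(plant_spec(n_tillers = 3L, rng_seed = 7))
  fit <- reconstruct_plant(gen$cloud)
  rep <- fit$report
  expect_identical(rep$n_tillers, 3L)
  expect_identical(rep$n_leaves, 9L)
  expect_identical(rep$n_ears, 3L)
  expect_true(rep$main_stem_id %in% 1:3)
  expect_true(all(c("length_cm", "angle_main_deg", "azimuth_deg") %in%
                    names(rep$tillers)))
  expect_true(all(rep$leaves$angle_deg >= 0 & rep$leaves$angle_deg <= 180,
                  na.rm = TRUE))
  expect_true(all(rep$tillers$azimuth_deg >= 0 & rep$tillers$azimuth_deg < 360,
                  na.rm = TRUE))
  expect_length(rep$venules, 9L)
  expect_true(all(vapply(rep$venules, nrow, integer(1)) >= 4L))
  expect_true(all(rep$ears$volume_cm3 > 0))

  flat <- as.data.frame(rep)
  expect_identical(sum(flat$organ == "tiller"), 3L)
  expect_identical(sum(flat$organ == "leaf"), 9L)

  f <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, f)
  back <- utils::read.csv(f)
  expect_equal(back$length_cm[back$organ == "leaf"], rep$leaves$length_cm,
               tolerance = 1e-9)

  # an unattached leaf keeps the report alive with NA angle/attachment
  m <- fit$model
  m$records[[1]]$unattached <- TRUE
  rep2 <- compile_report(m)
  expect_true(is.na(rep2$leaves$angle_deg[1]))
  expect_true(is.na(rep2$leaves$attach_x[1]))
  expect_false(anyNA(rep2$leaves$length_cm))
})
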