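test_that("FCM reaches the brute-force fixed point on the two-level toy", {
  x <- c(0, 0, 0, 10, 10, 10)
  fit <- fcm_cluster(matrix(x, 1, 6), fcm_params(c = 2, m = 2, tol = 1e-10))
  oracle <- fcm_fixed_point(x, c = 2, m = 2, centers0 = c(2, 8))
  expect_equal(fit$centers, oracle$centers, tolerance = 1e-6)
  u <- matrix(fit$memberships, 6, 2)
  expect_equal(rowSums(u), rep(1, 6), tolerance = 1e-12)
  # low-intensity pixels belong almost crisply to the low cluster
  expect_true(all(u[1:3, 1] > 0.95))
  expect_true(all(u[4:6, 2] > 0.95))
  expect_error(fcm_cluster(matrix(5, 2, 4), fcm_params(c = 2)), "distinct")
})

test_that("FCM objective is non-increasing and memberships stay normalized", {
  s <- fix_sag$volume$slices[[10]]
  fit <- fcm_cluster(s, fcm_params(c = 3))
  expect_true(all(diff(fit$objective) <= 1e-6 * fit$objective[1]))
  sums <- apply(fit$memberships, c(1, 2), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-9)
  expect_equal(fit$centers, sort(fit$centers))
})

test_that("fuzzy connectivity matches max-min path oracles on small rasters", {
  # 1x3 raster: the only path to pixel 3 passes pixel 2
  img <- matrix(c(10, 10, 0), 1, 3)
  res <- fc_connectivity(img, data.frame(row = 1, col = 1))
  W <- affinity_matrix(img, res$stats)
  expect_equal(res$connectivity[1, 1], 1)
  expect_equal(res$connectivity[1, 3], min(W[1, 2], W[2, 3]), tolerance = 1e-12)
  expect_equal(as.vector(res$connectivity), fw_maxmin_conn(W, 1),
               tolerance = 1e-12)
  # random small rasters against DP and exhaustive path enumeration
  set.seed(42)
  for (i in 1:10) {
    m <- matrix(sample(0:2, 9, replace = TRUE) * 10, 3, 3)
    seed <- data.frame(row = sample(3, 1), col = sample(3, 1))
    r <- fc_connectivity(m, seed, fc_params())
    W <- affinity_matrix(m, r$stats)
    sidx <- seed$row + (seed$col - 1) * 3
    expect_equal(as.vector(r$connectivity), fw_maxmin_conn(W, sidx),
                 tolerance = 1e-12)
    expect_equal(as.vector(r$connectivity), dfs_maxmin_conn(W, sidx),
                 tolerance = 1e-12)
  }
  expect_error(fc_connectivity(img, data.frame(row = 5, col = 1)), "bounds")
})

test_that("area guard picks the closest achievable area and never over-segments", {
  # nested level sets with areas 10 / 50 / 200
  conn <- matrix(0.05, 20, 20)
  ctr <- 10
  conn[(ctr - 6):(ctr + 7), (ctr - 6):(ctr + 7)] <- 0.2   # 196 -> pad to 200
  conn[(ctr - 7), ctr:(ctr + 3)] <- 0.2
  conn[(ctr - 3):(ctr + 3), (ctr - 3):(ctr + 3)] <- 0.5   # 49 -> 50
  conn[(ctr - 4), ctr] <- 0.5
  conn[(ctr - 1):(ctr + 1), (ctr - 1):(ctr + 1)] <- 0.9   # 9 -> 10
  conn[(ctr - 2), ctr] <- 0.9
  seed <- data.frame(row = ctr, col = ctr)
  g <- area_constrained_mask(conn, seed, 60)
  oracle <- sweep_area_oracle(conn, c(ctr, ctr), 60)
  expect_equal(g$area, 50)
  expect_equal(g$area, oracle$area)
  expect_equal(g$threshold, oracle$threshold)
  # monotonicity: area non-increasing in threshold
  expect_true(all(diff(oracle$all_areas) >= 0))  # taus descending
  # conn identically 1: smallest threshold keeps everything
  g2 <- area_constrained_mask(matrix(1, 8, 8), data.frame(row = 4, col = 4),
                              64)
  expect_equal(g2$area, 64)
  expect_equal(g2$threshold, 1)
})

test_that("area guard agrees with the exhaustive sweep on random maps", {
  set.seed(7)
  for (i in 1:20) {
    conn <- matrix(round(runif(15 * 15), 2), 15, 15)
    seed <- data.frame(row = 8, col = 8)
    target <- sample(5:120, 1)
    g <- area_constrained_mask(conn, seed, target, tol = 0.15)
    o <- sweep_area_oracle(conn, c(8, 8), target)
    expect_equal(g$area, o$area)
    expect_equal(g$threshold, o$threshold)
    # no over-segmentation beyond tolerance when a conforming level exists
    if (any(abs(o$all_areas - target) / target <= 0.15)) {
      expect_true(g$conforming)
      expect_lte(g$area, 1.15 * target)
    }
  }
})

test_that("patella seed relocation follows the distance-then-conformity rule", {
  engine <- function(seed) list(area = if (seed$row >= 5) 100 else 10)
  # seed already on the skeleton and conforming: returned unchanged
  sk <- cbind(c(3, 5), c(3, 5))
  out <- relocate_patella_seed(data.frame(row = 3, col = 3),
                               rbind(c(3, 3), c(5, 5)),
                               function(s) list(area = 100), 100)
  expect_equal(c(out$row, out$col), c(3, 3))
  expect_equal(out$origin, "atlas")
  # single distant candidate
  out2 <- relocate_patella_seed(data.frame(row = 3, col = 3),
                                matrix(c(5, 5), 1, 2), engine, 100)
  expect_equal(c(out2$row, out2$col), c(5, 5))
  expect_equal(out2$origin, "relocated")
  expect_true(attr(out2, "conforming"))
  # nothing conforms: best candidate flagged
  out3 <- relocate_patella_seed(data.frame(row = 3, col = 3),
                                rbind(c(1, 1), c(5, 5)),
                                function(s) list(area = s$row), 1000)
  expect_false(attr(out3, "conforming"))
  expect_equal(out3$row, 5)
  expect_error(relocate_patella_seed(data.frame(row = 1, col = 1),
                                     matrix(0, 0, 2), engine, 10),
               "empty skeleton")
})

test_that("post-processing smooths, de-noises and fills holes", {
  disc <- matrix(0, 64, 64)
  for (r in 1:64) for (cc in 1:64)
    if ((r - 32)^2 + (cc - 32)^2 <= 225) disc[r, cc] <- 1
  out <- postprocess(disc)
  expect_gte(dice(out, disc), 98)
  # salt noise removed
  noisy <- disc
  noisy[5, 5] <- 1; noisy[60, 7] <- 1
  out2 <- postprocess(noisy, seeds = data.frame(row = 32, col = 32))
  expect_equal(out2[5, 5], 0)
  expect_equal(out2[60, 7], 0)
  # interior hole filled
  holed <- disc; holed[30:34, 30:34] <- 0
  out3 <- postprocess(holed, seeds = data.frame(row = 20, col = 32))
  expect_equal(sum(out3[30:34, 30:34]), 25)
  expect_equal(sum(postprocess(matrix(0, 16, 16))), 0)
})

test_that("slice segmentation honours atlas absences and finds phantom bones", {
  ph <- generate_volume(small_spec(seed = 41, noise_sd = 0,
                                   geometry_jitter = 0))
  a <- build_atlas(list(ph, generate_volume(small_spec(seed = 42,
                                                       geometry_jitter = 0))))
  # sagittal set 1: no patella -> empty result
  r0 <- segment_slice(ph$volume$slices[[1]], a, 1, "patella", "FC",
                      knee = ph$masks[[1]]$knee, working_size = 64L)
  expect_false(r0$present)
  expect_equal(sum(r0$mask), 0)
  # noise-free femur: near-perfect extraction, both methods close
  i <- 10
  dfc <- dfcm <- NULL
  for (m in c("FC", "FCM")) {
    r <- segment_slice(ph$volume$slices[[i]], a, assign_set(i, 20), "femur",
                       m, knee = ph$masks[[i]]$knee, working_size = 64L)
    d <- dice(r$mask, ph$masks[[i]]$femur)
    expect_gte(d, 95)
    if (m == "FC") dfc <- d else dfcm <- d
    expect_true(r$present)
    expect_equal(dim(r$mask), dim(ph$volume$slices[[i]]$pixels))
  }
  expect_lte(abs(dfc - dfcm), 5)
})

test_that("segmentation is deterministic end to end", {
  ph <- fix_sag
  a <- build_atlas(list(ph))
  r1 <- segment_slice(ph$volume$slices[[8]], a, assign_set(8, 20), "tibia",
                      "FC", knee = ph$masks[[8]]$knee, working_size = 64L)
  r2 <- segment_slice(ph$volume$slices[[8]], a, assign_set(8, 20), "tibia",
                      "FC", knee = ph$masks[[8]]$knee, working_size = 64L)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$threshold, r2$threshold)
})
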