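test_that("set assignment anchors endpoints and partitions contiguously", {
  expect_equal(assign_set(1, 22), 1L)
  expect_equal(assign_set(22, 22), 11L)
  expect_equal(assign_set(11, 21), 6L)   # floor(11*10/20) + 1
  expect_equal(assign_set(2, 25), 1L)    # floor(11*1/24) + 1
  expect_error(assign_set(1, 1), "n_slices >= 2")
  for (n in c(11, 17, 20, 24, 25, 33)) {
    sets <- assign_set(1:n, n)
    expect_true(all(diff(sets) >= 0))          # monotone
    expect_true(all(diff(sets) <= 1))          # contiguous runs
    expect_equal(sets[1], 1L)
    expect_equal(sets[n], 11L)
    if (n >= 11) expect_setequal(unique(sets), 1:11)
  }
  expect_equal(assign_set(1:11, 11), 1:11)     # identity at n = 11
})

test_that("slice features: centroids, areas, boundary and skeleton", {
  img <- matrix(10, 256, 256)
  s <- knee_slice(img, modality = "CT", plane = "transverse")
  knee <- matrix(0, 256, 256); knee[1:100, 1:100] <- 1  # area 10000
  bone <- matrix(0, 256, 256); bone[65, 129] <- 1        # 0-based (64, 128)
  f <- slice_features(s, list(patella = bone), knee)
  expect_equal(unname(f$patella$centroids[1, "x"]), 128 / 255, tolerance = 1e-9)
  expect_equal(unname(f$patella$centroids[1, "y"]), 64 / 255, tolerance = 1e-9)
  expect_equal(f$patella$area_fraction, 1e-4)
  # empty mask: absent with (0,0) sentinel
  expect_false(f$femur$present)
  expect_equal(unname(f$femur$centroids[1, ]), c(0, 0))
  # filled disc: centroid at disc center, skeleton near center, boundary ring
  disc <- matrix(0, 64, 64)
  ctr <- c(33, 33)
  for (r in 1:64) for (cc in 1:64)
    if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= 100) disc[r, cc] <- 1
  s2 <- knee_slice(matrix(10, 64, 64), modality = "CT", plane = "transverse")
  f2 <- slice_features(s2, list(femur = disc), knee = disc)
  expect_equal(unname(f2$femur$centroids[1, "x"]), 32 / 63, tolerance = 1e-3)
  dmin <- min(sqrt((f2$femur$skeleton[, 1] - 33)^2 +
                   (f2$femur$skeleton[, 2] - 33)^2))
  expect_lte(dmin, 1.5)
  expect_equal(f2$femur$perimeter, nrow(f2$femur$edges))
  expect_error(slice_features(s2, list(femur = disc), knee = disc * 0),
               "empty knee")
})

test_that("two major components give two centroids ordered by decreasing x", {
  m <- matrix(0, 64, 64)
  m[28:38, 10:20] <- 1   # left blob
  m[28:38, 44:54] <- 1   # right blob
  s <- knee_slice(matrix(1, 64, 64), modality = "CT", plane = "transverse")
  f <- slice_features(s, list(tibia = m), knee = matrix(1, 64, 64))
  expect_equal(nrow(f$tibia$centroids), 2L)
  expect_gt(f$tibia$centroids[1, "x"], f$tibia$centroids[2, "x"])
})

test_that("atlas building averages per set and is permutation-invariant", {
  ph <- generate_volume(small_spec(seed = 21, geometry_jitter = 0))
  ph2 <- generate_volume(small_spec(seed = 22, geometry_jitter = 0))
  # identical annotated volumes: atlas equals the single-volume features
  a1 <- build_atlas(list(ph, ph))
  a_single <- build_atlas(list(ph))
  for (k in c(3, 6, 9))
    expect_equal(a1$sets[[k]]$bones$femur$centroids,
                 a_single$sets[[k]]$bones$femur$centroids)
  # permutation invariance
  a12 <- build_atlas(list(ph, ph2))
  a21 <- build_atlas(list(ph2, ph))
  for (k in 1:11)
    for (b in c("patella", "femur", "tibia"))
      expect_equal(a12$sets[[k]]$bones[[b]], a21$sets[[k]]$bones[[b]])
  # two volumes: centroid is the mean over member slices of both
  x12 <- a12$sets[[6]]$bones$patella$centroids[1, "x"]
  xs <- c(a_single$sets[[6]]$bones$patella$centroids[1, "x"],
          build_atlas(list(ph2))$sets[[6]]$bones$patella$centroids[1, "x"])
  expect_equal(unname(x12), mean(xs), tolerance = 1e-12)
  expect_error(build_atlas(list()), "empty teaching group")
})

test_that("atlas built from a jittered teaching group recovers the geometry", {
  spec <- phantom_spec("sagittal", image_size = 64L, geometry_jitter = 0.02,
                       rng_seed = 31)
  tg <- generate_teaching_group(10, spec)
  a <- build_atlas(tg)
  lay <- kneeatlas:::phantom_layout("sagittal")
  for (b in c("femur", "tibia")) {
    cen <- a$sets[[6]]$bones[[b]]$centroids[1, ]
    expect_lt(abs(cen["x"] - lay[[b]]$cx), 0.02)
    expect_lt(abs(cen["y"] - lay[[b]]$cy), 0.02)
  }
  expect_false(a$sets[[1]]$bones$patella$present)
  expect_false(a$sets[[11]]$bones$patella$present)
})

test_that("reference atlas matches the published tables and round-trips", {
  a <- load_reference_atlas("sagittal", "MR")
  expect_equal(unname(a$sets[[3]]$bones$patella$centroids[1, ]),
               c(0.188, 0.324))
  expect_false(a$sets[[1]]$bones$patella$present)
  expect_false(a$sets[[11]]$bones$patella$present)
  at <- load_reference_atlas("transverse", "CT")
  expect_equal(at$sets[[6]]$bones$patella$area_fraction, 0.0596)
  expect_equal(unname(at$sets[[11]]$bones$femur$centroids),
               matrix(c(0.633, 0.518, 0.469, 0.568), 2, 2))
  expect_equal(unname(at$sets[[1]]$bones$tibia$centroids[, "x"]),
               c(0.635, 0.522))
  # all area fractions valid
  for (aa in list(a, at))
    for (k in 1:11)
      for (b in c("patella", "femur", "tibia")) {
        af <- aa$sets[[k]]$bones[[b]]$area_fraction
        expect_true(af >= 0 && af <= 1)
      }
  expect_error(load_reference_atlas("transverse", "MR"), "no reference atlas")
  # JSON serialization round-trips exactly
  f <- withr::local_tempfile(fileext = ".json")
  atlas_write_json(at, f)
  back <- atlas_read_json(f)
  for (k in 1:11)
    for (b in c("patella", "femur", "tibia")) {
      expect_identical(unname(back$sets[[k]]$bones[[b]]$centroids),
                       unname(at$sets[[k]]$bones[[b]]$centroids))
      expect_identical(back$sets[[k]]$bones[[b]]$area_fraction,
                       at$sets[[k]]$bones[[b]]$area_fraction)
    }
})

test_that("atlas centroids convert to pixel seeds, honouring absences", {
  a <- load_reference_atlas("sagittal", "MR")
  expect_null(atlas_to_seed(a, 1, "patella", 256, 256))
  # normalized (0.5, 0.5) on a 257x257 grid is 0-based pixel (128, 128)
  fake <- a
  fake$sets[[5]]$bones$femur$centroids <- matrix(c(0.5, 0.5), 1, 2,
    dimnames = list(NULL, c("x", "y")))
  sd5 <- atlas_to_seed(fake, 5, "femur", 257, 257)
  expect_equal(c(sd5$row, sd5$col) - 1L, c(128L, 128L))
  at <- load_reference_atlas("transverse", "CT")
  expect_equal(nrow(atlas_to_seed(at, 1, "tibia", 256, 256)), 2L)
  expect_equal(nrow(atlas_to_seed(at, 11, "femur", 256, 256)), 2L)
  expect_equal(nrow(atlas_to_seed(at, 6, "femur", 256, 256)), 1L)
})
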