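test_that("Otsu binarization agrees with the exhaustive-search oracle", {
  withr::with_seed(42, {
    for (k in 1:5) {
      v <- c(rnorm(400, 0.2, 0.04), rnorm(150 + 50 * k, 0.8, 0.06))
      img <- matrix(sample(v), nrow = 25)
      bw <- binarize(img)
      expect_identical(bw$mask, img > brute_force_threshold(as.vector(img)))
    }
  })
})

test_that("binarize handles manual thresholds and degenerate input", {
  img <- matrix(0, 10, 10)
  bw <- binarize(img, "manual", threshold = 0.5)
  expect_false(any(bw$mask))
  expect_error(binarize(img), "constant")
  # two-valued image: automatic cut separates the populations exactly
  img2 <- matrix(0.2, 20, 20); img2[5:10, 5:15] <- 0.8
  bw2 <- binarize(img2)
  expect_equal(sum(bw2$mask), 6 * 11)
})

test_that("grain detection recovers centers and radii within a pixel", {
  centers <- rbind(c(30, 30), c(90, 34), c(60, 90))
  sc <- make_grain_scene(scene_spec(image_size = c(128L, 128L),
                                    grain_centers = centers,
                                    grain_radius = 10, thickness = 0,
                                    seed = 1))
  det <- detect_grains(sc$masks$foreground, expected_radius = 10,
                       pixel_size = 0.5)
  expect_equal(nrow(det), 3)
  ord <- order(det$x + 1000 * det$y)
  truth <- centers[order(centers[, 1] + 1000 * centers[, 2]), ]
  expect_true(all(abs(det$x[ord] - truth[, 1]) <= 1))
  expect_true(all(abs(det$y[ord] - truth[, 2]) <= 1))
  expect_true(all(abs(det$radius_um - 10) <= 0.5))  # 1 px = 0.5 um
})

test_that("grain detection edge cases behave per contract", {
  expect_error(detect_grains(matrix(TRUE, 50, 50), expected_radius = 10,
                             pixel_size = 0.5,
                             layout = data.frame(x = 45, y = 25,
                                                 radius_um = 10)),
               "bounds")
  lay <- data.frame(x = 25, y = 25, radius_um = 10)
  ok <- detect_grains(matrix(TRUE, 50, 50), 10, 0.5, layout = lay)
  expect_equal(ok$x, 25)
  expect_warning(det <- detect_grains(matrix(FALSE, 50, 50), 5, 0.5),
                 "no grain")
  expect_equal(nrow(det), 0)
})

test_that("radial profiles recover uniform, bare and sinusoidal annuli", {
  px <- 0.5
  sc <- make_grain_scene(scene_spec(thickness = 10, seed = 1))
  prof <- radial_profile(sc$masks$foreground, unlist(sc$layout[1, c("x", "y")]),
                         sc$layout$radius_um[1], px)
  expect_true(all(abs(prof$thickness_um - 10) <= px))  # 1 px-equivalent
  st <- thickness_stats(prof)
  expect_equal(st$mean_thickness_um, 10, tolerance = 0.02)
  expect_equal(st$n_capped, 0)

  bare <- make_grain_scene(scene_spec(thickness = 0, seed = 1))
  pb <- radial_profile(bare$masks$foreground,
                       unlist(bare$layout[1, c("x", "y")]),
                       bare$layout$radius_um[1], px)
  expect_true(all(pb$thickness_um <= px))  # zero within pixel resolution
  stb <- thickness_stats(pb)
  expect_lt(stb$mean_thickness_um, px / 2)
  expect_lt(stb$roughness_um, px / 2)

  sinsc <- make_grain_scene(scene_spec(
    thickness = function(th) 10 + 4 * sin(th), seed = 1))
  ps <- radial_profile(sinsc$masks$foreground,
                       unlist(sinsc$layout[1, c("x", "y")]),
                       sinsc$layout$radius_um[1], px)
  expected <- 10 + 4 * sin(ps$angles)
  expect_true(all(abs(ps$thickness_um - expected) <= 2 * px))
  sts <- thickness_stats(ps)
  expect_equal(sts$roughness_um, 4 / sqrt(2), tolerance = 0.05)
})

test_that("profiles warn without a pillar and cap bridged biofilm", {
  m <- matrix(FALSE, 64, 64)
  m[20:44, 20:44] <- TRUE  # square blob, center off-foreground case below
  expect_warning(radial_profile(m, c(5, 5), radius_um = 1, pixel_size = 0.5,
                                cap_um = 2), "foreground")
  # a full-foreground image hits the cap at every angle
  full <- matrix(TRUE, 64, 64)
  pr <- radial_profile(full, c(31.5, 31.5), radius_um = 3, pixel_size = 0.5,
                       cap_um = 5)
  expect_true(all(pr$capped))
  expect_true(all(pr$thickness_um <= 5 + 1e-9))
})

test_that("thickness statistics follow the population-SD definition", {
  prof <- structure(list(angles = seq(0, 2 * pi, length.out = 5)[-5],
                         thickness_um = c(2, 4, 6, 8),
                         capped = rep(FALSE, 4)),
                    class = "biofilm_profile")
  st <- thickness_stats(prof)
  expect_equal(st$mean_thickness_um, 5)
  expect_equal(st$roughness_um, sqrt(5))  # divide-by-n SD
  prof$thickness_um <- rep(3, 4)
  expect_equal(thickness_stats(prof)$roughness_um, 0)
})

test_that("thickness is invariant to translation and 90-degree rotation", {
  tfun <- function(th) 8 + 3 * sin(2 * th + 0.7)
  base <- scene_spec(image_size = c(160L, 160L),
                     grain_centers = matrix(c(70, 70), 1),
                     thickness = tfun, grain_radius = 20, seed = 1)
  shifted <- scene_spec(image_size = c(160L, 160L),
                        grain_centers = matrix(c(82, 79), 1),
                        thickness = tfun, grain_radius = 20, seed = 1)
  stats_of <- function(sc, center) {
    thickness_stats(radial_profile(sc$masks$foreground, center, 20, 0.5,
                                   cap_um = 18))
  }
  s0 <- stats_of(make_grain_scene(base), c(70, 70))
  s1 <- stats_of(make_grain_scene(shifted), c(82, 79))
  expect_equal(s1$mean_thickness_um, s0$mean_thickness_um, tolerance = 1e-9)
  expect_equal(s1$roughness_um, s0$roughness_um, tolerance = 1e-9)

  sc <- make_grain_scene(base)
  rot <- t(sc$masks$foreground)[, rev(seq_len(160))]  # 90-degree rotation
  s2 <- thickness_stats(radial_profile(rot, c(160 - 1 - 70, 70), 20, 0.5,
                                       cap_um = 18))
  expect_equal(s2$mean_thickness_um, s0$mean_thickness_um, tolerance = 1e-6)
  expect_equal(s2$roughness_um, s0$roughness_um, tolerance = 1e-6)
})

test_that("thickness scales linearly with pixel size for a fixed mask", {
  sc <- make_grain_scene(scene_spec(thickness = 10, seed = 2))
  center <- unlist(sc$layout[1, c("x", "y")])
  a <- thickness_stats(radial_profile(sc$masks$foreground, center, 25, 0.5,
                                      cap_um = 20))
  b <- thickness_stats(radial_profile(sc$masks$foreground, center, 50, 1.0,
                                      cap_um = 40))
  expect_equal(b$mean_thickness_um, 2 * a$mean_thickness_um,
               tolerance = 1e-9)
  expect_equal(b$roughness_um, 2 * a$roughness_um, tolerance = 1e-9)
})

test_that("genus area fractions follow the definition and sum to one", {
  bio <- matrix(FALSE, 40, 50); bio[1:25, 1:40] <- TRUE  # 1000 px
  a <- matrix(FALSE, 40, 50); a[1:25, 1:28] <- TRUE      # 700 in biofilm
  b <- matrix(FALSE, 40, 50); b[1:25, 29:40] <- TRUE     # 300 in biofilm
  fr <- genus_area_fractions(list(A = a, B = b), bio)
  expect_equal(unname(fr$fractions), c(0.7, 0.3))
  expect_equal(sum(fr$fractions), 1)
  expect_equal(fr$unassigned_px, 0)

  only_a <- genus_area_fractions(list(A = a, B = matrix(FALSE, 40, 50)), bio)
  expect_equal(unname(only_a$fractions), c(1, 0))

  none <- genus_area_fractions(list(A = matrix(FALSE, 40, 50)), bio)
  expect_identical(none$flag, "no_labeled_area")
  expect_true(all(is.na(none$fractions)))

  # overlap resolved toward the brighter channel when intensities given
  ov_b <- a  # channel B claims the same pixels as A
  ia <- matrix(0.3, 40, 50); ib <- matrix(0.9, 40, 50)
  fr_ov <- genus_area_fractions(list(A = a, B = ov_b), bio,
                                intensities = list(A = ia, B = ib))
  expect_equal(unname(fr_ov$fractions), c(0, 1))
  expect_equal(fr_ov$overlap_px, 700)
})

test_that("analyze_scene recovers generator ground truth at noise zero", {
  sc <- make_grain_scene(scene_spec(
    thickness = function(th) 9 + 2.5 * sin(3 * th),
    channel_mix = c(pseu = 0.7, arth = 0.3), seed = 6))
  res <- analyze_scene(sc)
  expect_equal(res$mean_thickness_um, sc$ground_truth$mean_thickness_um,
               tolerance = 0.02)
  expect_equal(res$roughness_um, sc$ground_truth$roughness_um,
               tolerance = 0.05)
  expect_equal(res$frac_pseu, sc$ground_truth$frac_pseu, tolerance = 1e-12)
})
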