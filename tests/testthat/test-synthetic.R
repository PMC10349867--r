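test_that("every generator is deterministic given its seed", {
  s1 <- make_grain_scene(scene_spec(noise_sd = 0.05, seed = 11,
                                    channel_mix = c(A = 0.6, B = 0.4)))
  s2 <- make_grain_scene(scene_spec(noise_sd = 0.05, seed = 11,
                                    channel_mix = c(A = 0.6, B = 0.4)))
  s3 <- make_grain_scene(scene_spec(noise_sd = 0.05, seed = 12,
                                    channel_mix = c(A = 0.6, B = 0.4)))
  expect_identical(s1$channels, s2$channels)
  expect_false(identical(s1$channels, s3$channels))

  b1 <- make_breakthrough(list(kind = "gaussian", mean = 50, sd = 5),
                          noise_sd = 1e-3, seed = 5)
  b2 <- make_breakthrough(list(kind = "gaussian", mean = 50, sd = 5),
                          noise_sd = 1e-3, seed = 5)
  expect_identical(b1$C, b2$C)

  q1 <- make_qpcr(1.047, noise_sd = 0.2, seed = 3)
  q2 <- make_qpcr(1.047, noise_sd = 0.2, seed = 3)
  expect_identical(q1$cq, q2$cq)

  c1 <- make_community_series(assembly_regime("neutral", n_taxa = 30,
                                              n_samples = 4, depth = 500,
                                              seed = 7))
  c2 <- make_community_series(assembly_regime("neutral", n_taxa = 30,
                                              n_samples = 4, depth = 500,
                                              seed = 7))
  expect_identical(c1$abundance, c2$abundance)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))

  y1 <- make_coculture_table(40, noise_sd = 0.05, seed = 2)
  y2 <- make_coculture_table(40, noise_sd = 0.05, seed = 2)
  expect_identical(y1, y2)

  m1 <- make_metabolite_series(c("monotone_up", "v_shaped"), seed = 4)
  m2 <- make_metabolite_series(c("monotone_up", "v_shaped"), seed = 4)
  expect_identical(m1$values, m2$values)
})

test_that("grain scene ground truth is analytic and exact", {
  # uniform annulus: mean 10, roughness 0
  sc <- make_grain_scene(scene_spec(thickness = 10, seed = 1))
  expect_equal(sc$ground_truth$mean_thickness_um, 10)
  expect_equal(sc$ground_truth$roughness_um, 0)

  # sinusoidal annulus: population SD of 10 + 4 sin(theta) is 4/sqrt(2)
  sc <- make_grain_scene(scene_spec(thickness = function(th) 10 + 4 * sin(th),
                                    seed = 1))
  expect_equal(sc$ground_truth$mean_thickness_um, 10, tolerance = 1e-10)
  expect_equal(sc$ground_truth$roughness_um, 4 / sqrt(2), tolerance = 1e-10)

  # foreground is exactly grain disks plus biofilm annuli, disjointly
  expect_true(all(sc$masks$foreground == (sc$masks$grain | sc$masks$biofilm)))
  expect_false(any(sc$masks$grain & sc$masks$biofilm))
})

test_that("genus labels are allocated exactly per the requested mix", {
  sc <- make_grain_scene(scene_spec(channel_mix = c(A = 0.7, B = 0.3),
                                    seed = 21))
  n_bio <- sum(sc$masks$biofilm)
  expect_equal(sum(sc$labels == 1), round(0.7 * n_bio))
  expect_equal(sc$ground_truth$frac_A, round(0.7 * n_bio) / n_bio,
               tolerance = 1e-12)
  expect_equal(sc$ground_truth$frac_A + sc$ground_truth$frac_B, 1)
})

test_that("scene geometry preconditions are enforced", {
  expect_error(make_grain_scene(scene_spec(
    image_size = c(128L, 128L),
    grain_centers = rbind(c(40, 64), c(80, 64)),
    grain_radius = 12, thickness = 5, seed = 1)),
    "overlap")
  # same layout allowed with the explicit flag
  expect_s3_class(make_grain_scene(scene_spec(
    image_size = c(128L, 128L),
    grain_centers = rbind(c(40, 64), c(80, 64)),
    grain_radius = 12, thickness = 5, seed = 1, allow_overlap = TRUE)),
    "grain_scene")
  expect_error(make_grain_scene(scene_spec(
    image_size = c(64L, 64L), grain_centers = matrix(c(5, 32), 1),
    grain_radius = 10, thickness = 0, seed = 1)),
    "bounds")
  expect_error(make_grain_scene(scene_spec(thickness = -1, seed = 1)))
})

test_that("breakthrough ground truth matches closed forms", {
  bc <- make_breakthrough(list(kind = "gaussian", mean = 50, sd = 5),
                          T = 200, dt = 0.5)
  expect_equal(attr(bc, "tau_true"), 50, tolerance = 1e-6)
  expect_true(all(bc$C >= 0))

  bc <- make_breakthrough(list(kind = "exponential", rate = 0.05),
                          T = 200, dt = 0.1)
  tau_closed <- 1 / 0.05 - 200 * exp(-0.05 * 200) / (1 - exp(-0.05 * 200))
  expect_equal(attr(bc, "tau_true"), tau_closed)
  expect_equal(tau_closed, 19.99, tolerance = 1e-3)

  bc <- make_breakthrough(list(kind = "delta", at = 10), T = 200, dt = 0.5)
  expect_equal(attr(bc, "tau_true"), 10)

  expect_warning(
    make_breakthrough(list(kind = "gaussian", mean = 190, sd = 30), T = 200),
    "mass")
})

test_that("qPCR generator follows the standard-curve closed forms", {
  qd <- make_qpcr(1.0, intercept = 40, dilution_levels = 10^(2:6))
  gt <- attr(qd, "ground_truth")
  expect_equal(gt$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(gt$slope, -3.3219, tolerance = 1e-4)
  expect_equal(qd$cq[qd$copies == 1e6][1], 40 - 6 / log10(2),
               tolerance = 1e-12)
  expect_equal(qd$cq[qd$copies == 1e6][1], 20.068, tolerance = 1e-3)
  # zero-noise round trip recovers the planted efficiency exactly
  fit <- fit_standard_curve(qd$copies, qd$cq)
  expect_equal(fit$efficiency, 1.0, tolerance = 1e-9)
})

test_that("planted coculture classes are the noiseless classification", {
  tab <- make_coculture_table(n_pairs = 60, noise_sd = 0, seed = 9)
  calls <- classify_coculture(tab$y_a, tab$y_b, tab$y_co)
  expect_identical(as.character(calls$class),
                   as.character(tab$planted_class))
  expect_setequal(levels(tab$planted_class),
                  c("positive", "weak_negative", "strong_negative"))
})

test_that("metabolite labels are consistent with the Spearman rule", {
  ms <- make_metabolite_series(c("monotone_up", "monotone_down", "v_shaped",
                                 "flat"), seed = 3)
  expect_identical(ms$labels$planted_class,
                   c("released", "consumed", "other", "other"))
  # symmetric V over 7 equispaced times has exactly rho = 0
  v <- ms$values[3, ]
  expect_equal(suppressWarnings(cor(v, ms$times, method = "spearman")), 0)
  expect_error(trend_spec("v_shaped", n_timepoints = 3))
})

test_that("neutral same-pool draws are closer than disjoint-pool draws", {
  neu <- make_community_series(assembly_regime("neutral", n_taxa = 50,
                                               n_samples = 2, depth = 2000,
                                               seed = 31))
  dl <- make_community_series(assembly_regime("dispersal_limitation",
                                              n_taxa = 50, n_samples = 2,
                                              depth = 2000, seed = 31))
  bc_of <- function(ab) bray_loop(ab[, 1] / sum(ab[, 1]),
                                  ab[, 2] / sum(ab[, 2]))
  expect_lt(bc_of(neu$abundance), bc_of(dl$abundance))
  expect_equal(bc_of(dl$abundance), 1)  # disjoint pools: complete turnover
})

test_that("strong homogeneous selection concentrates all samples on one clade", {
  cs <- make_community_series(assembly_regime("homogeneous_selection",
                                              n_taxa = 40, n_samples = 3,
                                              selection_strength = 60,
                                              depth = 2000, seed = 17))
  top <- apply(cs$abundance, 2, which.max)
  expect_true(length(unique(top)) == 1)   # same fittest taxon dominates
  expect_true(all(apply(cs$abundance, 2, max) / colSums(cs$abundance) > 0.5))
})

test_that("regime validation enforces the neutral/selection contract", {
  expect_error(assembly_regime("neutral", selection_strength = 2))
  expect_error(assembly_regime("homogeneous_selection",
                               selection_strength = 0))
  expect_error(assembly_regime("neutral", n_taxa = 1))
})

test_that("community series round-trips through TSV/Newick/CSV", {
  cs <- make_community_series(assembly_regime("neutral", n_taxa = 20,
                                              n_samples = 3, depth = 300,
                                              seed = 5))
  dir <- withr::local_tempdir()
  write_community_series(cs, dir)
  back <- read_community_series(dir)
  expect_equal(unname(back$abundance), unname(cs$abundance))
  expect_identical(sort(back$tree$tip.label), sort(cs$tree$tip.label))
  expect_equal(back$sample_time, cs$sample_time)
})
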