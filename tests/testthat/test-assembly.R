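test_that("phylogenetic binning splits clades and respects the cutoff", {
  tree <- two_clade_tree()
  bins <- bin_taxa(tree, d_max = 0.2, min_bin_size = 1)
  expect_length(bins, 2)
  # brute-force check: within-bin cophenetic distances all <= d_max
  D <- ape::cophenetic.phylo(tree)
  for (b in bins) {
    expect_true(all(D[b$taxa, b$taxa] <= 0.2 + 1e-12))
  }
  expect_setequal(unlist(lapply(bins, `[[`, "taxa")), tree$tip.label)
})

test_that("star trees split to singletons and merge when forced", {
  tree <- star_tree(4)  # all pairwise distances 0.5 > 0.2
  bins <- bin_taxa(tree, d_max = 0.2, min_bin_size = 1)
  expect_length(bins, 4)
  merged <- bin_taxa(tree, d_max = 0.2, min_bin_size = 4)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$taxa, tree$tip.label)
  expect_warning(bin_taxa(star_tree(3), min_bin_size = 12), "single bin")
})

test_that("bins always partition the taxa (random trees)", {
  withr::with_seed(77, {
    for (i in 1:5) {
      tree <- ape::rphylo(40, birth = 1, death = 0)
      bins <- bin_taxa(tree, d_max = 0.3, min_bin_size = 5)
      taxa <- unlist(lapply(bins, `[[`, "taxa"))
      expect_length(taxa, 40)
      expect_false(any(duplicated(taxa)))
      expect_true(all(vapply(bins, function(b) length(b$taxa),
                             numeric(1)) >= 5))
    }
  })
})

test_that("beta-NRI matches the exhaustive 3-taxon enumeration oracle", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      D <- matrix(runif(9, 0.1, 1), 3); D <- (D + t(D)) / 2; diag(D) <- 0
      xA <- rpois(3, 5) + c(1, 0, 0)
      xB <- rpois(3, 5) + c(0, 1, 0)
      if (sum(xA > 0) < 2 || sum(xB > 0) < 2) next
      got <- beta_nri(xA, xB, D, n_null = "exhaustive")
      nulls <- vapply(perms3, function(p) bmpd_loop(xA[p], xB[p], D),
                      numeric(1))
      want <- (bmpd_loop(xA, xB, D) - mean(nulls)) / sd(nulls)
      expect_equal(got$beta_nri, want, tolerance = 1e-12)
      expect_equal(got$n_null, 6)
    }
  })
})

test_that("beta-NRI sign convention: clustered communities score negative", {
  # taxa 1-2 are a tight clade; both communities live there
  D <- matrix(0.9, 4, 4); diag(D) <- 0; D[1, 2] <- D[2, 1] <- 0.05
  got <- beta_nri(c(8, 6, 0, 0), c(5, 9, 0, 0), D, n_null = "exhaustive")
  expect_lt(got$beta_nri, 0)
})

test_that("beta-NRI flags undefined cases", {
  D <- matrix(0.5, 3, 3); diag(D) <- 0
  expect_identical(beta_nri(c(5, 0, 0), c(1, 1, 1), D)$flag, "undefined")
  # equidistant star: every permutation gives the same betaMPD -> sd 0
  expect_identical(beta_nri(c(2, 1, 1), c(1, 2, 1), D)$flag, "undefined")
})

test_that("beta-NRI z-scores are calibrated under the matched null", {
  # data generated by the shuffle itself: abundances placed uniformly at
  # random on the taxa, scored against the within-bin shuffle null
  withr::with_seed(99, {
    n <- 10
    D <- as.matrix(dist(cbind(runif(n), runif(n))))
    hits <- replicate(300, {
      xA <- rmultinom(1, 150, rep(1 / n, n))[, 1][sample.int(n)]
      xB <- rmultinom(1, 150, rep(1 / n, n))[, 1][sample.int(n)]
      z <- beta_nri(xA, xB, D, n_null = 300,
                    seed = sample.int(1e6, 1))$beta_nri
      !is.na(z) && abs(z) > 1.96
    })
  })
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.11)
})

test_that("Raup-Crick follows its counting definition on tiny cases", {
  # two taxa, fully segregated: exhaustive null is {0, 1, 1, 0} vs obs 1
  got <- rc_metric(c(5, 0), c(0, 5), n_null = "exhaustive")
  expect_equal(got$rc, 2 * ((2 + 0.5 * 2) / 4) - 1)  # = 0.5
  # identical one-taxon-dominant communities: obs 0 below every unequal null
  got2 <- rc_metric(c(5, 0), c(5, 0), n_null = "exhaustive")
  expect_equal(got2$rc, 2 * ((0 + 0.5 * 2) / 4) - 1)  # = -0.5
  # degenerate null: all permutations give the same dissimilarity
  got3 <- rc_metric(c(3, 3), c(3, 3), n_null = "exhaustive")
  expect_equal(got3$rc, 0)
  expect_identical(got3$flag, "degenerate")
})

test_that("Raup-Crick stays in [-1, 1] and hits the boundaries", {
  withr::with_seed(12, {
    rcs <- replicate(40, {
      n <- sample(3:8, 1)
      rc_metric(rpois(n, 3), rpois(n, 3), n_null = 100,
                seed = sample.int(1e6, 1))$rc
    })
  })
  expect_true(all(rcs >= -1 & rcs <= 1, na.rm = TRUE))
  # fully segregated communities with distinct abundances: the observed
  # dissimilarity (1) exceeds every sampled null draw, so RC hits +1
  x <- c(seq(20, 48, by = 2), rep(0, 15))
  y <- c(rep(0, 15), seq(21, 49, by = 2))
  expect_equal(rc_metric(x, y, n_null = 500, seed = 3)$rc, 1)
})

test_that("process assignment follows the threshold rules", {
  expect_identical(assign_process(-2.5, NA)[1], "HoS")
  expect_identical(assign_process(2.5, NA)[1], "HeS")
  expect_identical(assign_process(0.5, 0.97)[1], "DL")
  expect_identical(assign_process(0.5, -0.99)[1], "HD")
  expect_identical(assign_process(0.0, 0.0)[1], "DR")
  expect_identical(assign_process(1.96, 0.95)[1], "DR")   # closed boundaries
  expect_identical(assign_process(NA, 0.99)[1], "DL")     # rc-only path
  expect_true(is.na(assign_process(NA, NA)[1]))
})

test_that("process aggregation is a normalized weighted sum", {
  expect_equal(unname(aggregate_processes(rep("HoS", 5), rep(1, 5))["HoS"]),
               1)
  two <- aggregate_processes(c("HoS", "DR"), c(1, 1))
  expect_equal(unname(two[c("HoS", "DR")]), c(0.5, 0.5))
  wt <- aggregate_processes(c("HoS", "DR"), c(0.9, 0.1))
  expect_equal(unname(wt[c("HoS", "DR")]), c(0.9, 0.1))
  expect_equal(sum(wt), 1, tolerance = 1e-9)
  expect_error(aggregate_processes(c("HoS"), 0), "zero total weight")
  expect_error(aggregate_processes("nope", 1), "unknown")
})

test_that("assembly_processes is reproducible and fractions sum to one", {
  cs <- make_community_series(assembly_regime("neutral", n_taxa = 40,
                                              n_samples = 5, depth = 1500,
                                              seed = 3))
  a1 <- assembly_processes(cs, min_bin_size = 8, n_null = 200, seed = 4)
  a2 <- assembly_processes(cs, min_bin_size = 8, n_null = 200, seed = 4)
  expect_identical(a1$scores, a2$scores)
  expect_equal(sum(a1$fractions), 1, tolerance = 1e-9)
  a3 <- assembly_processes(cs, min_bin_size = 8, n_null = 200, seed = 5)
  expect_false(identical(a1$scores$beta_nri, a3$scores$beta_nri))
})

test_that("succession trend detects convergence and flags degeneracy", {
  # identical communities: all dissimilarities zero, trend undefined
  ab <- matrix(rep(c(5, 3, 2), 5), nrow = 3)
  tr <- succession_trend(ab, sample_time = seq(0, 48, by = 12))
  expect_true(all(tr$intervals$bray_curtis == 0))
  expect_identical(tr$flag, "constant")

  # geometric convergence toward a fixed composition: BC strictly
  # decreasing, negative correlation with time
  p0 <- c(0.7, 0.2, 0.1); pf <- c(0.05, 0.15, 0.8)
  times <- seq(0, 60, by = 12)
  comp <- sapply(seq_along(times), function(i) {
    w <- 1 - 0.5^(i - 1)
    (1 - w) * p0 + w * pf
  })
  tr2 <- succession_trend(comp * 1000, times)
  expect_true(all(diff(tr2$intervals$bray_curtis) < 0))
  expect_lt(tr2$pearson_r, 0)
  expect_identical(tr2$flag, "ok")

  # complete turnover between two samples: BC = 1 (trend needs >= 3)
  ab2 <- cbind(c(1, 0), c(0, 1))
  tr3 <- succession_trend(ab2, c(0, 12))
  expect_equal(tr3$intervals$bray_curtis, 1)
  expect_identical(tr3$flag, "too_few")
})
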