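#' Partition taxa into phylogenetic bins
#'
#' Single-linkage agglomeration on the cophenetic (tree) distance with
#' cutoff `d_max`, followed by merging of undersized bins: a bin smaller
#' than `min_bin_size` is absorbed into the bin containing its
#' phylogenetically nearest neighbor (minimum cross-bin cophenetic
#' distance; ties broken toward the smaller bin id).  The result is a
#' partition of the tips.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param d_max within-bin phylogenetic distance threshold (default 0.2).
#' @param min_bin_size minimum bin size after merging (default 12).
#' @return a list of class `phylo_bins`; each element has `bin_id` and
#'   `taxa`.  Attribute `merged` counts merge operations.
#' @export
bin_taxa <- function(tree, d_max = 0.2, min_bin_size = 12) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  D <- ape::cophenetic.phylo(tree)
  if (n < min_bin_size) {
    warning("fewer taxa than min_bin_size: returning a single bin")
    memb <- setNames(rep(1L, n), tree$tip.label)
  } else {
    hc <- hclust(as.dist(D), method = "single")
    memb <- cutree(hc, h = d_max)
  }
  merged <- 0L
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_bin_size]
    if (length(small) == 0 || length(sizes) == 1) break
    b <- small[order(sizes[small], as.integer(small))][1]
    in_b <- names(memb)[memb == as.integer(b)]
    others <- setdiff(unique(memb), as.integer(b))
    near <- vapply(sort(others), function(o) {
      min(D[in_b, names(memb)[memb == o], drop = FALSE])
    }, numeric(1))
    target <- sort(others)[which.min(near)]
    memb[memb == as.integer(b)] <- target
    merged <- merged + 1L
  }
  ids <- sort(unique(memb))
  bins <- lapply(seq_along(ids), function(k) {
    list(bin_id = k, taxa = names(memb)[memb == ids[k]])
  })
  structure(bins, class = "phylo_bins", merged = merged,
            d_max = d_max, min_bin_size = min_bin_size)
}

# abundance-weighted between-community mean pairwise phylogenetic distance
beta_mpd_w <- function(pA, pB, D) as.numeric(pA %*% D %*% pB)

#' Beta net relatedness index for one community pair within a bin
#'
#' The observed abundance-weighted between-community mean pairwise
#' phylogenetic distance (beta-MPD) is standardized against a "taxa
#' shuffle" null: tip labels are permuted within the bin (one shared
#' permutation per randomization, applied to the distance matrix), keeping
#' both abundance vectors fixed.  `betaNRI = (obs - mean(null)) /
#' sd(null)`.  Deterministic given `seed`; `n_null = "exhaustive"`
#' enumerates all permutations (bins of <= 8 taxa).
#'
#' @param xA,xB abundance vectors over the bin's taxa (same order as the
#'   rows of `D`).
#' @param D cophenetic distance submatrix for the bin's taxa.
#' @param n_null number of randomizations (default 1000) or
#'   `"exhaustive"`.
#' @param seed integer seed.
#' @param weighted use abundance weighting (default TRUE; FALSE gives
#'   presence/absence weights).
#' @return a list `(beta_nri, obs, null_mean, null_sd, n_null, flag)`;
#'   `beta_nri` is `NA` with flag `"undefined"` when fewer than two taxa
#'   are present in either sample or the null SD is zero.
#' @export
beta_nri <- function(xA, xB, D, n_null = 1000, seed = 1L, weighted = TRUE) {
  xA <- as.numeric(xA); xB <- as.numeric(xB)
  n <- length(xA)
  stopifnot(length(xB) == n, all(dim(D) == n))
  if (!weighted) { xA <- as.numeric(xA > 0); xB <- as.numeric(xB > 0) }
  if (sum(xA > 0) < 2 || sum(xB > 0) < 2 || sum(xA) == 0 || sum(xB) == 0) {
    return(list(beta_nri = NA_real_, obs = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_, n_null = 0L, flag = "undefined"))
  }
  pA <- xA / sum(xA); pB <- xB / sum(xB)
  obs <- beta_mpd_w(pA, pB, D)
  perms <- if (identical(n_null, "exhaustive")) {
    all_permutations(n)
  } else {
    withr::with_seed(as.integer(seed),
                     t(replicate(n_null, sample.int(n))))
  }
  A <- matrix(pA[t(perms)], nrow = nrow(perms), byrow = TRUE)
  B <- matrix(pB[t(perms)], nrow = nrow(perms), byrow = TRUE)
  null <- rowSums((A %*% D) * B)
  mu <- mean(null); s <- sd(null)
  if (!is.finite(s) || s == 0) {
    return(list(beta_nri = NA_real_, obs = obs, null_mean = mu,
                null_sd = s, n_null = nrow(perms), flag = "undefined"))
  }
  list(beta_nri = (obs - mu) / s, obs = obs, null_mean = mu, null_sd = s,
       n_null = nrow(perms), flag = "ok")
}

bray_curtis <- function(a, b) {
  tot <- sum(a) + sum(b)
  if (tot == 0) return(NA_real_)
  sum(abs(a - b)) / tot
}

#' Modified Raup-Crick metric for one community pair within a bin
#'
#' The observed Bray-Curtis dissimilarity on the bin's abundances is
#' compared to a null distribution in which taxon identities are shuffled
#' within the bin independently for each sample (each sample's within-bin
#' abundance multiset is preserved, the assignment to taxa randomized).
#' `RC = 2 * (P(null < obs) + 0.5 * P(null = obs)) - 1`, confined to
#' `[-1, 1]`.  The abundance-based Bray-Curtis dialect is used (see the
#' methods vignette); `n_null = "exhaustive"` enumerates all permutation
#' pairs for tiny bins.
#'
#' @inheritParams beta_nri
#' @return a list `(rc, obs, n_null, flag)`; a degenerate null (all values
#'   equal to the observation) gives `rc = 0` with flag `"degenerate"`.
#' @export
rc_metric <- function(xA, xB, n_null = 1000, seed = 1L) {
  xA <- as.numeric(xA); xB <- as.numeric(xB)
  n <- length(xA)
  stopifnot(length(xB) == n)
  if (sum(xA) == 0 || sum(xB) == 0) {
    return(list(rc = NA_real_, obs = NA_real_, n_null = 0L,
                flag = "undefined"))
  }
  obs <- bray_curtis(xA, xB)
  if (identical(n_null, "exhaustive")) {
    pa <- all_permutations(n); pb <- all_permutations(n)
    null <- as.vector(vapply(seq_len(nrow(pa)), function(i) {
      vapply(seq_len(nrow(pb)), function(j) {
        bray_curtis(xA[pa[i, ]], xB[pb[j, ]])
      }, numeric(1))
    }, numeric(nrow(pb))))
  } else {
    null <- withr::with_seed(as.integer(seed), {
      PA <- t(replicate(n_null, sample.int(n)))
      PB <- t(replicate(n_null, sample.int(n)))
      A <- matrix(xA[t(PA)], nrow = n_null, byrow = TRUE)
      B <- matrix(xB[t(PB)], nrow = n_null, byrow = TRUE)
      rowSums(abs(A - B)) / (sum(xA) + sum(xB))
    })
  }
  eps <- 1e-12
  below <- sum(null < obs - eps)
  equal <- sum(abs(null - obs) <= eps)
  m <- length(null)
  if (equal == m) {
    return(list(rc = 0, obs = obs, n_null = m, flag = "degenerate"))
  }
  rc <- 2 * ((below + 0.5 * equal) / m) - 1
  list(rc = max(-1, min(1, rc)), obs = obs, n_null = m, flag = "ok")
}

#' Assign an assembly process from null-model scores
#'
#' Threshold rules: `betaNRI < -1.96` homogeneous selection (HoS);
#' `betaNRI > 1.96` heterogeneous selection (HeS); otherwise the
#' taxonomic null decides: `RC < -0.95` homogenizing dispersal (HD),
#' `RC > 0.95` dispersal limitation (DL), `|RC| <= 0.95` drift (DR).
#' An undefined betaNRI falls through to the RC path with a flag.
#'
#' @param beta_nri numeric vector of standardized phylogenetic scores
#'   (`NA` allowed).
#' @param rc numeric vector of Raup-Crick scores in `[-1, 1]` (`NA`
#'   allowed when `|betaNRI| > 1.96`).
#' @param sig_bnri,sig_rc significance cutoffs (defaults 1.96 and 0.95; the
#'   matching one-sided confidence level 0.975 is recorded as an
#'   attribute).
#' @return a character vector with levels HoS/HeS/HD/DL/DR (`NA` when both
#'   scores are missing).
#' @export
assign_process <- function(beta_nri, rc, sig_bnri = 1.96, sig_rc = 0.95) {
  n <- max(length(beta_nri), length(rc))
  beta_nri <- rep_len(beta_nri, n); rc <- rep_len(rc, n)
  out <- rep(NA_character_, n)
  hos <- !is.na(beta_nri) & beta_nri < -sig_bnri
  hes <- !is.na(beta_nri) & beta_nri > sig_bnri
  out[hos] <- "HoS"; out[hes] <- "HeS"
  rest <- !hos & !hes
  out[rest & !is.na(rc) & rc < -sig_rc] <- "HD"
  out[rest & !is.na(rc) & rc > sig_rc] <- "DL"
  out[rest & !is.na(rc) & abs(rc) <= sig_rc] <- "DR"
  attr(out, "confidence_level") <- 0.975
  out
}

#' Aggregate per-bin process labels into process fractions
#'
#' Relative importance of process `P` is the weight-normalized sum of
#' `weight * 1[label == P]` over (bin, pair) observations; weights are
#' typically the mean relative abundance of the bin across the two samples
#' of the pair.  Fractions sum to 1.
#'
#' @param labels character vector of process labels (HoS/HeS/HD/DL/DR;
#'   `NA` observations are dropped with their weight).
#' @param weights nonnegative weights, same length.
#' @return a named numeric vector of class `process_fractions` over
#'   `c("HoS", "HeS", "HD", "DL", "DR")`.
#' @export
aggregate_processes <- function(labels, weights) {
  procs <- c("HoS", "HeS", "HD", "DL", "DR")
  if (length(labels) != length(weights)) stop("labels/weights length mismatch")
  if (any(weights < 0)) stop("weights must be >= 0")
  keep <- !is.na(labels)
  labels <- labels[keep]; weights <- weights[keep]
  if (length(labels) == 0 || sum(weights) == 0)
    stop("zero total weight: process fractions undefined")
  if (!all(labels %in% procs)) stop("unknown process label")
  w <- vapply(procs, function(p) sum(weights[labels == p]), numeric(1))
  structure(w / sum(w), class = "process_fractions")
}

#' @export
print.process_fractions <- function(x, ...) {
  cat("assembly process fractions:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Full phylogenetic-bin null-model analysis of a community series
#'
#' Bins the taxa on the tree, then scores every requested sample pair in
#' every bin: abundance-weighted beta-MPD standardized by the within-bin
#' taxa-shuffle null (betaNRI), with the Raup-Crick taxonomic null deciding
#' the non-significant pairs.  Per-(bin, pair) labels are aggregated into
#' process fractions weighted by the bin's mean relative abundance across
#' the two samples.
#'
#' @param series a `community_series` (see [make_community_series()]) or a
#'   list with `abundance` (taxa x samples matrix, rownames = tip labels)
#'   and `tree`.
#' @param d_max,min_bin_size binning parameters (defaults 0.2 and 12).
#' @param n_null randomizations per comparison (default 1000).
#' @param seed integer seed; every comparison receives a derived sub-seed.
#' @param pairs optional two-column matrix/data frame of sample indices or
#'   names; default all unordered pairs.
#' @return a list of class `assembly_result`: `scores` (one row per
#'   bin x pair with `beta_nri`, `rc`, `process`, `weight`), `fractions`
#'   (overall [aggregate_processes()]), and `bins`.
#' @export
assembly_processes <- function(series, d_max = 0.2, min_bin_size = 12,
                               n_null = 1000, seed = 1L, pairs = NULL) {
  ab <- series$abundance
  tree <- series$tree
  stopifnot(is.matrix(ab), inherits(tree, "phylo"))
  if (is.null(rownames(ab)) || !all(rownames(ab) %in% tree$tip.label))
    stop("every abundance row must map to a tree tip")
  samples <- colnames(ab) %||% as.character(seq_len(ncol(ab)))
  colnames(ab) <- samples
  if (is.null(pairs)) {
    idx <- utils::combn(length(samples), 2)
    pairs <- data.frame(a = samples[idx[1, ]], b = samples[idx[2, ]])
  } else {
    pairs <- data.frame(a = as.character(pairs[, 1]),
                        b = as.character(pairs[, 2]))
  }
  bins <- bin_taxa(tree, d_max = d_max, min_bin_size = min_bin_size)
  Dfull <- ape::cophenetic.phylo(tree)
  totals <- colSums(ab)
  rows <- vector("list", length(bins) * nrow(pairs))
  k <- 0L
  for (b in seq_along(bins)) {
    taxa <- intersect(bins[[b]]$taxa, rownames(ab))
    if (length(taxa) == 0) next
    Db <- Dfull[taxa, taxa, drop = FALSE]
    sub <- ab[taxa, , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      k <- k + 1L
      sa <- pairs$a[p]; sb <- pairs$b[p]
      xA <- sub[, sa]; xB <- sub[, sb]
      w <- mean(c(sum(xA) / totals[sa], sum(xB) / totals[sb]))
      sd_bn <- derive_seed(seed, 2L * k)
      bn <- beta_nri(xA, xB, Db, n_null = n_null, seed = sd_bn)
      rc <- NA_real_
      if (is.na(bn$beta_nri) || abs(bn$beta_nri) <= 1.96) {
        rc <- rc_metric(xA, xB, n_null = n_null,
                        seed = derive_seed(seed, 2L * k + 1L))$rc
      }
      rows[[k]] <- data.frame(
        sample_a = sa, sample_b = sb, bin_id = bins[[b]]$bin_id,
        n_taxa = length(taxa), weight = w,
        beta_nri = bn$beta_nri, rc = rc,
        process = assign_process(bn$beta_nri, rc))
    }
  }
  scores <- do.call(rbind, rows)
  fractions <- aggregate_processes(scores$process, scores$weight)
  structure(list(scores = scores, fractions = fractions, bins = bins),
            class = "assembly_result")
}

#' Bray-Curtis succession trend between adjacent time points
#'
#' Computes Bray-Curtis dissimilarity on relative abundances between
#' consecutive time points within each replicate, then the Pearson
#' correlation of dissimilarity with time (interval end).  A negative
#' correlation indicates a community approaching steady state.
#'
#' @param abundance taxa x samples matrix.
#' @param sample_time numeric time (hours) per sample.
#' @param replicate replicate id per sample (default: one replicate).
#' @return a list with `intervals` (replicate, t_from, t_to, bray_curtis),
#'   `pearson_r`, `p_value` and `flag` (`"ok"`, `"constant"` when all
#'   dissimilarities are equal, `"too_few"` for < 3 intervals).
#' @export
succession_trend <- function(abundance, sample_time, replicate = NULL) {
  stopifnot(is.matrix(abundance), ncol(abundance) == length(sample_time))
  replicate <- replicate %||% rep(1L, length(sample_time))
  rel <- sweep(abundance, 2, pmax(colSums(abundance), 1e-300), "/")
  rows <- list()
  for (r in unique(replicate)) {
    sel <- which(replicate == r)
    sel <- sel[order(sample_time[sel])]
    if (length(sel) < 2) next
    for (i in seq_len(length(sel) - 1)) {
      a <- sel[i]; b <- sel[i + 1]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, t_from = sample_time[a], t_to = sample_time[b],
        bray_curtis = as.numeric(
          vegan::vegdist(t(rel[, c(a, b)]), method = "bray")))
    }
  }
  intervals <- do.call(rbind, rows)
  if (is.null(intervals) || nrow(intervals) < 3) {
    return(list(intervals = intervals, pearson_r = NA_real_,
                p_value = NA_real_, flag = "too_few"))
  }
  if (sd(intervals$bray_curtis) == 0 || sd(intervals$t_to) == 0) {
    return(list(intervals = intervals, pearson_r = NA_real_,
                p_value = NA_real_, flag = "constant"))
  }
  ct <- cor.test(intervals$bray_curtis, intervals$t_to)
  list(intervals = intervals, pearson_r = unname(ct$estimate),
       p_value = ct$p.value, flag = "ok")
}
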