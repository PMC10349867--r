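#' Specify a community assembly regime
#'
#' The stated world for validating the null-model module: a pure-birth
#' (Yule) phylogeny with branch lengths scaled to a chosen mean root-to-tip
#' depth, a lognormal metacommunity abundance distribution, Brownian-motion
#' trait evolution with tunable phylogenetic conservatism, and one of four
#' sampling regimes.
#'
#' Regimes: \describe{
#'   \item{neutral}{each sample is a multinomial draw from the shared
#'     metacommunity with taxon identities independently permuted across
#'     the tree tips — the data-generating analogue of the "taxa shuffle"
#'     null, so phylogenetic null scores are calibrated by construction.}
#'   \item{homogeneous_selection}{sampling probabilities are biased by a
#'     shared phylogenetically conserved trait:
#'     `p ~ metacommunity * exp(strength * trait)`.}
#'   \item{heterogeneous_selection}{as above but the trait's sign flips
#'     between the two halves of the samples (two contrasting filters).}
#'   \item{dispersal_limitation}{the taxon pool is partitioned disjointly
#'     across samples.}
#' }
#'
#' @param kind regime name (see above).
#' @param n_taxa number of tips (>= 2; default 160).
#' @param n_samples number of samples (default 14).
#' @param tree_depth mean root-to-tip distance after scaling (default 1, so
#'   the 0.2 binning threshold is meaningful).
#' @param trait_conservatism Pagel-lambda-like scalar in `[0, 1]` mixing
#'   Brownian (1) and independent (0) trait components.
#' @param selection_strength selective bias scalar; must be 0 iff `kind =
#'   "neutral"` (default 5 for selective regimes).
#' @param depth sequencing depth per sample (multinomial size; default
#'   5000).
#' @param time_gradient logical; for selective regimes, ramp the strength
#'   linearly from 0 to `selection_strength` across samples, emulating
#'   selection tightening as the biofilm matures.
#' @param seed integer seed.
#' @return an object of class `assembly_regime`.
#' @export
assembly_regime <- function(kind = c("neutral", "homogeneous_selection",
                                     "heterogeneous_selection",
                                     "dispersal_limitation"),
                            n_taxa = 160, n_samples = 14, tree_depth = 1,
                            trait_conservatism = 1,
                            selection_strength = NULL,
                            depth = 5000, time_gradient = FALSE,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (n_samples < 2) stop("n_samples must be >= 2")
  selection_strength <- selection_strength %||%
    (if (kind == "neutral") 0 else 5)
  if ((kind == "neutral") != (selection_strength == 0))
    stop("selection_strength must be 0 iff kind is 'neutral'")
  if (trait_conservatism < 0 || trait_conservatism > 1)
    stop("trait_conservatism must lie in [0, 1]")
  structure(list(kind = kind, n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples), tree_depth = tree_depth,
                 trait_conservatism = trait_conservatism,
                 selection_strength = selection_strength,
                 depth = as.integer(depth),
                 time_gradient = isTRUE(time_gradient),
                 seed = as.integer(seed)),
            class = "assembly_regime")
}

# Brownian-motion trait along the tree edges, standardized
bm_trait <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  x <- numeric(n_node)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    x[child] <- x[par] + rnorm(1, 0, sqrt(max(ord$edge.length[i], 1e-12)))
  }
  z <- x[seq_len(n_tip)]
  (z - mean(z)) / max(sd(z), 1e-12)
}

#' Generate a synthetic community time series on a simulated phylogeny
#'
#' See [assembly_regime()] for the generative model.  Abundances are
#' multinomial counts (the counting-noise model for amplicon data); the
#' returned regime label is the planted ground truth.
#'
#' @param regime an [assembly_regime()].
#' @return a list of class `community_series`: `abundance` (taxa x samples
#'   integer matrix, rownames = tip labels), `tree` (`phylo`),
#'   `sample_time` (hours), `replicate`, `trait` (per-tip, standardized)
#'   and `regime`.
#' @export
make_community_series <- function(regime) {
  stopifnot(inherits(regime, "assembly_regime"))
  withr::with_seed(regime$seed, {
    n <- regime$n_taxa; S <- regime$n_samples
    tree <- ape::rphylo(n, birth = 1, death = 0)
    tree$tip.label <- sprintf("asv_%03d", seq_len(n))
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    tree$edge.length <- tree$edge.length * regime$tree_depth / mean(depths)

    meta_p <- sort(rlnorm(n, 0, 1.5), decreasing = TRUE)
    meta_p <- meta_p / sum(meta_p)
    base_assign <- sample.int(n)       # fixed placement on the tips
    p_tips <- meta_p[base_assign]      # metacommunity probability per tip

    bm <- bm_trait(tree)
    lam <- regime$trait_conservatism
    noise <- rnorm(n); noise <- (noise - mean(noise)) / max(sd(noise), 1e-12)
    trait <- sqrt(lam) * bm + sqrt(1 - lam) * noise

    s_per_sample <- rep(regime$selection_strength, S)
    if (regime$time_gradient)
      s_per_sample <- regime$selection_strength * (seq_len(S) - 1) / (S - 1)

    ab <- matrix(0L, n, S, dimnames = list(tree$tip.label, NULL))
    if (regime$kind == "dispersal_limitation") {
      block <- sample(rep_len(seq_len(S), n))
    }
    for (s in seq_len(S)) {
      p <- switch(regime$kind,
        neutral = p_tips[sample.int(n)],
        homogeneous_selection = p_tips * exp(s_per_sample[s] * trait),
        heterogeneous_selection = p_tips *
          exp((if (s <= S / 2) 1 else -1) * s_per_sample[s] * trait),
        dispersal_limitation = p_tips * (block == s))
      if (sum(p) == 0) p <- p_tips   # empty block fallback (tiny n)
      ab[, s] <- rmultinom(1, regime$depth, p / sum(p))
    }
    colnames(ab) <- sprintf("s%02d", seq_len(S))
    structure(list(abundance = ab, tree = tree,
                   sample_time = (seq_len(S) - 1) * 12,
                   replicate = rep(1L, S), trait = trait, regime = regime),
              class = "community_series")
  })
}

#' Write / read a community series in standard text formats
#'
#' TSV for the ASV table, Newick for the tree, CSV for sample metadata.
#'
#' @param series a `community_series`.
#' @param dir output directory.
#' @param name file-name stem.
#' @return `write_community_series` invisibly returns the files written;
#'   `read_community_series` returns a `community_series`-shaped list.
#' @export
write_community_series <- function(series, dir, name = "community") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_tab <- file.path(dir, paste0(name, "_asv.tsv"))
  tab <- data.frame(taxon = rownames(series$abundance), series$abundance,
                    check.names = FALSE)
  write.table(tab, f_tab, sep = "\t", row.names = FALSE, quote = FALSE)
  f_tree <- file.path(dir, paste0(name, "_tree.nwk"))
  ape::write.tree(series$tree, f_tree)
  f_meta <- file.path(dir, paste0(name, "_samples.csv"))
  write.csv(data.frame(sample = colnames(series$abundance),
                       time_h = series$sample_time,
                       replicate = series$replicate),
            f_meta, row.names = FALSE)
  invisible(c(f_tab, f_tree, f_meta))
}

#' @rdname write_community_series
#' @export
read_community_series <- function(dir, name = "community") {
  tab <- read.delim(file.path(dir, paste0(name, "_asv.tsv")),
                    check.names = FALSE)
  ab <- as.matrix(tab[, -1, drop = FALSE])
  rownames(ab) <- tab$taxon
  meta <- read.csv(file.path(dir, paste0(name, "_samples.csv")))
  structure(list(abundance = ab,
                 tree = ape::read.tree(file.path(dir, paste0(name, "_tree.nwk"))),
                 sample_time = meta$time_h, replicate = meta$replicate),
            class = "community_series")
}
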