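# shared fixtures and independent mini-oracles used across test files

# brute-force Otsu oracle: scan every candidate cut between sorted unique
# values, minimizing within-class variance
brute_force_threshold <- function(v) {
  u <- sort(unique(v))
  cuts <- (u[-1] + u[-length(u)]) / 2
  wcv <- vapply(cuts, function(th) {
    lo <- v[v <= th]; hi <- v[v > th]
    (length(lo) * if (length(lo) > 1) var(lo) * (length(lo) - 1) / length(lo) else 0) +
      (length(hi) * if (length(hi) > 1) var(hi) * (length(hi) - 1) / length(hi) else 0)
  }, numeric(1))
  cuts[which.min(wcv)]
}

# independent enumeration of the 3! tip permutations (kept free of the
# package's own permutation helper)
perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
               c(3, 1, 2), c(3, 2, 1))

# abundance-weighted between-community MPD, plain triple loop
bmpd_loop <- function(xA, xB, D) {
  pA <- xA / sum(xA); pB <- xB / sum(xB)
  s <- 0
  for (i in seq_along(pA)) for (j in seq_along(pB))
    s <- s + pA[i] * pB[j] * D[i, j]
  s
}

bray_loop <- function(a, b) sum(abs(a - b)) / (sum(a) + sum(b))

# small two-clade tree: within-clade cophenetic distance 0.1, between 0.6
two_clade_tree <- function() {
  ape::read.tree(text = "((a:0.05,b:0.05,c:0.05):0.25,(d:0.05,e:0.05,f:0.05):0.25);")
}

star_tree <- function(n = 4) {
  ape::read.tree(text = paste0("(", paste(sprintf("t%d:0.25", seq_len(n)),
                                          collapse = ","), ");"))
}
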