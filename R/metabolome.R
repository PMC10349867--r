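#' Standardize a series to z-scores
#'
#' `(v - mean) / sd` with the population (divide-by-n) standard deviation.
#' A constant series returns all zeros with a degenerate flag.
#'
#' @param values numeric vector (>= 2 values).
#' @return numeric z-scores with logical attribute `degenerate`.
#' @examples
#' zscore(c(1, 2, 3))   # -1.2247, 0, 1.2247
#' @export
zscore <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need >= 2 values")
  s <- pop_sd(values)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - mean(values)) / s
  attr(out, "degenerate") <- FALSE
  out
}

#' Classify a metabolite's temporal trend
#'
#' Spearman rank correlation (average ranks for ties) between the values
#' and the time points: \emph{released} when `rho > 0.5`, \emph{consumed}
#' when `rho < -0.5`, \emph{other} otherwise.  A constant series has an
#' undefined rho and is classified \emph{other} with a flag.  Because the
#' rule is rank-based it is invariant under strictly monotone transforms
#' of the values.
#'
#' @param values peak areas or concentrations per time point (>= 4).
#' @param times time points, same length.
#' @param rho_threshold classification threshold (default 0.5).
#' @return a list `(class, rho, flag)` with class in
#'   released/consumed/other.
#' @examples
#' classify_trend(c(5, 4, 3, 2, 3, 4, 5), 1:7)  # rho = 0 -> other
#' @export
classify_trend <- function(values, times, rho_threshold = 0.5) {
  values <- as.numeric(values); times <- as.numeric(times)
  if (length(values) != length(times) || length(values) < 4)
    stop("need >= 4 paired time points")
  if (pop_sd(values) == 0) {
    return(list(class = "other", rho = NA_real_, flag = "constant"))
  }
  rho <- suppressWarnings(cor(values, times, method = "spearman"))
  cls <- if (rho > rho_threshold) "released"
         else if (rho < -rho_threshold) "consumed" else "other"
  list(class = cls, rho = rho, flag = "ok")
}

#' Screen feature-feature Spearman correlations across shared samples
#'
#' For every pair of one row of `features_a` and one row of `features_b`
#' (shared sample columns, >= 5 required) the Spearman correlation and its
#' two-sided p-value are computed; rows are retained when `|r| >= r_min`
#' and `p <= alpha`, with significance stars at 0.05 / 0.01 / 0.001.  No
#' multiple-testing correction is applied by default; Benjamini-Hochberg is
#' available via `adjust = "BH"` (applied before filtering).
#'
#' @param features_a,features_b numeric matrices, features x samples, with
#'   sample names as column names.
#' @param r_min minimum absolute correlation (default 0.5).
#' @param alpha p-value cutoff (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a data frame `(feature_a, feature_b, rho, p_value, stars,
#'   retained)`; the attribute `retained` gives the filtered subset.
#' @export
feature_correlations <- function(features_a, features_b, r_min = 0.5,
                                 alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(features_a), is.matrix(features_b))
  shared <- intersect(colnames(features_a), colnames(features_b))
  if (length(shared) < 5) stop("need >= 5 shared samples")
  A <- features_a[, shared, drop = FALSE]
  B <- features_b[, shared, drop = FALSE]
  grid <- expand.grid(ia = seq_len(nrow(A)), ib = seq_len(nrow(B)))
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    a <- A[grid$ia[k], ]; b <- B[grid$ib[k], ]
    ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
    data.frame(feature_a = rownames(A)[grid$ia[k]] %||% grid$ia[k],
               feature_b = rownames(B)[grid$ib[k]] %||% grid$ib[k],
               rho = unname(ct$estimate), p_value = ct$p.value)
  }))
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$stars <- cut(res$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  res$retained <- abs(res$rho) >= r_min & res$p_value <= alpha
  attr(res, "retained") <- res[res$retained, , drop = FALSE]
  res
}

#' Procrustes concordance between two sample ordinations
#'
#' Symmetric least-squares Procrustes superimposition (translation,
#' uniform scaling, rotation/reflection) of two sample configurations,
#' e.g. community and metabolome ordinations.  The concordance statistic
#' is `sqrt(1 - m2)` where `m2` is the standardized residual sum of
#' squares; significance is assessed by permuting the sample labels of the
#' second configuration (deterministic given `seed`).
#'
#' @param ordination_a,ordination_b numeric matrices, samples x dimensions,
#'   same samples (matched by rownames when present, else by order).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a list of class `procrustes_concordance`: `correlation`, `m2`,
#'   `p_value`, `n_perm`, `flag` (`"ok"` or `"rank_deficient"`).
#' @export
concordance <- function(ordination_a, ordination_b, n_perm = 999,
                        seed = 1L) {
  X <- as.matrix(ordination_a); Y <- as.matrix(ordination_b)
  if (nrow(X) < 3) stop("need >= 3 samples")
  if (nrow(X) != nrow(Y)) stop("configurations must share samples")
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y)))
      stop("configurations must share samples")
    Y <- Y[rownames(X), , drop = FALSE]
  }
  norm_cfg <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    f <- sqrt(sum(M^2))
    if (f == 0) return(NULL)
    M / f
  }
  Xn <- norm_cfg(X); Yn <- norm_cfg(Y)
  if (is.null(Xn) || is.null(Yn)) {
    return(structure(list(correlation = NA_real_, m2 = NA_real_,
                          p_value = NA_real_, n_perm = 0L,
                          flag = "rank_deficient"),
                     class = "procrustes_concordance"))
  }
  pro_corr <- function(A, B) sum(svd(crossprod(A, B))$d)
  obs <- pro_corr(Xn, Yn)
  flag <- if (qr(Xn)$rank < ncol(Xn) || qr(Yn)$rank < ncol(Yn))
    "rank_deficient" else "ok"
  perm_ge <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_perm), function(i) {
      pro_corr(Xn, Yn[sample.int(nrow(Yn)), , drop = FALSE])
    }, numeric(1)) >= obs - 1e-12)
  })
  structure(list(correlation = obs, m2 = 1 - obs^2,
                 p_value = (perm_ge + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), flag = flag),
            class = "procrustes_concordance")
}

#' @export
print.procrustes_concordance <- function(x, ...) {
  cat(sprintf("Procrustes correlation = %.3f (m2 = %.3f), permutation p = %.4g [%d perms]%s\n",
              x$correlation, x$m2, x$p_value, x$n_perm,
              if (x$flag != "ok") paste0(" (", x$flag, ")") else ""))
  invisible(x)
}
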