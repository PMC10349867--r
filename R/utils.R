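`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed
#'
#' Linear-congruential mixing keeps the result a positive 32-bit integer so
#' it can be passed to [set.seed()] on any platform.
#'
#' @param seed master integer seed.
#' @param offset integer stream identifier (stage or iteration index).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer(1L + ((abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 7919) %%
                     2147483645))
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# all permutations of 1..n (n small); used for exhaustive null enumeration
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

stop_if_not_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
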