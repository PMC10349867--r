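#' Generate a synthetic co-culture yield table with planted classes
#'
#' Monoculture yields are uniform on `[0.2, 1]` OD units; the co-culture
#' yield is then placed strictly inside the planted class's region
#' (positive: `(1.1..1.5) * Y_sum`; weak negative: the interior 5-95\% of
#' `[Y_min, Y_sum]`; strong negative: `(0.1..0.8) * Y_min`), so the planted
#' label is by construction the classification of the noiseless yields.
#' Gaussian noise (clamped at 0) is added afterwards.
#'
#' @param n_pairs number of strain pairs.
#' @param class_mix named proportions over
#'   `c("positive", "weak_negative", "strong_negative")`, summing to 1.
#' @param noise_sd additive OD noise.
#' @param seed integer seed.
#' @return a data frame `(pair_id, y_a, y_b, y_co, planted_class)`.
#' @export
make_coculture_table <- function(n_pairs = 50,
                                 class_mix = c(positive = 0.5,
                                               weak_negative = 0.3,
                                               strong_negative = 0.2),
                                 noise_sd = 0, seed = 1L) {
  classes <- c("positive", "weak_negative", "strong_negative")
  class_mix <- unlist(class_mix)
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% classes) ||
      abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must be named proportions over the three classes summing to 1")
  withr::with_seed(as.integer(seed), {
    planted <- sample(names(class_mix), n_pairs, replace = TRUE,
                      prob = class_mix)
    y_a <- runif(n_pairs, 0.2, 1)
    y_b <- runif(n_pairs, 0.2, 1)
    y_min <- pmin(y_a, y_b); y_sum <- y_a + y_b
    y_co <- numeric(n_pairs)
    pos <- planted == "positive"
    wk <- planted == "weak_negative"
    st <- planted == "strong_negative"
    y_co[pos] <- y_sum[pos] * runif(sum(pos), 1.1, 1.5)
    y_co[wk] <- y_min[wk] + runif(sum(wk), 0.05, 0.95) *
      (y_sum[wk] - y_min[wk])
    y_co[st] <- y_min[st] * runif(sum(st), 0.1, 0.8)
    if (noise_sd > 0) {
      y_a <- pmax(0, y_a + rnorm(n_pairs, 0, noise_sd))
      y_b <- pmax(0, y_b + rnorm(n_pairs, 0, noise_sd))
      y_co <- pmax(0, y_co + rnorm(n_pairs, 0, noise_sd))
    }
    data.frame(pair_id = seq_len(n_pairs), y_a = y_a, y_b = y_b,
               y_co = y_co,
               planted_class = factor(planted, levels = classes))
  })
}

#' Specify a synthetic exometabolite trend
#'
#' @param shape one of `"monotone_up"`, `"monotone_down"`, `"v_shaped"`,
#'   `"flat"`.
#' @param n_timepoints number of time points (>= 4; default 7 so the
#'   V-shape is exactly rank-symmetric).
#' @param noise_sd additive noise on the (z-scale) values.
#' @param seed integer seed.
#' @return an object of class `trend_spec` whose `class_label`
#'   (released/consumed/other) is derived from the noiseless Spearman rule.
#' @export
trend_spec <- function(shape = c("monotone_up", "monotone_down", "v_shaped",
                                 "flat"),
                       n_timepoints = 7, noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  if (n_timepoints < 4) stop("n_timepoints must be >= 4")
  structure(list(shape = shape, n_timepoints = as.integer(n_timepoints),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 class_label = switch(shape, monotone_up = "released",
                                      monotone_down = "consumed",
                                      v_shaped = "other", flat = "other")),
            class = "trend_spec")
}

trend_values <- function(shape, n) {
  switch(shape,
         monotone_up = seq(1, 5, length.out = n),
         monotone_down = seq(5, 1, length.out = n),
         v_shaped = {
           mid <- (n + 1) / 2
           2 + abs(seq_len(n) - mid) * 6 / (n - 1)
         },
         flat = rep(3, n))
}

#' Generate synthetic exometabolite peak-area series with planted labels
#'
#' Emulates effluent metabolite dynamics during biofilm development,
#' including the characteristic V-shaped trajectory of compounds that are
#' first consumed and later re-released.  Planted labels are always
#' obtained by applying the Spearman threshold rule (see
#' [classify_trend()]) to the noiseless values.
#'
#' @param specs a list of [trend_spec()]s, or a character vector of shapes.
#' @param times time points in hours (default equispaced, 12 h apart).
#' @param seed integer master seed (per-metabolite sub-seeds derived).
#' @return a list: `values` (metabolite x time matrix), `times`, and
#'   `labels` data frame `(metabolite, shape, planted_class)`.
#' @export
make_metabolite_series <- function(specs, times = NULL, seed = 1L) {
  if (is.character(specs)) specs <- lapply(specs, trend_spec)
  stopifnot(all(vapply(specs, inherits, logical(1), "trend_spec")))
  n_t <- specs[[1]]$n_timepoints
  if (!all(vapply(specs, function(s) s$n_timepoints, integer(1)) == n_t))
    stop("all specs must share n_timepoints")
  times <- times %||% ((seq_len(n_t) - 1) * 12)
  vals <- matrix(NA_real_, length(specs), n_t,
                 dimnames = list(sprintf("met_%03d", seq_along(specs)), NULL))
  labels <- data.frame(metabolite = rownames(vals),
                       shape = vapply(specs, `[[`, character(1), "shape"),
                       planted_class = NA_character_)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    base <- trend_values(sp$shape, n_t)
    # planted label from the noiseless values under the Spearman rule
    labels$planted_class[i] <- classify_trend(base, times)$class
    v <- base
    if (sp$noise_sd > 0) {
      v <- withr::with_seed(derive_seed(seed, i),
                            v + rnorm(n_t, 0, sp$noise_sd))
    }
    vals[i, ] <- v
  }
  list(values = vals, times = times, labels = labels)
}
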