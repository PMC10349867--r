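#' Generate a synthetic breakthrough curve with analytic mean travel time
#'
#' Emulates the effluent fluorescence record of a pulse of colloidal
#' microspheres traversing the porous chamber.  The residence-time
#' distribution is sampled on a regular grid over `[0, T]`; the analytic
#' mean travel time of the distribution truncated to the acquisition window
#' is attached as ground truth (computed in closed form, never from the
#' rendered samples).
#'
#' @param dist residence-time distribution: `list(kind = "gaussian", mean,
#'   sd)`, `list(kind = "exponential", rate)`, or `list(kind = "delta",
#'   at)`.
#' @param T acquisition window duration in minutes.
#' @param dt sampling interval in minutes.
#' @param noise_sd additive Gaussian noise on the signal (clamped at 0).
#' @param seed integer seed.
#' @return a `breakthrough_curve` (see [breakthrough_curve()]) with
#'   attributes `tau_true` (analytic truncated mean, minutes) and
#'   `mass_warning` (TRUE when more than 1\% of the distribution mass lies
#'   outside the window).
#' @examples
#' bc <- make_breakthrough(list(kind = "gaussian", mean = 50, sd = 5),
#'                         T = 200, dt = 0.5)
#' attr(bc, "tau_true")
#' @export
make_breakthrough <- function(dist, T = 200, dt = 0.5, noise_sd = 0, seed = 1L) {
  stopifnot(is.list(dist), !is.null(dist$kind))
  if (dt <= 0 || T <= 0) stop("T and dt must be > 0")
  t <- seq(0, T, by = dt)
  kind <- match.arg(dist$kind, c("gaussian", "exponential", "delta"))
  if (kind == "gaussian") {
    mu <- dist$mean; s <- dist$sd
    C <- dnorm(t, mu, s)
    mass <- pnorm(T, mu, s) - pnorm(0, mu, s)
    # mean of the Gaussian truncated to [0, T]
    a <- (0 - mu) / s; b <- (T - mu) / s
    tau <- mu + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  } else if (kind == "exponential") {
    k <- dist$rate
    C <- k * exp(-k * t)
    mass <- 1 - exp(-k * T)
    tau <- 1 / k - T * exp(-k * T) / (1 - exp(-k * T))
  } else {
    at <- dist$at
    if (at < 0 || at > T) stop("delta pulse must lie inside [0, T]")
    C <- numeric(length(t))
    C[which.min(abs(t - at))] <- 1
    mass <- 1
    tau <- at
  }
  mass_warning <- mass < 0.99
  if (mass_warning)
    warning(sprintf("%.1f%% of distribution mass lies outside [0, T]",
                    100 * (1 - mass)))
  if (noise_sd > 0) {
    C <- withr::with_seed(as.integer(seed),
                          pmax(0, C + rnorm(length(C), 0, noise_sd)))
  }
  bc <- breakthrough_curve(t, C, T)
  attr(bc, "tau_true") <- tau
  attr(bc, "mass_warning") <- mass_warning
  bc
}

#' Generate synthetic qPCR standard-curve data
#'
#' Cq values follow the standard-curve model
#' `Cq = intercept + slope * log10(copies)` with
#' `slope = -1 / log10(1 + efficiency)`, plus optional additive Gaussian
#' noise on the Cq scale.  An efficiency of 1 (100\%) corresponds to the
#' textbook slope of -3.3219 cycles per decade.
#'
#' @param efficiency true amplification efficiency as a fraction
#'   (`(0.5, 1.5]`; e.g. 1.047 for the 104.7\% universal-primer assay).
#' @param intercept Cq at 1 copy.
#' @param dilution_levels template copy numbers (>= 3 distinct levels).
#' @param reps technical replicates per level.
#' @param noise_sd Gaussian Cq noise standard deviation (cycles).
#' @param seed integer seed.
#' @return a data frame `(copies, replicate, cq)` with attribute
#'   `ground_truth = list(efficiency, slope, intercept)`.
#' @examples
#' qd <- make_qpcr(1.0, intercept = 40, dilution_levels = 10^(2:6))
#' head(qd)
#' @export
make_qpcr <- function(efficiency, intercept = 40,
                      dilution_levels = 10^(2:6), reps = 3,
                      noise_sd = 0, seed = 1L) {
  stop_if_not_scalar_num(efficiency, "efficiency")
  if (efficiency <= 0.5 || efficiency > 1.5)
    stop("efficiency must lie in (0.5, 1.5]")
  dilution_levels <- sort(unique(as.numeric(dilution_levels)), decreasing = TRUE)
  if (length(dilution_levels) < 3) stop("need >= 3 distinct dilution levels")
  if (any(dilution_levels <= 0)) stop("copy numbers must be > 0")
  slope <- -1 / log10(1 + efficiency)
  df <- expand.grid(replicate = seq_len(reps), copies = dilution_levels)
  df <- df[, c("copies", "replicate")]
  df$cq <- intercept + slope * log10(df$copies)
  if (noise_sd > 0) {
    df$cq <- withr::with_seed(as.integer(seed),
                              df$cq + rnorm(nrow(df), 0, noise_sd))
  }
  attr(df, "ground_truth") <- list(efficiency = efficiency, slope = slope,
                                   intercept = intercept)
  df
}
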