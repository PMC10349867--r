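#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on `log10(copies)`.  Technical-replicate
#' Cq values at the same dilution level are averaged on the Cq scale before
#' fitting.  The amplification efficiency follows from the slope as
#' `E = 10^(-1/slope) - 1` (a perfect doubling assay has slope -3.3219 and
#' `E = 1`, i.e. 100\%).
#'
#' @param copies template copy numbers (> 0).
#' @param cq measured quantification cycles, same length.
#' @return an object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency` (fraction), and the calibrated `cq_range`.
#' @examples
#' qd <- make_qpcr(1.047, dilution_levels = 10^(2:6))
#' fit_standard_curve(qd$copies, qd$cq)
#' @export
fit_standard_curve <- function(copies, cq) {
  copies <- as.numeric(copies); cq <- as.numeric(cq)
  if (length(copies) != length(cq)) stop("copies and cq must have equal length")
  if (any(copies <= 0)) stop("copy numbers must be > 0")
  lvl <- log10(copies)
  if (length(unique(signif(lvl, 10))) < 3)
    stop("need >= 3 distinct dilution levels")
  mcq <- tapply(cq, lvl, mean)
  x <- as.numeric(names(mcq)); y <- as.numeric(mcq)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope >= 0) stop("fitted slope is non-negative: inverted standard curve")
  r2 <- if (length(y) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 cq_range = range(y)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Cq = %.4f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency = %.1f%%, R^2 = %.4f\n",
              100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Convert Cq values to absolute copy numbers
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept) / slope)`,
#' monotone decreasing in Cq.  Values outside the calibrated Cq range are
#' returned but flagged as extrapolations.
#'
#' @param cq numeric Cq values.
#' @param curve a fitted [fit_standard_curve()] object.
#' @param copies_per_cell optional conversion factor (marker copies per
#'   cell); when given, the result is divided by it to report cells.
#' @return numeric copy (or cell) numbers with logical attribute
#'   `extrapolated`.
#' @export
quantify <- function(cq, curve, copies_per_cell = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  cq <- as.numeric(cq)
  out <- 10^((cq - curve$intercept) / curve$slope)
  if (!is.null(copies_per_cell)) {
    stop_if_not_scalar_num(copies_per_cell, "copies_per_cell")
    out <- out / copies_per_cell
  }
  extra <- cq < curve$cq_range[1] - 1e-9 | cq > curve$cq_range[2] + 1e-9
  if (any(extra)) warning(sprintf("%d Cq value(s) outside the calibrated range",
                                  sum(extra)))
  attr(out, "extrapolated") <- extra
  out
}

#' Partition chamber populations into planktonic and biofilm compartments
#'
#' Planktonic cells are those carried in the effluent:
#' `C_planktonic = D_planktonic * V_chip`.  Biofilm cells are the remainder
#' of the whole-chamber count: `C_biofilm = C_entire - C_planktonic`.
#' A negative remainder (measurement noise) is clamped to zero with a
#' warning carrying the raw value.
#'
#' @param D_planktonic effluent cell density (cells/uL).
#' @param V_chip chamber volume in uL (default 3.0, the chip design value).
#' @param C_entire total cell number recovered from the whole chamber.
#' @return a list of class `compartment_counts` with `C_planktonic`,
#'   `C_biofilm`, `C_entire`, the raw (pre-clamp) biofilm value and a
#'   `clamped` flag.
#' @examples
#' partition_cells(2e6, 3.0, 1e7)  # 6e6 planktonic, 4e6 biofilm
#' @export
partition_cells <- function(D_planktonic, V_chip = 3.0, C_entire) {
  for (v in c(D_planktonic, V_chip, C_entire))
    if (!is.numeric(v) || any(v < 0) || any(!is.finite(v)))
      stop("inputs must be finite and >= 0")
  C_planktonic <- D_planktonic * V_chip
  raw <- C_entire - C_planktonic
  clamped <- raw < 0
  if (any(clamped))
    warning(sprintf("negative biofilm estimate clamped to 0 (raw: %s)",
                    paste(signif(raw[clamped], 4), collapse = ", ")))
  structure(list(D_planktonic = D_planktonic, V_chip = V_chip,
                 C_planktonic = C_planktonic,
                 C_biofilm = pmax(raw, 0), C_entire = C_entire,
                 C_biofilm_raw = raw, clamped = clamped),
            class = "compartment_counts")
}

#' Fit a logistic growth profile
#'
#' Least-squares fit of `K / (1 + exp(-r * (t - t_mid)))` to a cell-count
#' time series, initialized from the data (`K0` = max count, `t_mid0` =
#' time of half-maximum) and bounded so that `K > 0`.
#'
#' @param t time points (>= 4).
#' @param counts cell counts (> 0), same length.
#' @return a list with `K`, `r`, `t_mid`, `fitted`, `residual_sd`,
#'   `converged` and `flag` (`"ok"`, `"degenerate_constant"`,
#'   `"negative_rate"` or `"non_convergence"`; parameters are `NA` in the
#'   last case).
#' @export
fit_logistic <- function(t, counts) {
  t <- as.numeric(t); counts <- as.numeric(counts)
  if (length(t) != length(counts) || length(t) < 4)
    stop("need >= 4 paired time points")
  if (any(counts <= 0)) stop("counts must be > 0")
  if (sd(counts) < 1e-12 * mean(counts)) {
    return(list(K = mean(counts), r = 0, t_mid = NA_real_,
                fitted = rep(mean(counts), length(t)), residual_sd = 0,
                converged = TRUE, flag = "degenerate_constant"))
  }
  K0 <- max(counts) * 1.05
  t_mid0 <- t[which.min(abs(counts - K0 / 2))]
  # slope sign from the data decides the starting rate
  r0 <- unname(coef(lm(log(counts) ~ t))[2])
  if (abs(r0) < 1e-6) r0 <- 1e-3
  fit <- tryCatch(
    nls(counts ~ K / (1 + exp(-r * (t - t_mid))),
        start = list(K = K0, r = r0, t_mid = t_mid0),
        lower = c(K = .Machine$double.eps, r = -Inf, t_mid = -Inf),
        algorithm = "port",
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(K = NA_real_, r = NA_real_, t_mid = NA_real_, fitted = NULL,
                residual_sd = NA_real_, converged = FALSE,
                flag = "non_convergence"))
  }
  p <- coef(fit)
  list(K = unname(p["K"]), r = unname(p["r"]), t_mid = unname(p["t_mid"]),
       fitted = as.numeric(predict(fit)),
       residual_sd = sqrt(mean(residuals(fit)^2)),
       converged = TRUE,
       flag = if (p["r"] < 0) "negative_rate" else "ok")
}
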