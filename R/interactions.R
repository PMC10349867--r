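#' Classify a pairwise co-culture interaction from biofilm yields
#'
#' Uses the monoculture-derived references: `Y_min = min(Y_a, Y_b)`,
#' `Y_sum = Y_a + Y_b` (`Y_ave` and `Y_max` are reported for completeness
#' but play no role in the rule).  The co-culture yield `Y_co` is called
#' \emph{positive} when `Y_co > Y_sum`, \emph{strong negative} when
#' `Y_co < Y_min`, and \emph{weak negative} on the closed middle band
#' `Y_sum >= Y_co >= Y_min`.  The classification is total and mutually
#' exclusive for all nonnegative yields.
#'
#' @param y_a,y_b monoculture biofilm yields (OD units, >= 0); vectorized.
#' @param y_co co-culture biofilm yield (>= 0); vectorized.
#' @return a data frame of class `interaction_call` with columns `class`
#'   (factor positive/weak_negative/strong_negative), `margin` (distance of
#'   `y_co` from the nearest class boundary), and the derived yields
#'   `y_min`, `y_ave`, `y_max`, `y_sum`.
#' @examples
#' classify_coculture(0.5, 0.6, 1.2)  # positive (1.2 > 1.1)
#' @export
classify_coculture <- function(y_a, y_b, y_co) {
  n <- max(length(y_a), length(y_b), length(y_co))
  y_a <- rep_len(as.numeric(y_a), n)
  y_b <- rep_len(as.numeric(y_b), n)
  y_co <- rep_len(as.numeric(y_co), n)
  if (any(c(y_a, y_b, y_co) < 0)) stop("yields must be >= 0")
  y_min <- pmin(y_a, y_b); y_max <- pmax(y_a, y_b)
  y_sum <- y_a + y_b; y_ave <- y_sum / 2
  class <- ifelse(y_co > y_sum, "positive",
                  ifelse(y_co < y_min, "strong_negative", "weak_negative"))
  out <- data.frame(
    class = factor(class, levels = c("positive", "weak_negative",
                                     "strong_negative")),
    margin = pmin(abs(y_co - y_min), abs(y_co - y_sum)),
    y_min = y_min, y_ave = y_ave, y_max = y_max, y_sum = y_sum)
  class(out) <- c("interaction_call", class(out))
  out
}

#' Classify an interaction from conditioned-medium growth
#'
#' Growth in medium conditioned by a partner (`Y_c`) is compared to growth
#' in unconditioned medium (`Y_u`): \emph{positive} when `Y_c >= Y_u`,
#' \emph{weak negative} when `1 > Y_c/Y_u >= 0.5`, \emph{strong negative}
#' when `Y_c/Y_u < 0.5`.  A zero `Y_u` makes the ratio undefined and yields
#' an explicit `NA` call.
#'
#' @param y_c growth in conditioned medium (>= 0); vectorized.
#' @param y_u growth in unconditioned medium (>= 0); vectorized.
#' @return a data frame of class `interaction_call` with `class`, `ratio`
#'   and `margin` (distance of the ratio from the nearest boundary in
#'   `{0.5, 1}`).
#' @export
classify_conditioned <- function(y_c, y_u) {
  n <- max(length(y_c), length(y_u))
  y_c <- rep_len(as.numeric(y_c), n)
  y_u <- rep_len(as.numeric(y_u), n)
  if (any(c(y_c, y_u) < 0)) stop("growth yields must be >= 0")
  ratio <- ifelse(y_u > 0, y_c / y_u, NA_real_)
  class <- ifelse(is.na(ratio), NA_character_,
                  ifelse(ratio >= 1, "positive",
                         ifelse(ratio >= 0.5, "weak_negative",
                                "strong_negative")))
  if (any(is.na(class)))
    warning("y_u = 0: undefined ratio, null interaction call")
  out <- data.frame(
    class = factor(class, levels = c("positive", "weak_negative",
                                     "strong_negative")),
    ratio = ratio,
    margin = pmin(abs(ratio - 0.5), abs(ratio - 1)))
  class(out) <- c("interaction_call", class(out))
  out
}

#' Genotype frequencies per compartment with a median test against 0.5
#'
#' For each replicate and compartment (e.g. plankton, biofilm, total,
#' inoculum), the frequency of the focal genotype is its count divided by
#' the compartment total.  Per compartment, frequencies are summarized by
#' their median and tested against 0.5 with a two-sided Wilcoxon
#' signed-rank test (exact null for n <= 25 when there are no ties;
#' normal approximation otherwise).  If an inoculum compartment is present,
#' the per-replicate frequency change relative to the inoculum is reported.
#'
#' @param counts data frame with columns `replicate`, `genotype`,
#'   `compartment`, `count` (counts >= 0).
#' @param focal name of the focal genotype.
#' @return a list with `frequencies` (replicate x compartment data frame)
#'   and `tests` (per-compartment median, n, p-value and flag).
#' @export
frequency_metrics <- function(counts, focal) {
  need <- c("replicate", "genotype", "compartment", "count")
  if (!all(need %in% names(counts)))
    stop("counts needs columns replicate, genotype, compartment, count")
  if (any(counts$count < 0)) stop("counts must be >= 0")
  if (!focal %in% counts$genotype) stop("focal genotype not present")
  agg <- split(counts, list(counts$replicate, counts$compartment),
               drop = TRUE, sep = "\r")
  freq <- do.call(rbind, lapply(agg, function(d) {
    tot <- sum(d$count)
    data.frame(replicate = d$replicate[1], compartment = d$compartment[1],
               frequency = if (tot > 0) sum(d$count[d$genotype == focal]) / tot
                           else NA_real_)
  }))
  rownames(freq) <- NULL
  if ("inoculum" %in% freq$compartment) {
    ino <- freq[freq$compartment == "inoculum", c("replicate", "frequency")]
    names(ino)[2] <- "inoculum_frequency"
    freq <- merge(freq, ino, by = "replicate", all.x = TRUE)
    freq$change_vs_inoculum <- freq$frequency - freq$inoculum_frequency
  }
  tests <- do.call(rbind, lapply(split(freq, freq$compartment), function(d) {
    f <- d$frequency[!is.na(d$frequency)]
    diffs <- f - 0.5
    if (length(f) == 0 || all(diffs == 0)) {
      p <- 1; flag <- "degenerate"
    } else {
      exact <- length(f) <= 25 && !any(diffs == 0) &&
        !any(duplicated(abs(diffs[diffs != 0])))
      p <- suppressWarnings(
        wilcox.test(f, mu = 0.5, exact = exact)$p.value)
      flag <- "ok"
    }
    data.frame(compartment = d$compartment[1], n = length(f),
               median_frequency = median(f), p_value = p, flag = flag)
  }))
  rownames(tests) <- NULL
  list(frequencies = freq, tests = tests)
}
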