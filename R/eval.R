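#' Rate (risk) ratio of two binomial proportions
#'
#' Estimates `(a/N1) / (b/N2)` — e.g. the proportion of pathogenic variants
#' falling in a score bin over the proportion of benign variants in that bin
#' — with a Katz log-normal confidence interval and a two-sided normal
#' p-value on the log scale. Zero numerators get a 0.5 continuity correction
#' on all four counts (noted in the `method` field).
#'
#' @param a,N1 Count in bin and total for group 1.
#' @param b,N2 Count in bin and total for group 2.
#' @param ci_level Confidence level (default 0.95).
#' @return An `hmc_rate_comparison` one-row tibble with `estimate`, `ci_low`,
#'   `ci_high`, `p_value` and the counts.
#' @export
rate_ratio <- function(a, N1, b, N2, ci_level = 0.95) {
  if (N1 <= 0 || N2 <= 0) abort_data("group totals must be positive")
  if (a > N1 || b > N2 || a < 0 || b < 0) abort_data("counts out of range")
  corrected <- (a == 0 || b == 0)
  cc <- if (corrected) 0.5 else 0
  aa <- a + cc; bb <- b + cc; n1 <- N1 + cc; n2 <- N2 + cc
  est <- (a / N1) / (b / N2)
  log_est <- log((aa / n1) / (bb / n2))
  se <- sqrt(1 / aa - 1 / n1 + 1 / bb - 1 / n2)
  z <- qnorm(1 - (1 - ci_level) / 2)
  p <- 2 * pnorm(-abs(log_est / se))
  if (corrected) inform("zero cell in rate_ratio; 0.5 continuity correction")
  new_rate_comparison(
    estimate = est, ci_low = exp(log_est - z * se),
    ci_high = exp(log_est + z * se), p_value = p,
    a = a, N1 = N1, b = b, N2 = N2,
    method = if (corrected) "katz+cc" else "katz")
}

new_rate_comparison <- function(estimate, ci_low, ci_high, p_value,
                                a, N1, b, N2, method) {
  structure(
    tibble(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
           p_value = p_value, a = a, N1 = N1, b = b, N2 = N2,
           method = method),
    class = c("hmc_rate_comparison", class(tibble())))
}

#' @export
#' @importFrom generics tidy
tidy.hmc_rate_comparison <- function(x, ...) {
  class(x) <- class(tibble())
  x
}

#' De novo mutation burden (observed over expected)
#'
#' Burden of DNMs against the context-model expectation, `obs/exp`, with the
#' Garwood exact Poisson confidence interval
#' (`[qgamma(l, obs), qgamma(u, obs + 1)] / exp`; lower bound 0 at
#' `obs = 0`) and a one-sided Poisson p-value for enrichment.
#'
#' @param observed Observed DNM count.
#' @param expected Expected DNM count (> 0).
#' @param ci_level Confidence level (default 0.95).
#' @return An `hmc_rate_comparison`.
#' @export
dnm_burden <- function(observed, expected, ci_level = 0.95) {
  if (expected <= 0) abort_data("expected must be positive")
  if (observed < 0) abort_data("observed must be non-negative")
  tail <- (1 - ci_level) / 2
  lo <- if (observed == 0) 0 else qgamma(tail, shape = observed) / expected
  hi <- qgamma(1 - tail, shape = observed + 1) / expected
  p <- ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  new_rate_comparison(estimate = observed / expected, ci_low = lo,
                      ci_high = hi, p_value = p,
                      a = observed, N1 = NA_real_, b = NA_real_,
                      N2 = NA_real_, method = "garwood")
}

#' Odds ratio from a 2x2 carrier table
#'
#' `OR = (a * d) / (b * c)` for case carriers `a`, case non-carriers `b`,
#' control carriers `c`, control non-carriers `d`, with Woolf (log-normal)
#' confidence interval; any zero cell triggers the Haldane–Anscombe 0.5
#' correction on all cells.
#'
#' @param case_carriers,case_noncarriers,control_carriers,control_noncarriers
#'   Non-negative counts; both row totals must be positive.
#' @param ci_level Confidence level.
#' @return An `hmc_rate_comparison`.
#' @export
odds_ratio_2x2 <- function(case_carriers, case_noncarriers,
                           control_carriers, control_noncarriers,
                           ci_level = 0.95) {
  cells <- c(case_carriers, case_noncarriers, control_carriers,
             control_noncarriers)
  if (any(cells < 0)) abort_data("counts must be non-negative")
  if (case_carriers + case_noncarriers == 0 ||
      control_carriers + control_noncarriers == 0) {
    abort_data("a whole row of the 2x2 table is zero")
  }
  corrected <- any(cells == 0)
  cc <- if (corrected) 0.5 else 0
  a <- case_carriers + cc; b <- case_noncarriers + cc
  c_ <- control_carriers + cc; d <- control_noncarriers + cc
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- qnorm(1 - (1 - ci_level) / 2)
  p <- 2 * pnorm(-abs(log(or) / se))
  new_rate_comparison(estimate = or, ci_low = exp(log(or) - z * se),
                      ci_high = exp(log(or) + z * se), p_value = p,
                      a = case_carriers, N1 = case_carriers + case_noncarriers,
                      b = control_carriers,
                      N2 = control_carriers + control_noncarriers,
                      method = if (corrected) "woolf+haldane" else "woolf")
}

#' Precision-sensitivity curve for a variant score
#'
#' Sweeps thresholds over the distinct score values, grouping ties
#' (all-or-none at a threshold), and reports precision and sensitivity at
#' each, plus the trapezoidal area under the curve. With
#' `direction = "lower_is_deleterious"` (the constraint-score convention) a
#' variant is called deleterious when `score < t` for the strict named
#' thresholds used by [pr_at_threshold()], while the curve itself is swept
#' inclusively at each achieved score value. The curve is invariant under
#' strictly monotone transforms of the score.
#'
#' @param data Tibble with score and label columns.
#' @param score,label Column names (tidy-eval) of the numeric score and the
#'   binary label (1/TRUE = positive/pathogenic).
#' @param direction `"lower_is_deleterious"` or `"higher_is_deleterious"`.
#' @return An `hmc_pr_curve`: list with `curve` (threshold, tp, fp, fn,
#'   precision, sensitivity), `auc`, `direction` and the raw data.
#' @export
precision_sensitivity <- function(data, score, label,
                                  direction = c("lower_is_deleterious",
                                                "higher_is_deleterious")) {
  direction <- match.arg(direction)
  s <- dplyr::pull(data, {{ score }})
  y <- as.integer(as.logical(dplyr::pull(data, {{ label }})))
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]; y <- y[keep]
  if (length(unique(y)) < 2) {
    abort_data("precision-sensitivity curve needs both label classes")
  }
  sgn <- if (direction == "lower_is_deleterious") 1 else -1
  ord <- order(sgn * s)
  s_o <- s[ord]; y_o <- y[ord]
  n_pos <- sum(y)
  grp <- !duplicated(s_o, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(y_o)[grp]
  np <- seq_along(s_o)[grp]
  curve <- tibble(threshold = s_o[grp], tp = tp, fp = np - tp,
                  fn = n_pos - tp,
                  precision = tp / np, sensitivity = tp / n_pos)
  auc <- trapezoid_area(c(0, curve$sensitivity),
                        c(curve$precision[1], curve$precision))
  structure(list(curve = curve, auc = auc, direction = direction,
                 scores = s, labels = y),
            class = "hmc_pr_curve")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.hmc_pr_curve <- function(x, ...) {
  cat(sprintf("<hmc_pr_curve> %d thresholds, AUC = %.3f (%s)\n",
              nrow(x$curve), x$auc, x$direction))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.hmc_pr_curve <- function(x, ...) x$curve

#' @export
#' @importFrom generics glance
glance.hmc_pr_curve <- function(x, ...) {
  tibble(auc = x$auc, n = length(x$labels), n_pos = sum(x$labels),
         direction = x$direction)
}

#' Precision and sensitivity at a named threshold
#'
#' Uses the strict comparison conventions of the score (`score < t` deems a
#' variant deleterious when lower scores are deleterious, `score > t`
#' otherwise).
#'
#' @param pr An `hmc_pr_curve`.
#' @param threshold Score threshold.
#' @return One-row tibble `threshold`, `precision`, `sensitivity`, `n_called`.
#' @export
pr_at_threshold <- function(pr, threshold) {
  stopifnot(inherits(pr, "hmc_pr_curve"))
  called <- if (pr$direction == "lower_is_deleterious") {
    pr$scores < threshold
  } else {
    pr$scores > threshold
  }
  tp <- sum(pr$labels == 1 & called)
  tibble(threshold = threshold,
         precision = if (sum(called) > 0) tp / sum(called) else NA_real_,
         sensitivity = tp / sum(pr$labels == 1),
         n_called = sum(called))
}

#' Per-bin risk-ratio report for labeled variants
#'
#' Joins a labeled variant set (e.g. pathogenic/benign) onto the score table
#' by allele key, assigns score bins, and computes one [rate_ratio()]
#' (positive-label rate in bin vs negative-label rate in bin) per bin.
#' Variants without a powered score form their own `unassessable` stratum.
#' With `cumulative = TRUE`, bins are the nested thresholds `score < edge`
#' (plus a final `>= last edge` stratum) instead of disjoint intervals.
#'
#' @param scores Score table from [score_variants()].
#' @param labeled Tibble with `chrom`, `pos`, `ref`, `alt`, `label`
#'   (1/TRUE = positive class).
#' @param bins Interior bin edges on the score (default
#'   `c(0.5, 0.6, 0.8, 1)`).
#' @param cumulative Use nested `score < edge` bins.
#' @param ci_level Confidence level for the per-bin interval.
#' @return Tibble with one row per bin: `bin`, counts `a`, `N1`, `b`, `N2`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value` (NA rows where a group has
#'   no assessed variants in the bin denominator).
#' @export
bin_report <- function(scores, labeled, bins = c(0.5, 0.6, 0.8, 1),
                       cumulative = FALSE, ci_level = 0.95) {
  joined <- labeled |>
    mutate(label = as.integer(as.logical(.data$label))) |>
    left_join(scores |>
                distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                         .keep_all = TRUE) |>
                select("chrom", "pos", "ref", "alt", "hmc", "class"),
              by = c("chrom", "pos", "ref", "alt"))
  if (all(is.na(joined$hmc))) {
    warn("bin_report: no labeled variant matched a scored variant")
  }
  N1 <- sum(joined$label == 1)
  N2 <- sum(joined$label == 0)
  if (cumulative) {
    strata <- c(sprintf("<%g", bins), sprintf(">=%g", bins[length(bins)]),
                "unassessable")
    member <- function(stratum, hmc) {
      if (stratum == "unassessable") return(is.na(hmc))
      if (startsWith(stratum, "<")) {
        !is.na(hmc) & hmc < as.numeric(sub("<", "", stratum))
      } else {
        !is.na(hmc) & hmc >= as.numeric(sub(">=", "", stratum))
      }
    }
  } else {
    edges <- c(0, bins, Inf)
    labs <- levels(cut(numeric(0), edges, right = FALSE))
    strata <- c(labs, "unassessable")
    binned <- as.character(cut(joined$hmc, edges, right = FALSE))
    member <- function(stratum, hmc) {
      if (stratum == "unassessable") return(is.na(hmc))
      !is.na(hmc) & binned == stratum
    }
  }
  purrr::map_dfr(strata, function(st) {
    inb <- member(st, joined$hmc)
    a <- sum(inb & joined$label == 1)
    b <- sum(inb & joined$label == 0)
    if (N1 == 0 || N2 == 0 || (a == 0 && b == 0)) {
      return(tibble(bin = st, a = a, N1 = N1, b = b, N2 = N2,
                    estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_))
    }
    rr <- suppressMessages(rate_ratio(a, N1, b, N2, ci_level = ci_level))
    tibble(bin = st, a = a, N1 = N1, b = b, N2 = N2,
           estimate = rr$estimate, ci_low = rr$ci_low,
           ci_high = rr$ci_high, p_value = rr$p_value)
  })
}
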