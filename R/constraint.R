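#' Homologous missense constraint score
#'
#' With `observed ~ Poisson(lambda * expected)` and a flat (improper uniform)
#' prior on the rate ratio `lambda`, the posterior of `lambda` is
#' `Gamma(shape = observed + 1, rate = expected)`. The constraint score is
#' the upper bound of the equal-tailed 90% credible interval, i.e. the 0.95
#' posterior quantile. A score below 1 is equivalent to one-sided posterior
#' evidence of depletion, `P(lambda >= 1) < 0.05`; at `observed = 0` the
#' posterior is exponential and the score has the closed form
#' `-log(1 - quantile) / expected`.
#'
#' @param observed Non-negative integer count(s) of distinct rare missense
#'   variants.
#' @param expected Positive expected count(s).
#' @param quantile Posterior quantile reported (default 0.95, the upper bound
#'   of the 90% equal-tailed interval).
#' @return Numeric score(s); deterministic.
#' @export
hmc_score <- function(observed, expected, quantile = 0.95) {
  if (any(expected <= 0)) abort_data("expected must be positive")
  if (any(observed < 0)) abort_data("observed must be non-negative")
  qgamma(quantile, shape = observed + 1, rate = expected)
}

#' One-sided depletion significance of a score
#'
#' By construction of [hmc_score()], `score < 1` is exactly equivalent to
#' posterior `P(lambda >= 1) < alpha` at a powered position; the boundary
#' `score == 1` is not significant.
#'
#' @param hmc Score value(s).
#' @return Logical: significant depletion.
#' @export
significant_depletion <- function(hmc) {
  hmc < 1
}

#' Power (assessability) filter
#'
#' A meta-position is powered iff a complete depletion (`observed = 0`) could
#' still be called constrained, i.e. `hmc_score(0, expected) < 1`, which is
#' `expected > -log(alpha)` (about 2.996 at alpha = 0.05). Positions failing
#' this can never show significant depletion regardless of the data.
#'
#' @param expected Expected count(s), >= 0.
#' @param alpha Significance level.
#' @return Logical vector.
#' @export
power_filter <- function(expected, alpha = 0.05) {
  expected > -log(alpha)
}

#' Classify constraint from score and power
#'
#' Bins are half-open on score with strict upper comparisons: the default
#' `[0, 0.5), [0.5, 0.6), [0.6, 0.8), [0.8, 1.0), [1.0, Inf)`. Classes:
#' `highly_constrained` (powered, score < 0.8), `constrained` (powered,
#' 0.8 <= score < 1), `unconstrained` (powered, score >= 1), `unassessable`
#' (not powered).
#'
#' @param hmc Score value(s).
#' @param powered Logical from [power_filter()].
#' @param bins Increasing interior bin edges (default `c(0.5, 0.6, 0.8, 1)`).
#' @return Tibble with `class` and `bin` (factor of interval labels,
#'   `NA` when unassessable).
#' @export
classify_constraint <- function(hmc, powered, bins = c(0.5, 0.6, 0.8, 1)) {
  if (is.unsorted(bins, strictly = TRUE)) {
    abort_config("bins must be strictly increasing")
  }
  edges <- c(0, bins, Inf)
  bin <- cut(hmc, breaks = edges, right = FALSE)
  cls <- dplyr::case_when(
    !powered ~ "unassessable",
    hmc < 0.8 ~ "highly_constrained",
    hmc < 1 ~ "constrained",
    TRUE ~ "unconstrained")
  tibble(class = cls, bin = ifelse(powered, as.character(bin), NA_character_))
}

#' Aggregate constraint per meta-position
#'
#' Groups annotated missense candidates by meta-position and computes the
#' per-position record: `observed` (distinct rare missense alleles seen at
#' any homologous residue), `expected` (summed per-variant expectation over
#' all assessable missense candidates), the point estimate `mle = obs/exp`,
#' the [hmc_score()], the power flag, and the constraint class. Common
#' variants were already excluded from both sides by the rarity filter.
#' Positions with candidates but zero total expectation are unassessable.
#'
#' @param variants Annotated variant tibble (after [join_meta_positions()],
#'   [apply_rarity_filter()], [annotate_mutability()], [expected_counts()]).
#' @param alpha Significance level for the power filter.
#' @param quantile Posterior quantile for the score.
#' @param bins Bin edges for [classify_constraint()].
#' @param min_copies Minimum number of domain copies for a position to be
#'   assessable (default 2; a single-copy "family" aggregates nothing).
#' @return An `hmc_constraint` tibble: one row per (family_id, column) with
#'   `observed`, `expected`, `n_copies`, `mle`, `hmc`, `powered`, `class`,
#'   `bin`.
#' @export
aggregate_constraint <- function(variants, alpha = 0.05, quantile = 0.95,
                                 bins = c(0.5, 0.6, 0.8, 1), min_copies = 2) {
  stopifnot(alpha > 0, alpha < 1, quantile > 0, quantile < 1)
  cand <- variants |>
    filter(!is.na(.data$family_id), .data$consequence == "missense")
  rec <- cand |>
    group_by(.data$family_id, .data$column) |>
    summarise(
      observed = n_distinct(variant_key(.data$chrom, .data$pos, .data$ref,
                                        .data$alt)[.data$observed_rare &
                                                     .data$assessable]),
      expected = sum(.data$expected[.data$assessable]),
      n_copies = first(.data$n_copies),
      .groups = "drop") |>
    arrange(.data$family_id, .data$column)
  rec <- rec |>
    mutate(
      powered = power_filter(.data$expected, alpha) &
        .data$n_copies >= min_copies,
      mle = ifelse(.data$expected > 0, .data$observed / .data$expected, NA),
      hmc = ifelse(.data$expected > 0,
                   qgamma(quantile, shape = .data$observed + 1,
                          rate = pmax(.data$expected, .Machine$double.xmin)),
                   NA))
  cls <- classify_constraint(rec$hmc, rec$powered, bins)
  rec$class <- ifelse(is.na(rec$hmc), "unassessable", cls$class)
  rec$bin <- cls$bin
  structure(rec,
            class = c("hmc_constraint", class(tibble())),
            alpha = alpha, quantile = quantile, bins = bins,
            min_copies = min_copies)
}

#' @export
print.hmc_constraint <- function(x, ...) {
  cat(sprintf(
    "<hmc_constraint> %d meta-positions (%d powered, %d scored < 1)\n",
    nrow(x), sum(x$powered), sum(x$powered & x$hmc < 1, na.rm = TRUE)))
  NextMethod()
}

#' Tidy a constraint table
#'
#' @param x An `hmc_constraint`.
#' @param ... Unused.
#' @return A plain tibble of per-meta-position records.
#' @export
#' @importFrom generics tidy
tidy.hmc_constraint <- function(x, ...) {
  as_tibble(unclass2(x))
}

unclass2 <- function(x) {
  attr(x, "alpha") <- NULL; attr(x, "quantile") <- NULL
  attr(x, "bins") <- NULL; attr(x, "min_copies") <- NULL
  class(x) <- class(tibble())
  x
}

#' One-row summary of a constraint analysis
#'
#' @param x An `hmc_constraint`.
#' @param ... Unused.
#' @return Tibble with position counts and the fractions called constrained
#'   and highly constrained among powered positions.
#' @export
#' @importFrom generics glance
glance.hmc_constraint <- function(x, ...) {
  pw <- x$powered
  tibble(
    n_positions = nrow(x),
    n_powered = sum(pw),
    frac_constrained = mean(x$hmc[pw] < 1, na.rm = TRUE),
    frac_highly_constrained = mean(x$hmc[pw] < 0.8, na.rm = TRUE),
    median_mle = median(x$mle[pw], na.rm = TRUE),
    alpha = attr(x, "alpha"), quantile = attr(x, "quantile"))
}

#' Score every possible missense variant
#'
#' Propagates each meta-position's record onto all possible missense SNVs at
#' its residues: variants at one meta-position share one score. Variants at
#' unpowered positions are kept with class `unassessable` and `NA` score;
#' variants outside domains are dropped.
#'
#' @param records An `hmc_constraint` from [aggregate_constraint()].
#' @param variants Annotated variant tibble.
#' @return Score-table tibble: `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `transcript_id`, `family_id`, `column`, `observed`, `expected`, `mle`,
#'   `hmc`, `class`.
#' @export
score_variants <- function(records, variants) {
  rec <- tidy(records) |>
    select("family_id", "column", "observed", "expected", "mle", "hmc",
           "powered", "class")
  variants |>
    filter(.data$consequence == "missense", !is.na(.data$family_id)) |>
    select("chrom", "pos", "ref", "alt", "gene_id", "transcript_id",
           "family_id", "column") |>
    inner_join(rec, by = c("family_id", "column")) |>
    mutate(mle = ifelse(.data$powered, .data$mle, NA_real_),
           hmc = ifelse(.data$powered, .data$hmc, NA_real_),
           class = ifelse(.data$powered, .data$class, "unassessable")) |>
    select("chrom", "pos", "ref", "alt", "gene_id", "transcript_id",
           "family_id", "column", "observed", "expected", "mle", "hmc",
           "class")
}

#' Per-gene fraction of assessable missense variants
#'
#' @param possible Possible-variant tibble (all transcripts).
#' @param scores Score table from [score_variants()].
#' @return Tibble `gene_id`, `n_missense`, `n_assessable`,
#'   `frac_assessable`: the share of a gene's possible missense SNVs that
#'   received a powered score.
#' @export
gene_assessable_fraction <- function(possible, scores) {
  tot <- possible |>
    filter(.data$consequence == "missense") |>
    count(.data$gene_id, name = "n_missense")
  ok <- scores |>
    filter(.data$class != "unassessable") |>
    count(.data$gene_id, name = "n_assessable")
  tot |>
    left_join(ok, by = "gene_id") |>
    mutate(n_assessable = dplyr::coalesce(.data$n_assessable, 0L),
           frac_assessable = .data$n_assessable / .data$n_missense)
}
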