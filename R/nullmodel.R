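#' Load a trinucleotide mutation-rate table
#'
#' The rate table is the null mutability model: a relative rate `mu` for every
#' (coding-strand trinucleotide context, alternate base) pair, stratified by
#' CpG methylation level (0 = unmethylated / non-CpG, 1 = intermediate,
#' 2 = high). All 192 (context, alt) pairs must be present at level 0; CpG
#' contexts (middle base C followed by G) may additionally carry rows for
#' levels 1 and 2 — missing methylation rows fall back to the level-0 rate
#' with a warning at lookup time. Rates are relative: any global rescaling is
#' absorbed by [calibrate_expected()].
#'
#' @param x Path to a TSV with columns `context`, `alt`, `methyl_level`,
#'   `mu`, or a data frame with those columns.
#' @return Validated rate-table tibble.
#' @export
load_rate_table <- function(x) {
  tab <- if (is.data.frame(x)) as_tibble(x) else {
    if (!file.exists(x)) abort_data(paste0("no such file: ", x))
    readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  }
  missing_cols <- setdiff(c("context", "alt", "methyl_level", "mu"),
                          names(tab))
  if (length(missing_cols) > 0) {
    abort_data(paste0("rate table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(tab$mu) | tab$mu <= 0)) {
    abort_data("rate table contains non-positive or non-finite mu")
  }
  tab$methyl_level <- as.integer(tab$methyl_level)
  tab$mu <- as.numeric(tab$mu)
  full <- all_context_alt_pairs()
  have <- paste(tab$context[tab$methyl_level == 0],
                tab$alt[tab$methyl_level == 0])
  gaps <- setdiff(paste(full$context, full$alt), have)
  if (length(gaps) > 0) {
    abort_data(paste0("rate table incomplete at methyl_level 0; missing: ",
                      paste(head(gsub(" ", ">", gaps), 5), collapse = ", "),
                      if (length(gaps) > 5) sprintf(" (+%d more)",
                                                    length(gaps) - 5) else ""))
  }
  if (anyDuplicated(tab[c("context", "alt", "methyl_level")])) {
    abort_data("rate table has duplicated (context, alt, methyl_level) rows")
  }
  tab
}

all_context_alt_pairs <- function() {
  ctx <- do.call(paste0, expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                                     stringsAsFactors = FALSE)[, c(1, 2, 3)])
  mid <- substr(ctx, 2, 2)
  out <- tidyr::expand_grid(context = ctx, alt = DNA_BASES)
  out[substr(out$context, 2, 2) != out$alt, ]
}

#' Sequencing-coverage correction model
#'
#' A piecewise, non-decreasing correction factor `c(depth)` in [0, 1] applied
#' multiplicatively to mutability: sites sequenced deeply enough need no
#' correction (`c = 1` at depth >= `high_cov_cutoff`), sites below
#' `min_cov_cutoff` are unassessable (`c = 0`), and depths in between follow
#' a user-supplied table (columns `depth`, `factor`) or, by default, a linear
#' ramp.
#'
#' @param high_cov_cutoff Depth at and above which no correction applies.
#' @param min_cov_cutoff Depth below which sites are excluded.
#' @param table Optional tibble (`depth`, `factor`) for intermediate depths;
#'   factors must be non-decreasing in depth and within [0, 1].
#' @return An `hmc_coverage_model` object; call it on depths via
#'   [coverage_factor()].
#' @export
coverage_model <- function(high_cov_cutoff = 30, min_cov_cutoff = 10,
                           table = NULL) {
  if (min_cov_cutoff > high_cov_cutoff) {
    abort_config("min_cov_cutoff must be <= high_cov_cutoff")
  }
  if (!is.null(table)) {
    table <- as_tibble(table)[order(table$depth), ]
    if (any(table$factor < 0 | table$factor > 1) ||
        is.unsorted(table$factor)) {
      abort_config("coverage table factors must be non-decreasing in [0, 1]")
    }
  }
  structure(list(high = high_cov_cutoff, min = min_cov_cutoff, table = table),
            class = "hmc_coverage_model")
}

#' Evaluate a coverage model at given depths
#'
#' @param model An [coverage_model()] object.
#' @param depth Numeric vector of median sequencing depths; `NA` means the
#'   site has no coverage record and gets factor 0.
#' @return Correction factors in [0, 1].
#' @export
coverage_factor <- function(model, depth) {
  stopifnot(inherits(model, "hmc_coverage_model"))
  depth <- ifelse(is.na(depth), -Inf, depth)
  out <- numeric(length(depth))
  out[depth >= model$high] <- 1
  mid <- depth >= model$min & depth < model$high
  if (any(mid)) {
    if (!is.null(model$table)) {
      f <- stats::approxfun(c(model$min - 1, model$table$depth, model$high),
                            c(0, model$table$factor, 1),
                            method = "constant", rule = 2)
      out[mid] <- f(depth[mid])
    } else if (model$high == model$min) {
      out[mid] <- 1
    } else {
      out[mid] <- (depth[mid] - model$min) / (model$high - model$min)
    }
  }
  out
}

#' Annotate per-variant adjusted mutability
#'
#' Looks up `mu(context, alt, methyl_level)` and multiplies by the coverage
#' factor: `mu_adj = mu * c(depth)`. Methylation levels apply only at CpG
#' contexts (middle C followed by G on the coding strand); other sites are
#' level 0. CpG sites whose (context, alt, level) row is missing fall back to
#' the level-0 rate with one warning. Variants with `'N'` in context or a
#' zero coverage factor become unassessable rather than erroring.
#'
#' @param variants Possible-variant tibble (needs `context`, `alt_coding`,
#'   and positional columns if `coverage`/`methylation` are supplied).
#' @param rate_table From [load_rate_table()].
#' @param coverage Optional BED-like tibble or TSV path with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `median_depth`. `NULL` means all
#'   sites are taken as fully covered.
#' @param methylation Optional tibble or TSV path with `chrom`, `pos`,
#'   `level` for methylated CpG sites; unlisted CpG sites are level 0.
#' @param cov_model An [coverage_model()].
#' @return `variants` with `methyl_level`, `depth`, `cov_factor`, `mu`,
#'   `mu_adj` columns; `assessable` updated.
#' @export
annotate_mutability <- function(variants, rate_table, coverage = NULL,
                                methylation = NULL,
                                cov_model = coverage_model()) {
  rate_table <- load_rate_table(rate_table)
  is_cpg <- substr(variants$context, 2, 3) == "CG"
  methyl_level <- integer(nrow(variants))
  if (!is.null(methylation)) {
    if (!is.data.frame(methylation)) {
      methylation <- readr::read_tsv(methylation, show_col_types = FALSE,
                                     progress = FALSE)
    }
    m <- match(variant_site_key(variants$chrom, variants$pos),
               variant_site_key(methylation$chrom, methylation$pos))
    lvl <- methylation$level[m]
    methyl_level <- ifelse(is_cpg & !is.na(lvl), lvl, 0L)
  }
  if (is.null(coverage)) {
    depth <- rep(Inf, nrow(variants))
  } else {
    if (!is.data.frame(coverage)) {
      coverage <- readr::read_tsv(coverage, show_col_types = FALSE,
                                  progress = FALSE)
    }
    depth <- lookup_depth(variants$chrom, variants$pos, coverage)
  }
  cov_factor <- coverage_factor(cov_model, depth)

  key <- paste(variants$context, variants$alt_coding, methyl_level)
  tab_key <- paste(rate_table$context, rate_table$alt,
                   rate_table$methyl_level)
  mu <- rate_table$mu[match(key, tab_key)]
  fallback <- is.na(mu) & methyl_level > 0
  if (any(fallback)) {
    warn(sprintf(
      "%d CpG variant(s) lack methylation-stratified rates; using level 0",
      sum(fallback)))
    key0 <- paste(variants$context[fallback], variants$alt_coding[fallback], 0L)
    mu[fallback] <- rate_table$mu[match(key0, tab_key)]
  }
  variants |>
    mutate(methyl_level = as.integer(methyl_level), depth = depth,
           cov_factor = cov_factor, mu = mu,
           mu_adj = .data$mu * .data$cov_factor,
           assessable = .data$assessable & !is.na(.data$mu) &
             .data$cov_factor > 0)
}

variant_site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# interval lookup of median depth; BED convention (0-based half-open)
lookup_depth <- function(chrom, pos, coverage) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    cov_ch <- coverage[coverage$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (nrow(cov_ch) == 0) next
    cov_ch <- cov_ch[order(cov_ch$start), , drop = FALSE]
    i <- findInterval(pos[sel] - 1L, cov_ch$start)
    hit <- i > 0 & (pos[sel] - 1L) < cov_ch$end[pmax(i, 1L)]
    out[sel][hit] <- cov_ch$median_depth[i[hit]]
  }
  out
}

#' Calibrate expected counts on synonymous variation
#'
#' Synonymous variants are taken as neutral, so the global scaling factor `k`
#' that converts relative mutability into an expected count of rare variants
#' is chosen to make the two agree exactly:
#' `k = (# synonymous candidates observed as rare) / (sum of mu_adj over all
#' assessable synonymous candidates)`. The per-variant expectation is then
#' `expected = k * mu_adj`, which conserves the synonymous total by
#' construction and is invariant to a global rescaling of the rate table.
#'
#' @param variants Variant tibble carrying `consequence`, `assessable`,
#'   `observed_rare` and `mu_adj` (from [annotate_mutability()] +
#'   [apply_rarity_filter()]).
#' @return An `hmc_calibration` object with `k`, `n_syn_observed`,
#'   `sum_mu_syn`.
#' @export
calibrate_expected <- function(variants) {
  syn <- variants |>
    filter(.data$consequence == "synonymous", .data$assessable)
  if (nrow(syn) == 0) abort_data("no assessable synonymous candidates")
  n_obs <- sum(syn$observed_rare)
  s_mu <- sum(syn$mu_adj)
  if (s_mu <= 0) abort_data("total synonymous mutability is zero")
  structure(list(k = n_obs / s_mu, n_syn_observed = n_obs, sum_mu_syn = s_mu),
            class = "hmc_calibration")
}

#' @export
print.hmc_calibration <- function(x, ...) {
  cat(sprintf(
    "<hmc_calibration> k = %.4g (%d rare synonymous / sum mu %.4g)\n",
    x$k, x$n_syn_observed, x$sum_mu_syn))
  invisible(x)
}

#' Attach per-variant expected counts
#'
#' @param variants Variant tibble with `mu_adj`.
#' @param calibration From [calibrate_expected()].
#' @return `variants` with an `expected` column (`k * mu_adj`; 0 where
#'   unassessable).
#' @export
expected_counts <- function(variants, calibration) {
  stopifnot(inherits(calibration, "hmc_calibration"))
  variants |>
    mutate(expected = ifelse(.data$assessable,
                             calibration$k * .data$mu_adj, 0))
}
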