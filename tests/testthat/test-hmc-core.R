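test_that("score has the exponential closed form at zero observed", {
  e <- c(0.5, 1, 2.9957, 10, 50)
  expect_equal(hmc_score(0, e), -log(0.05) / e, tolerance = 1e-12)
  expect_equal(hmc_score(0, -log(0.05)), 1, tolerance = 1e-12)
  expect_error(hmc_score(1, 0), "positive")
  expect_error(hmc_score(-1, 1), "non-negative")
})

test_that("score matches a Monte-Carlo posterior quantile", {
  set.seed(5)
  draws <- rgamma(1e7, shape = 5 + 1, rate = 10)
  expect_equal(hmc_score(5, 10),
               unname(quantile(draws, 0.95)), tolerance = 1e-3)
})

test_that("score exceeds the MLE and is monotone in its arguments", {
  grid <- tidyr::expand_grid(o = c(0L, 1L, 3L, 10L, 50L),
                             e = c(0.1, 1, 5, 20, 100))
  s <- hmc_score(grid$o, grid$e)
  expect_true(all(s > grid$o / grid$e))
  # non-increasing in expected at fixed observed
  for (o in unique(grid$o)) {
    expect_true(all(diff(hmc_score(o, sort(unique(grid$e)))) < 0))
  }
  # non-decreasing in observed at fixed expected
  for (e in unique(grid$e)) {
    expect_true(all(diff(hmc_score(sort(unique(grid$o)), e)) > 0))
  }
})

test_that("score < 1 is exactly the one-sided posterior depletion call", {
  expect_true(significant_depletion(0.99))
  expect_false(significant_depletion(1.0))
  # O = 0, E = 3.1 > -ln(0.05): significant
  expect_true(significant_depletion(hmc_score(0, 3.1)))
  # agreement with the posterior tail probability on a grid
  grid <- tidyr::expand_grid(o = 0:20, e = c(2, 3, 5, 10, 20))
  p_ge_1 <- 1 - pgamma(1, shape = grid$o + 1, rate = grid$e)
  expect_equal(hmc_score(grid$o, grid$e) < 1, p_ge_1 < 0.05)
})

test_that("power filter asks whether full depletion would be callable", {
  expect_false(power_filter(1.0))        # hmc(0, 1) = 2.996 >= 1
  expect_true(power_filter(3.5))         # hmc(0, 3.5) = 0.856 < 1
  expect_equal(power_filter(2.9), hmc_score(0, 2.9) < 1)
  # alpha -> 1 limit: every position with any expectation is powered
  expect_true(all(power_filter(c(1e-6, 1, 100), alpha = 1 - 1e-12)))
})

test_that("classification uses strict thresholds and half-open bins", {
  got <- classify_constraint(c(0.608, 0.85, 1.2, 0.3), rep(TRUE, 4))
  expect_equal(got$class, c("highly_constrained", "constrained",
                            "unconstrained", "highly_constrained"))
  expect_equal(got$bin, c("[0.6,0.8)", "[0.8,1)", "[1,Inf)", "[0,0.5)"))
  # boundary values fall in the upper bin (half-open, strict <)
  expect_equal(classify_constraint(c(0.8, 1), c(TRUE, TRUE))$class,
               c("constrained", "unconstrained"))
  expect_equal(classify_constraint(0.2, FALSE)$class, "unassessable")
  expect_error(classify_constraint(0.5, TRUE, bins = c(0.8, 0.5)),
               "increasing")
})

test_that("aggregation matches a brute-force tally on a toy family", {
  # one family, 3 gapless copies of length 2; codons 2-3 of each protein
  aln <- domain_alignment("PF_T", tibble::tibble(
    protein_id = c("PA", "PB", "PC"), env_start = 2L, env_end = 3L,
    aligned_seq = "WW"))
  meta <- build_meta_positions(aln)
  cds <- paste0("ATG", "TGG", "TGG", "TAA")
  txs <- dplyr::bind_rows(
    make_tx(cds, id = "TA", gene = "GA", protein = "PA", chrom = "c1"),
    make_tx(cds, id = "TB", gene = "GB", protein = "PB", chrom = "c2"),
    make_tx(cds, id = "TC", gene = "GC", protein = "PC", chrom = "c3"))
  # two rare missense variants at column 1 (codon 2), one common at column 2
  obs <- tibble::tibble(
    chrom = c("c1", "c2", "c1"), pos = c(1004L, 1004L, 1007L),
    ref = c("T", "T", "T"), alt = c("A", "C", "A"),
    af = c(5e-4, 1e-4, 0.05), passes_filters = TRUE)
  v <- enumerate_snvs(txs) |>
    join_meta_positions(meta) |>
    annotate_mutability(uniform_rate_table(1)) |>
    apply_rarity_filter(obs) |>
    dplyr::mutate(expected = ifelse(.data$assessable, 0.1, 0))
  rec <- aggregate_constraint(v, min_copies = 2)
  expect_equal(nrow(rec), 2)
  c1 <- rec[rec$column == 1, ]
  c2 <- rec[rec$column == 2, ]
  expect_equal(c1$observed, 2L)     # two distinct rare alleles
  expect_equal(c1$n_copies, 3L)
  # brute force: 3 copies x codon TGG: 7 missense SNVs per codon, all
  # assessable except edge contexts (none here: codons are interior)
  n_cand_c1 <- v |>
    dplyr::filter(column == 1, consequence == "missense", assessable) |>
    nrow()
  expect_equal(c1$expected, 0.1 * n_cand_c1)
  # the common variant contributes to neither observed nor candidates
  expect_equal(c2$observed, 0L)
  n_cand_c2 <- v |>
    dplyr::filter(column == 2, consequence == "missense", assessable) |>
    nrow()
  expect_equal(c2$expected, 0.1 * n_cand_c2)
  expect_lt(n_cand_c2, n_cand_c1)   # the common allele left the candidate set
  expect_equal(c1$mle, c1$observed / c1$expected)
  expect_equal(c1$hmc, hmc_score(c1$observed, c1$expected))
})

test_that("variant scores are shared within a meta-position", {
  res <- shared_pipeline()
  scored <- res$scores |> dplyr::filter(class != "unassessable")
  per_pos <- scored |>
    dplyr::group_by(family_id, column) |>
    dplyr::summarise(n_hmc = dplyr::n_distinct(hmc),
                     n_class = dplyr::n_distinct(class), .groups = "drop")
  expect_true(all(per_pos$n_hmc == 1))
  expect_true(all(per_pos$n_class == 1))

  # filler genes have no domains, hence zero assessable variants
  frac <- gene_assessable_fraction(res$variants, res$scores)
  filler <- frac[grepl("FILLER", frac$gene_id), ]
  expect_true(nrow(filler) > 0)
  expect_true(all(filler$n_assessable == 0))

  # hand count on one domain gene
  g <- setdiff(unique(res$scores$gene_id), filler$gene_id)[1]
  by_hand <- res$scores |>
    dplyr::filter(gene_id == g, class != "unassessable") |>
    nrow()
  expect_equal(frac$n_assessable[frac$gene_id == g], by_hand)
})

test_that("per-column depletion is recovered by the MLE", {
  # fixed 50% depletion, large families so per-variant expectation << 1
  rec <- generics::tidy(shared_e50()$res$records)
  expect_gt(mean(rec$expected), 30)
  expect_lt(abs(median(rec$mle[rec$powered]) - 0.5), 0.05)
})
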