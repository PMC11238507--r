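test_that("rate ratio arithmetic, symmetry and reciprocity hold", {
  rr <- rate_ratio(10, 100, 5, 100)
  expect_equal(rr$estimate, 2.0)
  expect_true(rr$ci_low < 2 && rr$ci_high > 2)

  sym <- rate_ratio(7, 50, 7, 50)
  expect_equal(sym$estimate, 1.0)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)

  # reciprocity without zero cells
  set.seed(91)
  for (i in 1:20) {
    a <- sample(1:30, 1); b <- sample(1:30, 1)
    f <- rate_ratio(a, 40, b, 40)
    g <- rate_ratio(b, 40, a, 40)
    expect_equal(f$estimate * g$estimate, 1)
    expect_equal(f$ci_low, 1 / g$ci_high)
  }

  # zero-cell continuity correction matches the closed form
  expect_message(z <- rate_ratio(0, 50, 5, 60), "continuity")
  log_est <- log((0.5 / 50.5) / (5.5 / 60.5))
  se <- sqrt(1 / 0.5 - 1 / 50.5 + 1 / 5.5 - 1 / 60.5)
  expect_equal(z$ci_high, exp(log_est + qnorm(0.975) * se))
  expect_equal(z$estimate, 0)
  expect_error(rate_ratio(1, 0, 1, 10), "positive")
})

test_that("DNM burden uses the exact Poisson interval", {
  b <- dnm_burden(12, 12)
  expect_equal(b$estimate, 1.0)
  expect_true(b$ci_low < 1 && b$ci_high > 1)

  # observed = 0: lower bound 0, upper from the Gamma/chi-square identity
  z <- dnm_burden(0, 4)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, -log(0.025) / 4, tolerance = 1e-12)

  # interval endpoints agree with stats::poisson.test (same construction)
  pt <- stats::poisson.test(7, r = 10)
  b7 <- dnm_burden(7, 10)
  expect_equal(b7$ci_low, pt$conf.int[1] / 10)
  expect_equal(b7$ci_high, pt$conf.int[2] / 10)

  # coverage of the exact interval is at least nominal
  set.seed(92)
  lam <- 6
  o <- rpois(1e4, lam)
  lo <- ifelse(o == 0, 0, qgamma(0.025, shape = o)) / lam
  hi <- qgamma(0.975, shape = o + 1) / lam
  expect_gte(mean(lo <= 1 & 1 <= hi), 0.95)
  expect_error(dnm_burden(1, 0), "positive")
})

test_that("odds ratios follow the 2x2 closed forms", {
  expect_equal(odds_ratio_2x2(10, 90, 10, 90)$estimate, 1.0)
  expect_equal(odds_ratio_2x2(20, 80, 10, 90)$estimate, 2.25)
  z <- odds_ratio_2x2(0, 10, 5, 5)
  or <- (0.5 * 5.5) / (10.5 * 5.5)
  expect_equal(z$estimate, or)
  se <- sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5)
  expect_equal(z$ci_low, exp(log(or) - qnorm(0.975) * se))
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "row")
})

test_that("precision-sensitivity handles separation, ties and thresholds", {
  # perfectly separating scores: precision 1 at every achieved sensitivity
  sep <- tibble::tibble(score = c(0.1, 0.2, 0.3, 1.5, 2, 3),
                        label = c(1, 1, 1, 0, 0, 0))
  pr <- precision_sensitivity(sep, score, label)
  expect_true(all(pr$curve$precision[pr$curve$sensitivity <= 1 &
                                       pr$curve$threshold < 1.5] == 1))
  expect_equal(max(pr$curve$sensitivity), 1)

  # 6-variant toy, hand tally at threshold 0.8 (strict <):
  # called = scores {0.5, 0.7, 0.7}; 2 of 3 are positive
  toy <- tibble::tibble(score = c(0.5, 0.7, 0.7, 0.9, 1.1, 1.3),
                        label = c(1, 1, 0, 1, 0, 0))
  at <- pr_at_threshold(precision_sensitivity(toy, score, label), 0.8)
  expect_equal(at$n_called, 3L)
  expect_equal(at$precision, 2 / 3)
  expect_equal(at$sensitivity, 2 / 3)

  # ties are grouped: one curve row per distinct score
  prt <- precision_sensitivity(toy, score, label)
  expect_equal(nrow(prt$curve), 5)

  # invariance under a strictly monotone transform
  trans <- toy |> dplyr::mutate(score = exp(3 * score))
  prx <- precision_sensitivity(trans, score, label)
  expect_equal(prt$curve[c("precision", "sensitivity")],
               prx$curve[c("precision", "sensitivity")])
  expect_equal(prt$auc, prx$auc)

  # random scores, balanced labels: precision about prevalence
  set.seed(93)
  rnd <- tibble::tibble(score = runif(4000), label = rep(0:1, 2000))
  prr <- precision_sensitivity(rnd, score, label)
  half <- prr$curve[prr$curve$sensitivity > 0.25, ]
  expect_lt(max(abs(half$precision - 0.5)), 0.08)

  expect_error(precision_sensitivity(
    tibble::tibble(score = 1:3, label = c(1, 1, 1)), score, label),
    "both label classes")
})

test_that("bin report recovers planted enrichment and handles empty bins", {
  scores <- tibble::tibble(
    chrom = "chr1", pos = 1:400, ref = "A", alt = "G",
    hmc = c(runif(100, 0.2, 0.5), runif(100, 0.5, 0.8),
            runif(100, 0.8, 1.0), runif(100, 1.0, 2.0)),
    class = "x")
  set.seed(94)
  # pathogenic labels concentrated below 0.8, benign uniform
  path_idx <- sample(1:200, 80)
  ben_idx <- sample(1:400, 80)
  labeled <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = path_idx, ref = "A", alt = "G",
                   label = 1),
    tibble::tibble(chrom = "chr1", pos = ben_idx, ref = "A", alt = "G",
                   label = 0))
  rep_ <- bin_report(scores, labeled, bins = c(0.5, 0.8, 1))
  rr <- setNames(rep_$estimate, rep_$bin)
  expect_gt(rr[["[0,0.5)"]], rr[["[1,Inf)"]])
  expect_gt(rr[["[0.5,0.8)"]], rr[["[1,Inf)"]])

  # all labels in one bin: other bins yield NA rows, not errors
  one_bin <- labeled |> dplyr::filter(pos <= 100)
  rep_one <- bin_report(scores, one_bin, bins = c(0.5, 0.8, 1))
  expect_true(any(is.na(rep_one$estimate)))
  expect_equal(nrow(rep_one), 5)  # 4 intervals + unassessable stratum
})
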