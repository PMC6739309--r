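test_that("confusion matrices count group-by-outcome membership", {
  co <- cohort_table(data.frame(subject_id = c("a", "b", "c", "d"),
                                outcome = c(1, 1, 0, 0),
                                bm = c(20, 18, 16, 5)),
                     biomarkers = "bm")
  d <- dichotomize_by_threshold(co, "bm", 15)
  m <- from_groups(d, setNames(co$outcome, co$subject_id))
  expect_equal(unlist(m[c("a", "b", "c", "d")]),
               c(a = 2, b = 1, c = 0, d = 1))
  expect_equal(m$a + m$b, length(d$high_ids))

  # empty high group
  d2 <- dichotomize_by_threshold(co, "bm", 100)
  m2 <- from_groups(d2, setNames(co$outcome, co$subject_id))
  expect_equal(m2$a + m2$b, 0)

  expect_error(from_groups(d, setNames(c(1, NA, 0, 0), co$subject_id)),
               "missing")
  expect_error(confusion_matrix(-1, 0, 0, 0), "nonnegative")
})

test_that("Fisher exact p follows the minimum-likelihood enumeration", {
  # zero row margin is degenerate with p = 1
  deg <- fisher_exact_two_sided(confusion_matrix(0, 0, 3, 5))
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)

  # (3,1,1,3): point probs {1,16,36,16,1}/70, those <= 16/70 sum to 34/70
  expect_equal(fisher_exact_two_sided(confusion_matrix(3, 1, 1, 3))$p,
               34 / 70, tolerance = 1e-12)

  # toy scan table (3,1,0,4): support probs {4,24,24,4}/56, p = 8/56
  expect_equal(fisher_exact_two_sided(confusion_matrix(3, 1, 0, 4))$p,
               1 / 7, tolerance = 1e-12)

  # printed cohort table agrees with the exact enumeration oracle
  expect_equal(fisher_exact_two_sided(confusion_matrix(31, 40, 3, 26))$p,
               fisher_oracle(31, 40, 3, 26), tolerance = 1e-10)
})

test_that("Fisher exact matches oracle and stats::fisher.test on random tables", {
  set.seed(8)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    cells <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    m <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    res <- fisher_exact_two_sided(m)
    expect_equal(res$p, fisher_oracle(cells[1], cells[2], cells[3],
                                      cells[4]),
                 tolerance = 1e-9,
                 label = paste(cells, collapse = ","))
    if (!res$degenerate) {
      ft <- fisher.test(matrix(c(cells[1], cells[3], cells[2], cells[4]),
                               2))
      expect_equal(res$p, ft$p.value, tolerance = 1e-7)
    }
  }
})

test_that("Pearson chi-square matches hand arithmetic and chisq.test", {
  null <- pearson_chi_square(confusion_matrix(10, 10, 10, 10))
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)

  m <- confusion_matrix(31, 40, 3, 26)
  raw <- pearson_chi_square(m)
  expect_equal(raw$statistic, 10.185, tolerance = 1e-3)
  expect_equal(raw$p, 0.001416, tolerance = 1e-3)
  yat <- pearson_chi_square(m, yates = TRUE)
  expect_equal(yat$statistic, 8.7546, tolerance = 1e-3)
  expect_equal(yat$p, 0.003088, tolerance = 1e-3)

  mt <- matrix(c(31, 3, 40, 26), 2)
  expect_equal(raw$statistic,
               unname(chisq.test(mt, correct = FALSE)$statistic),
               tolerance = 1e-10)
  expect_equal(yat$statistic,
               unname(chisq.test(mt, correct = TRUE)$statistic),
               tolerance = 1e-10)
  expect_error(pearson_chi_square(confusion_matrix(0, 0, 3, 5)), "margin")
})

test_that("risk and odds ratios follow Katz/Woolf closed forms", {
  null <- risk_ratio_ci(confusion_matrix(10, 10, 10, 10))
  expect_equal(null$estimate, 1)
  expect_lt(null$ci_low, 1); expect_gt(null$ci_high, 1)

  rr <- risk_ratio_ci(confusion_matrix(31, 40, 3, 26))
  expect_equal(rr$estimate, (31 / 71) / (3 / 29), tolerance = 1e-12)
  expect_equal(rr$estimate, 4.2207, tolerance = 1e-4)
  expect_equal(rr$ci_low, 1.3999, tolerance = 1e-3)
  expect_equal(rr$ci_high, 12.7247, tolerance = 1e-3)
  expect_false(rr$corrected)

  # Haldane-Anscombe on a zero event cell
  cr <- risk_ratio_ci(confusion_matrix(5, 5, 0, 10))
  expect_true(cr$corrected)
  expect_equal(cr$estimate, (5.5 / 11) / (0.5 / 11), tolerance = 1e-12)

  or <- odds_ratio_ci(confusion_matrix(31, 40, 3, 26))
  expect_equal(or$estimate, 31 * 26 / (40 * 3), tolerance = 1e-12)
  expect_equal(odds_ratio_ci(confusion_matrix(1, 1, 1, 1))$estimate, 1)
  cor_ <- odds_ratio_ci(confusion_matrix(5, 5, 0, 10))
  expect_true(cor_$corrected)
  expect_equal(cor_$estimate, (5.5 * 10.5) / (5.5 * 0.5), tolerance = 1e-12)

  expect_error(risk_ratio_ci(confusion_matrix(0, 0, 3, 5)), "empty")
})

test_that("2x2 statistics obey their symmetry invariants", {
  set.seed(9)
  for (i in 1:50) {
    cells <- as.vector(rmultinom(1, sample(8:60, 1), runif(4, 0.1, 1)))
    m <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    swapped <- confusion_matrix(cells[3], cells[4], cells[1], cells[2])
    both <- confusion_matrix(cells[4], cells[3], cells[2], cells[1])

    # row swap inverts RR and OR; bounds swap and invert
    if (all(cells > 0)) {
      rr <- risk_ratio_ci(m); rs <- risk_ratio_ci(swapped)
      expect_equal(rs$estimate, 1 / rr$estimate, tolerance = 1e-12)
      expect_equal(rs$ci_low, 1 / rr$ci_high, tolerance = 1e-12)
      expect_equal(rs$ci_high, 1 / rr$ci_low, tolerance = 1e-12)
      expect_true(rr$ci_low <= rr$estimate && rr$estimate <= rr$ci_high)
      or <- odds_ratio_ci(m); os <- odds_ratio_ci(swapped)
      expect_equal(os$estimate, 1 / or$estimate, tolerance = 1e-12)
    }

    # simultaneous row+column swap leaves Fisher and chi-square unchanged
    f1 <- fisher_exact_two_sided(m); f2 <- fisher_exact_two_sided(both)
    expect_equal(f1$p, f2$p, tolerance = 1e-12)
    expect_gt(f1$p, 0); expect_lte(f1$p, 1)
    if (sum(cells[c(1, 3)]) > 0 && sum(cells[c(2, 4)]) > 0 &&
        sum(cells[1:2]) > 0 && sum(cells[3:4]) > 0) {
      expect_equal(pearson_chi_square(m)$statistic,
                   pearson_chi_square(both)$statistic, tolerance = 1e-10)
    }
  }
})
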