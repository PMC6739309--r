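test_that("logistic fits match closed forms on intercept-only data", {
  # 34 events / 66 non-events: b0 = ln(34/66), BIC = -2 loglik + ln 100
  y <- rep(c(1, 0), c(34, 66))
  f <- fit_logistic_glm(data.frame(row.names = 1:100), y)
  expect_equal(unname(f$coefficients), log(34 / 66), tolerance = 1e-7)
  expect_equal(f$loglik, 34 * log(0.34) + 66 * log(0.66), tolerance = 1e-7)
  expect_equal(f$bic, 132.8123, tolerance = 1e-4)
  expect_equal(f$k, 1)

  # balanced outcomes: b0 = 0
  f50 <- fit_logistic_glm(data.frame(row.names = 1:40),
                          rep(c(0, 1), 20))
  expect_equal(unname(f50$coefficients), 0, tolerance = 1e-9)

  # rank-deficient design is a named error
  X <- data.frame(x1 = rnorm(30))
  X$x2 <- 2 * X$x1
  expect_error(fit_logistic_glm(X, rbinom(30, 1, 0.5)), "x2")
})

test_that("logistic regression recovers known parameters at n = 5000", {
  set.seed(41)
  x <- rnorm(5000)
  p <- plogis(-2 + 1 * x)
  y <- as.numeric(runif(5000) < p)
  f <- fit_logistic_glm(data.frame(x = x), y)
  expect_lt(abs(f$coefficients["(Intercept)"] - (-2)) /
              f$se["(Intercept)"], 3)
  expect_lt(abs(f$coefficients["x"] - 1) / f$se["x"], 3)
  expect_true(f$converged)
  expect_false(f$separation)

  # canonical-link score equations hold at convergence
  Xmat <- cbind(1, x)
  expect_lt(max(abs(crossprod(Xmat, y - f$fitted))), 1e-6)
  # BIC is re-derivable from the stored parts
  expect_equal(f$bic, -2 * f$loglik + f$k * log(f$n), tolerance = 1e-12)
})

test_that("analysis of deviance follows the chi-square closed forms", {
  set.seed(42)
  co <- generate_cohort(sepsis_generator_config(n = 200, seed = 42))
  small <- riskscan:::fit_effect_set
  f0 <- small(co, character())
  f1 <- small(co, "eNAPRT")
  f2 <- small(co, c("eNAPRT", "CRP"))
  expect_equal(anova_deviance(f1, f1), 1)
  p <- anova_deviance(f0, f1)
  expect_equal(p, pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # deviance never increases when effects are added
  expect_gte(f0$deviance - f1$deviance, -1e-6)
  expect_gte(f1$deviance - f2$deviance, -1e-6)
  # quantile identities on 1 df
  expect_equal(pchisq(10.83, 1, lower.tail = FALSE), 0.001, tolerance = 1e-3)
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-2)
  expect_error(anova_deviance(f2, f1), "nested")
})

test_that("marginality constrains enumeration and the repair operator", {
  cand <- c("A", "B", "A:B")
  subsets <- riskscan:::enumerate_valid_subsets(cand)
  expect_equal(nrow(subsets), 5)  # 2^2 main sets + full model
  # two mains, no interaction: plain power set
  expect_equal(nrow(riskscan:::enumerate_valid_subsets(c("A", "B"))), 4)
  expect_equal(nrow(riskscan:::enumerate_valid_subsets(character())), 1)

  inc <- c(FALSE, TRUE, TRUE)  # orphan interaction: A missing
  expect_equal(riskscan:::repair_marginality(inc, cand),
               c(FALSE, TRUE, FALSE))
})

test_that("exhaustive oracle ranks all valid subsets by BIC", {
  co <- generate_cohort(sepsis_generator_config(n = 150, seed = 44))
  res <- exhaustive_oracle(co, c("eNAPRT", "CRP", "eNAPRT:CRP"))
  expect_length(res$models, 5)
  expect_true(all(diff(res$bic) >= 0))
  # intercept-only result for an empty candidate list
  res0 <- exhaustive_oracle(co, character())
  expect_length(res0$models, 1)
  expect_equal(res0$models[[1]]$k, 1)
  expect_error(exhaustive_oracle(co, paste0("V", 1:16)), "15")
})

test_that("GA search is deterministic and matches the exhaustive oracle", {
  co <- generate_cohort(sepsis_generator_config(n = 150, seed = 45))
  cand <- c("eNAPRT", "CRP", "PCT", "WBC", "eNAMPT",
            "eNAPRT:CRP", "eNAPRT:PCT", "eNAPRT:WBC")
  cfg <- ga_config(pop_size = 30, generations = 25, seed = 7)
  g1 <- ga_search(co, cand, cfg)
  g2 <- ga_search(co, cand, cfg)
  expect_identical(g1$bic, g2$bic)
  expect_identical(g1$inclusions, g2$inclusions)

  ex <- exhaustive_oracle(co, cand)
  expect_equal(g1$bic[1], ex$bic[1], tolerance = 1e-9)
  # GA best never beats the oracle and never loses to the seeded extremes
  full_bic <- ex$bic[apply(ex$inclusions, 1, all)]
  null_bic <- ex$bic[apply(!ex$inclusions, 1, all)]
  expect_lte(g1$bic[1], full_bic + 1e-9)
  expect_lte(g1$bic[1], null_bic + 1e-9)
  # the GA trace never worsens (elitism)
  expect_true(all(diff(g1$trace) <= 1e-9))

  expect_error(ga_search(co, c("eNAPRT", "eNAPRT:CRP"),
                         ga_config(seed = 1)), "main effect")
  expect_error(ga_search(co, c("eNAPRT", "CRP"),
                         ga_config(pop_size = 50, seed = 1)),
               "pop_size")
  r0 <- ga_search(co, character(), ga_config(seed = 3))
  expect_length(r0$models, 1)
  expect_equal(r0$models[[1]]$k, 1)
})

test_that("Pearson correlation matches its t-transform and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  set.seed(46)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  res <- pearson_correlation(a, b)
  ct <- cor.test(a, b)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  ls <- lm(b ~ a)
  expect_equal(res$slope, unname(coef(ls)[2]), tolerance = 1e-9)
  expect_equal(res$intercept, unname(coef(ls)[1]), tolerance = 1e-9)

  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "3 complete")
})

test_that("calibrated copula yields the expected correlation at cohort scale", {
  # single cohorts of n = 92 scatter widely, so check the centre of the
  # sampling distribution over seeded replicates instead of one draw
  rs <- vapply(1:25, function(s) {
    co <- generate_cohort(sepsis_generator_config(n = 92, seed = s))
    pearson_correlation(co$CRP, co$eNAPRT)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.31), 0.08)
  expect_gt(mean(rs > 0), 0.9)
})
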