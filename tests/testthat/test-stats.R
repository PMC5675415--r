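test_that("group_summary computes mean, SEM and n with missing data", {
  gs <- group_summary(measure_matrix(matrix(c(1, 2, 3), 3, 1,
                                            dimnames = list(NULL, "D0"))))
  expect_equal(gs$mean, 2)
  expect_equal(gs$sem, 1 / sqrt(3), tolerance = 1e-12) # sd = 1, n = 3
  expect_identical(gs$n, 3L)

  m <- measure_matrix(matrix(c(10, NA, NA, NA), 2, 2,
                             dimnames = list(NULL, c("D0", "D1"))))
  gs2 <- group_summary(m)
  expect_equal(gs2$mean, c(10, NA_real_))
  expect_true(all(is.na(gs2$sem))) # single animal: SEM undefined
  expect_identical(gs2$n, c(1L, 0L))
})

test_that("measure_matrix builds from long tables and flags duplicates", {
  long <- data.frame(animal = c("a", "a", "b"), day = c("D0", "D1", "D0"),
                     value = c(1, 2, 3))
  m <- measure_matrix(long)
  expect_equal(m["a", "D1"], 2)
  expect_true(is.na(m["b", "D1"]))
  expect_error(measure_matrix(rbind(long, long[1, ])), "duplicate")
})

test_that("rm_anova matches the aov oracle on a deterministic sweep", {
  for (tab in enumerate_tables()) {
    m <- measure_matrix(tab)
    got <- rm_anova(m, alpha = 0.05)
    want <- oracle_rm_anova_F(tab)
    if (!is.finite(want[["F"]]) || want[["F"]] > 1e9 || got$F > 1e9) {
      # degenerate zero-error tables: both implementations blow up together
      expect_gt(got$F, 1e9)
    } else {
      expect_equal(got$F, unname(want[["F"]]), tolerance = 1e-8)
      expect_equal(got$p, unname(want[["p"]]), tolerance = 1e-8)
    }
    expect_identical(got$df_effect, as.integer(want[["df1"]]))
    expect_identical(got$df_error, as.integer(want[["df2"]]))
  }
})

test_that("rm_anova handles constants, permutations and input contracts", {
  const <- measure_matrix(matrix(5, 4, 3))
  r <- rm_anova(const, alpha = 0.05)
  expect_identical(r$F, 0)
  expect_identical(r$decision, "retain")

  set.seed(1)
  m <- matrix(rnorm(15), 5, 3)
  f1 <- rm_anova(measure_matrix(m), alpha = 0.05)$F
  f2 <- rm_anova(measure_matrix(m[, c(3, 1, 2)]), alpha = 0.05)$F
  expect_equal(f1, f2)

  # listwise completion drops incomplete animals and reports n
  m_na <- m; m_na[2, 3] <- NA
  r2 <- rm_anova(measure_matrix(m_na), alpha = 0.05)
  expect_identical(r2$n_animals, 4L)
  expect_equal(r2$F, rm_anova(measure_matrix(m[-2, ]), alpha = 0.05)$F)

  expect_error(rm_anova(measure_matrix(m)), "alpha")
  expect_error(rm_anova(measure_matrix(m[1, , drop = FALSE]), alpha = 0.05),
               "at least 2 animals")
  # Greenhouse-Geisser epsilon is reported within its theoretical range
  expect_gte(f_ <- rm_anova(measure_matrix(m), alpha = 0.05)$gg_epsilon,
             1 / (ncol(m) - 1))
  expect_lte(f_, 1)
})

test_that("tukey_kramer reduces to TukeyHSD with equal n", {
  set.seed(3)
  m <- matrix(rnorm(24, mean = rep(c(0, 1, 0.5), each = 8)), 8, 3,
              dimnames = list(NULL, c("D0", "D1", "D2")))
  got <- tukey_kramer(measure_matrix(m), alpha = 0.05)
  df <- data.frame(y = as.vector(m), g = factor(rep(colnames(m), each = 8)))
  hsd <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  # same pairs in the same order (combn order matches TukeyHSD's rownames)
  key <- paste(got$day2, got$day1, sep = "-")
  expect_setequal(key, rownames(hsd))
  expect_equal(got$p_adj, unname(hsd[key, "p adj"]), tolerance = 1e-8)

  # identical groups: nothing significant
  eqm <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  expect_false(any(tukey_kramer(measure_matrix(eqm), alpha = 0.05)$significant))
})

test_that("tukey_kramer applies the unequal-n Kramer correction", {
  set.seed(4)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("D0", "D1", "D2")))
  m[9:10, 2] <- NA # unequal group sizes
  got <- tukey_kramer(measure_matrix(m), alpha = 0.05)
  # brute-force studentized range: q = |diff| / sqrt(MSE/2 (1/n1 + 1/n2))
  groups <- lapply(1:3, function(j) m[!is.na(m[, j]), j])
  ns <- lengths(groups)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) /
    (sum(ns) - 3)
  for (r in seq_len(nrow(got))) {
    i <- match(got$day1[r], c("D0", "D1", "D2"))
    j <- match(got$day2[r], c("D0", "D1", "D2"))
    q <- abs(mean(groups[[i]]) - mean(groups[[j]])) /
      sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    expect_equal(got$q[r], q, tolerance = 1e-10)
    expect_equal(got$p_adj[r],
                 stats::ptukey(q, 3, sum(ns) - 3, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # a 10-sd shift with n = 6 per group is flagged
  set.seed(5)
  shifted <- cbind(D0 = rnorm(6), D1 = rnorm(6) + 10, D2 = rnorm(6))
  tk <- tukey_kramer(measure_matrix(shifted), alpha = 0.05)
  expect_true(tk$significant[tk$day1 == "D0" & tk$day2 == "D1"])
})

test_that("bonferroni_pairwise corrects by the number of pairs", {
  set.seed(6)
  base <- matrix(rnorm(27), 9, 3, dimnames = list(NULL, c("D0", "D1", "D21")))
  r <- bonferroni_pairwise(measure_matrix(base), alpha = 0.05)
  expect_identical(nrow(r), 3L)
  expect_equal(r$p_adj, pmin(1, r$p * 3))
  # raw p ~0.02 with 3 pairs is not significant at alpha 0.05
  expect_true(all(r$significant == (r$p < 0.05 / 3)))

  # a +5 sd shift at D1 is detected
  shifted <- base; shifted[, "D1"] <- shifted[, "D1"] + 5
  r2 <- bonferroni_pairwise(measure_matrix(shifted), alpha = 0.05)
  expect_true(r2$significant[r2$day1 == "D0" & r2$day2 == "D1"])

  # decisions do not depend on pair order (columns permuted)
  r3 <- bonferroni_pairwise(measure_matrix(shifted[, c(3, 1, 2)]),
                            days = c("D0", "D1", "D21"), alpha = 0.05)
  key <- function(x) paste(pmin(x$day1, x$day2), pmax(x$day1, x$day2))
  expect_identical(r2$significant[order(key(r2))],
                   r3$significant[order(key(r3))])

  expect_error(bonferroni_pairwise(measure_matrix(base[, 1:2]),
                                   alpha = 0.05), "D21")
  # identical days: nothing significant
  same <- cbind(D0 = 1:9, D1 = 1:9 + 0.0, D21 = 1:9 + 0.0)
  same[, "D1"] <- same[, "D0"]
  same[, "D21"] <- same[, "D0"]
  expect_false(any(suppressWarnings(
    bonferroni_pairwise(measure_matrix(same + matrix(rnorm(27, 0, 1e-8), 9)),
                        alpha = 0.05)
  )$significant))
})

test_that("critical_value_decision reproduces the F-table test", {
  expect_false(critical_value_decision(0, 2, 8, alpha = 0.05)$reject)
  expect_false(critical_value_decision(0, 2, 8, alpha = 0.5)$reject)
  # the published decision: F values 3.491 and 7.056 against a critical
  # value of 2.8 at 99% confidence (matched at df = 8, 64)
  d <- critical_value_decision(3.491, 8, 64, alpha = 0.01)
  expect_equal(d$critical_value, 2.8, tolerance = 0.01)
  expect_true(d$reject)
  expect_true(critical_value_decision(7.056, 8, 64, alpha = 0.01)$reject)
  # quantile cross-checked via the beta-distribution identity
  qf_beta <- function(p, d1, d2) {
    b <- stats::qbeta(p, d1 / 2, d2 / 2)
    (d2 / d1) * b / (1 - b)
  }
  expect_equal(critical_value_decision(1, 2, 8, alpha = 0.05)$critical_value,
               qf_beta(0.95, 2, 8), tolerance = 1e-10)
  expect_error(critical_value_decision(1, 0, 8, alpha = 0.05), "positive")
  expect_error(critical_value_decision(1, 2, 8), "alpha")
})
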