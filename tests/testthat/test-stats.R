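test_that("condition summaries compute mean and SEM over retained points", {
  s <- aggregateCondition(c(1, 2, 3) * 1e-5)
  expect_equal(s$mean_Pd, 2e-5)
  expect_equal(s$sem_Pd, 1e-5 / sqrt(3))
  expect_equal(s$n, 3L)

  expect_warning(s1 <- aggregateCondition(5e-6), "n = 1")
  expect_equal(s1$sem_Pd, 0)

  df <- data.frame(Pd_cm_s = c(1e-5, 2e-5, 9e-5), focal_leak = c(F, F, T),
                   error = NA_character_)
  s2 <- aggregateCondition(df)
  expect_equal(s2$n, 2L)
  expect_equal(s2$n_excluded, 1L)
  expect_equal(s2$mean_Pd, 1.5e-5)
  df$focal_leak <- TRUE
  expect_error(aggregateCondition(df), "no measurements")
})

test_that("Student's t-test matches the closed-form pooled evaluation", {
  a <- c(3.2, 3.8, 3.5, 4.1, 3.6)
  b <- c(2.1, 2.6, 2.4, 2.2)
  res <- pdTTest(a, b)
  # independent closed-form evaluation
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tExp <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  pExp <- 2 * pt(-abs(tExp), df = na + nb - 2)
  expect_equal(res$t_statistic, tExp, tolerance = 1e-12)
  expect_equal(res$p_value, pExp, tolerance = 1e-7)
  expect_equal(res$df, na + nb - 2)
  expect_equal(res$fold_change, mean(a) / mean(b))
  expect_true(res$significant)

  # identical samples: t = 0, p = 1, fold change 1
  same <- pdTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$fold_change, 1)

  # clearly separated groups are significant
  expect_true(pdTTest(c(1, 2, 3), c(1, 2, 3) + 100)$significant)

  # exchange symmetry
  ab <- pdTTest(a, b); ba <- pdTTest(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$t_statistic, -ba$t_statistic)

  expect_error(pdTTest(1, c(1, 2)), "at least 2")
  expect_error(pdTTest(c(1, 1), c(2, 2)), "zero variance")
})

test_that("fold changes reproduce the reported barrier-tightening ratios", {
  # Ang-1 on 10 kDa dextran
  expect_equal(foldChange(3.50e-5, 2.23e-5), 1.57)
  expect_equal(foldChange(3.50e-5, 1.61e-5), 2.17)
  # Ang-1 on 70 kDa dextran
  expect_equal(foldChange(2.47e-5, 1.27e-5), 1.94)
  expect_equal(foldChange(2.47e-5, 3.60e-6), 6.86)
  # pCPT-cAMP
  expect_equal(foldChange(3.50e-5, 1.22e-5), 2.87)
  expect_equal(foldChange(2.47e-5, 4.88e-6), 5.06, tolerance = 0.01)
  expect_equal(foldChange(2e-5, 2e-5), 1)
  expect_error(foldChange(1e-5, 0), "> 0")
})

test_that("reciprocal fold changes multiply to one", {
  set.seed(3)
  for (i in 1:20) {
    x <- runif(1, 1e-6, 1e-4); y <- runif(1, 1e-6, 1e-4)
    expect_equal(foldChange(x, y) * foldChange(y, x), 1, tolerance = 5e-3)
  }
})

test_that("tumor-to-normal ratios propagate uncertainty", {
  tum <- aggregateCondition(c(4.8, 5.1, 5.4) * 1e-5, "untreated", "40nm")
  nor <- aggregateCondition(c(0.9, 1.0, 1.1) * 1e-5, "treated", "40nm")
  tnr <- computeTNR(tum, nor)
  expect_equal(tnr$tnr, tum$mean_Pd / nor$mean_Pd)
  expect_equal(tnr$tnr_se,
               tnr$tnr * sqrt((tum$sem_Pd / tum$mean_Pd)^2 +
                                (nor$sem_Pd / nor$mean_Pd)^2))
  expect_equal(computeTNR(tum, tum)$tnr, 1)
  five <- tum; five$mean_Pd <- 5 * nor$mean_Pd; five$sem_Pd <- 0
  expect_equal(computeTNR(five, nor)$tnr, 5)
  bad <- nor; bad$probe <- "100nm"
  expect_error(computeTNR(tum, bad), "probe mismatch")
})

test_that("size-selectivity tables order probes and test adjacent pairs", {
  set.seed(8)
  df <- data.frame(
    d_h = rep(c(100, 20, 40), each = 6),
    Pd_cm_s = c(rnorm(6, 1.0e-5, 5e-7), rnorm(6, 3.0e-5, 5e-7),
                rnorm(6, 2.0e-5, 5e-7)))
  tab <- sizeSelectivityTable(df)
  expect_equal(tab$d_h, c(20, 40, 100))
  expect_true(all(diff(tab$mean_Pd) < 0))
  expect_true(is.na(tab$p_adjacent[1]))
  expect_true(all(tab$significant_adjacent[-1]))
  expect_error(sizeSelectivityTable(df[df$d_h == 20, ]), "at least 2")
})
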