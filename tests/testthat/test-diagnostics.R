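round2 <- function(x) floor(x * 100 + 0.5) / 100

test_that("Wilson intervals reproduce the published diagnostic metrics", {
  # overall group, per-vessel 2x2: tp 16, fp 4, fn 8, tn 15
  tv <- structure(list(tp = 16, fp = 4, fn = 8, tn = 15),
                  class = "confusion_table")
  mv <- proportion_metrics(tv)
  expect_equal(round2(mv$sensitivity$estimate), 66.67)
  expect_equal(round2(mv$sensitivity$lower), 46.71)
  expect_equal(round2(mv$sensitivity$upper), 82.03)
  expect_equal(round2(mv$specificity$estimate), 78.95)
  expect_equal(round2(mv$specificity$lower), 56.67)
  expect_equal(round2(mv$specificity$upper), 91.49)
  expect_equal(round2(mv$ppv$estimate), 80.00)
  expect_equal(round2(mv$ppv$lower), 58.40)
  expect_equal(round2(mv$ppv$upper), 91.93)
  expect_equal(round2(mv$npv$estimate), 65.22)
  expect_equal(round2(mv$npv$lower), 44.89)
  expect_equal(round2(mv$npv$upper), 81.19)

  # per-patient 2x2: tp 16, fp 1, fn 7, tn 7
  tp <- structure(list(tp = 16, fp = 1, fn = 7, tn = 7),
                  class = "confusion_table")
  mp <- proportion_metrics(tp)
  expect_equal(round2(mp$sensitivity$estimate), 69.57)
  expect_equal(round2(mp$sensitivity$lower), 49.13)
  expect_equal(round2(mp$sensitivity$upper), 84.40)
  expect_equal(round2(mp$specificity$estimate), 87.50)
  expect_equal(round2(mp$ppv$estimate), 94.12)
  expect_equal(round2(mp$npv$estimate), 50.00)
  expect_equal(round2(mp$npv$lower), 26.80)
  expect_equal(round2(mp$npv$upper), 73.20)
})

test_that("Wilson interval properties: symmetry at p = 1/2, boundary, width", {
  w <- coroflow:::.wilson(7, 14)
  expect_equal(w[["lower"]] + w[["upper"]], 1, tolerance = 1e-12)
  w0 <- coroflow:::.wilson(0, 10)
  expect_equal(w0[["lower"]], 0)
  # width shrinks monotonically with n at fixed p
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    w <- coroflow:::.wilson(n / 2, n)
    w[["upper"]] - w[["lower"]]
  }, 1)
  expect_true(all(diff(widths) < 0))
  # zero denominator flagged undefined, not NaN
  m <- proportion_metrics(structure(list(tp = 0, fp = 0, fn = 0, tn = 5),
                                    class = "confusion_table"))
  expect_false(m$sensitivity$defined)
  expect_true(m$specificity$defined)
})

test_that("confusion_table counts strictly below threshold on both sides", {
  p <- reference_cohort_fixture()
  cv <- confusion_table(p, level = "vessel")
  expect_equal(unlist(cv[c("tp", "fp", "fn", "tn")]),
               c(tp = 16, fp = 4, fn = 8, tn = 15))
  cp <- confusion_table(p, level = "patient")
  expect_equal(unlist(cp[c("tp", "fp", "fn", "tn")]),
               c(tp = 16, fp = 1, fn = 7, tn = 7))
  # perfect agreement
  q <- paired_ffr(1:6, rep("v", 6), c(0.5, 0.7, 0.9, 0.85, 0.6, 0.95),
                  c(0.5, 0.7, 0.9, 0.85, 0.6, 0.95))
  cq <- confusion_table(q)
  expect_equal(cq$fp + cq$fn, 0)
})

test_that("AUC equals the exhaustive pairwise concordance", {
  # perfectly separated
  p <- paired_ffr(1:6, rep("v", 6),
                  c(0.5, 0.6, 0.7, 0.9, 0.92, 0.95),
                  c(0.6, 0.7, 0.75, 0.85, 0.9, 0.95))
  expect_equal(roc_auc(p)$auc, 1.0)
  # all scores identical -> 0.5
  p2 <- paired_ffr(1:6, rep("v", 6), rep(0.8, 6),
                   c(0.6, 0.7, 0.75, 0.85, 0.9, 0.95))
  expect_equal(roc_auc(p2)$auc, 0.5)
  # seeded sample vs brute force over all positive x negative pairs
  set.seed(11)
  virt <- round(runif(20, 0.3, 1), 2)   # ties likely at 2 decimals
  inv <- pmin(1, pmax(0.2, virt + rnorm(20, 0, 0.15)))
  p3 <- paired_ffr(1:20, rep("v", 20), virt, inv)
  lab <- inv < 0.8
  sc <- 1 - virt
  brute <- mean(outer(sc[lab], sc[!lab], function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(p3)$auc, brute, tolerance = 1e-12)
  # invariance under strictly monotone transform of scores
  p4 <- p3
  p4$virtual_ffr <- exp(-(1 - p3$virtual_ffr))  # order-preserving remap
  expect_equal(roc_auc(p4)$auc, roc_auc(p3)$auc, tolerance = 1e-12)
  expect_error(roc_auc(paired_ffr(1:3, rep("v", 3), c(0.9, 0.9, 0.85),
                                  c(0.9, 0.95, 0.9))), "classes")
})

test_that("Bland-Altman agrees with direct formulas", {
  p <- paired_ffr(1:5, rep("v", 5),
                  c(0.72, 0.85, 0.64, 0.91, 0.78),
                  c(0.70, 0.80, 0.70, 0.85, 0.75))
  d <- p$virtual_ffr - p$invasive_ffr
  ba <- bland_altman(p)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd, sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  # identical columns and constant offset
  pi1 <- paired_ffr(1:3, rep("v", 3), c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  expect_equal(bland_altman(pi1)$bias, 0)
  expect_equal(bland_altman(pi1)$sd, 0)
  po <- paired_ffr(1:3, rep("v", 3), c(0.75, 0.85, 0.95), c(0.7, 0.8, 0.9))
  expect_equal(bland_altman(po)$bias, 0.05)
  expect_equal(bland_altman(po)$sd, 0, tolerance = 1e-12)
  # bias sign flips when the columns swap
  ps <- paired_ffr(p$patient_id, p$vessel_id, p$invasive_ffr, p$virtual_ffr)
  expect_equal(bland_altman(ps)$bias, -ba$bias)
  expect_error(bland_altman(paired_ffr(1, "v", 0.8, 0.7)), "2")
})

test_that("Spearman rho is the Pearson correlation of mid-ranks", {
  up <- paired_ffr(1:5, rep("v", 5), seq(0.5, 0.9, 0.1), seq(0.4, 0.8, 0.1))
  expect_equal(spearman_rho(up), 1)
  dn <- paired_ffr(1:5, rep("v", 5), seq(0.5, 0.9, 0.1), seq(0.8, 0.4, -0.1))
  expect_equal(spearman_rho(dn), -1)
  # tie-containing fixture vs explicit mid-rank computation
  v <- c(0.6, 0.6, 0.8, 0.9, 0.7, 0.8)
  iv <- c(0.5, 0.7, 0.7, 0.95, 0.6, 0.8)
  pt <- paired_ffr(1:6, rep("v", 6), v, iv)
  midrank <- function(x) {
    sapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2)
  }
  rv <- midrank(v); ri <- midrank(iv)
  brute <- sum((rv - mean(rv)) * (ri - mean(ri))) /
    sqrt(sum((rv - mean(rv))^2) * sum((ri - mean(ri))^2))
  expect_equal(spearman_rho(pt), brute, tolerance = 1e-12)
  expect_error(spearman_rho(paired_ffr(1:3, rep("v", 3), rep(0.8, 3),
                                       c(0.7, 0.8, 0.9))), "constant")
})

test_that("paired_ffr validates its inputs", {
  expect_error(paired_ffr("p1", "v", 1.5, 0.8), "0, 1.2")
  expect_error(paired_ffr(c("p", "p"), c("v", "v"), c(0.8, 0.9), c(0.8, 0.9)),
               "duplicate")
})
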