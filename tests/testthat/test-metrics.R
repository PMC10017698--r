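## brute-force per-epoch tally oracle, independent of confusionTable()
bruteReport <- function(r, p) {
  tp <- fp <- fn <- numeric(3)
  agree <- 0
  tab <- matrix(0, 3, 3)
  for (i in seq_along(r)) {
    tab[r[i], p[i]] <- tab[r[i], p[i]] + 1
    if (r[i] == p[i]) agree <- agree + 1
  }
  for (s in 1:3) {
    tp[s] <- sum(r == s & p == s)
    fp[s] <- sum(r != s & p == s)
    fn[s] <- sum(r == s & p != s)
  }
  recall <- tp / (tp + fn); precision <- tp / (tp + fp)
  pe <- sum(rowSums(tab) * colSums(tab)) / length(r)^2
  acc <- agree / length(r)
  list(tab = tab, recall = recall, precision = precision,
       f1 = 2 / (1 / recall + 1 / precision), accuracy = acc,
       kappa = (acc - pe) / (1 - pe))
}

randPair <- function(n = 200) {
  list(r = sample(1:3, n, TRUE, prob = c(.45, .4, .15)),
       p = sample(1:3, n, TRUE, prob = c(.4, .4, .2)))
}

test_that("confusion table tallies per-epoch counts", {
  tab <- confusionTable(c(1, 1, 2), c(1, 2, 2))
  expect_equal(unname(tab),
               rbind(c(1L, 1L, 0L), c(0L, 1L, 0L), c(0L, 0L, 0L)))
  expect_equal(unname(confusionTable(1:3, 1:3)), diag(3) * 1L)
  expect_error(confusionTable(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(confusionTable(integer(0), integer(0)), "empty")
})

test_that("metrics reproduce the brute-force tally on random sequences", {
  set.seed(11)
  for (i in 1:40) {
    z <- randPair(sample(c(20, 100, 1000), 1))
    ref <- bruteReport(z$r, z$p)
    tab <- confusionTable(z$r, z$p)
    expect_equal(unname(tab), unname(ref$tab))
    sm <- stageMetrics(tab)
    expect_equal(sm$recall, ref$recall)
    expect_equal(sm$precision, ref$precision)
    expect_equal(sm$f1, ref$f1)
    expect_equal(agreementRate(tab), ref$accuracy)
    expect_equal(cohensKappa(tab), ref$kappa)
  }
})

test_that("kappa agrees with an independent implementation", {
  set.seed(12)
  for (i in 1:10) {
    z <- randPair(500)
    tab <- confusionTable(z$r, z$p)
    expect_equal(cohensKappa(tab),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    expect_equal(agreementRate(tab), e1071::classAgreement(tab)$diag)
  }
})

test_that("the hand-evaluated kappa example is reproduced", {
  tab <- rbind(c(4L, 1L, 0L), c(0L, 4L, 0L), c(0L, 0L, 1L))
  expect_equal(agreementRate(tab), 0.9)
  # p_e = (5*4 + 4*5 + 1*1)/100 = 0.41; kappa = 0.49/0.59
  expect_equal(cohensKappa(tab), 0.49 / 0.59)
  expect_equal(cohensKappa(tab), 0.8305, tolerance = 1e-4)
})

test_that("f1 is the harmonic mean of recall and precision", {
  # recall 0.8, precision 1.0 -> f1 = 0.888...
  tab <- rbind(c(8L, 2L, 0L), c(0L, 10L, 0L), c(0L, 0L, 5L))
  sm <- stageMetrics(tab)
  expect_equal(sm$recall[1], 0.8)
  expect_equal(sm$precision[1], 1.0)
  expect_equal(sm$f1[1], 2 / (1 / 0.8 + 1 / 1.0))
})

test_that("swapping the raters swaps recall and precision, f1 invariant", {
  set.seed(13)
  for (i in 1:100) {
    z <- randPair(60)
    a <- stageMetrics(confusionTable(z$r, z$p))
    b <- stageMetrics(confusionTable(z$p, z$r))
    expect_identical(a$recall, b$precision)
    expect_identical(a$precision, b$recall)
    expect_identical(a$f1, b$f1)
  }
})

test_that("agreement is invariant under joint relabeling of stage codes", {
  set.seed(14)
  z <- randPair(300)
  perm <- c(2L, 3L, 1L)
  expect_equal(agreementRate(confusionTable(z$r, z$p)),
               agreementRate(confusionTable(perm[z$r], perm[z$p])))
  expect_equal(cohensKappa(confusionTable(z$r, z$p)),
               cohensKappa(confusionTable(perm[z$r], perm[z$p])))
})

test_that("independent raters give kappa near zero; kappa <= accuracy", {
  set.seed(15)
  n <- 1e5
  r <- sample(1:3, n, TRUE, prob = c(.5, .4, .1))
  p <- sample(1:3, n, TRUE, prob = c(.3, .5, .2))
  tab <- confusionTable(r, p)
  expect_lt(abs(cohensKappa(tab)), 0.02)
  # kappa <= accuracy whenever p_e >= 0
  set.seed(16)
  for (i in 1:20) {
    z <- randPair(100)
    tab <- confusionTable(z$r, z$p)
    expect_lte(cohensKappa(tab), agreementRate(tab) + 1e-12)
  }
})

test_that("degenerate identical-constant raters give the guarded kappa", {
  expect_equal(cohensKappa(confusionTable(rep(1, 5), rep(1, 5))), 1)
  expect_equal(cohensKappa(confusionTable(rep(1, 5), rep(2, 5))), 0)
})

test_that("a stage absent from both raters yields NaN metrics, not errors", {
  tab <- confusionTable(c(1, 1, 2), c(1, 2, 2))
  sm <- stageMetrics(tab)
  expect_true(is.nan(sm$recall[3]))
  expect_true(is.nan(sm$f1[3]))
  expect_false(anyNA(sm$recall[1:2]))
})

test_that("per-recording report: single recording equals pooled", {
  set.seed(17)
  z <- randPair(80)
  rep1 <- perRecordingReport(list(z$r), list(z$p), "only")
  expect_equal(rep1[rep1$recording_id == "only", -1],
               rep1[rep1$recording_id == "pooled", -1],
               ignore_attr = TRUE)
})

test_that("pooled kappa differs from the mean per-recording kappa", {
  # two recordings with very different marginals
  r1 <- c(rep(1L, 16), 2L, 2L, 3L, 2L)
  p1 <- c(rep(1L, 15), 2L, 2L, 3L, 3L, 2L)
  r2 <- c(rep(3L, 14), rep(2L, 4), 1L, 1L)
  p2 <- c(rep(3L, 13), 2L, rep(2L, 4), 1L, 3L)
  rep2 <- perRecordingReport(list(r1, r2), list(p1, p2))
  per <- rep2[rep2$recording_id != "pooled", ]
  pooled <- rep2[rep2$recording_id == "pooled", ]
  expect_false(isTRUE(all.equal(mean(per$kappa), pooled$kappa)))

  # threshold summary: all-perfect recordings -> 100% above both bars
  rep3 <- perRecordingReport(list(1:3, c(2L, 2L, 3L)),
                             list(1:3, c(2L, 2L, 3L)))
  ts <- attr(rep3, "threshold_summary")
  expect_equal(unname(ts[["frac_accuracy_gt_0.9"]]), 1)
  expect_equal(unname(ts[["frac_kappa_gt_0.8"]]), 1)
})
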