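test_that("confusion counts follow the one-vs-rest definitions", {
  ## perfect prediction
  cc <- confusionCounts(rep(c(0, 1, 2), c(4, 3, 3)),
                        rep(c(0, 1, 2), c(4, 3, 3)), 3)
  expect_equal(classCounts(cc, 0), c(TP = 4, FP = 0, TN = 6, FN = 0),
               ignore_attr = TRUE)
  ## everything predicted class 0
  cc0 <- confusionCounts(c(0, 0, 1, 2, 3), rep(0, 5), 4)
  expect_equal(unname(classCounts(cc0, 0)["FP"]), 3)
  ## hand-counted mixed case
  cc1 <- confusionCounts(c(0, 0, 1, 2), c(0, 1, 1, 1), 3)
  expect_equal(classCounts(cc1, 1), c(TP = 1, FP = 2, TN = 1, FN = 0),
               ignore_attr = TRUE)
  expect_error(confusionCounts(integer(0), integer(0)), "empty")
})

test_that("overall accuracy is the fraction of the diagonal", {
  cc <- confusionCounts(c(0, 1, 2, 3), c(0, 1, 2, 0), 4)
  expect_equal(overallAccuracy(cc), 0.75)
  expect_equal(overallAccuracy(confusionCounts(0:3, 0:3, 4)), 1)
  expect_equal(overallAccuracy(confusionCounts(0:3, c(1, 2, 3, 0), 4)), 0)
})

test_that("sensitivity and specificity use the standard ratios", {
  cc <- confusionCounts(c(rep(0, 5), rep(1, 10)),
                        c(rep(0, 5), rep(0, 2), rep(1, 8)), 2)
  expect_equal(sensitivity(cc, 0), 1)           # TP=5, FN=0
  expect_equal(specificity(cc, 0), 0.8)         # TN=8, FP=2
  expect_equal(accPerClass(cc, 0), sensitivity(cc, 0))
  ## empty denominator reported as missing, not zero
  ccNA <- confusionCounts(c(0, 0), c(0, 0), 2)
  expect_true(is.na(sensitivity(ccNA, 1)))
})

test_that("MCC handles the perfect, inverted and degenerate cases", {
  perfect <- confusionCounts(rep(0:1, each = 5), rep(0:1, each = 5), 2)
  expect_equal(mcc(perfect, 0), 1)
  expect_equal(mccNorm(perfect, 0), 1)
  inverted <- confusionCounts(rep(0:1, each = 5), rep(1:0, each = 5), 2)
  expect_equal(mcc(inverted, 0), -1)
  expect_equal(mccNorm(inverted, 0), 0)
  ## TP=TN=FP=FN=1
  even <- confusionCounts(c(0, 0, 1, 1), c(0, 1, 0, 1), 2)
  expect_equal(mcc(even, 0), 0)
  expect_equal(mccNorm(even, 0), 0.5)
  ## zero denominator convention
  allSame <- confusionCounts(c(0, 0), c(0, 0), 2)
  expect_equal(mcc(allSame, 0), 0)
})

test_that("figure of merit rewards balanced accuracy profiles", {
  expect_equal(fom(c(1, 1, 1, 1)), 1)
  expect_equal(fom(c(0, 0)), 0)
  expect_equal(fom(c(1, 0)), 0.25)
  ## symmetric under permutation; equals the mean when all equal
  set.seed(1)
  a <- runif(4)
  expect_equal(fom(a), fom(rev(a)))
  expect_equal(fom(rep(0.7, 5)), 0.7)
  ## bounded by the best pairwise mean
  expect_lte(fom(a), max(combn(a, 2, mean)))
  expect_error(fom(0.5), "at least 2")
})

test_that("penalized fitness trades error against subset size", {
  expect_equal(fitnessValue(penalizedFitness(1, 5, 128)), 0)
  expect_equal(fitnessValue(penalizedFitness(0.8, 48, 128)), 0.275)
  ## strictly increasing in bands for imperfect base
  fAll <- fitnessValue(penalizedFitness(0.9, 128, 128))
  fOne <- fitnessValue(penalizedFitness(0.9, 1, 128))
  expect_gt(fAll, fOne)
  ## strictly decreasing in the base metric
  expect_gt(fitnessValue(penalizedFitness(0.5, 10, 128)),
            fitnessValue(penalizedFitness(0.9, 10, 128)))
  expect_error(penalizedFitness(0.5, 200, 128), "nSelected")
})

test_that("vectorized metrics agree with the brute-force counting oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    truth <- sample(0:3, n, replace = TRUE)
    pred <- sample(0:3, n, replace = TRUE)
    cc <- confusionCounts(truth, pred, 4)
    expect_equal(overallAccuracy(cc), oracleOA(truth, pred))
    for (cl in 0:3) {
      k <- oracleCounts(truth, pred, cl)
      expect_equal(classCounts(cc, cl), k, ignore_attr = TRUE)
      sens <- if (k["TP"] + k["FN"] == 0) NA_real_
              else unname(k["TP"] / (k["TP"] + k["FN"]))
      expect_equal(sensitivity(cc, cl), sens)
      expect_equal(mcc(cc, cl), oracleMCC(k))
      expect_gte(mccNorm(cc, cl), 0)
      expect_lte(mccNorm(cc, cl), 1)
    }
    accs <- runif(4)
    expect_equal(fom(accs), oracleFoM(accs))
  }
})

test_that("overall accuracy equals the prevalence-weighted mean recall", {
  set.seed(11)
  truth <- sample(0:3, 200, replace = TRUE)
  pred <- sample(0:3, 200, replace = TRUE)
  cc <- confusionCounts(truth, pred, 4)
  w <- as.numeric(table(factor(truth, 0:3))) / 200
  recalls <- vapply(0:3, function(c) sensitivity(cc, c), numeric(1))
  expect_equal(overallAccuracy(cc), sum(w * recalls, na.rm = TRUE))
})

test_that("metricsReport assembles all scores consistently", {
  truth <- c(rep(0, 10), rep(1, 10), rep(2, 10), rep(3, 10))
  pred <- truth; pred[c(1, 11, 21, 31)] <- (truth[c(1, 11, 21, 31)] + 1) %% 4
  r <- metricsReport(confusionCounts(truth, pred, 4))
  expect_equal(r@oa, 0.9)
  expect_equal(unname(r@sensitivity), rep(0.9, 4))
  expect_equal(r@fom, 0.9)
  expect_equal(r@mccNorm, (r@mcc + 1) / 2)
  agg <- aggregateReports(list(r, r))
  expect_equal(agg$mean[agg$metric == "oa"], 0.9)
  expect_equal(agg$sd[agg$metric == "oa"], 0)
})
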