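test_that("permutation p-values follow the +1-corrected exceedance formula", {
  expect_equal(vasca:::.permPValue(5, c(1, 2, 3)), 1 / 4)
  expect_equal(vasca:::.permPValue(0, c(0, 1, 2)), 1)  # ties count as >=
  expect_equal(vasca:::.permPValue(10, rep(10, 4)), 1)
})

test_that("forced identity permutations reproduce the observed statistics", {
  tf <- randomTwoFactor(2, n.vars = 5)
  fit <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "center")
  idperm <- matrix(seq_len(nObs(tf$design)), ncol = 1)
  ps <- permutedVariableStats(fit, "A", "fratio", permutations = idperm)
  expect_equal(unname(ps[1, ]), unname(variableStatistics(fit, "A", "fratio")),
               tolerance = 1e-12)
  # every test is degenerate at p = 1 under the identity null
  expect_equal(pValue(ascaTest(fit, "A", "fratio", permutations = idperm)), 1)
  v <- vascaTest(fit, "A", "fratio", permutations = idperm)
  expect_true(all(pCurve(v) == 1))
})

test_that("a fixed seed makes every permutation procedure bit-reproducible", {
  tf <- randomTwoFactor(8, n.vars = 6)
  fit <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "center")
  plan <- permutationPlan(60, seed = 33)
  expect_identical(permutedVariableStats(fit, "A", "fratio", plan),
                   permutedVariableStats(fit, "A", "fratio", plan))
  expect_identical(pCurve(vascaTest(fit, "A", "fratio", plan)),
                   pCurve(vascaTest(fit, "A", "fratio", plan)))
  expect_identical(univariatePvalues(fit, "A", "fratio", plan),
                   univariatePvalues(fit, "A", "fratio", plan))
})

test_that("the VASCA p-curve at m = M is bit-identical to the ASCA p-value", {
  for (seed in c(3, 14, 27)) {
    tf <- randomTwoFactor(seed, n.vars = 7)
    fit <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "center")
    plan <- permutationPlan(99, seed = seed + 100)
    for (term in c("A", "B")) {
      a <- ascaTest(fit, term, "fratio", plan)
      v <- vascaTest(fit, term, "fratio", plan)
      expect_identical(pCurve(v)[7], pValue(a))
    }
  }
})

test_that("informative variables lead the ordering and are selected", {
  set.seed(21)
  n <- 10
  d <- parseDesign(data.frame(g = rep(c("a", "b"), each = 5)))
  offs <- ifelse(rep(c("a", "b"), each = 5) == "a", 3, -3)
  x <- cbind(v1 = offs + rnorm(n, sd = 0.3), v2 = -offs + rnorm(n, sd = 0.3),
             noise = rnorm(n))
  fit <- fitGLM(x, buildCoding(d), "center")
  v <- vascaTest(fit, "g", "fratio", permutationPlan(399, 5), alpha = 0.05)
  expect_setequal(v@curve@order[1:2], 1:2)
  expect_gte(v@selectedM, 2)
  expect_true(all(1:2 %in% selectedVariables(v)))
  # the observed 2-variable sub-matrix beats every permuted counterpart,
  # except shuffles that reproduce the class partition (which can only tie)
  eng <- vasca:::.nullSSQ(fit, "g", permutationPlan(399, 5))
  obs2 <- subsetStatistic(fit, "g", v@curve@order[1:2], "fratio")
  strictWins <- 0
  for (k in 1:399) {
    z <- eng$null$ssqZ$g[k, ]; e <- eng$null$ssqE[k, ]
    ord <- order(-(z / e))
    permuted2 <- (sum(z[ord[1:2]]) / eng$df[["g"]]) /
      (sum(e[ord[1:2]]) / eng$df[["residuals"]])
    expect_lte(permuted2, obs2 * (1 + 1e-9))
    strictWins <- strictWins + (permuted2 < obs2 * (1 - 1e-9))
  }
  expect_gt(strictWins / 399, 0.95)
})

test_that("the ssq statistic demands autoscaled data", {
  tf <- randomTwoFactor(4)
  fitC <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "center")
  expect_error(vascaTest(fitC, "A", "ssq"), "autoscale")
  fitA <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "autoscale")
  expect_no_error(vascaTest(fitA, "A", "ssq", permutationPlan(20, 1)))
})

test_that("univariate p-values respect boundaries and tie handling", {
  obs <- c(10, 1)
  draws <- matrix(c(1:5 / 10, rep(1, 5)), 5, 2)
  p <- vasca:::.univariateP(obs, draws, pool = FALSE)
  expect_equal(p, c(1 / 6, 1))  # above all draws; all draws tie observed
  pPool <- vasca:::.univariateP(obs, draws, pool = TRUE)
  expect_equal(pPool[1], 1 / 11)
  expect_equal(pPool[2], (5 + 1) / 11)  # five pooled draws >= 1
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(c(0.5, 0.9)), c(0.9, 0.9))
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bruteForceBH(p))
  }
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("nested permutation sets move p-values by at most the grid resolution", {
  tf <- randomTwoFactor(16, n.vars = 5)
  fit <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "center")
  set.seed(50)
  n <- nObs(tf$design)
  perms <- matrix(vapply(1:80, function(k) sample.int(n), integer(n)), n)
  pPrev <- NULL
  for (K in c(20, 40, 80)) {
    a <- ascaTest(fit, "A", "fratio", permutations = perms[, 1:K])
    count <- pValue(a) * (K + 1) - 1  # recover the exceedance count
    if (!is.null(pPrev)) expect_lte(pPrev, count)
    pPrev <- count
  }
})

test_that("fdrTest combines pooled permutation p-values with BH", {
  tf <- randomTwoFactor(23, n.vars = 6)
  fit <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "center")
  plan <- permutationPlan(50, 9)
  f <- fdrTest(fit, "A", "fratio", plan, alpha = 0.05)
  expect_equal(f@pAdjusted, bhAdjust(f@pRaw))
  expect_true(all(f@pAdjusted >= f@pRaw - 1e-12))
  expect_true(all(f@pAdjusted <= 1))
  expect_equal(selectedVariables(f), which(f@pAdjusted <= 0.05))
})
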