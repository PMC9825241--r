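test_that("preprocessing modes behave and flag degenerate columns", {
  x <- cbind(a = c(1, 3, 5, 7), b = c(2, 2, 4, 4))
  auto <- preprocessMatrix(x, "autoscale")
  expect_equal(colMeans(auto$x), c(a = 0, b = 0))
  expect_equal(apply(auto$x, 2, sd), c(a = 1, b = 1))
  expect_equal(preprocessMatrix(x, "none")$x, x)
  expect_equal(colMeans(preprocessMatrix(x, "center")$x), c(a = 0, b = 0))
  xc <- cbind(a = c(1, 3, 5), const = c(2, 2, 2))
  expect_error(preprocessMatrix(xc, "autoscale"), "const")
  expect_warning(out <- preprocessMatrix(xc, "autoscale", dropConstant = TRUE),
                 "zero-variance")
  expect_equal(colnames(out$x), "a")
})

test_that("the single-factor decomposition matches the hand computation", {
  fit <- handFit()
  expect_equal(fit@mean, 4)
  expect_equal(as.numeric(effectMatrix(fit, "g")), c(-2, -2, 2, 2))
  expect_equal(as.numeric(residuals(fit)), c(-1, 1, -1, 1))
  expect_equal(unname(fit@df), c(1, 2))
})

test_that("noise-free data reconstructs with zero residuals", {
  d <- fullFactorial(c(3, 2), 2, c("A", "B"))
  C <- buildCoding(d, c("A", "B", "A:B"))
  set.seed(4)
  theta <- matrix(rnorm(ncol(codingValues(C)) * 3), ncol(codingValues(C)), 3)
  x <- codingValues(C) %*% theta
  fit <- fitGLM(x, C, preprocess = "none")
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("decomposition reconstructs the data and satisfies Pythagoras on balanced designs", {
  for (seed in 1:5) {
    tf <- randomTwoFactor(seed)
    C <- buildCoding(tf$design, c("A", "B", "A:B"))
    fit <- fitGLM(tf$x, C, preprocess = "center")
    rec <- matrix(rep(fit@mean, each = nrow(tf$x)), nrow(tf$x)) +
      Reduce(`+`, fit@effects) + residuals(fit)
    expect_lt(max(abs(rec - fit@x)), 1e-8)
    # balanced designs: effect matrices of distinct terms are orthogonal
    expect_lt(abs(sum(effectMatrix(fit, "A") * effectMatrix(fit, "B"))), 1e-8)
    # SSQ additivity
    tot <- sum(fit@x^2)
    parts <- sum(vapply(fit@effects, function(z) sum(z^2), numeric(1))) +
      sum(residuals(fit)^2)
    expect_equal(parts, tot, tolerance = 1e-8)
  }
})

test_that("balanced fits equal the closed-form cell-means decomposition", {
  tf <- randomTwoFactor(11, n.vars = 3)
  C <- buildCoding(tf$design, c("A", "B", "A:B"))
  fit <- fitGLM(tf$x, C, preprocess = "none")
  df <- as.data.frame(tf$design)
  for (v in 1:3) {
    y <- tf$x[, v]
    mu <- mean(y)
    aEff <- tapply(y, df$A, mean) - mu
    bEff <- tapply(y, df$B, mean) - mu
    expect_equal(unname(effectMatrix(fit, "A")[, v]),
                 as.numeric(aEff[as.character(df$A)]), tolerance = 1e-8)
    expect_equal(unname(effectMatrix(fit, "B")[, v]),
                 as.numeric(bEff[as.character(df$B)]), tolerance = 1e-8)
    cellMean <- tapply(y, list(df$A, df$B), mean)
    abEff <- cellMean[cbind(as.character(df$A), as.character(df$B))] - mu -
      aEff[as.character(df$A)] - bEff[as.character(df$B)]
    expect_equal(unname(effectMatrix(fit, "A:B")[, v]), as.numeric(abEff),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient codings are rejected with the aliased term named", {
  d <- parseDesign(data.frame(g = c("a", "a", "b", "b"),
                              h = c("x", "x", "y", "y")))
  C <- buildCoding(d, c("g", "h"))  # h duplicates g
  expect_error(fitGLM(matrix(rnorm(8), 4, 2), C), "aliased")
  expect_error(fitGLM(matrix(rnorm(9), 3, 3), buildCoding(tempPhDesign())),
               "rows")
})

test_that("Type-III equals Type-I on balanced designs and differs when unbalanced", {
  fit <- handFit()
  C <- fit@coding
  expect_equal(unname(type3SSQ(cbind(y = c(1, 3, 5, 7)), C, "g", "none")), 16)
  expect_equal(unname(type3SSQ(cbind(y = c(1, 3, 5, 7)), C, "g", "none")),
               unname(colSums(effectMatrix(fit, "g")^2)))

  tf <- randomTwoFactor(7, n.vars = 4)
  C2 <- buildCoding(tf$design, c("A", "B"))
  t3 <- type3SSQ(tf$x, C2, "A", "center")
  fit2 <- fitGLM(tf$x, C2, "center")
  expect_equal(unname(t3), unname(colSums(effectMatrix(fit2, "A")^2)),
               tolerance = 1e-8)

  # drop one row: mildly unbalanced; brute-force via two explicit fits
  keep <- 2:12
  dU <- parseDesign(as.data.frame(tf$design)[keep, ],
                    levelOrder = designLevels(tf$design))
  CU <- buildCoding(dU, c("A", "B"))
  xU <- tf$x[keep, ]
  t3U <- type3SSQ(xU, CU, "A", "center")
  expect_true(all(t3U >= -1e-10))
  xc <- preprocessMatrix(xU, "center")$x
  full <- lm.fit(codingValues(CU), xc)
  red <- lm.fit(codingValues(CU)[, -codingBlocks(CU)$A, drop = FALSE], xc)
  brute <- colSums(red$residuals^2) - colSums(full$residuals^2)
  expect_equal(unname(t3U), unname(brute), tolerance = 1e-8)
  fitU <- fitGLM(xU, CU, "center")
  expect_gt(max(abs(t3U - colSums(effectMatrix(fitU, "A")^2))), 1e-6)
})

test_that("zero-effect terms give zero Type-III SSQ", {
  d <- fullFactorial(c(2, 2), 2, c("A", "B"))
  C <- buildCoding(d, c("A", "B"))
  bEff <- ifelse(as.data.frame(d)$B == "L1", 1, -1)
  x <- cbind(v = bEff)  # pure B effect, no A effect, no noise
  expect_equal(unname(type3SSQ(x, C, "A", "none")), 0, tolerance = 1e-10)
})
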