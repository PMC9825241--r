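test_that("background correlation follows the level dial", {
  x0 <- simulateBackground(40, 60, 0, seed = 2)
  r0 <- abs(cor(x0)[upper.tri(diag(60))])
  # independent normals: E|r| ~ 0.8/sqrt(N)
  expect_lt(abs(mean(r0) - 0.8 / sqrt(40)), 0.03)

  x10 <- simulateBackground(200, 60, 10, seed = 2)
  ev <- svd(scale(x10, scale = FALSE), nu = 0, nv = 0)$d^2
  expect_gt(ev[1] / sum(ev), 0.9)

  meanAbs <- function(lvl) {
    x <- simulateBackground(120, 50, lvl, seed = 7)
    mean(abs(cor(x)[upper.tri(diag(50))]))
  }
  expect_lt(meanAbs(2), meanAbs(5))
  expect_lt(meanAbs(5), meanAbs(8))

  expect_identical(simulateBackground(10, 5, 7, seed = 9),
                   simulateBackground(10, 5, 7, seed = 9))
  # unit variance by construction
  xs <- simulateBackground(5000, 8, 7, seed = 4)
  expect_equal(unname(apply(xs, 2, sd)), rep(1, 8), tolerance = 0.08)
  expect_error(simulateBackground(10, 5, 11), "corrLevel")
})

test_that("scenarios have the documented shapes, truths and determinism", {
  s1 <- generateScenario("ex1", seed = 5)
  expect_equal(dim(s1$x), c(40, 400))
  expect_length(s1$truth, 0)
  expect_length(designLevels(s1$design)$class, 2)

  s1b <- generateScenario("ex1b", seed = 5)
  expect_equal(dim(s1b$x), c(48, 400))
  expect_equal(vapply(designLevels(s1b$design), length, integer(1)),
               c(F1 = 4L, F2 = 3L))

  s2 <- generateScenario("ex2", seed = 5)
  expect_equal(s2$truth, 1:3)
  expect_equal(dim(s2$x), c(40, 400))

  s4 <- generateScenario("ex4", seed = 5)
  expect_equal(dim(s4$x), c(48, 400))
  expect_equal(s4$truth, 1:3)

  expect_identical(generateScenario("ex3", seed = 8),
                   generateScenario("ex3", seed = 8))
  expect_false(identical(generateScenario("ex3", seed = 8)$x,
                         generateScenario("ex3", seed = 9)$x))
})

test_that("ex2 biases the informative variables by twice the bias between classes", {
  diffs <- replicate(40, {
    s <- generateScenario("ex2", seed = sample.int(1e6, 1))
    cls <- as.data.frame(s$design)$class
    mean(colMeans(s$x[cls == levels(cls)[1], 1:3]) -
           colMeans(s$x[cls == levels(cls)[2], 1:3]))
  })
  expect_equal(mean(abs(diffs)), 10, tolerance = 0.5)
  # background variables carry no class signal
  s <- generateScenario("ex2", seed = 31)
  cls <- as.data.frame(s$design)$class
  gap <- colMeans(s$x[cls == levels(cls)[1], 4:400]) -
    colMeans(s$x[cls == levels(cls)[2], 4:400])
  expect_lt(max(abs(gap)), 2)
})

test_that("ex3 classes are the sign of the informative sum, with no single separating variable", {
  s <- generateScenario("ex3", seed = 13)
  cls <- as.data.frame(s$design)$class
  sums <- rowSums(s$x[, 1:3])
  expect_true(all(table(sign(sums), cls) %in%
                    c(0, as.numeric(table(cls)))))
  # each informative variable alone misclassifies some observations
  for (v in 1:3) {
    byVar <- sign(s$x[, v])
    expect_gt(min(table(byVar, cls)), 0)
  }
})

test_that("replicate seeds derive deterministically from the master seed", {
  expect_identical(vasca:::.replicateSeed(5, "ex2", 7),
                   vasca:::.replicateSeed(5, "ex2", 7))
  expect_false(vasca:::.replicateSeed(5, "ex2", 7) ==
                 vasca:::.replicateSeed(5, "ex2", 8))
  expect_false(vasca:::.replicateSeed(5, "ex2", 7) ==
                 vasca:::.replicateSeed(5, "ex4", 7))
  expect_true(vasca:::.replicateSeed(2^31 - 1, "ex4", 1000) < 2^31)
})

test_that("a one-replicate benchmark produces a structurally sound report", {
  r <- runBenchmark("ex2", c("asca", "vasca", "fdr"), reps = 1, nPerm = 1,
                    alpha = 0.5, seed = 3)
  expect_s4_class(r, "BenchmarkReport")
  expect_true(all(r@rates$value >= 0 & r@rates$value <= 1))
  expect_true(all(c("fpr", "power_ge1", "power_ge3") %in% r@rates$metric))
  expect_true(all(r@rates$value[r@rates$metric %in%
                                  c("power_ge1", "power_ge2", "power_ge3")]
                  %in% c(0, 1)))
  expect_equal(nrow(r@pcurves), 800)  # vasca + fdr curves, 400 vars each
})

test_that("benchmarks are reproducible under a master seed", {
  r1 <- runBenchmark("ex2", c("vasca", "fdr"), reps = 2, nPerm = 30,
                     alpha = 0.05, seed = 17)
  r2 <- runBenchmark("ex2", c("vasca", "fdr"), reps = 2, nPerm = 30,
                     alpha = 0.05, seed = 17)
  expect_identical(r1@rates, r2@rates)
  expect_identical(r1@pcurves, r2@pcurves)
})

test_that("asca_genes is skipped with a notice on designs without 2-df terms", {
  expect_message(
    r <- runBenchmark("ex2", c("vasca", "asca_genes"), reps = 1, nPerm = 5,
                      alpha = 0.05, seed = 2),
    "skipped")
  expect_false("asca_genes" %in% r@rates$method)
})
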