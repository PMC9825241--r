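test_that("the analysis bundle contains per-term reports and round-trips to disk", {
  set.seed(12)
  d <- tempPhDesign()
  x <- matrix(rnorm(12 * 5), 12, 5,
              dimnames = list(NULL, paste0("V", 1:5)))
  out <- withr::local_tempdir()
  bundle <- runAnalysis(x, d,
                        terms = c("temperature", "pH", "temperature:pH"),
                        nPerm = 60, alpha = 0.1, seed = 4,
                        methods = c("asca", "fdr"), bootstrapB = 0,
                        outDir = out)
  expect_named(bundle$terms, c("temperature", "pH", "temperature:pH"))
  for (t in names(bundle$terms)) {
    expect_s4_class(bundle$terms[[t]]$vasca, "VascaResult")
    expect_s4_class(bundle$terms[[t]]$asca, "AscaTestResult")
    expect_s4_class(bundle$terms[[t]]$fdr, "FdrResult")
  }
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "vasca_temperature.csv")))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(js$config$seed, 4)
  expect_equal(js$config$nPerm, 60)
})

test_that("analysis inputs are validated with descriptive errors", {
  d <- tempPhDesign()
  expect_error(runAnalysis(matrix(rnorm(10), 5, 2), d, nPerm = 5), "rows")
  expect_error(runAnalysis(matrix(rnorm(24), 12, 2), d, terms = "weight",
                           nPerm = 5), "unknown")
  expect_error(runAnalysis("/nonexistent/data.csv", d), "not found")
  expect_error(runAnalysis(matrix(rnorm(24), 12, 2), d, statistic = "ssq",
                           preprocess = "center", nPerm = 5), "autoscale")
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1:12, b = letters[1:12]), f,
                   row.names = FALSE)
  expect_error(readMatrixCSV(f), "non-numeric")
})

test_that("a CSV round-trip analysis of an ex2 dataset finds the planted variables", {
  s <- generateScenario("ex2", seed = 99)
  dataFile <- withr::local_tempfile(fileext = ".csv")
  designFile <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(s$x), dataFile, row.names = FALSE)
  utils::write.csv(as.data.frame(s$design), designFile, row.names = FALSE)
  bundle <- runAnalysis(dataFile, designFile, nPerm = 199, alpha = 0.01,
                        seed = 7, methods = c("asca", "fdr"), bootstrapB = 200)
  res <- bundle$terms$class
  expect_true(all(1:3 %in% selectedVariables(res$vasca)))
  expect_true(all(1:3 %in% selectedVariables(res$fdr)))
  # the factor is invisible to the whole-matrix test
  expect_gt(pValue(res$asca), 0.05)
  # bootstrap pruning keeps the three informative variables
  keep <- selectedVariables(res$vasca)[res$bootstrap@significant]
  expect_true(all(1:3 %in% keep))
})

test_that("p-curve export stacks methods, clamps FDR values and stays sorted", {
  tf <- randomTwoFactor(41, n.vars = 6)
  fit <- fitGLM(tf$x, buildCoding(tf$design, c("A", "B")), "center")
  plan <- permutationPlan(40, 2)
  res <- list(vasca = vascaTest(fit, "A", "fratio", plan),
              fdr = fdrTest(fit, "A", "fratio", plan),
              asca = ascaTest(fit, "A", "fratio", plan))
  tab <- exportPcurve(res)
  expect_equal(sum(tab$method == "vasca"), 6)
  expect_equal(sum(tab$method == "fdr"), 6)
  expect_equal(sum(tab$method == "asca"), 1)
  expect_true(all(tab$p <= 1))
  expect_false(is.unsorted(tab$p[tab$method == "fdr"]))
  expect_identical(tab, tab[order(tab$method, tab$m), ],
                   ignore_attr = TRUE)
  expect_equal(attr(tab, "referenceLevels"), c(0.05, 0.01))
  expect_error(exportPcurve(list()), "no VASCA")
})

test_that("re-running a bundle's embedded configuration reproduces its numbers", {
  s <- generateScenario("ex3", seed = 55)
  args <- list(data = s$x, design = s$design, nPerm = 50, alpha = 0.05,
               seed = 21, methods = "asca", bootstrapB = 0)
  b1 <- do.call(runAnalysis, args)
  cfg <- b1$config
  b2 <- runAnalysis(s$x, s$design, terms = cfg$terms,
                    statistic = cfg$statistic, preprocess = cfg$preprocess,
                    nPerm = cfg$nPerm, alpha = cfg$alpha, seed = cfg$seed,
                    methods = cfg$methods, bootstrapB = cfg$bootstrapB)
  expect_identical(pCurve(b1$terms$class$vasca), pCurve(b2$terms$class$vasca))
  expect_identical(pValue(b1$terms$class$asca), pValue(b2$terms$class$asca))
})
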