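# Multi-method benchmark over simulated scenario replicates.
#
# One replicate = one dataset + one permutation stream shared by every
# method (the permuted per-variable SSQs are computed once and each method
# consumes them), exactly the comparability protocol of the simulation
# study. Counting conventions:
#   - ASCA: FPR = fraction of null replicates with whole-matrix p <= alpha.
#   - variable-selecting methods (VASCA, VASCA+bootstrap, FDR, ASCA-genes):
#     "fpr" = fraction of non-informative variables called significant,
#     pooled over replicates (a variable inside a significant VASCA
#     sub-matrix counts as called); for VASCA on null scenarios the
#     per-dataset rate P(any significant sub-matrix) is also reported as
#     "fpr_dataset".
#   - power at >= t: fraction of replicates recovering at least t of the
#     informative variables.

# All methods' selections for one term of one fitted replicate.
.runMethodsOnce <- function(eng, decomp, term, statistic, alpha, methods,
                            bootstrapB, bootSeed) {
  out <- list()
  dfZ <- eng$df[[term]]; dfE <- eng$df[["residuals"]]
  if ("asca" %in% methods) {
    S <- (sum(eng$obs$ssqZ[[term]]) / dfZ) / (sum(eng$obs$ssqE) / dfE)
    draws <- (rowSums(eng$null$ssqZ[[term]]) / dfZ) /
      (rowSums(eng$null$ssqE) / dfE)
    out$asca <- list(p = .permPValue(S, draws))
  }
  needVasca <- any(c("vasca", "vasca_bootstrap") %in% methods)
  if (needVasca) {
    pc <- .vascaPCurve(eng, term, statistic)
    s <- .obsVariableStats(eng, term, statistic)
    ord <- .statOrder(s)
    m <- if (any(pc <= alpha)) max(which(pc <= alpha)) else 0L
    out$vasca <- list(pCurve = pc, selected = ord[seq_len(m)])
  }
  if ("fdr" %in% methods) {
    obs <- .obsVariableStats(eng, term, statistic)
    padj <- bhAdjust(.univariateP(obs, .nullVariableStats(eng, term, statistic)))
    out$fdr <- list(pAdjusted = padj, selected = which(padj <= alpha))
  }
  if ("asca_genes" %in% methods && dfZ >= 2L) {
    i <- match(term, names(eng$termMaps))
    rows <- which(eng$rowGroup == i + 1L)
    nc <- min(dfZ, 2L)
    obsLS <- .leverageSpeFromU(eng$obsCoef[rows, , drop = FALSE], nc)
    nul <- .nullLeverageSpe(eng, term, nc)
    limL <- stats::quantile(nul$leverage, 1 - alpha, names = FALSE)
    limS <- stats::quantile(nul$spe, 1 - alpha, names = FALSE)
    out$asca_genes <- list(
      selected = which(obsLS$leverage > limL | obsLS$spe > limS))
  }
  if ("vasca_bootstrap" %in% methods) {
    sel <- out$vasca$selected
    out$vasca_bootstrap <- list(selected = integer(0))
    if (length(sel)) {
      bl <- bootstrapLoadings(decomp, term, sel,
                              r = min(dfZ, length(sel)),
                              B = bootstrapB, seed = bootSeed, alpha = alpha)
      out$vasca_bootstrap$selected <- sel[bl@significant]
    }
  }
  out
}

#' Benchmark ASCA, VASCA and baselines on a simulated scenario
#'
#' Repeats a scenario `reps` times; in each replicate one dataset is
#' generated, one permutation stream is drawn, and every requested method is
#' evaluated on that shared stream. Reports false positive rates, power at
#' recovering at least 1/2/3 of the informative variables, binomial standard
#' errors, and mean ordered p-value curves.
#'
#' @param scenario scenario id (see [generateScenario()]).
#' @param methods subset of `"asca"`, `"vasca"`, `"fdr"`, `"asca_genes"`,
#'   `"vasca_bootstrap"`. ASCA-genes is skipped with a notice on terms with
#'   fewer than 2 df.
#' @param reps number of replicates.
#' @param nPerm permutations per test (K).
#' @param alpha significance level.
#' @param seed master seed; replicate r runs on a seed derived from
#'   (seed, scenario, r), so subsets of replicates reproduce in isolation.
#' @param bias effect size for ex2.
#' @param bootstrapB bootstrap resamples for `"vasca_bootstrap"`.
#' @param statistic `"fratio"` (default) or `"ssq"` (autoscales the data).
#' @param terms design factors to test (default: all).
#' @param verbose print a progress line every 100 replicates.
#' @return a [BenchmarkReport-class].
#' @export
runBenchmark <- function(scenario, methods = c("asca", "vasca", "fdr"),
                         reps = 100L, nPerm = 1000L, alpha = 0.01,
                         seed = 1L, bias = 5, bootstrapB = 1000L,
                         statistic = c("fratio", "ssq"), terms = NULL,
                         verbose = FALSE) {
  statistic <- match.arg(statistic)
  methods <- match.arg(methods, c("asca", "vasca", "fdr", "asca_genes",
                                  "vasca_bootstrap"), several.ok = TRUE)
  if (reps < 1L) stop("reps must be >= 1")
  probe <- generateScenario(scenario, seed = 1L, bias = bias)
  terms <- if (is.null(terms)) factorNames(probe$design)
  else match.arg(terms, factorNames(probe$design), several.ok = TRUE)
  truth <- probe$truth
  nVars <- ncol(probe$x)
  nNull <- nVars - length(truth)
  if ("asca_genes" %in% methods) {
    lowDf <- terms[vapply(terms, function(t)
      length(designLevels(probe$design)[[t]]) < 3L, logical(1))]
    if (length(lowDf)) {
      message("asca_genes skipped for 1-df term(s): ",
              paste(lowDf, collapse = ", "))
      if (length(lowDf) == length(terms))
        methods <- setdiff(methods, "asca_genes")
    }
  }

  hit <- function() stats::setNames(
    rep(0, length(terms)), terms)
  counts <- list()
  for (m in methods) counts[[m]] <- list(fprRep = hit(), fprVar = hit(),
                                         pow1 = hit(), pow2 = hit(),
                                         pow3 = hit())
  pcSum <- pcSqSum <- list()

  for (r in seq_len(reps)) {
    sd_r <- .replicateSeed(seed, scenario, r)
    dat <- generateScenario(scenario, seed = sd_r, bias = bias)
    decomp <- fitGLM(dat$x, buildCoding(dat$design), preprocess = "autoscale")
    plan <- permutationPlan(nPerm, sd_r)
    eng <- .nullSSQ(decomp, terms, plan)
    for (t in terms) {
      res <- .runMethodsOnce(eng, decomp, t, statistic, alpha, methods,
                             bootstrapB, bootSeed = sd_r)
      for (m in intersect(names(res), methods)) {
        sel <- res[[m]]$selected
        if (m == "asca") {
          counts$asca$fprRep[t] <- counts$asca$fprRep[t] +
            (res$asca$p <= alpha)
        } else {
          counts[[m]]$fprRep[t] <- counts[[m]]$fprRep[t] +
            (length(sel) > 0L)
          counts[[m]]$fprVar[t] <- counts[[m]]$fprVar[t] +
            length(setdiff(sel, truth))
          if (length(truth)) {
            nfound <- length(intersect(sel, truth))
            counts[[m]]$pow1[t] <- counts[[m]]$pow1[t] + (nfound >= 1L)
            counts[[m]]$pow2[t] <- counts[[m]]$pow2[t] + (nfound >= 2L)
            counts[[m]]$pow3[t] <- counts[[m]]$pow3[t] + (nfound >= 3L)
          }
        }
      }
      if (!is.null(res$vasca)) {
        key <- paste(t, "vasca", sep = ".")
        pc <- res$vasca$pCurve
        if (is.null(pcSum[[key]])) pcSum[[key]] <- pcSqSum[[key]] <- 0
        pcSum[[key]] <- pcSum[[key]] + pc
        pcSqSum[[key]] <- pcSqSum[[key]] + pc^2
      }
      if (!is.null(res$fdr)) {
        key <- paste(t, "fdr", sep = ".")
        pc <- pmin(sort(res$fdr$pAdjusted), 1)
        if (is.null(pcSum[[key]])) pcSum[[key]] <- pcSqSum[[key]] <- 0
        pcSum[[key]] <- pcSum[[key]] + pc
        pcSqSum[[key]] <- pcSqSum[[key]] + pc^2
      }
    }
    if (verbose && r %% 100L == 0L)
      message(sprintf("[%s] replicate %d/%d", scenario, r, reps))
  }

  binom <- function(k, n) {
    p <- k / n
    list(value = p, se = sqrt(pmax(p * (1 - p), 0) / n))
  }
  rows <- list()
  addRow <- function(term, method, metric, k, n) {
    b <- binom(k, n)
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, method = method, metric = metric,
      value = b$value, se = b$se, n = n)
  }
  for (m in methods) for (t in terms) {
    if (m == "asca") {
      addRow(t, m, if (length(truth)) "significant" else "fpr",
             counts$asca$fprRep[t], reps)
    } else {
      addRow(t, m, "fpr", counts[[m]]$fprVar[t], reps * nNull)
      if (!length(truth) && m %in% c("vasca", "vasca_bootstrap"))
        addRow(t, m, "fpr_dataset", counts[[m]]$fprRep[t], reps)
    }
    if (length(truth) && m != "asca") {
      addRow(t, m, "power_ge1", counts[[m]]$pow1[t], reps)
      addRow(t, m, "power_ge2", counts[[m]]$pow2[t], reps)
      addRow(t, m, "power_ge3", counts[[m]]$pow3[t], reps)
    }
  }
  pcrows <- list()
  for (key in names(pcSum)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    mu <- pcSum[[key]] / reps
    v <- pmax(pcSqSum[[key]] / reps - mu^2, 0)
    pcrows[[key]] <- data.frame(term = parts[1L], method = parts[2L],
                                m = seq_along(mu), mean = mu,
                                sd = sqrt(v * reps / max(reps - 1L, 1L)))
  }
  new("BenchmarkReport", scenario = scenario,
      rates = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      pcurves = if (length(pcrows))
        do.call(rbind, c(pcrows, list(make.row.names = FALSE)))
      else data.frame(),
      reps = as.integer(reps), nPerm = as.integer(nPerm), alpha = alpha,
      seed = as.integer(seed))
}

#' Extract one rate from a benchmark report
#' @param report a [BenchmarkReport-class].
#' @param method,metric,term row selectors; `term` defaults to the first
#'   term present.
#' @return the rate (a single number).
#' @export
benchmarkRate <- function(report, method, metric = "fpr", term = NULL) {
  r <- report@rates
  if (is.null(term)) term <- r$term[1L]
  hit <- r$method == method & r$metric == metric & r$term == term
  if (!any(hit)) stop("no such rate: ", method, "/", metric, "/", term)
  r$value[hit]
}

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport '%s': %d replicates, K = %d, alpha = %g\n",
              object@scenario, object@reps, object@nPerm, object@alpha))
  print(object@rates, row.names = FALSE, digits = 3)
})
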