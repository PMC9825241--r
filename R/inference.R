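#' Define a permutation plan
#'
#' A plan fixes K and the seed of the permutation stream. Every procedure
#' run under the same plan — [ascaTest()], [vascaTest()],
#' [univariatePvalues()], [ascaGenesTest()] — sees the identical sequence of
#' row shuffles, which makes their results directly comparable.
#'
#' @param nPerm number of permutations K (default 1000).
#' @param seed integer seed.
#' @return a [PermutationPlan-class].
#' @export
permutationPlan <- function(nPerm = 1000L, seed = 1L) {
  new("PermutationPlan", nPerm = as.integer(nPerm), seed = as.integer(seed))
}

# Statistic/preprocessing contract: the raw-SSQ statistic compares variables
# on their absolute scale, so it is only meaningful on autoscaled data.
.checkStatistic <- function(decomp, statistic) {
  if (statistic == "ssq" && !identical(decomp@preprocess$mode, "autoscale"))
    stop("the 'ssq' statistic requires autoscaled data; refit with ",
         "fitGLM(..., preprocess = \"autoscale\") or use statistic = \"fratio\"")
}

#' Per-variable statistics under row permutations
#'
#' Refits the decomposition after each of K random row shuffles of the data
#' matrix and returns the per-variable statistics of every refit. This is
#' the raw material of the ASCA, VASCA and univariate permutation tests.
#'
#' @param decomp an [AscaDecomposition-class].
#' @param term fitted term.
#' @param statistic `"fratio"` or `"ssq"` (see [variableStatistics()]).
#' @param plan a [PermutationPlan-class].
#' @param permutations optional explicit N x K permutation matrix overriding
#'   the plan's draws (testing hook; column k is the row shuffle of
#'   permutation k).
#' @return K x M numeric matrix of permuted per-variable statistics.
#' @export
permutedVariableStats <- function(decomp, term, statistic = c("fratio", "ssq"),
                                  plan = permutationPlan(),
                                  permutations = NULL) {
  statistic <- match.arg(statistic)
  .checkStatistic(decomp, statistic)
  eng <- .nullSSQ(decomp, term, plan, permutations)
  .nullVariableStats(eng, term, statistic)
}

# p-value per the +1-corrected exceedance count (ties count as >=).
.permPValue <- function(obs, draws) {
  (sum(draws >= obs) + 1) / (length(draws) + 1)
}

#' Whole-matrix ASCA permutation test
#'
#' Tests one term of the decomposition by comparing the observed
#' whole-matrix statistic with its distribution under K random row shuffles
#' of the data; p = (#\{S*_k >= S\} + 1)/(K + 1).
#'
#' @inheritParams permutedVariableStats
#' @param statistic `"fratio"`, `"ssq"`, or `"pc2ssq"` (sum of the two
#'   leading squared singular values of the effect matrix).
#' @return an [AscaTestResult-class].
#' @export
ascaTest <- function(decomp, term, statistic = c("fratio", "ssq", "pc2ssq"),
                     plan = permutationPlan(), permutations = NULL) {
  statistic <- match.arg(statistic)
  if (statistic != "pc2ssq") .checkStatistic(decomp, statistic)
  eng <- .nullSSQ(decomp, term, plan, permutations)
  if (statistic == "pc2ssq") {
    i <- match(term, names(eng$termMaps))
    rows <- which(eng$rowGroup == i + 1L)
    top2 <- function(U) {
      ev <- eigen(tcrossprod(U), symmetric = TRUE, only.values = TRUE)$values
      sum(pmax(ev, 0)[seq_len(min(2L, length(ev)))]
      )
    }
    S <- top2(eng$obsCoef[rows, , drop = FALSE])
    draws <- vapply(seq_len(eng$K), function(k)
      top2(eng$big[(k - 1L) * eng$q + rows, , drop = FALSE]), numeric(1))
  } else {
    dfZ <- eng$df[[term]]; dfE <- eng$df[["residuals"]]
    if (statistic == "ssq") {
      S <- sum(eng$obs$ssqZ[[term]])
      draws <- rowSums(eng$null$ssqZ[[term]])
    } else {
      S <- (sum(eng$obs$ssqZ[[term]]) / dfZ) / (sum(eng$obs$ssqE) / dfE)
      draws <- (rowSums(eng$null$ssqZ[[term]]) / dfZ) /
        (rowSums(eng$null$ssqE) / dfE)
    }
  }
  new("AscaTestResult", observed = S, nullDraws = as.numeric(draws),
      pValue = .permPValue(S, draws), statistic = statistic, term = term)
}

# VASCA p-curve from engine output: within each permutation the variables
# are re-ranked by their own permuted statistic before accumulating, so the
# null sub-matrix at size m is the permutation's own best-m set.
.vascaPCurve <- function(eng, term, statistic) {
  dfZ <- eng$df[[term]]; dfE <- eng$df[["residuals"]]
  K <- eng$K; M <- eng$M
  nz <- eng$null$ssqZ[[term]]; ne <- eng$null$ssqE
  ratio <- dfE / dfZ
  # all permutations at once: one two-key radix sort orders every
  # permutation's variables by decreasing statistic, then blocked cumsums
  # build the K cumulative curves without an explicit loop
  oz <- eng$obs$ssqZ[[term]]; oe <- eng$obs$ssqE
  obsOrd <- if (statistic == "ssq") order(-oz, method = "radix")
  else order(-(oz / oe), method = "radix")
  obsCum <- if (statistic == "ssq") cumsum(oz[obsOrd])
  else ratio * cumsum(oz[obsOrd]) / cumsum(oe[obsOrd])
  stat <- if (statistic == "ssq") as.vector(nz) else as.vector(nz / ne)
  o <- order(rep.int(seq_len(K), M), -stat, method = "radix")
  blockCumsum <- function(v) {
    S <- cumsum(v)
    if (K == 1L) return(S)
    base <- rep(c(0, S[seq_len(K - 1L) * M]), each = M)
    S - base
  }
  zo <- blockCumsum(as.vector(nz)[o])
  cum <- if (statistic == "ssq") zo
  else ratio * zo / blockCumsum(as.vector(ne)[o])
  mId <- rep.int(seq_len(M), K)
  hits <- cum >= obsCum[mId]
  exceed <- tabulate(mId[hits], nbins = M)
  (exceed + 1) / (K + 1)
}

#' VASCA: step-up variable selection inside the permutation test
#'
#' Ranks variables by decreasing per-variable statistic and tests every
#' nested sub-matrix of the top-m variables, m = 1..M. Crucially, within
#' each permutation the variables are re-ranked by their own permuted
#' statistics before the permuted cumulative statistic is formed, so the
#' null at size m is always "the best m variables of that shuffle" — the
#' selection mechanism itself is part of the null. The null hypothesis is
#' rejected for the largest m with p_m <= alpha; `pCurve[M]` reproduces the
#' ordinary ASCA p-value under the same plan.
#'
#' @inheritParams permutedVariableStats
#' @param alpha significance level for the selection rule.
#' @return a [VascaResult-class].
#' @export
vascaTest <- function(decomp, term, statistic = c("fratio", "ssq"),
                      plan = permutationPlan(), alpha = 0.05,
                      permutations = NULL) {
  statistic <- match.arg(statistic)
  .checkStatistic(decomp, statistic)
  eng <- .nullSSQ(decomp, term, plan, permutations)
  pc <- .vascaPCurve(eng, term, statistic)
  curve <- statCurve(decomp, term, statistic)
  sel <- which(pc <= alpha)
  m <- if (length(sel)) max(sel) else 0L
  new("VascaResult", curve = curve, pCurve = pc, selectedM = as.integer(m),
      selected = curve@order[seq_len(m)], alpha = alpha,
      nPerm = eng$K, seed = if (is.null(permutations)) plan@seed else NA_integer_)
}

#' Univariate permutation p-values
#'
#' Per-variable p-values for one term, from the same permutation stream as
#' the multivariate tests. By default the null distribution pools the
#' permuted statistics of all variables (K x M draws), which is what gives a
#' BH-corrected baseline enough resolution to reject at small alpha when K
#' is moderate; pooling is sound for scale-free statistics (the F-ratio, or
#' SSQ on autoscaled data). `pool = FALSE` compares each variable against
#' its own K draws only.
#'
#' @inheritParams permutedVariableStats
#' @param pool pool permuted statistics across variables (default TRUE).
#' @return numeric vector of per-variable p-values, each >= 1/(n_draws + 1).
#' @export
univariatePvalues <- function(decomp, term, statistic = c("fratio", "ssq"),
                              plan = permutationPlan(), pool = TRUE,
                              permutations = NULL) {
  statistic <- match.arg(statistic)
  .checkStatistic(decomp, statistic)
  eng <- .nullSSQ(decomp, term, plan, permutations)
  obs <- .obsVariableStats(eng, term, statistic)
  draws <- .nullVariableStats(eng, term, statistic)
  .univariateP(obs, draws, pool)
}

# p-values from an observed vector and a K x M draw matrix.
.univariateP <- function(obs, draws, pool = TRUE) {
  M <- length(obs)
  if (pool) {
    all <- sort(as.numeric(draws))
    n <- length(all)
    # exceedances of each observed value among all pooled draws:
    # findInterval(..., left.open) counts draws < obs, so n minus it is >=
    ge <- n - findInterval(obs, all, left.open = TRUE)
    (ge + 1) / (n + 1)
  } else {
    vapply(seq_len(M), function(v) .permPValue(obs[v], draws[, v]), numeric(1))
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: sort p ascending, q_(i) = p_(i) * M / i, enforce monotonicity
#' from the largest rank down, clamp at 1, return in the original order.
#' Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' FDR baseline: univariate permutation p-values with BH correction
#'
#' @inheritParams univariatePvalues
#' @param alpha level for the significant set.
#' @return an [FdrResult-class].
#' @export
fdrTest <- function(decomp, term, statistic = c("fratio", "ssq"),
                    plan = permutationPlan(), alpha = 0.05, pool = TRUE,
                    permutations = NULL) {
  statistic <- match.arg(statistic)
  praw <- univariatePvalues(decomp, term, statistic, plan, pool, permutations)
  padj <- bhAdjust(praw)
  new("FdrResult", pRaw = praw, pAdjusted = padj,
      significant = which(padj <= alpha), alpha = alpha, pooled = pool)
}

#' @rdname pValue
#' @export
setMethod("pValue", "AscaTestResult", function(object) object@pValue)

#' @rdname pValue
#' @export
setMethod("pValue", "FdrResult", function(object) object@pAdjusted)

#' @rdname pCurve
#' @export
setMethod("pCurve", "VascaResult", function(object) object@pCurve)

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "VascaResult", function(object) object@selected)

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "FdrResult", function(object) object@significant)

setMethod("show", "AscaTestResult", function(object) {
  cat(sprintf("ASCA permutation test, term '%s' (%s): S = %.4g, p = %.4g (K = %d)\n",
              object@term, object@statistic, object@observed, object@pValue,
              length(object@nullDraws)))
})

setMethod("show", "VascaResult", function(object) {
  cat(sprintf("VASCA, term '%s' (%s): %d/%d variables selected at alpha = %g\n",
              object@curve@term, object@curve@statistic, object@selectedM,
              length(object@pCurve), object@alpha))
  cat(sprintf("  whole-matrix p = %.4g; min p_m = %.4g at m = %d (K = %d)\n",
              object@pCurve[length(object@pCurve)], min(object@pCurve),
              which.min(object@pCurve), object@nPerm))
  if (object@selectedM > 0L)
    cat("  selected: ", paste(utils::head(object@selected, 10L), collapse = ", "),
        if (object@selectedM > 10L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "FdrResult", function(object) {
  cat(sprintf("FDR (BH) baseline: %d/%d variables at alpha = %g (%s null)\n",
              length(object@significant), length(object@pRaw), object@alpha,
              if (object@pooled) "pooled" else "per-variable"))
})
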