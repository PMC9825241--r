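#' Leverage and squared prediction error of variables in an effect matrix
#'
#' PCA-based relevance indices from multivariate statistical process
#' control, as used by the ASCA-genes screening baseline. A PCA with
#' `nComponents` components is fitted to the effect matrix Z; per variable v
#' the leverage is the summed squared loading \eqn{\sum_a P_{va}^2} and the
#' SPE is the squared reconstruction error
#' \eqn{\|Z(\cdot,v) - \hat Z(\cdot,v)\|^2}. Relevant variables are expected
#' to combine high leverage with low SPE.
#'
#' The approach needs at least two retained components, hence terms with at
#' least two degrees of freedom (a factor with >= 3 levels); for one-df
#' terms use [vascaTest()], which has no such restriction.
#'
#' @param Z effect matrix (observations x variables), e.g. from
#'   [effectMatrix()].
#' @param nComponents number of PCA components (>= 2, <= rank of Z).
#' @return list with numeric vectors `leverage` and `spe`.
#' @export
leverageSPE <- function(Z, nComponents = 2L) {
  Z <- as.matrix(Z)
  nComponents <- as.integer(nComponents)
  if (nComponents < 2L)
    stop("leverage/SPE screening needs >= 2 components (a term with >= 2 df, ",
         "i.e. a factor with at least 3 levels); for 1-df terms use vascaTest()")
  sv <- svd(Z)
  rk <- sum(sv$d > max(sv$d, 0) * 1e-10)
  if (nComponents > rk)
    stop(sprintf("nComponents = %d exceeds rank(Z) = %d", nComponents, rk))
  P <- sv$v[, seq_len(nComponents), drop = FALSE]
  lev <- rowSums(P^2)
  recon2 <- (P * matrix(sv$d[seq_len(nComponents)]^2, nrow(P), nComponents,
                        byrow = TRUE)) * P
  spe <- pmax(colSums(Z^2) - rowSums(recon2), 0)
  spe[spe < 1e-10 * max(colSums(Z^2), 0)] <- 0   # clip reconstruction dust
  list(leverage = lev, spe = as.numeric(spe))
}

#' ASCA-genes style screening with permutation control limits
#'
#' The comparison baseline for VASCA: leverage and SPE of every variable on
#' the term's effect matrix, with control limits obtained by recomputing
#' both indices on the permuted effect matrices — without any re-ranking of
#' variables — and taking the empirical (1 - alpha) quantile of the pooled
#' permutations x variables null. Variables are classified by the 2x2 rule:
#' high leverage / low SPE = relevant, high / high = poorly-modelled,
#' low / high = odd, low / low = not-relevant. Everything except
#' "not-relevant" exceeds a control limit and counts as a detection.
#'
#' @inheritParams permutedVariableStats
#' @param nComponents PCA components for the indices; default: the term's df
#'   capped at 2.
#' @param alpha level of the control limits.
#' @return a [LeverageSpeResult-class].
#' @export
ascaGenesTest <- function(decomp, term, plan = permutationPlan(),
                          nComponents = NULL, alpha = 0.01,
                          permutations = NULL) {
  dfZ <- decomp@df[[term]]
  if (is.null(nComponents)) nComponents <- min(dfZ, 2L)
  nComponents <- as.integer(nComponents)
  if (dfZ < 2L || nComponents < 2L)
    stop("leverage/SPE screening needs a term with >= 2 df ",
         "(a factor with at least 3 levels); for 1-df terms use vascaTest()")
  eng <- .nullSSQ(decomp, term, plan, permutations)
  i <- match(term, names(eng$termMaps))
  rows <- which(eng$rowGroup == i + 1L)
  obs <- .leverageSpeFromU(eng$obsCoef[rows, , drop = FALSE], nComponents)
  nul <- .nullLeverageSpe(eng, term, nComponents)
  limits <- c(leverage = as.numeric(stats::quantile(nul$leverage, 1 - alpha,
                                                    names = FALSE)),
              spe = as.numeric(stats::quantile(nul$spe, 1 - alpha,
                                               names = FALSE)))
  hiL <- obs$leverage > limits[["leverage"]]
  hiS <- obs$spe > limits[["spe"]]
  flags <- factor(ifelse(hiL & !hiS, "relevant",
                  ifelse(hiL & hiS, "poorly-modelled",
                  ifelse(!hiL & hiS, "odd", "not-relevant"))),
                  levels = c("relevant", "poorly-modelled", "odd",
                             "not-relevant"))
  new("LeverageSpeResult", leverage = obs$leverage, spe = obs$spe,
      limits = limits, flags = flags, nComponents = nComponents,
      alpha = alpha)
}

#' @rdname leverage
#' @export
setMethod("leverage", "LeverageSpeResult", function(object) object@leverage)

#' @rdname spe
#' @export
setMethod("spe", "LeverageSpeResult", function(object) object@spe)

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "LeverageSpeResult", function(object)
  which(object@flags != "not-relevant"))

setMethod("show", "LeverageSpeResult", function(object) {
  tab <- table(object@flags)
  cat(sprintf("Leverage/SPE screening (%d components, alpha = %g)\n",
              object@nComponents, object@alpha))
  cat(sprintf("  limits: leverage %.4g, SPE %.4g\n",
              object@limits[["leverage"]], object@limits[["spe"]]))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "; "), "\n")
})
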