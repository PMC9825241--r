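#' Per-variable test statistics of a fitted term
#'
#' The variable-wise building blocks of both the whole-matrix ASCA test and
#' the VASCA variable ranking:
#' \describe{
#'   \item{ssq}{\eqn{S^v = \|Z(\cdot,v)\|^2}, the effect sum of squares of
#'     variable v. Intended for autoscaled data so all variables share the
#'     same null scale.}
#'   \item{fratio}{\eqn{S^v = (SSQ_Z^v / df_Z) / (SSQ_D^v / df_D)} with D the
#'     denominator term (residuals by default); scale-free by construction.}
#' }
#'
#' @param decomp an [AscaDecomposition-class].
#' @param term fitted term to test.
#' @param statistic `"fratio"` or `"ssq"`.
#' @param denominator denominator term for the F-ratio (`"residuals"` or a
#'   fitted higher-order term).
#' @return numeric vector of length M (variables). A variable with zero
#'   denominator SSQ gets `Inf` with a warning; it still participates in
#'   ordering, and cumulative statistics stay finite because they are built
#'   from summed SSQs.
#' @examples
#' d <- parseDesign(data.frame(g = c("a", "a", "b", "b")))
#' fit <- fitGLM(cbind(y = c(1, 3, 5, 7)), buildCoding(d), preprocess = "none")
#' variableStatistics(fit, "g", "ssq")     # 16
#' variableStatistics(fit, "g", "fratio")  # (16/1)/(4/2) = 8
#' @export
variableStatistics <- function(decomp, term, statistic = c("fratio", "ssq"),
                               denominator = "residuals") {
  statistic <- match.arg(statistic)
  Z <- effectMatrix(decomp, term)
  ssqZ <- colSums(Z^2)
  if (statistic == "ssq") return(ssqZ)
  D <- effectMatrix(decomp, denominator)
  dfD <- decomp@df[[denominator]]
  if (dfD <= 0) stop("denominator term has no degrees of freedom")
  ssqD <- colSums(D^2)
  if (any(zero <- ssqD < .Machine$double.eps * nrow(Z)))
    warning(sum(zero), " variable(s) have zero denominator SSQ; F set to Inf")
  (ssqZ / decomp@df[[term]]) / (ssqD / dfD)
}

#' Sub-matrix statistic over a set of variables
#'
#' The multivariate statistic of the data sub-matrix restricted to `subset`:
#' summed SSQ, the F-ratio of summed SSQs, or (whole-matrix testing only)
#' the squared singular values of the two leading principal components of
#' the effect sub-matrix (`"pc2ssq"`).
#'
#' @inheritParams variableStatistics
#' @param subset non-empty integer vector of variable indices.
#' @param statistic `"fratio"`, `"ssq"` or `"pc2ssq"`.
#' @return a single number.
#' @export
subsetStatistic <- function(decomp, term, subset,
                            statistic = c("fratio", "ssq", "pc2ssq"),
                            denominator = "residuals") {
  statistic <- match.arg(statistic)
  subset <- as.integer(subset)
  if (length(subset) < 1L) stop("subset must be non-empty")
  Z <- effectMatrix(decomp, term)[, subset, drop = FALSE]
  if (statistic == "pc2ssq") {
    sv <- svd(Z, nu = 0, nv = 0)$d
    return(sum(sv[seq_len(min(2L, length(sv)))]^2))
  }
  ssqZ <- sum(Z^2)
  if (statistic == "ssq") return(ssqZ)
  D <- effectMatrix(decomp, denominator)[, subset, drop = FALSE]
  (ssqZ / decomp@df[[term]]) / (sum(D^2) / decomp@df[[denominator]])
}

# Shared ordering rule: decreasing statistic, ties broken by ascending
# original column index (stable radix sort on the negated values).
.statOrder <- function(s) order(-s, method = "radix")

# Cumulative curve from per-variable numerator/denominator SSQs, used by
# both the observed curve and every permutation (running sums, O(M log M)).
.cumulativeStat <- function(ssqZ, ssqE, dfZ, dfE, statistic, ord = NULL) {
  if (is.null(ord)) {
    s <- if (statistic == "ssq") ssqZ else (ssqZ / dfZ) / (ssqE / dfE)
    ord <- .statOrder(s)
  }
  if (statistic == "ssq") cumsum(ssqZ[ord])
  else (cumsum(ssqZ[ord]) / dfZ) / (cumsum(ssqE[ord]) / dfE)
}

#' Ordered cumulative-statistic curve of a term
#'
#' Sorts variables by decreasing per-variable statistic (ties broken by
#' original column index) and accumulates the sub-matrix statistic over the
#' nested sets of the top-m variables, m = 1..M. `cumulative[M]` equals the
#' whole-matrix statistic, so the curve nests the ordinary ASCA test.
#'
#' @inheritParams variableStatistics
#' @return a [StatCurve-class].
#' @export
statCurve <- function(decomp, term, statistic = c("fratio", "ssq"),
                      denominator = "residuals") {
  statistic <- match.arg(statistic)
  s <- variableStatistics(decomp, term, statistic, denominator)
  ord <- .statOrder(s)
  ssqZ <- colSums(effectMatrix(decomp, term)^2)
  ssqE <- if (statistic == "fratio")
    colSums(effectMatrix(decomp, denominator)^2) else NULL
  cum <- .cumulativeStat(ssqZ, ssqE, decomp@df[[term]],
                         decomp@df[[denominator]], statistic, ord)
  new("StatCurve", order = as.integer(ord), perVariable = s,
      cumulative = unname(cum), statistic = statistic, term = term)
}

#' StatCurve as a data.frame
#' @param x a [StatCurve-class].
#' @param ... ignored.
#' @return data.frame with rank m, variable index, per-variable statistic
#'   and cumulative sub-matrix statistic.
#' @export
setMethod("as.data.frame", "StatCurve", function(x, ...) {
  data.frame(m = seq_along(x@order), variable = x@order,
             statistic = x@perVariable[x@order], cumulative = x@cumulative)
})

setMethod("show", "StatCurve", function(object) {
  cat(sprintf("StatCurve (%s, term '%s'): %d variables; top: %s\n",
              object@statistic, object@term, length(object@order),
              paste(utils::head(object@order, 5L), collapse = ", ")))
})
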