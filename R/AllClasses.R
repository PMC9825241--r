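#' @import methods
NULL

#' DesignTable: categorical design of a multivariate experiment
#'
#' Holds one categorical factor per column, one observation per row. Levels
#' are stored as integer indices into an ordered level set per factor
#' (first-appearance order unless an explicit order was supplied at parse
#' time). The last level of each factor is the one that receives the -1
#' deviation coding in [buildCoding()].
#'
#' @slot assignments integer matrix, observations x factors; entry (n, f) is
#'   the level index of observation n on factor f.
#' @slot levels named list; one character vector of level labels per factor,
#'   in coding order.
#' @export
setClass("DesignTable",
  representation(assignments = "matrix", levels = "list"),
  validity = function(object) {
    a <- object@assignments
    lv <- object@levels
    if (!is.numeric(a)) return("assignments must be an integer matrix")
    if (nrow(a) < 2L) return("a design needs at least 2 observations")
    if (ncol(a) != length(lv)) return("one level set per factor is required")
    if (is.null(names(lv)) || any(!nzchar(names(lv))))
      return("factors must be named")
    if (!identical(colnames(a), names(lv)))
      return("assignment columns and level sets must use the same factor names")
    for (f in seq_along(lv)) {
      L <- length(lv[[f]])
      if (L < 1L) return(sprintf("factor '%s' has no levels", names(lv)[f]))
      if (anyNA(a[, f]) || any(a[, f] < 1L | a[, f] > L))
        return(sprintf("factor '%s' has out-of-range level assignments",
                       names(lv)[f]))
      if (length(unique(a[, f])) < L)
        return(sprintf("factor '%s' declares unused levels", names(lv)[f]))
    }
    TRUE
  })

#' CodingMatrix: sum/deviation-coded regressors for a design
#'
#' The regressor matrix `C = [1, C_A, C_B, C_AB, ...]` built from a
#' [DesignTable-class]. Each term (including the intercept) owns a contiguous
#' block of columns; a factor with L levels owns L-1 columns and a two-factor
#' interaction owns the element-wise products of its parents' columns.
#'
#' @slot values numeric matrix, observations x regressors.
#' @slot blocks named list of integer column indices, one per term
#'   ("(intercept)" first).
#' @slot df named integer vector: columns per term.
#' @slot design the originating [DesignTable-class] (kept for stratified
#'   resampling and reporting).
#' @export
setClass("CodingMatrix",
  representation(values = "matrix", blocks = "list", df = "integer",
                 design = "DesignTable"),
  validity = function(object) {
    v <- object@values; b <- object@blocks
    if (!identical(names(b), names(object@df)))
      return("blocks and df must name the same terms")
    idx <- unlist(b, use.names = FALSE)
    if (!identical(sort(idx), seq_len(ncol(v))))
      return("term blocks must partition the columns")
    ib <- b[["(intercept)"]]
    if (is.null(ib) || length(ib) != 1L || any(v[, ib] != 1))
      return("the intercept block must be a single all-ones column")
    TRUE
  })

#' AscaDecomposition: least-squares factorization of a data matrix
#'
#' The ASCA+ decomposition X = 1 m' + sum_terms Z_term + E, estimated by
#' regressing the (preprocessed) data on a [CodingMatrix-class].
#'
#' @slot x the preprocessed data matrix actually decomposed.
#' @slot coding the [CodingMatrix-class] used.
#' @slot mean fitted grand-mean row vector (intercept coefficients).
#' @slot coefficients full coefficient matrix Theta (regressors x variables).
#' @slot effects named list of effect matrices Z_term = C_term Theta_term.
#' @slot residuals residual matrix E.
#' @slot df named numeric: model df per term plus "residuals".
#' @slot preprocess list recording mode ("none"/"center"/"autoscale") and the
#'   fitted column centers/scales.
#' @export
setClass("AscaDecomposition",
  representation(x = "matrix", coding = "CodingMatrix", mean = "numeric",
                 coefficients = "matrix", effects = "list",
                 residuals = "matrix", df = "numeric", preprocess = "list"))

#' PermutationPlan: how many permutations, from which seed
#'
#' A plan fixes the permutation sequence: every test handed the same plan
#' (ASCA, VASCA, univariate/FDR, ASCA-genes) draws the identical sequence of
#' row shuffles, which is what makes the methods directly comparable.
#'
#' @slot nPerm number of permutations K.
#' @slot seed integer seed for the permutation stream.
#' @export
setClass("PermutationPlan",
  representation(nPerm = "integer", seed = "integer"),
  validity = function(object) {
    if (object@nPerm < 1L) return("nPerm must be >= 1")
    TRUE
  })

#' StatCurve: ordered per-variable statistics and their running totals
#'
#' Variables sorted by decreasing per-variable statistic; `cumulative[m]` is
#' the sub-matrix statistic of the m top-ranked variables, so
#' `cumulative[M]` is the whole-matrix ASCA statistic.
#'
#' @slot order integer: variable indices in decreasing-statistic order.
#' @slot perVariable per-variable statistics (original variable order).
#' @slot cumulative sub-matrix statistic at each m along `order`.
#' @slot statistic "fratio" or "ssq".
#' @slot term tested term.
#' @export
setClass("StatCurve",
  representation(order = "integer", perVariable = "numeric",
                 cumulative = "numeric", statistic = "character",
                 term = "character"))

#' AscaTestResult: whole-matrix permutation test
#'
#' @slot observed observed statistic S.
#' @slot nullDraws permuted statistics S*_k, k = 1..K.
#' @slot pValue (#\{S*_k >= S\} + 1)/(K + 1).
#' @slot statistic,term what was tested.
#' @export
setClass("AscaTestResult",
  representation(observed = "numeric", nullDraws = "numeric",
                 pValue = "numeric", statistic = "character",
                 term = "character"),
  validity = function(object) {
    K <- length(object@nullDraws)
    p <- object@pValue
    if (p < 1 / (K + 1) - 1e-12 || p > 1 + 1e-12)
      return("pValue outside [1/(K+1), 1]")
    TRUE
  })

#' VascaResult: step-up variable-selection permutation test
#'
#' @slot curve observed [StatCurve-class].
#' @slot pCurve p_m for m = 1..M (nested sub-matrices of the m top-ranked
#'   variables, null re-ranked inside every permutation).
#' @slot selectedM largest m with p_m <= alpha (0 when none).
#' @slot selected indices of the selected variables (first selectedM of the
#'   observed order).
#' @slot alpha significance level used for selection.
#' @slot nPerm,seed the permutation plan used.
#' @export
setClass("VascaResult",
  representation(curve = "StatCurve", pCurve = "numeric",
                 selectedM = "integer", selected = "integer",
                 alpha = "numeric", nPerm = "integer", seed = "integer"))

#' FdrResult: univariate permutation p-values with BH correction
#'
#' @slot pRaw per-variable permutation p-values.
#' @slot pAdjusted BH-adjusted p-values (clamped at 1).
#' @slot significant indices with adjusted p <= alpha.
#' @slot alpha level used.
#' @slot pooled whether the permutation null was pooled across variables.
#' @export
setClass("FdrResult",
  representation(pRaw = "numeric", pAdjusted = "numeric",
                 significant = "integer", alpha = "numeric",
                 pooled = "logical"))

#' LeverageSpeResult: ASCA-genes style leverage/SPE screening
#'
#' @slot leverage per-variable leverage on the retained components.
#' @slot spe per-variable squared prediction error.
#' @slot limits named numeric: permutation control limits (leverage, spe).
#' @slot flags factor per variable: relevant / poorly-modelled / odd /
#'   not-relevant (the four leverage x SPE quadrants).
#' @slot nComponents components retained.
#' @slot alpha level of the control limits.
#' @export
setClass("LeverageSpeResult",
  representation(leverage = "numeric", spe = "numeric", limits = "numeric",
                 flags = "factor", nComponents = "integer", alpha = "numeric"))

#' ComponentModel: PCA of an effect matrix
#'
#' @slot loadings variables x components, orthonormal columns.
#' @slot scores effect scores T = Z P.
#' @slot projected scores of Z + E projected on the same loadings.
#' @slot explainedSSQ squared singular value per retained component.
#' @slot variables indices of the variables modelled.
#' @export
setClass("ComponentModel",
  representation(loadings = "matrix", scores = "matrix",
                 projected = "matrix", explainedSSQ = "numeric",
                 variables = "integer"))

#' LoadingBootstrap: bootstrap significance of PCA loadings
#'
#' @slot point point-estimate loadings (variables x components).
#' @slot lower,upper percentile interval bounds per loading.
#' @slot significant logical per variable: some component's interval
#'   excludes 0.
#' @slot B number of resamples.
#' @slot alpha interval level (1 - alpha coverage).
#' @export
setClass("LoadingBootstrap",
  representation(point = "matrix", lower = "matrix", upper = "matrix",
                 significant = "logical", B = "integer", alpha = "numeric"))

#' BenchmarkReport: multi-method simulation summary
#'
#' @slot scenario scenario id.
#' @slot rates data.frame: term, method, metric, value, se, n.
#' @slot pcurves data.frame of mean/sd p-value curves per method and term
#'   (the material of the ordered p-value figures).
#' @slot reps,nPerm,alpha,seed run parameters.
#' @export
setClass("BenchmarkReport",
  representation(scenario = "character", rates = "data.frame",
                 pcurves = "data.frame", reps = "integer", nPerm = "integer",
                 alpha = "numeric", seed = "integer"))
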