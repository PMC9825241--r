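#' @rdname DesignTable-class
#' @param object,x an object.
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))

#' @rdname DesignTable-class
#' @export
setGeneric("factorNames", function(object) standardGeneric("factorNames"))

#' @rdname DesignTable-class
#' @export
setGeneric("designLevels", function(object) standardGeneric("designLevels"))

#' Effect matrix of a fitted term
#' @param object an [AscaDecomposition-class].
#' @param term term name, e.g. `"temperature"` or `"temperature:pH"`.
#' @export
setGeneric("effectMatrix", function(object, term) standardGeneric("effectMatrix"))

#' Permutation p-value(s) of a test result
#' @param object a test result object.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' The per-m p-value curve of a VASCA test
#' @param object a [VascaResult-class].
#' @export
setGeneric("pCurve", function(object) standardGeneric("pCurve"))

#' Variables selected by a test
#' @param object a [VascaResult-class] or [FdrResult-class].
#' @export
setGeneric("selectedVariables", function(object) standardGeneric("selectedVariables"))

#' PCA loadings
#' @param object a [ComponentModel-class] or [LoadingBootstrap-class].
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))

#' PCA scores
#' @param object a [ComponentModel-class].
#' @param projected if `TRUE` return the scores of Z + E projected on the
#'   effect loadings (the usual ASCA scores plot); otherwise the effect
#'   scores Z P.
#' @export
setGeneric("scores", function(object, projected = TRUE) standardGeneric("scores"))

#' Leverage of variables on a component subspace
#' @param object a [LeverageSpeResult-class].
#' @export
setGeneric("leverage", function(object) standardGeneric("leverage"))

#' Squared prediction error of variables from a component subspace
#' @param object a [LeverageSpeResult-class].
#' @export
setGeneric("spe", function(object) standardGeneric("spe"))
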