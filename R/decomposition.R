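#' Column-wise preprocessing of a measurement matrix
#'
#' `"center"` subtracts column means; `"autoscale"` additionally divides by
#' the column standard deviation (mean 0, unit variance). Autoscaling is
#' mandatory when the raw sum-of-squares statistic is used for testing, so
#' that all variables have comparable expected statistics under the null;
#' the F-ratio is scale-free and only needs centering.
#'
#' @param x numeric matrix, observations x variables (N >= 2).
#' @param mode one of `"none"`, `"center"`, `"autoscale"`.
#' @param dropConstant under autoscale, drop zero-variance columns with a
#'   warning instead of failing.
#' @return list with `x` (transformed matrix) and `spec` (list: mode,
#'   center, scale, kept column indices).
#' @examples
#' preprocessMatrix(cbind(a = c(1, 3, 5, 7)), "autoscale")$x
#' @export
preprocessMatrix <- function(x, mode = c("center", "autoscale", "none"),
                             dropConstant = FALSE) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (nrow(x) < 2L) stop("at least 2 observations are required")
  keep <- seq_len(ncol(x))
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (mode != "none") {
    center <- colMeans(x)
    x <- sweep(x, 2L, center)
  }
  if (mode == "autoscale") {
    scale <- apply(x, 2L, stats::sd)
    zero <- which(scale < .Machine$double.eps^0.5)
    if (length(zero)) {
      if (!dropConstant)
        stop("zero-variance column(s) under autoscale: ",
             paste(if (is.null(colnames(x))) zero else colnames(x)[zero],
                   collapse = ", "))
      warning("dropping ", length(zero), " zero-variance column(s)")
      keep <- setdiff(keep, zero)
      x <- x[, keep, drop = FALSE]
      center <- center[keep]; scale <- scale[keep]
    }
    x <- sweep(x, 2L, scale, "/")
  }
  list(x = x, spec = list(mode = mode, center = center, scale = scale,
                          kept = keep))
}

#' ASCA+ least-squares decomposition
#'
#' Factorizes the (preprocessed) data matrix as
#' X = 1 m' + Z_A + Z_B + ... + E by regressing X on the coding matrix C.
#' Coefficients are estimated through a QR factorization (numerically
#' equivalent to the normal-equations solution, better conditioned); each
#' term's effect matrix is Z = C_term Theta_term and E = X - C Theta.
#'
#' @param x numeric matrix, observations x variables.
#' @param coding a [CodingMatrix-class] whose rows match `x`.
#' @param preprocess preprocessing mode applied before fitting (see
#'   [preprocessMatrix()]).
#' @return an [AscaDecomposition-class].
#' @examples
#' d <- parseDesign(data.frame(g = c("a", "a", "b", "b")))
#' fit <- fitGLM(cbind(y = c(1, 3, 5, 7)), buildCoding(d), preprocess = "none")
#' effectMatrix(fit, "g")
#' @export
fitGLM <- function(x, coding, preprocess = c("center", "autoscale", "none")) {
  stopifnot(is(coding, "CodingMatrix"))
  x <- as.matrix(x)
  C <- coding@values
  if (nrow(x) != nrow(C))
    stop(sprintf("data has %d rows but the design has %d", nrow(x), nrow(C)))
  if (ncol(x) < 1L) stop("at least one variable is required")
  pp <- preprocessMatrix(x, match.arg(preprocess))
  x <- pp$x
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    d <- abs(diag(qr.R(qrC)))
    aliased <- sort(qrC$pivot[which(d < 1e-10 * max(d))])
    terms <- names(Filter(function(b) any(aliased %in% b), coding@blocks))
    stop("rank-deficient coding matrix; aliased term(s): ",
         paste(terms, collapse = ", "))
  }
  theta <- qr.coef(qrC, x)
  effects <- lapply(coding@blocks[-1L], function(b)
    C[, b, drop = FALSE] %*% theta[b, , drop = FALSE])
  resid <- x - C %*% theta
  df <- c(as.numeric(coding@df[-1L]),
          residuals = nrow(x) - qrC$rank)
  names(df)[seq_along(effects)] <- names(effects)
  new("AscaDecomposition", x = x, coding = coding,
      mean = as.numeric(theta[coding@blocks[["(intercept)"]], ]),
      coefficients = theta, effects = effects, residuals = resid,
      df = df, preprocess = pp$spec)
}

#' @rdname effectMatrix
#' @export
setMethod("effectMatrix", "AscaDecomposition", function(object, term) {
  if (identical(term, "residuals")) return(object@residuals)
  if (!term %in% names(object@effects))
    stop("term not fitted: ", term, " (available: ",
         paste(names(object@effects), collapse = ", "), ")")
  object@effects[[term]]
})

#' Residuals of an ASCA+ decomposition
#' @param object an [AscaDecomposition-class].
#' @param ... ignored.
#' @export
setMethod("residuals", "AscaDecomposition", function(object, ...) object@residuals)

#' Type-III sums of squares per variable
#'
#' For each variable, the difference between the residual sum of squares of
#' the reduced model (the term's block removed from the coding matrix) and
#' the full model. On balanced designs this equals the Type-I sum of squares
#' `colSums(Z^2)` of the term's effect matrix; on unbalanced designs they
#' differ.
#'
#' @param x data matrix (preprocessed the same way as the fit of interest).
#' @param coding a [CodingMatrix-class].
#' @param term term whose block is dropped in the reduced model.
#' @param preprocess preprocessing mode (see [fitGLM()]).
#' @return numeric vector, one nonnegative SSQ per variable.
#' @export
type3SSQ <- function(x, coding, term,
                     preprocess = c("center", "autoscale", "none")) {
  preprocess <- match.arg(preprocess)
  if (!term %in% names(coding@blocks)[-1L])
    stop("term not present in the coding matrix: ", term)
  pp <- preprocessMatrix(as.matrix(x), preprocess)
  x <- pp$x
  C <- coding@values
  full <- qr(C)
  drop <- coding@blocks[[term]]
  Cred <- C[, -drop, drop = FALSE]  # at minimum the intercept remains
  red <- qr(Cred)
  rssFull <- colSums(qr.resid(full, x)^2)
  rssRed <- colSums(qr.resid(red, x)^2)
  pmax(rssRed - rssFull, 0)
}

setMethod("show", "AscaDecomposition", function(object) {
  cat(sprintf("AscaDecomposition: %d obs x %d variables (%s)\n",
              nrow(object@x), ncol(object@x), object@preprocess$mode))
  for (t in names(object@effects))
    cat(sprintf("  %s: df=%d, SSQ=%.4g\n", t, as.integer(object@df[[t]]),
                sum(object@effects[[t]]^2)))
  cat(sprintf("  residuals: df=%d, SSQ=%.4g\n",
              as.integer(object@df[["residuals"]]),
              sum(object@residuals^2)))
})
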