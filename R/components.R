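#' PCA of an effect matrix, with projected scores
#'
#' Fits a PCA to the effect matrix of one term, restricted to a variable
#' subset (typically the VASCA selection). Loadings are the leading right
#' singular vectors; as in standard ASCA visualization, the number of
#' meaningful components is bounded by the term's degrees of freedom, and
#' the observation coordinates shown in scores plots are the projection of
#' Z + E onto the loadings.
#'
#' @param decomp an [AscaDecomposition-class].
#' @param term fitted term.
#' @param variables integer indices of the variables to model (default all).
#' @param r number of components; default `min(df, #variables)`. Truncated
#'   with a warning if it exceeds the rank of the effect sub-matrix.
#' @return a [ComponentModel-class].
#' @export
fitComponents <- function(decomp, term, variables = NULL, r = NULL) {
  Zfull <- effectMatrix(decomp, term)
  if (is.null(variables)) variables <- seq_len(ncol(Zfull))
  variables <- as.integer(variables)
  if (!length(variables)) stop("no variables to model")
  Z <- Zfull[, variables, drop = FALSE]
  dfZ <- decomp@df[[term]]
  if (is.null(r)) r <- min(dfZ, length(variables))
  sv <- svd(Z)
  rk <- sum(sv$d > max(sv$d, 0) * 1e-10)
  if (r > rk) {
    warning(sprintf("r = %d exceeds rank(Z) = %d; truncated", r, rk))
    r <- rk
  }
  if (r < 1L) stop("effect matrix has rank 0 for this term/subset")
  P <- sv$v[, seq_len(r), drop = FALSE]
  rownames(P) <- colnames(decomp@x)[variables]
  ZE <- Z + decomp@residuals[, variables, drop = FALSE]
  new("ComponentModel", loadings = P, scores = Z %*% P,
      projected = ZE %*% P, explainedSSQ = sv$d[seq_len(r)]^2,
      variables = variables)
}

#' @rdname loadings
#' @export
setMethod("loadings", "ComponentModel", function(object) object@loadings)

#' @rdname scores
#' @export
setMethod("scores", "ComponentModel", function(object, projected = TRUE)
  if (projected) object@projected else object@scores)

setMethod("show", "ComponentModel", function(object) {
  cat(sprintf("ComponentModel: %d variables, %d component(s); explained SSQ: %s\n",
              nrow(object@loadings), ncol(object@loadings),
              paste(sprintf("%.4g", object@explainedSSQ), collapse = ", ")))
})

# Align bootstrap loadings to the point estimate: greedy one-to-one match of
# components by maximal absolute congruence (inner product), then sign flip
# toward positive congruence. Required before pooling across resamples,
# where component order and sign are arbitrary.
.alignLoadings <- function(P, ref) {
  r <- ncol(ref)
  G <- crossprod(P, ref)                 # candidate x reference congruence
  out <- matrix(0, nrow(ref), r)
  usedC <- rep(FALSE, ncol(P))
  for (j in order(-apply(abs(G), 2L, max))) {
    g <- abs(G[, j]); g[usedC] <- -Inf
    i <- which.max(g)
    usedC[i] <- TRUE
    out[, j] <- P[, i] * sign(G[i, j])
  }
  out
}

#' Bootstrap significance of PCA loadings
#'
#' Resamples observations with replacement within each design cell (the
#' stratification preserves the balanced design, so the coding matrix is
#' unchanged), refits the GLM and the effect-matrix PCA on each resample,
#' aligns component order and sign to the point estimate by maximal absolute
#' congruence, and forms percentile intervals per loading. A variable whose
#' interval excludes 0 on at least one component has a loading significantly
#' different from 0; the others can be discarded a posteriori from a VASCA
#' selection.
#'
#' @inheritParams fitComponents
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed for the resampling stream.
#' @param alpha interval level: per-loading coverage 1 - alpha.
#' @return a [LoadingBootstrap-class].
#' @export
bootstrapLoadings <- function(decomp, term, variables = NULL, r = NULL,
                              B = 1000L, seed = 1L, alpha = 0.05) {
  B <- as.integer(B)
  if (B < 100L) stop("B must be >= 100")
  point <- fitComponents(decomp, term, variables, r)
  variables <- point@variables
  r <- ncol(point@loadings)
  x <- decomp@x[, variables, drop = FALSE]
  C <- decomp@coding@values
  block <- decomp@coding@blocks[[term]]
  maps <- .fitMaps(decomp@coding)
  Ct <- C[, block, drop = FALSE]
  cells <- .cellLabels(decomp@coding@design)
  byCell <- split(seq_len(nrow(x)), cells)
  draws <- array(0, c(length(variables), r, B))
  .withSeed(seed, {
    for (b in seq_len(B)) {
      # position n keeps the cell of observation n, so coding rows still match
      idx <- integer(nrow(x))
      for (i in byCell) idx[i] <- i[sample.int(length(i), length(i),
                                               replace = TRUE)]
      theta <- maps$coefMap[block, , drop = FALSE] %*% x[idx, , drop = FALSE]
      Zb <- Ct %*% theta
      svb <- svd(Zb, nv = min(r, ncol(Zb)))
      Pb <- svb$v[, seq_len(min(r, ncol(svb$v))), drop = FALSE]
      if (ncol(Pb) < r) Pb <- cbind(Pb, matrix(0, nrow(Pb), r - ncol(Pb)))
      draws[, , b] <- .alignLoadings(Pb, point@loadings)
    }
  })
  lower <- apply(draws, c(1L, 2L), stats::quantile, probs = alpha / 2,
                 names = FALSE)
  upper <- apply(draws, c(1L, 2L), stats::quantile, probs = 1 - alpha / 2,
                 names = FALSE)
  dimnames(lower) <- dimnames(upper) <- dimnames(point@loadings)
  sig <- apply(lower > 0 | upper < 0, 1L, any)
  new("LoadingBootstrap", point = point@loadings, lower = lower,
      upper = upper, significant = as.logical(sig), B = B, alpha = alpha)
}

#' @rdname loadings
#' @export
setMethod("loadings", "LoadingBootstrap", function(object) object@point)

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "LoadingBootstrap", function(object)
  which(object@significant))

setMethod("show", "LoadingBootstrap", function(object) {
  cat(sprintf("LoadingBootstrap: B = %d, %d/%d variables with loadings != 0 at %g%%\n",
              object@B, sum(object@significant), length(object@significant),
              100 * (1 - object@alpha)))
})

#' Long-format table of loadings with bootstrap intervals
#' @param x a [LoadingBootstrap-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "LoadingBootstrap", function(x, ...) {
  r <- ncol(x@point)
  data.frame(component = rep(seq_len(r), each = nrow(x@point)),
             variable = rep(if (is.null(rownames(x@point)))
               as.character(seq_len(nrow(x@point))) else rownames(x@point), r),
             loading = as.numeric(x@point),
             lower = as.numeric(x@lower), upper = as.numeric(x@upper),
             significant = rep(x@significant, r))
})
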