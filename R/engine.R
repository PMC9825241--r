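# Internal permutation engine.
#
# All permutation-based procedures (ASCA, VASCA, univariate/FDR p-values,
# ASCA-genes limits) consume the output of .nullSSQ(), which refits the GLM
# under K row shuffles of X and records per-variable effect and residual
# sums of squares. Because the coding matrix C is fixed while rows of X are
# shuffled, the refit reduces to fixed linear maps applied to permuted X:
#
#   Theta* = R^{-1} Q' X*          (QR of C, computed once)
#   SSQ_Z^v* = || G_Z Theta*_Z(.,v) ||^2,  G_Z = chol(C_Z' C_Z)
#   SSQ_E^v* = || X(.,v) ||^2 - || Q' X*(.,v) ||^2   (column norms of X are
#                                                     permutation-invariant)
#
# The maps Q' and G_Z R^{-1}[block] Q' are stacked for all K permutations
# into one tall matrix so that a single matrix product against X yields
# every refit; per-permutation sums of squares are then recovered with
# rowsum(). This keeps the 1000-permutation x 400-variable workloads of the
# simulation suite inside a few BLAS calls.

# Permutations drawn from a plan: an N x K integer matrix, column k the row
# shuffle of permutation k. A fixed seed fixes the whole sequence, which is
# the shared-draw contract across methods.
.makePermutations <- function(n, plan) {
  .withSeed(plan@seed, {
    matrix(vapply(seq_len(plan@nPerm), function(k) sample.int(n),
                  integer(n)), nrow = n)
  })
}

# Evaluate expr under a temporary RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Fixed linear maps for a decomposition: Q basis of col(C), and per-term
# whitened coefficient maps B_t (p_t x N) with rows G_t R^{-1}[block] Q'.
.fitMaps <- function(coding) {
  C <- coding@values
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("rank-deficient coding matrix")
  Q <- qr.Q(qrC)
  R <- qr.R(qrC)
  # undo any column pivoting so coefficient rows align with blocks
  piv <- qrC$pivot
  Rinv <- backsolve(R, diag(ncol(C)))[order(piv), , drop = FALSE]
  coefMap <- Rinv %*% t(Q)            # p x N: Theta = coefMap %*% X
  terms <- names(coding@blocks)[-1L]
  maps <- lapply(terms, function(t) {
    b <- coding@blocks[[t]]
    Ct <- C[, b, drop = FALSE]
    G <- chol(crossprod(Ct))
    G %*% coefMap[b, , drop = FALSE]
  })
  names(maps) <- terms
  list(Q = Q, coefMap = coefMap, termMaps = maps)
}

# Null (and observed) per-variable SSQs for every requested term plus the
# residuals, under the plan's permutations (or an explicit permutation
# matrix, the reproducibility/testing hook).
#
# Returns list(df, obs = list(ssqZ per term, ssqE), null = list(ssqZ per
# term: K x M, ssqE: K x M), maps).
.nullSSQ <- function(decomp, terms, plan = NULL, permutations = NULL) {
  x <- decomp@x
  n <- nrow(x); M <- ncol(x)
  maps <- .fitMaps(decomp@coding)
  termMaps <- maps$termMaps[terms]
  if (is.null(permutations)) permutations <- .makePermutations(n, plan)
  K <- ncol(permutations)
  colTot <- colSums(x^2)

  A <- rbind(t(maps$Q), do.call(rbind, termMaps))   # q x N
  q <- nrow(A)
  p <- ncol(maps$Q)
  rowGroup <- c(rep(1L, p),
                rep(seq_along(termMaps) + 1L,
                    vapply(termMaps, nrow, integer(1))))

  obs <- A %*% x
  obsSq <- rowsum(obs * obs, rowGroup)              # (1+nterm) x M
  obsE <- colTot - obsSq[1L, ]
  obsZ <- lapply(seq_along(termMaps), function(i) obsSq[i + 1L, ])
  names(obsZ) <- terms

  # stack permuted maps: block k holds A with columns re-indexed by the
  # inverse permutation, so bigA %*% x == rbind_k(A %*% x[perm_k, ]);
  # built with one gather + axis swap instead of a K-loop
  IP <- matrix(0L, n, K)
  IP[cbind(as.vector(permutations), rep(seq_len(K), each = n))] <-
    rep(seq_len(n), K)
  bigA <- A[, as.vector(IP), drop = FALSE]     # q x (n*K), k-major groups
  dim(bigA) <- c(q, n, K)
  bigA <- aperm(bigA, c(1L, 3L, 2L))
  dim(bigA) <- c(q * K, n)
  big <- bigA %*% x
  nt1 <- length(termMaps) + 1L
  # group sums of squared rows as one small matrix product: view big^2 as
  # (q) x (K*M) and hit it with the row-group indicator
  bigsq <- big * big
  dim(bigsq) <- c(q, K * M)
  ind <- matrix(0, nt1, q)
  ind[cbind(rowGroup, seq_len(q))] <- 1
  gs <- ind %*% bigsq                               # nt1 x (K*M), k fastest
  nullE <- matrix(colTot, K, M, byrow = TRUE) - matrix(gs[1L, ], K, M)
  nullZ <- lapply(seq_along(termMaps), function(i) matrix(gs[i + 1L, ], K, M))
  names(nullZ) <- terms

  list(df = decomp@df, M = M, K = K,
       obs = list(ssqZ = obsZ, ssqE = obsE),
       null = list(ssqZ = nullZ, ssqE = nullE),
       big = big, q = q, rowGroup = rowGroup, termMaps = termMaps,
       obsCoef = obs)
}

# Per-variable statistic matrices from engine output.
.nullVariableStats <- function(eng, term, statistic) {
  dfZ <- eng$df[[term]]; dfE <- eng$df[["residuals"]]
  if (statistic == "ssq") eng$null$ssqZ[[term]]
  else (eng$null$ssqZ[[term]] / dfZ) / (eng$null$ssqE / dfE)
}

.obsVariableStats <- function(eng, term, statistic) {
  dfZ <- eng$df[[term]]; dfE <- eng$df[["residuals"]]
  if (statistic == "ssq") eng$obs$ssqZ[[term]]
  else (eng$obs$ssqZ[[term]] / dfZ) / (eng$obs$ssqE / dfE)
}

# Leverage and SPE of the permuted (or observed) effect matrix of one term,
# from its whitened coefficients U = G_Z Theta_Z: Z = C_Z G^{-1} U with
# C_Z G^{-1} column-orthonormal, so Z and U share singular values and right
# singular vectors. Eigen-decomposing U U' (p_t x p_t) gives everything.
.leverageSpeFromU <- function(U, r) {
  cn2 <- colSums(U * U)
  if (r >= nrow(U)) {
    # all components retained: SPE is exactly 0 and the leverage is the
    # squared row norm of V = U' W S^{-1}, i.e. diag(U' (U U')^{-1} U)
    Ut <- t(U)
    lev <- rowSums((Ut %*% solve(tcrossprod(U))) * Ut)
    return(list(leverage = as.numeric(lev), spe = numeric(ncol(U))))
  }
  e <- eigen(tcrossprod(U), symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-12)
  r <- min(r, length(pos))
  if (r < 1L)
    return(list(leverage = numeric(ncol(U)), spe = cn2))
  W <- e$vectors[, pos[seq_len(r)], drop = FALSE]
  V <- crossprod(U, W)                       # M x r, columns sigma_a * v_a
  lam <- e$values[pos[seq_len(r)]]
  lev <- (V * V) %*% (1 / lam)               # sum_a v_{va}^2
  sp <- cn2 - rowSums(V * V)                 # ||U_v||^2 - sum sigma_a^2 v_va^2
  # squared reconstruction error of a retained-rank matrix is exactly 0;
  # clip the floating-point dust so downstream comparisons see true zeros
  sp[sp < 1e-10 * max(cn2)] <- 0
  list(leverage = as.numeric(lev), spe = as.numeric(pmax(sp, 0)))
}

# Leverage/SPE across all permutations for one term (K x M matrices).
# Closed-form batched paths cover the common cases (2-df term with both
# components retained; 3-df term with 2 retained); anything else falls back
# to a per-permutation eigendecomposition. Both paths agree with the SVD
# route in .leverageSpeFromU to numerical tolerance.
.nullLeverageSpe <- function(eng, term, r) {
  i <- match(term, names(eng$termMaps))
  rows <- which(eng$rowGroup == i + 1L)
  K <- eng$K; M <- eng$M; q <- eng$q
  p <- length(rows)
  rowOf <- function(j) eng$big[rep(rows[j], K) + (seq_len(K) - 1L) * q, ,
                               drop = FALSE]                     # K x M
  if (p == 2L && r >= 2L) {
    U1 <- rowOf(1L); U2 <- rowOf(2L)
    a <- rowSums(U1 * U1); b <- rowSums(U1 * U2); c <- rowSums(U2 * U2)
    det <- a * c - b * b
    lev <- (U1 * U1 * c - 2 * U1 * U2 * b + U2 * U2 * a) / det
    return(list(leverage = lev, spe = matrix(0, K, M)))
  }
  if (p == 3L && r == 2L) {
    U1 <- rowOf(1L); U2 <- rowOf(2L); U3 <- rowOf(3L)
    a11 <- rowSums(U1 * U1); a12 <- rowSums(U1 * U2); a13 <- rowSums(U1 * U3)
    a22 <- rowSums(U2 * U2); a23 <- rowSums(U2 * U3); a33 <- rowSums(U3 * U3)
    # smallest eigenvalue of each 3x3 Gram matrix (trigonometric formula)
    tr3 <- (a11 + a22 + a33) / 3
    p1 <- a12^2 + a13^2 + a23^2
    p2 <- (a11 - tr3)^2 + (a22 - tr3)^2 + (a33 - tr3)^2 + 2 * p1
    pp <- sqrt(pmax(p2, 0) / 6)
    b11 <- (a11 - tr3) / pp; b12 <- a12 / pp; b13 <- a13 / pp
    b22 <- (a22 - tr3) / pp; b23 <- a23 / pp; b33 <- (a33 - tr3) / pp
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
    l1 <- tr3 + 2 * pp * cos(phi)
    l3 <- tr3 + 2 * pp * cos(phi + 2 * pi / 3)   # smallest
    ok <- is.finite(pp) & pp > 0 & l3 > 0
    if (all(ok)) {
      # full-rank leverage via the closed-form 3x3 inverse (adjugate/det)
      detG <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
        a13 * (a12 * a23 - a22 * a13)
      i11 <- (a22 * a33 - a23^2) / detG
      i22 <- (a11 * a33 - a13^2) / detG
      i33 <- (a11 * a22 - a12^2) / detG
      i12 <- (a13 * a23 - a12 * a33) / detG
      i13 <- (a12 * a23 - a13 * a22) / detG
      i23 <- (a12 * a13 - a11 * a23) / detG
      levFull <- U1 * U1 * i11 + U2 * U2 * i22 + U3 * U3 * i33 +
        2 * (U1 * U2 * i12 + U1 * U3 * i13 + U2 * U3 * i23)
      # Cayley-Hamilton: (G - l1)(G - l2) = c w3 w3', so the quadratic form
      # U_v' (G - l1)(G - l2) U_v / c equals (U_v . w3)^2 = SPE_v
      l2 <- 3 * tr3 - l1 - l3
      cc <- (l3 - l1) * (l3 - l2)
      m11 <- (a11 - l1) * (a11 - l2) + a12 * a12 + a13 * a13
      m22 <- a12 * a12 + (a22 - l1) * (a22 - l2) + a23 * a23
      m33 <- a13 * a13 + a23 * a23 + (a33 - l1) * (a33 - l2)
      m12 <- (a11 - l1) * a12 + a12 * (a22 - l2) + a13 * a23
      m13 <- (a11 - l1) * a13 + a12 * a23 + a13 * (a33 - l2)
      m23 <- a12 * a13 + (a22 - l1) * a23 + a23 * (a33 - l2)
      sp <- (U1 * U1 * m11 + U2 * U2 * m22 + U3 * U3 * m33 +
               2 * (U1 * U2 * m12 + U1 * U3 * m13 + U2 * U3 * m23)) / cc
      sp[sp < 0] <- 0
      lev <- levFull - sp / l3
      lev[lev < 0] <- 0
      return(list(leverage = lev, spe = sp))
    }
  }
  lev <- matrix(0, K, M); sp <- matrix(0, K, M)
  for (k in seq_len(K)) {
    U <- eng$big[(k - 1L) * q + rows, , drop = FALSE]
    ls <- .leverageSpeFromU(U, r)
    lev[k, ] <- ls$leverage
    sp[k, ] <- ls$spe
  }
  list(leverage = lev, spe = sp)
}
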