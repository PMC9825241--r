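#' Correlated multivariate-normal background generator
#'
#' Draws an N x M matrix from a zero-mean multivariate normal whose
#' correlation structure is controlled by a single `corrLevel` dial between
#' 0 (independent columns) and 10 (near rank-1). The correlation matrix is
#' built as Sigma = U diag(lambda) U' with U a random orthonormal basis and
#' an eigenvalue profile that places a fraction
#' f(level) = 1/M + (level/10)^2 (0.98 - 1/M)
#' of the total variance on the leading eigenvector, the remainder decaying
#' exponentially (exp(-3 (j-2)/(M-2)) for j >= 2). Columns are standardized
#' to exact unit variance, so higher levels mean higher average absolute
#' pairwise correlation (monotone contract); level 0 gives lambda constant,
#' i.e. independent standard-normal columns, and level 10 concentrates the
#' variance so strongly that the first principal component of a generated
#' sample explains over 90% of it.
#'
#' @param nObs,nVars matrix dimensions.
#' @param corrLevel correlation level in \[0, 10\].
#' @param seed optional integer seed (the draw is a pure function of it).
#' @return numeric N x M matrix.
#' @export
simulateBackground <- function(nObs, nVars, corrLevel, seed = NULL) {
  if (corrLevel < 0 || corrLevel > 10) stop("corrLevel must be in [0, 10]")
  run <- function() {
    M <- as.integer(nVars)
    G <- matrix(stats::rnorm(nObs * M), nObs, M)
    if (corrLevel == 0 || M == 1L) return(G)
    f <- 1 / M + (corrLevel / 10)^2 * (0.98 - 1 / M)
    rest <- if (M > 2L) exp(-3 * (seq_len(M - 1L) - 1L) / (M - 2L)) else 1
    lambda <- c(f, (1 - f) * rest / sum(rest)) * M   # total variance M
    U <- qr.Q(qr(matrix(stats::rnorm(M * M), M, M), LAPACK = TRUE))
    V <- U * matrix(sqrt(lambda), M, M, byrow = TRUE)   # Sigma = V V'
    X <- G %*% t(V)
    sdv <- sqrt(rowSums(V^2))                           # true column sds
    sweep(X, 2L, sdv, "/")
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

# Scenario parameter table. Single-factor examples use 40 observations x 400
# variables with a binary class factor; two-factor examples use a balanced
# 4 x 3 full factorial with 4 replicates (48 rows).
.scenarioIds <- c("ex1", "ex1b", "ex2", "ex3", "ex4")

#' Generate one simulated dataset of the benchmark scenarios
#'
#' The five scenarios of the simulation study:
#' \describe{
#'   \item{ex1}{Null, single factor: X is a 40 x 400 correlated background
#'     (level 7); the binary class is the sign of independent N(0,1) draws,
#'     so design and data are unrelated. No informative variables.}
#'   \item{ex1b}{Null, two factors: 48 x 400 background (level 7),
#'     independent of a 4 x 3 full factorial with 4 replicates.}
#'   \item{ex2}{One-to-one associations: variables 1-3 are N(0,1) plus
#'     `bias` times the class code (+1/-1 deviation coding); variables 4-400
#'     are background (level 7). `bias = 5` is the strong version, 0.5 the
#'     weak one.}
#'   \item{ex3}{Additive multivariate association: variables 1-3 are N(0,1)
#'     and the class is the sign of their sum, so no single variable
#'     separates the classes; 397 background variables.}
#'   \item{ex4}{Two factors, 4 x 3 full factorial, 4 replicates: variables
#'     1-3 carry 0.5 x a random level effect per factor plus a correlated
#'     4 x 3 cell-noise block (level 8) shared by the cell's replicates;
#'     397 background variables (level 7).}
#' }
#'
#' @param scenario one of `"ex1"`, `"ex1b"`, `"ex2"`, `"ex3"`, `"ex4"`.
#' @param seed integer seed; the dataset is a pure function of it.
#' @param bias effect size for ex2 (default 5).
#' @return list with `x` (data matrix), `design` ([DesignTable-class]),
#'   `truth` (indices of the informative variables, empty for the null
#'   scenarios).
#' @export
generateScenario <- function(scenario = .scenarioIds, seed = 1L, bias = 5) {
  scenario <- match.arg(scenario)
  .withSeed(seed, {
    if (scenario %in% c("ex1", "ex2", "ex3")) {
      n <- 40L; M <- 400L
      if (scenario == "ex1") {
        x <- simulateBackground(n, M, 7)
        cls <- sign(stats::rnorm(n))
        truth <- integer(0)
      } else if (scenario == "ex2") {
        cls <- sign(stats::rnorm(n))
        info <- matrix(stats::rnorm(n * 3L), n, 3L) + bias * cls
        x <- cbind(info, simulateBackground(n, M - 3L, 7))
        truth <- 1:3
      } else {
        info <- matrix(stats::rnorm(n * 3L), n, 3L)
        x <- cbind(info, simulateBackground(n, M - 3L, 7))
        cls <- sign(rowSums(info))
        if (any(cls == 0)) cls[cls == 0] <- 1
        truth <- 1:3
      }
      design <- parseDesign(
        data.frame(class = ifelse(cls > 0, "pos", "neg")))
    } else {
      design <- fullFactorial(c(4L, 3L), 4L)
      n <- nObs(design); M <- 400L
      l1 <- design@assignments[, 1L]; l2 <- design@assignments[, 2L]
      if (scenario == "ex1b") {
        x <- simulateBackground(n, M, 7)
        truth <- integer(0)
      } else {
        info <- matrix(0, n, 3L)
        for (i in 1:3) {
          v1 <- stats::rnorm(4L); v2 <- stats::rnorm(3L)
          cellNoise <- simulateBackground(4L, 3L, 8)
          info[, i] <- cellNoise[cbind(l1, l2)] + 0.5 * v1[l1] + 0.5 * v2[l2]
        }
        x <- cbind(info, simulateBackground(n, M - 3L, 7))
        truth <- 1:3
      }
    }
    colnames(x) <- paste0("V", seq_len(ncol(x)))
    list(x = x, design = design, truth = truth)
  })
}

# Deterministic per-replicate seed from a master seed (kept < 2^31 so it is
# a valid R integer); lets any subset of replicates be reproduced alone.
.replicateSeed <- function(master, scenario, rep) {
  m0 <- as.numeric(master) %% 1e6
  off <- match(scenario, .scenarioIds, nomatch = 0L)
  as.integer((m0 * 2147483 + off * 1009 + as.numeric(rep) * 7919) %%
               2147483647) + 1L
}
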