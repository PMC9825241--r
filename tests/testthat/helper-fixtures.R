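# Shared fixtures, all built in code.

# The 12-row temperature x pH design (3 x 2 levels, duplicated rows) whose
# coding matrix is the package's worked reference example.
tempPhDesign <- function() {
  parseDesign(data.frame(
    temperature = rep(rep(c("10C", "20C", "30C"), each = 2), 2),
    pH = rep(c("4.0", "6.0"), each = 6)))
}

# Tiny single-factor dataset with a hand-computable decomposition:
# cell means 2 and 6, grand mean 4.
handFit <- function() {
  d <- parseDesign(data.frame(g = c("a", "a", "b", "b")))
  fitGLM(cbind(y = c(1, 3, 5, 7)), buildCoding(d), preprocess = "none")
}

# Random balanced two-factor dataset for property tests.
randomTwoFactor <- function(seed, n.vars = 6, levels = c(3, 2), reps = 2) {
  set.seed(seed)
  d <- fullFactorial(levels, reps, c("A", "B"))
  x <- matrix(rnorm(nObs(d) * n.vars), nObs(d), n.vars)
  colnames(x) <- paste0("V", seq_len(n.vars))
  list(design = d, x = x)
}

# Brute-force BH step-up, the independent oracle for bhAdjust().
bruteForceBH <- function(p) {
  M <- length(p)
  o <- order(p)
  q <- p[o] * M / seq_len(M)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(M)
  out[o] <- q
  out
}
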