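## Independent oracles used across the suite.  Deliberately avoid the
## package's multivariate-normal path: sequential stopping probabilities are
## recomputed by brute-force recursive grid quadrature on the score scale,
## and randomization path probabilities by exhaustive enumeration with a
## self-contained transition rule.

## Per-stage efficacy-crossing probabilities of a group sequential rule via
## density propagation.  The statistics Z_k (corr sqrt(u_j/u_k), means mu)
## correspond to a process B_k = sqrt(u_k) Z_k with independent increments;
## the continuation density is pushed through each stage on a trapezoid grid.
oracle_stage_probs <- function(a, b, u, mu, grid_n = 1501) {
  K <- length(u)
  mB <- mu * sqrt(u)
  bB <- b * sqrt(u)
  aB <- ifelse(is.finite(a), a * sqrt(u), -Inf)
  eff <- numeric(K)
  lo <- max(aB[1], mB[1] - 8.5 * sqrt(u[1]))
  hi <- min(bB[1], mB[1] + 8.5 * sqrt(u[1]))
  eff[1] <- pnorm(bB[1], mB[1], sqrt(u[1]), lower.tail = FALSE)
  if (K == 1) return(eff)
  x <- seq(lo, hi, length.out = grid_n)
  w <- rep(diff(x)[1], grid_n); w[c(1, grid_n)] <- w[1] / 2
  f <- dnorm(x, mB[1], sqrt(u[1]))
  for (k in 2:K) {
    dv <- u[k] - u[k - 1]
    dm <- mB[k] - mB[k - 1]
    eff[k] <- sum(w * f * pnorm(bB[k], x + dm, sqrt(dv), lower.tail = FALSE))
    if (k == K) break
    lo2 <- max(aB[k], min(x) + dm - 8.5 * sqrt(dv))
    hi2 <- min(bB[k], max(x) + dm + 8.5 * sqrt(dv))
    x2 <- seq(lo2, hi2, length.out = grid_n)
    w2 <- rep(diff(x2)[1], grid_n); w2[c(1, grid_n)] <- w2[1] / 2
    f2 <- vapply(x2, function(xx) sum(w * f * dnorm(xx, x + dm, sqrt(dv))), 0)
    x <- x2; w <- w2; f <- f2
  }
  eff
}

oracle_reject <- function(a, b, u, mu, grid_n = 1501)
  sum(oracle_stage_probs(a, b, u, mu, grid_n))

## Exhaustive path enumeration for the probability that the first s patients
## all land in one arm.  Transition probabilities are written out here,
## independent of the package's allocation-law code.
oracle_single_group <- function(kind, s, n = NULL, p = NULL, m = NULL, l = NULL) {
  prob_next_E <- function(nE, nC, blkE, blkN) {
    D <- nE - nC
    switch(kind,
      cr = 0.5,
      rar = (n / 2 - nE) / (n - nE - nC),
      pbr = (l / 2 - blkE) / (l - blkN),
      ebc = if (D == 0) 0.5 else if (D < 0) p else 1 - p,
      bsd = if (D <= -m) 1 else if (D >= m) 0 else 0.5,
      chen = if (D <= -m) 1 else if (D >= m) 0
             else if (D == 0) 0.5 else if (D < 0) p else 1 - p)
  }
  total <- 0
  recurse <- function(depth, nE, nC, blkE, blkN, pr) {
    if (pr == 0) return()
    if (depth == s) {
      if (nE == s || nC == s) total <<- total + pr
      return()
    }
    pE <- prob_next_E(nE, nC, blkE, blkN)
    nb <- blkN + 1; if (!is.null(l) && nb == l) nb <- 0
    eb <- if (nb == 0) 0 else blkE
    recurse(depth + 1, nE + 1, nC, if (nb == 0) 0 else blkE + 1, nb, pr * pE)
    recurse(depth + 1, nE, nC + 1, eb, nb, pr * (1 - pE))
  }
  recurse(0, 0, 0, 0, 0, 1)
  total
}

## Frequently used fixtures
balanced_alloc <- function(n = 24, K = 3) {
  per <- n / K / 2
  summarize_stages(rep(rep(1:0, K), rep(per, 2 * K)), stage_plan(n, K))
}

## the worked 24-patient example: stages allocate 6:2, 5:3, 2:6
fig_alloc <- function()
  summarize_stages(rep(rep(1:0, 3), c(6, 2, 5, 3, 2, 6)), stage_plan(24, 3))
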