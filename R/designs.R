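#' Alpha spending functions
#'
#' Cumulative one-sided type I error spent by information fraction `t`.
#' Two standard shapes are provided: the O'Brien-Fleming-like spending
#' function \eqn{\alpha(t) = 2\{1 - \Phi(z_{1-\alpha/2}/\sqrt{t})\}} and the
#' Pocock-like spending function \eqn{\alpha(t) = \alpha \log\{1 + (e-1)t\}}.
#' Both satisfy \eqn{\alpha(0) = 0} and \eqn{\alpha(1) = \alpha} and are
#' non-decreasing on \eqn{[0, 1]}.
#'
#' @param kind `"obf"` or `"pocock"`.
#' @param alpha One-sided significance level.
#' @param t Information fraction(s) in \eqn{[0, 1]}.
#' @return Cumulative alpha spent at `t` (vectorised).
#' @examples
#' spending_value("pocock", 0.025, 0.5)
#' spending_value("obf", 0.025, 1/3)
#' @export
spending_value <- function(kind = c("obf", "pocock"), alpha, t) {
  kind <- match.arg(kind)
  stopifnot(alpha > 0, alpha < 1)
  if (any(t < 0 | t > 1)) stop("'t' must lie in [0, 1]", call. = FALSE)
  switch(kind,
    obf = ifelse(t == 0, 0,
                 2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)))),
    pocock = alpha * log(1 + (exp(1) - 1) * t))
}

## ---- internal sequential crossing machinery ---------------------------------

## deterministic multivariate-normal quadrature; Miwa is exact quadrature and
## reproducible bit-for-bit, unlike the quasi-Monte-Carlo default
.mvn_alg <- function(K) mvtnorm::Miwa(steps = if (K <= 3L) 512L else 128L)

## rectangle probability with infinite limits clamped to +/-35 standard
## deviations (below quadrature accuracy; silences Miwa's Inf approximation)
.pmv <- function(lower, upper, mean, corr) {
  as.numeric(mvtnorm::pmvnorm(
    lower = pmax(lower, mean - 35), upper = pmin(upper, mean + 35),
    mean = mean, corr = corr, algorithm = .mvn_alg(length(mean)),
    keepAttr = FALSE))
}

## P(a_i <= Z_i < b_i for i < k, Z_k >= b_k) under N(mu, corr)
seq_cross_prob <- function(k, a, b, corr, mu) {
  if (k == 1L) return(stats::pnorm(b[1L], mean = mu[1L], lower.tail = FALSE))
  lw <- c(a[seq_len(k - 1L)], b[k])
  up <- c(b[seq_len(k - 1L)], Inf)
  fin <- is.finite(b[seq_len(k - 1L)]) | is.finite(a[seq_len(k - 1L)])
  fin <- c(fin, TRUE)
  if (sum(fin) == 1L)   # earlier stages unconstrained
    return(stats::pnorm(b[k], mean = mu[k], lower.tail = FALSE))
  idx <- which(fin)
  .pmv(lw[idx], up[idx], mu[idx], corr[idx, idx, drop = FALSE])
}

## correlation matrix sqrt(u_j / u_k) for j <= k, u increasing
corr_from_u <- function(u) {
  K <- length(u)
  outer(seq_len(K), seq_len(K),
        function(i, j) sqrt(pmin(u[i], u[j]) / pmax(u[i], u[j])))
}

## Solve stage-wise efficacy bounds so each stage's crossing probability under
## the null equals the incremental spend pi_k, with continuation regions
## truncated below at a_k (binding futility) or unbounded (a_k = -Inf).
solve_bounds_spend <- function(pi_k, fractions, a = NULL) {
  K <- length(pi_k)
  corr <- corr_from_u(fractions)
  if (is.null(a)) a <- rep(-Inf, K)
  mu0 <- rep(0, K)
  b <- rep(Inf, K)
  for (k in seq_len(K)) {
    if (pi_k[k] < 1e-13) next
    f <- function(x) { bb <- b; bb[k] <- x; seq_cross_prob(k, a, bb, corr, mu0) - pi_k[k] }
    lo <- if (is.finite(a[k])) a[k] + 1e-9 else stats::qnorm(1 - pi_k[k]) - 1
    if (f(lo) < 0)
      stop("stage ", k, ": infeasible incremental spend (",
           signif(pi_k[k], 4), ") given the futility bound", call. = FALSE)
    b[k] <- stats::uniroot(f, c(lo, 12), tol = 1e-9)$root
  }
  b
}

## classic shapes: b_k = c * shape_k with overall crossing probability alpha
solve_bounds_classic <- function(alpha, K, shape) {
  corr <- corr_from_u(seq_len(K))
  a <- rep(-Inf, K); mu0 <- rep(0, K)
  f <- function(cc) {
    b <- cc * shape
    sum(vapply(seq_len(K), function(k) seq_cross_prob(k, a, b, corr, mu0), 0)) - alpha
  }
  cc <- stats::uniroot(f, c(stats::qnorm(1 - alpha) / max(shape), 8),
                       extendInt = "downX", tol = 1e-9)$root
  cc * shape
}

## incremental spends from a spending shape at given fractions; the final
## analysis always spends the remaining alpha, so the overall level is met
## even when imbalance leaves the final information fraction below 1
incremental_spend <- function(spending, alpha, fractions) {
  cum <- spending_value(spending, alpha, pmin(fractions, 1))
  cum[length(cum)] <- alpha
  pi_k <- diff(c(0, cum))
  if (any(pi_k < -1e-12))
    stop("spending produced a negative incremental spend; check that the ",
         "information fractions are increasing", call. = FALSE)
  pmax(pi_k, 0)
}

#' Construct a group sequential design with solved boundaries
#'
#' Builds the full description of a one-sided two-arm group sequential design
#' and solves its efficacy boundaries on the standard normal scale.  Four
#' families are supported:
#'
#' * `method = "classic"`: the original Pocock (`boundary = "pocock"`,
#'   constant bounds \eqn{b_k = c}) or O'Brien-Fleming (`boundary = "obf"`,
#'   \eqn{b_k = c\sqrt{K/k}}) designs, which assume equally sized stages;
#' * `method = "ldm"`: Lan-DeMets alpha-spending boundaries with an
#'   OBF-like or Pocock-like spending function evaluated at the design's
#'   information fractions;
#' * `method = "inct"`: the inverse normal combination test, which combines
#'   stage-wise statistics with fixed `weights` and compares the combined
#'   statistics against pre-planned boundaries -- spending-based by default,
#'   or classic-shaped with `classic_bounds = TRUE`.
#'
#' With `futility = "binding"` the efficacy bounds are re-solved with the
#' continuation regions truncated below at the futility bounds, which lowers
#' them; with `"nonbinding"` the efficacy bounds are those of the
#' no-futility design and the futility bounds enter only the evaluation of
#' power and type I error.
#'
#' @param K Number of stages.
#' @param n Maximum sample size.
#' @param alpha One-sided significance level.
#' @param method `"ldm"`, `"inct"` or `"classic"`.
#' @param boundary Boundary shape / spending type, `"obf"` or `"pocock"`.
#' @param plan Optional [stage_plan()]; defaults to `K` equal stages.
#' @param fractions Optional information fractions for boundary solving;
#'   default is the planned balanced schedule `cumsum(sizes)/n`.
#' @param futility `"none"`, `"binding"` or `"nonbinding"`.
#' @param futility_bounds Interim futility bounds \eqn{a_1,\dots,a_{K-1}} on
#'   the z scale (e.g. `rep(0, K - 1)` to stop on any negative trend).
#' @param weights INCT stage weights; default equal. Only the relative sizes
#'   matter (they are normalised internally).
#' @param classic_bounds For `method = "inct"`: use classic-shaped bounds
#'   rather than spending-based ones.
#' @param test `"z"` (known variance 1) or `"t"` (pooled-variance t-test
#'   with quantile-substituted boundaries).
#'
#' @return An object of class `"gs_design"`; its `$bounds` data frame holds
#'   per-stage information fractions, futility and efficacy bounds and
#'   incremental spends.
#'
#' @examples
#' gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
#' gs_design(K = 3, n = 24, method = "ldm", boundary = "obf",
#'           futility = "binding", futility_bounds = c(0, 0))
#' @export
gs_design <- function(K, n, alpha = 0.025,
                      method = c("ldm", "inct", "classic"),
                      boundary = c("obf", "pocock"),
                      plan = NULL, fractions = NULL,
                      futility = c("none", "binding", "nonbinding"),
                      futility_bounds = NULL,
                      weights = NULL, classic_bounds = FALSE,
                      test = c("z", "t")) {
  method <- match.arg(method); boundary <- match.arg(boundary)
  futility <- match.arg(futility); test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1, K >= 1)
  if (is.null(plan)) plan <- stage_plan(n, K)
  stopifnot(inherits(plan, "stage_plan"), plan$K == K, plan$n == n)
  if (is.null(fractions)) fractions <- plan$cumulative / n
  stopifnot(length(fractions) == K, all(diff(c(0, fractions)) > 0))

  if (futility == "none") {
    if (!is.null(futility_bounds))
      stop("'futility_bounds' given but futility = \"none\"", call. = FALSE)
    a <- rep(-Inf, K)
  } else {
    if (K < 2L) stop("interim futility needs K >= 2", call. = FALSE)
    if (is.null(futility_bounds) || length(futility_bounds) != K - 1L)
      stop("'futility_bounds' must have length K - 1", call. = FALSE)
    a <- c(futility_bounds, -Inf)
  }
  if (method == "inct") {
    if (is.null(weights)) weights <- rep(1, K)
    stopifnot(length(weights) == K, all(weights > 0))
    weights <- weights / sqrt(sum(weights^2))
  } else if (!is.null(weights)) {
    stop("'weights' are a parameter of the inverse normal combination test only",
         call. = FALSE)
  }

  ## boundary fractions: INCT bounds are pre-planned, solved at the planned
  ## schedule no matter what is observed later; classic designs assume equal
  ## information steps by construction
  solve_fracs <- if (method == "classic") seq_len(K) / K else fractions

  if (method == "classic" || (method == "inct" && classic_bounds)) {
    shape <- if (boundary == "obf") sqrt(K / seq_len(K)) else rep(1, K)
    if (futility == "binding")
      stop("binding futility with classic-shaped bounds is not supported; ",
           "use spending-based bounds", call. = FALSE)
    b <- solve_bounds_classic(alpha, K, shape)
    pi_k <- stage_spends(b, a = rep(-Inf, K), solve_fracs)
  } else {
    pi_k <- incremental_spend(boundary, alpha, solve_fracs)
    b <- solve_bounds_spend(pi_k, solve_fracs,
                            a = if (futility == "binding") a else NULL)
  }

  df <- NULL; tb <- NULL; ta <- NULL
  if (test == "t") {
    df <- planned_df(plan, method)
    tb <- quantile_substitute(b, df)
    ta <- quantile_substitute(a, df)
  }

  structure(list(K = K, n = n, alpha = alpha, method = method,
                 boundary = boundary, plan = plan, fractions = fractions,
                 futility = futility, a = a, b = b, spend = pi_k,
                 weights = weights, classic_bounds = isTRUE(classic_bounds),
                 test = test, df = df, t_bounds = tb, t_futility = ta,
                 bounds = data.frame(stage = seq_len(K),
                                     fraction = solve_fracs,
                                     futility = a, efficacy = b,
                                     spend = pi_k)),
            class = "gs_design")
}

## per-stage null crossing probabilities of a given boundary set
stage_spends <- function(b, a, fractions) {
  K <- length(b)
  corr <- corr_from_u(fractions)
  vapply(seq_len(K),
         function(k) seq_cross_prob(k, a, b, corr, rep(0, K)), 0)
}

## planned degrees of freedom for the t-test: cumulative pooled df for
## cumulative-statistic families, stage-wise df for the INCT
planned_df <- function(plan, method) {
  if (method == "inct") plan$sizes - 2L else plan$cumulative - 2L
}

#' Quantile substitution of z-scale boundaries to the t scale
#'
#' Converts standard-normal boundary values into t-statistic boundaries by
#' matching tail probabilities: the stage-`k` t bound is the central-t
#' quantile with `df[k]` degrees of freedom at \eqn{\Phi(b_k)}.  For finite
#' df the t bound exceeds the z bound; as df grows it converges to it.
#'
#' @param b Numeric vector of z-scale bounds (`-Inf`/`Inf` pass through).
#' @param df Degrees of freedom per stage (recycled).
#' @return t-scale bounds.
#' @examples
#' quantile_substitute(qnorm(0.975), df = 10)  # 2.2281
#' @export
quantile_substitute <- function(b, df) {
  if (any(df <= 0)) stop("'df' must be positive", call. = FALSE)
  df <- rep_len(df, length(b))
  out <- b
  fin <- is.finite(b)
  ## matched tail probability, computed in the tail to preserve precision
  out[fin] <- stats::qt(stats::pnorm(b[fin], lower.tail = FALSE),
                        df = df[fin], lower.tail = FALSE)
  out
}

#' @export
print.gs_design <- function(x, ...) {
  lab <- switch(x$method,
    classic = sprintf("classic %s", if (x$boundary == "obf") "O'Brien-Fleming" else "Pocock"),
    ldm = sprintf("Lan-DeMets, %s-type spending",
                  if (x$boundary == "obf") "O'Brien-Fleming" else "Pocock"),
    inct = sprintf("inverse normal combination test, %s %s-type bounds",
                   if (x$classic_bounds) "classic" else "spending-based",
                   if (x$boundary == "obf") "O'Brien-Fleming" else "Pocock"))
  cat("Group sequential design (one-sided ", x$test, "-test, alpha = ",
      x$alpha, ")\n", sep = "")
  cat("  ", lab, "\n", sep = "")
  cat("  n = ", x$n, ", stages = ", paste(x$plan$sizes, collapse = "/"),
      if (x$futility != "none") paste0(", ", x$futility, " futility"), "\n",
      sep = "")
  df <- x$bounds
  if (x$test == "t") df$t_efficacy <- x$t_bounds
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.gs_design <- function(object, ...) {
  cat(sprintf("Total spend %.6f of alpha = %.6f\n",
              sum(object$spend), object$alpha))
  print(object)
}

#' @export
as.data.frame.gs_design <- function(x, ...) x$bounds
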