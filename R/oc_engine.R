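#' Statistical information of a two-sample comparison
#'
#' Inverse variance of the difference in arm means for unit-variance normal
#' outcomes: \eqn{(1/n_E + 1/n_C)^{-1}}.  For a fixed total it is maximised
#' at balance, which is why imbalanced allocations carry less information
#' than the planned 1:1 split.
#'
#' @param nE,nC Patients per arm (vectorised; both must be at least 1).
#' @return Information in units of inverse variance.
#' @examples
#' information(4, 4)   # 2
#' information(6, 2)   # 1.5: the imbalanced first stage of the worked example
#' @export
information <- function(nE, nC) {
  if (any(nE < 1 | nC < 1))
    stop("information is undefined when an arm has no patients", call. = FALSE)
  1 / (1 / nE + 1 / nC)
}

#' Joint law of the stage-wise decision statistics for one sequence
#'
#' Given the observed stage allocations, returns the mean vector and the
#' correlation structure of the \eqn{K} statistics that are compared to the
#' boundaries.
#'
#' For cumulative-statistic families (classic and Lan-DeMets) the statistic
#' at analysis \eqn{k} is the z statistic of all data so far, with mean
#' \eqn{\delta\sqrt{I_k}} and \eqn{corr(Z_j, Z_k) = \sqrt{I_j/I_k}} where
#' \eqn{I_k} is the cumulative information.  For the inverse normal
#' combination test the statistic is
#' \eqn{C_k = \sum_{i\le k} w_i Z^*_i / \sqrt{W_k}} with stage-wise
#' statistics \eqn{Z^*_i}, \eqn{W_k = \sum_{i\le k} w_i^2}; its mean is
#' \eqn{\sum_{i\le k} w_i \delta \sqrt{\tilde I_i} / \sqrt{W_k}} and
#' \eqn{corr(C_j, C_k) = \sqrt{W_j/W_k}} because stage increments are
#' independent.  Under exact stage balance and equal weights the two laws
#' coincide.
#'
#' @param alloc A [summarize_stages()] result.
#' @param method `"cumulative"` or `"inct"`.
#' @param delta Standardised effect \eqn{\mu_E - \mu_C} (common variance 1);
#'   0 gives the null law.
#' @param weights INCT weights (any positive scale); default equal.
#'
#' @return A list of class `"joint_law"` with `mu`, `u` (the variance-scale
#'   sequence whose ratios give the correlations), `corr` and `info`.
#' @export
joint_law <- function(alloc, method = c("cumulative", "inct"), delta = 0,
                      weights = NULL) {
  stopifnot(inherits(alloc, "stage_alloc"))
  method <- match.arg(method)
  K <- alloc$plan$K
  if (method == "cumulative") {
    if (min(alloc$cumulative[1L, ]) < 1L)
      stop("first-stage information undefined: one arm has no patients",
           call. = FALSE)
    I <- information(alloc$cumulative[, "nE"], alloc$cumulative[, "nC"])
    mu <- delta * sqrt(I)
    u <- I
  } else {
    if (any(apply(alloc$stage, 1L, min) < 1L))
      stop("a stage-wise statistic is undefined: some stage has a single-arm ",
           "allocation", call. = FALSE)
    if (is.null(weights)) weights <- rep(1, K)
    stopifnot(length(weights) == K, all(weights > 0))
    w <- weights / sqrt(sum(weights^2))
    Itil <- information(alloc$stage[, "nE"], alloc$stage[, "nC"])
    W <- cumsum(w^2)
    mu <- cumsum(w * delta * sqrt(Itil)) / sqrt(W)
    u <- W
    I <- Itil
  }
  structure(list(mu = mu, u = u, corr = corr_from_u(u), info = I,
                 method = method, delta = delta),
            class = "joint_law")
}

#' Stopping probabilities of a boundary set under a joint law
#'
#' Computes, by multivariate normal integration, the probability of stopping
#' for efficacy and for futility at each analysis, the overall rejection
#' probability and the expected stopping stage, for the law of one
#' randomization sequence.  Continuation at an interim requires the
#' statistic to fall in \eqn{[a_k, b_k)}; with no futility bound
#' \eqn{a_k = -\infty}.
#'
#' @param law A [joint_law()].
#' @param b Efficacy bounds (z scale), length `K`.
#' @param a Futility bounds, length `K` with `a[K] = -Inf`, or `NULL`.
#'
#' @return A list of class `"gs_oc"`: `reject`, per-stage `efficacy` and
#'   `futility` stopping probabilities (the final entry of `futility` is the
#'   probability of failing at the final analysis), `stop_dist` and
#'   `expected_stage`.
#' @export
rejection_probability <- function(law, b, a = NULL) {
  stopifnot(inherits(law, "joint_law"))
  K <- length(law$mu)
  if (inherits(b, "gs_design")) { a <- b$a; b <- b$b }
  stopifnot(length(b) == K)
  if (is.null(a)) a <- rep(-Inf, K)
  eff <- vapply(seq_len(K),
                function(k) seq_cross_prob(k, a, b, law$corr, law$mu), 0)
  ## futility mass: below a_k at interims, below b_K at the final look
  fut <- numeric(K)
  for (k in seq_len(K)) {
    thr <- if (k < K) a[k] else b[K]
    if (!is.finite(thr) && thr < 0) next
    ## P(continue through 1..k-1, Z_k < thr)
    fut[k] <- cont_prob(k - 1L, a, b, law) -
      cont_prob_upto(k, a, b, thr, law)
  }
  stop_dist <- eff + fut
  structure(list(reject = sum(eff), efficacy = eff, futility = fut,
                 stop_dist = stop_dist,
                 expected_stage = sum(seq_len(K) * stop_dist)),
            class = "gs_oc")
}

## P(a_i <= Z_i < b_i for i = 1..k); k = 0 gives 1
cont_prob <- function(k, a, b, law) {
  if (k == 0L) return(1)
  idx <- seq_len(k)
  fin <- is.finite(a[idx]) | is.finite(b[idx])
  if (!any(fin)) return(1)
  sub <- idx[fin]
  if (length(sub) == 1L)
    return(stats::pnorm(b[sub], law$mu[sub]) - stats::pnorm(a[sub], law$mu[sub]))
  .pmv(a[sub], b[sub], law$mu[sub], law$corr[sub, sub, drop = FALSE])
}

## P(a_i <= Z_i < b_i for i < k, Z_k >= thr)
cont_prob_upto <- function(k, a, b, thr, law) {
  bb <- b; bb[k] <- thr
  seq_cross_prob(k, a, bb, law$corr, law$mu)
}

#' @export
print.gs_oc <- function(x, ...) {
  K <- length(x$efficacy)
  cat(sprintf("Rejection probability: %.6f\n", x$reject))
  df <- data.frame(stage = seq_len(K),
                   stop_efficacy = x$efficacy,
                   stop_futility_or_fail = x$futility)
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("Expected stopping stage: %.3f\n", x$expected_stage))
  invisible(x)
}

## bounds actually applied to one sequence under a given mode
## mode "naive":    pre-planned bounds, regardless of the observed allocation
## mode "adjusted": Lan-DeMets bounds re-solved at the observed information
##                  fractions (planned maximum information n/4 in the
##                  denominator; the final look spends all remaining alpha)
## INCT bounds are always the pre-planned ones (its null law is unaffected
## by the observed allocations).
applied_bounds <- function(design, alloc, mode = c("adjusted", "naive")) {
  mode <- match.arg(mode)
  if (design$method == "inct" || mode == "naive")
    return(list(b = design$b, a = design$a))
  if (design$method == "classic")
    stop("classic Pocock/O'Brien-Fleming boundaries are fixed; only ",
         "mode = \"naive\" applies (use method = \"ldm\" for adjustment)",
         call. = FALSE)
  I <- information(alloc$cumulative[, "nE"], alloc$cumulative[, "nC"])
  t_obs <- I / (design$n / 4)
  pi_k <- incremental_spend(design$boundary, design$alpha, t_obs)
  b <- solve_bounds_spend(pi_k, t_obs,
                          a = if (design$futility == "binding") design$a else NULL)
  list(b = b, a = design$a)
}

#' Conditional power and type I error for one randomization sequence
#'
#' Evaluates the rejection probability of a design given the stage-wise
#' allocations actually realised by one randomization sequence.  In
#' `"naive"` mode the pre-planned boundaries are applied even though the
#' observed allocation (and hence information) differs from the plan -- the
#' type-I-error-inflation scenario.  In `"adjusted"` mode Lan-DeMets
#' boundaries are re-solved at the observed information fractions, which
#' restores the exact level; the inverse normal combination test keeps its
#' planned boundaries in both modes because its null law does not depend on
#' the allocations.
#'
#' @param design A [gs_design()].
#' @param alloc A [summarize_stages()] result for the sequence.
#' @param delta Standardised effect size.
#' @param mode `"adjusted"` or `"naive"`.
#' @return A `"gs_oc"` object (see [rejection_probability()]).
#' @examples
#' d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
#' al <- summarize_stages(rep(rep(1:0, 3), c(6, 2, 5, 3, 2, 6)), stage_plan(24, 3))
#' conditional_power(d, al, delta = 1)$reject
#' conditional_t1e(d, al, mode = "naive")   # exceeds 0.025
#' @export
conditional_power <- function(design, alloc, delta,
                              mode = c("adjusted", "naive")) {
  stopifnot(inherits(design, "gs_design"), inherits(alloc, "stage_alloc"))
  mode <- match.arg(mode)
  method <- if (design$method == "inct") "inct" else "cumulative"
  law <- joint_law(alloc, method, delta, weights = design$weights)
  bd <- applied_bounds(design, alloc, mode)
  rejection_probability(law, bd$b, bd$a)
}

#' @rdname conditional_power
#' @return For `conditional_t1e`, the null rejection probability as a number.
#' @export
conditional_t1e <- function(design, alloc, mode = c("adjusted", "naive")) {
  conditional_power(design, alloc, 0, mode)$reject
}

#' Mean operating characteristics over simulated randomization sequences
#'
#' Generates randomization sequences, applies the family's exclusion rules,
#' evaluates the exact conditional rejection probability of each included
#' sequence by multivariate normal integration, and summarises over
#' sequences -- the sequence-conditional evaluation underlying the study's
#' power and type I error tables.  `delta = 0` gives the mean conditional
#' type I error.
#'
#' Identical stage-allocation patterns lead to identical conditional values,
#' so results are cached per pattern; with a few hundred distinct patterns
#' per 1000 sequences this keeps exact evaluation fast.
#'
#' @param rp A [rand_spec()].
#' @param design A [gs_design()].
#' @param delta Vector of standardised effect sizes.
#' @param n_sequences Sequences to simulate per effect size grid.
#' @param seed Integer seed for sequence generation.
#' @param mode Boundary mode, see [conditional_power()].
#'
#' @return A data frame of class `"seq_oc_summary"` with one row per
#'   `delta`: mean, sd, se, min, max of the conditional metric plus
#'   inclusion accounting.  The per-sequence values of the last effect size
#'   are attached as attribute `"per_sequence"`.
#' @examples
#' \donttest{
#' d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
#' mean_operating_characteristics(rand_spec("pbr", n = 24, l = 4), d,
#'                                delta = 1, n_sequences = 50, seed = 1)
#' }
#' @export
mean_operating_characteristics <- function(rp, design, delta = 0,
                                           n_sequences = 1000, seed = 1,
                                           mode = c("adjusted", "naive")) {
  stopifnot(inherits(rp, "rand_spec"), inherits(design, "gs_design"))
  mode <- match.arg(mode)
  method <- if (design$method == "inct") "inct" else "cumulative"
  seqs <- generate_sequences(rp, n_sequences, seed = seed)
  allocs <- apply(seqs, 1L, summarize_stages, plan = design$plan,
                  simplify = FALSE)
  keep <- logical(n_sequences); reasons <- character(n_sequences)
  for (i in seq_len(n_sequences)) {
    cl <- classify_sequence(allocs[[i]], method, design$test)
    keep[i] <- cl$included; reasons[i] <- cl$reason
  }
  if (!any(keep))
    stop("every generated sequence was excluded; the configuration is ",
         "degenerate for this design family", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(delta, function(d) {
    vals <- vapply(which(keep), function(i) {
      al <- allocs[[i]]
      key <- paste(c(d, al$stage[, "nE"]), collapse = ",")
      v <- cache[[key]]
      if (is.null(v)) {
        v <- conditional_power(design, al, d, mode)$reject
        cache[[key]] <- v
      }
      v
    }, 0)
    data.frame(delta = d, mean = mean(vals), sd = stats::sd(vals),
               se = stats::sd(vals) / sqrt(length(vals)),
               min = min(vals), max = max(vals),
               included = sum(keep), excluded = sum(!keep))
  })
  out <- do.call(rbind, rows)
  excl <- table(reasons[!keep])
  attr(out, "exclusion_reasons") <- excl
  attr(out, "rp") <- rp
  attr(out, "mode") <- mode
  class(out) <- c("seq_oc_summary", class(out))
  out
}

#' @export
print.seq_oc_summary <- function(x, ...) {
  cat("Mean conditional operating characteristics (",
      attr(x, "mode"), " boundaries)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  ex <- attr(x, "exclusion_reasons")
  if (length(ex)) {
    cat("Exclusions:\n")
    for (nm in names(ex)) cat("  ", nm, ": ", ex[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Per-sequence conditional type I error
#'
#' Returns the conditional type I error of each included sequence -- the
#' data behind violin-style displays of type-I-error inflation under naive
#' boundary use.
#'
#' @inheritParams mean_operating_characteristics
#' @return A data frame with columns `sequence_id` and `t1e`.
#' @export
per_sequence_t1e <- function(rp, design, n_sequences = 1000, seed = 1,
                             mode = c("naive", "adjusted")) {
  mode <- match.arg(mode)
  method <- if (design$method == "inct") "inct" else "cumulative"
  seqs <- generate_sequences(rp, n_sequences, seed = seed)
  cache <- new.env(parent = emptyenv())
  ids <- integer(0); vals <- numeric(0)
  for (i in seq_len(n_sequences)) {
    al <- summarize_stages(seqs[i, ], design$plan)
    if (!classify_sequence(al, method, design$test)$included) next
    key <- paste(al$stage[, "nE"], collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- conditional_t1e(design, al, mode)
      cache[[key]] <- v
    }
    ids <- c(ids, i); vals <- c(vals, v)
  }
  data.frame(sequence_id = ids, t1e = vals)
}
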