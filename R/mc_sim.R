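#' Monte Carlo rejection rate for one randomization sequence
#'
#' Simulates patient-level trials for a fixed randomization sequence and
#' applies the group sequential stopping rule, for both the z-test (known
#' variance 1) and the pooled-variance t-test.  Cumulative-statistic
#' families test all data accumulated so far at each analysis;
#' the inverse normal combination test computes a statistic from each
#' stage's data alone, transforms stage-wise t statistics to the normal
#' scale through their p-values, and combines them with the design weights,
#' so the pre-planned z-scale boundaries apply without substitution.  For
#' cumulative t-tests the z boundaries are converted by quantile
#' substitution at the observed cumulative degrees of freedom.
#'
#' @param design A [gs_design()].
#' @param x Randomization sequence: 0/1 integer vector (1 = experimental) or
#'   a `"rand_seq"`.
#' @param delta Standardised effect size.
#' @param n_trials Number of simulated trials.
#' @param mode Boundary mode for cumulative families, see
#'   [conditional_power()].
#'
#' @return A list of class `"mc_estimate"`: `estimate` (rejection fraction),
#'   `n_trials`, `se` (binomial standard error) and `stop_stage` counts.
#' @examples
#' \donttest{
#' d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
#' x <- generate_sequence(rand_spec("pbr", n = 24, l = 4), seed = 1)
#' simulate_trials(d, x, delta = 1, n_trials = 5000)
#' }
#' @export
simulate_trials <- function(design, x, delta, n_trials = 2000,
                            mode = c("adjusted", "naive")) {
  stopifnot(inherits(design, "gs_design"))
  mode <- match.arg(mode)
  if (inherits(x, "rand_seq")) x <- x$x
  x <- as.integer(x)
  plan <- design$plan
  stopifnot(length(x) == plan$n)
  alloc <- summarize_stages(x, plan)
  method <- if (design$method == "inct") "inct" else "cumulative"
  cl <- classify_sequence(alloc, method, design$test)
  if (!cl$included)
    stop("sequence is excluded for this design family: ", cl$reason,
         call. = FALSE)

  K <- plan$K
  bd <- applied_bounds(design, alloc, mode)
  if (design$test == "t" && method == "cumulative") {
    df <- alloc$cumulative[, "nE"] + alloc$cumulative[, "nC"] - 2L
    b_use <- quantile_substitute(bd$b, df)
    a_use <- quantile_substitute(bd$a, df)
  } else {
    b_use <- bd$b; a_use <- bd$a
  }
  w <- design$weights

  Y <- matrix(stats::rnorm(plan$n * n_trials, mean = delta * x), nrow = plan$n)
  isE <- x == 1L
  reject <- logical(n_trials); active <- rep(TRUE, n_trials)
  stop_stage <- rep(K, n_trials)
  comb <- numeric(n_trials)            # running INCT numerator
  stage_start <- c(1L, plan$cumulative[-K] + 1L)

  for (k in seq_len(K)) {
    if (method == "cumulative") {
      idx <- seq_len(plan$cumulative[k])
      ek <- isE[idx]
      stat <- two_sample_stat(Y[idx, , drop = FALSE], ek, design$test)
    } else {
      idx <- stage_start[k]:plan$cumulative[k]
      ek <- isE[idx]
      zk <- two_sample_stat(Y[idx, , drop = FALSE], ek, design$test,
                            as_z = TRUE)
      comb <- comb + w[k] * zk
      stat <- comb / sqrt(cumsum(w^2)[k])
    }
    hit_eff <- active & stat >= b_use[k]
    reject[hit_eff] <- TRUE
    stop_stage[active & hit_eff] <- k
    active <- active & !hit_eff
    if (k < K && is.finite(a_use[k])) {
      hit_fut <- active & stat < a_use[k]
      stop_stage[hit_fut] <- k
      active <- active & !hit_fut
    }
  }
  p <- mean(reject)
  structure(list(estimate = p, n_trials = n_trials,
                 se = sqrt(p * (1 - p) / n_trials),
                 stop_stage = tabulate(stop_stage, K)),
            class = "mc_estimate")
}

## two-sample statistic over the columns of Y; z uses known unit variance,
## t uses the pooled variance; as_z = TRUE maps a t statistic to the normal
## scale through its tail p-value (inverse normal transformation)
two_sample_stat <- function(Y, isE, test, as_z = FALSE) {
  nE <- sum(isE); nC <- sum(!isE)
  mE <- colMeans(Y[isE, , drop = FALSE])
  mC <- colMeans(Y[!isE, , drop = FALSE])
  scale <- sqrt(1 / nE + 1 / nC)
  if (test == "z") return((mE - mC) / scale)
  ssE <- colSums(Y[isE, , drop = FALSE]^2) - nE * mE^2
  ssC <- colSums(Y[!isE, , drop = FALSE]^2) - nC * mC^2
  df <- nE + nC - 2L
  tt <- (mE - mC) / (sqrt((ssE + ssC) / df) * scale)
  if (!as_z) return(tt)
  stats::qnorm(stats::pt(tt, df, lower.tail = FALSE), lower.tail = FALSE)
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC rejection rate %.4f (se %.4f, %d trials)\n",
              x$estimate, x$se, x$n_trials))
  invisible(x)
}

#' Monte Carlo power averaged over randomization sequences
#'
#' Generates sequences from a randomization procedure, applies the exclusion
#' rules, estimates each included sequence's rejection probability by
#' simulated trials, and averages -- the trial-simulation counterpart of
#' [mean_operating_characteristics()], and the primary engine for the
#' t-test, whose stage-wise statistics have no tractable joint law.
#'
#' @inheritParams mean_operating_characteristics
#' @param n_trials Simulated trials per sequence.
#' @return A data frame of class `"seq_oc_summary"`, one row per `delta`.
#' @examples
#' \donttest{
#' d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf", test = "t")
#' estimate_power_mc(rand_spec("pbr", n = 24, l = 4), d, delta = 1,
#'                   n_sequences = 20, n_trials = 500, seed = 1)
#' }
#' @export
estimate_power_mc <- function(rp, design, delta = 0, n_sequences = 1000,
                              n_trials = 2000, seed = 1,
                              mode = c("adjusted", "naive")) {
  stopifnot(inherits(rp, "rand_spec"), inherits(design, "gs_design"))
  mode <- match.arg(mode)
  method <- if (design$method == "inct") "inct" else "cumulative"
  set.seed(seed)
  seqs <- generate_sequences(rp, n_sequences)
  keep <- logical(n_sequences)
  allocs <- vector("list", n_sequences)
  reasons <- character(n_sequences)
  for (i in seq_len(n_sequences)) {
    allocs[[i]] <- summarize_stages(seqs[i, ], design$plan)
    cl <- classify_sequence(allocs[[i]], method, design$test)
    keep[i] <- cl$included; reasons[i] <- cl$reason
  }
  if (!any(keep))
    stop("every generated sequence was excluded", call. = FALSE)
  rows <- lapply(delta, function(d) {
    vals <- vapply(which(keep), function(i)
      simulate_trials(design, seqs[i, ], d, n_trials, mode)$estimate, 0)
    data.frame(delta = d, mean = mean(vals), sd = stats::sd(vals),
               se = stats::sd(vals) / sqrt(length(vals)),
               min = min(vals), max = max(vals),
               included = sum(keep), excluded = sum(!keep))
  })
  out <- do.call(rbind, rows)
  attr(out, "exclusion_reasons") <- table(reasons[!keep])
  attr(out, "rp") <- rp
  attr(out, "mode") <- mode
  class(out) <- c("seq_oc_summary", class(out))
  out
}

#' Validate the exact engine against trial simulation
#'
#' For a set of randomization sequences compares the exact multivariate
#' normal rejection probability with the Monte Carlo estimate from simulated
#' trials (z-test only) and flags discrepancies beyond `flag_at` binomial
#' standard errors.
#'
#' @param design A z-test [gs_design()].
#' @param rp A [rand_spec()] to draw sequences from.
#' @param delta Effect sizes to check (each sequence is checked at each).
#' @param n_sequences Number of sequences.
#' @param n_trials Trials per sequence and effect size.
#' @param seed Integer seed.
#' @param mode Boundary mode.
#' @param flag_at Number of standard errors beyond which a discrepancy is
#'   flagged.
#'
#' @return A data frame with one row per (sequence, delta): `exact`, `mc`,
#'   `se`, `z_discrepancy` and `flag`.
#' @export
validate_against_exact <- function(design, rp, delta = c(0, 1),
                                   n_sequences = 50, n_trials = 1e5,
                                   seed = 1, mode = c("adjusted", "naive"),
                                   flag_at = 4) {
  stopifnot(design$test == "z")
  mode <- match.arg(mode)
  method <- if (design$method == "inct") "inct" else "cumulative"
  set.seed(seed)
  seqs <- generate_sequences(rp, n_sequences)
  rows <- list()
  for (i in seq_len(n_sequences)) {
    al <- summarize_stages(seqs[i, ], design$plan)
    if (!classify_sequence(al, method, design$test)$included) next
    for (d in delta) {
      exact <- conditional_power(design, al, d, mode)$reject
      mc <- simulate_trials(design, seqs[i, ], d, n_trials, mode)
      se <- max(mc$se, sqrt(exact * (1 - exact) / n_trials), 1e-12)
      zd <- (mc$estimate - exact) / se
      rows[[length(rows) + 1L]] <-
        data.frame(sequence_id = i, delta = d, exact = exact,
                   mc = mc$estimate, se = se, z_discrepancy = zd,
                   flag = abs(zd) > flag_at)
    }
  }
  do.call(rbind, rows)
}
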