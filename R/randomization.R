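#' Specify a restricted randomization procedure
#'
#' Constructs the specification of a two-arm randomization procedure for a
#' trial of `n` patients with an intended 1:1 allocation ratio.  Seven
#' procedures are supported, from unrestricted coin flipping to designs that
#' enforce a maximum tolerated imbalance at every point of the allocation
#' sequence.
#'
#' @param kind Procedure, one of:
#'   * `"cr"`   -- complete randomization (fair coin per patient),
#'   * `"rar"`  -- random allocation rule (random permutation of `n/2`
#'                 experimental and `n/2` control labels; `n` must be even),
#'   * `"pbr"`  -- permuted block randomization with block length `l`
#'                 (random allocation rule within each block),
#'   * `"rpbr"` -- permuted blocks with the length of each block drawn
#'                 uniformly from `block_set`,
#'   * `"ebc"`  -- Efron's biased coin: probability `p` in favour of the
#'                 arm with fewer allocations so far, fair coin at a tie,
#'   * `"bsd"`  -- big stick design: fair coin until the absolute imbalance
#'                 reaches `m`, then a deterministic assignment to the
#'                 lagging arm,
#'   * `"chen"` -- Chen's design: Efron's biased coin with the big stick's
#'                 deterministic assignment at imbalance `m`.
#' @param n Total (maximum) sample size.
#' @param p Bias of the coin for `"ebc"` and `"chen"`; must lie strictly
#'   between 1/2 and 1.
#' @param m Maximum tolerated imbalance for `"bsd"` and `"chen"`.
#' @param l Block length for `"pbr"`; must be a positive even integer.
#' @param block_set Set of admissible block lengths for `"rpbr"`; all must
#'   be positive even integers.
#'
#' @return An object of class `"rand_spec"`.
#'
#' @examples
#' rand_spec("pbr", n = 24, l = 4)
#' rand_spec("chen", n = 24, p = 2/3, m = 3)
#' @export
rand_spec <- function(kind = c("cr", "rar", "pbr", "rpbr", "ebc", "bsd", "chen"),
                      n, p = NULL, m = NULL, l = NULL, block_set = NULL) {
  kind <- match.arg(kind)
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  need <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  if (kind %in% c("ebc", "chen")) {
    need(!is.null(p) && length(p) == 1L && p > 0.5 && p < 1,
         "'p' must be a single probability strictly between 1/2 and 1")
  } else need(is.null(p), sprintf("'p' is not a parameter of %s", toupper(kind)))
  if (kind %in% c("bsd", "chen")) {
    need(!is.null(m) && length(m) == 1L && m >= 1 && m == round(m),
         "'m' must be a positive integer")
    m <- as.integer(m)
  } else need(is.null(m), sprintf("'m' is not a parameter of %s", toupper(kind)))
  if (kind == "pbr") {
    need(!is.null(l) && length(l) == 1L && l >= 2 && l == round(l) && l %% 2 == 0,
         "'l' must be a positive even integer")
    l <- as.integer(l)
  } else need(is.null(l), sprintf("'l' is not a parameter of %s", toupper(kind)))
  if (kind == "rpbr") {
    need(!is.null(block_set) && length(block_set) >= 1 &&
           all(block_set >= 2 & block_set == round(block_set) & block_set %% 2 == 0),
         "'block_set' must contain positive even integers")
    block_set <- as.integer(block_set)
  } else need(is.null(block_set), "'block_set' is only a parameter of RPBR")
  if (kind == "rar" && n %% 2 != 0)
    stop("the random allocation rule requires an even 'n'", call. = FALSE)
  structure(list(kind = kind, n = n, p = p, m = m, l = l, block_set = block_set),
            class = "rand_spec")
}

#' @export
print.rand_spec <- function(x, ...) {
  lab <- switch(x$kind,
    cr = "CR", rar = "RAR",
    pbr = sprintf("PBR(%d)", x$l),
    rpbr = sprintf("RPBR({%s})", paste(x$block_set, collapse = ",")),
    ebc = sprintf("EBC(%.4g)", x$p),
    bsd = sprintf("BSD(%d)", x$m),
    chen = sprintf("Chen(%.4g, %d)", x$p, x$m))
  cat("Randomization procedure: ", lab, ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

## Conditional probability that the next patient is assigned to E, given the
## current state, vectorised over sequences.  This is the single place where
## each procedure's allocation law lives; the generator and the exact path
## enumeration both call it.
##   j      : 0-based number of patients already allocated (scalar)
##   nE     : experimental allocations so far (vector)
##   blk_nE : E allocations within the current block (vector; PBR/RPBR)
##   blk_pos: position within the current block (vector; PBR/RPBR)
##   blk_len: current block length (vector; RPBR)
alloc_prob_E <- function(rp, j, nE, blk_nE = NULL, blk_pos = NULL, blk_len = NULL) {
  D <- 2 * nE - j
  switch(rp$kind,
    cr  = rep(0.5, length(nE)),
    rar = (rp$n / 2 - nE) / (rp$n - j),
    pbr = (rp$l / 2 - blk_nE) / (rp$l - blk_pos),
    rpbr = (blk_len / 2 - blk_nE) / (blk_len - blk_pos),
    ebc = ifelse(D == 0, 0.5, ifelse(D < 0, rp$p, 1 - rp$p)),
    bsd = ifelse(D <= -rp$m, 1, ifelse(D >= rp$m, 0, 0.5)),
    chen = ifelse(D <= -rp$m, 1,
           ifelse(D >= rp$m, 0,
           ifelse(D == 0, 0.5, ifelse(D < 0, rp$p, 1 - rp$p)))))
}

#' Generate randomization sequences
#'
#' Draws `count` randomization sequences of length `n` from a procedure.
#' The procedure is applied over the whole trial; it is never restarted at
#' stage boundaries.
#'
#' @param rp A [rand_spec()] object.
#' @param count Number of sequences.
#' @param seed Optional integer seed; when supplied the generator is
#'   reproducible independently of the caller's RNG state (which is restored
#'   afterwards).
#'
#' @return An integer matrix of class `"rand_seqs"` with `count` rows and
#'   `n` columns; entry 1 codes the experimental arm, 0 the control arm.
#'   Use [as.data.frame()] for a long-format export with the running
#'   imbalance.
#'
#' @examples
#' s <- generate_sequences(rand_spec("bsd", n = 24, m = 3), 5, seed = 1)
#' apply(s, 1, function(x) max(abs(cumsum(2 * x - 1))))  # never exceeds m
#' @export
generate_sequences <- function(rp, count = 1L, seed = NULL) {
  stopifnot(inherits(rp, "rand_spec"), count >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- rp$n
  x <- matrix(0L, count, n)
  nE <- integer(count)
  blk_nE <- integer(count); blk_pos <- integer(count)
  blk_len <- if (rp$kind == "rpbr")
    sample(rp$block_set, count, replace = TRUE) else rep(rp$l %||% 0L, count)
  for (j in seq_len(n)) {
    pE <- alloc_prob_E(rp, j - 1L, nE, blk_nE, blk_pos, blk_len)
    e <- as.integer(stats::runif(count) < pE)
    x[, j] <- e
    nE <- nE + e
    if (rp$kind %in% c("pbr", "rpbr")) {
      blk_nE <- blk_nE + e
      blk_pos <- blk_pos + 1L
      done <- blk_pos == blk_len
      if (any(done)) {
        blk_pos[done] <- 0L; blk_nE[done] <- 0L
        if (rp$kind == "rpbr")
          blk_len[done] <- sample(rp$block_set, sum(done), replace = TRUE)
      }
    }
  }
  structure(x, class = c("rand_seqs", class(x)), rp = rp)
}

#' @export
as.data.frame.rand_seqs <- function(x, ...) {
  n <- ncol(x); count <- nrow(x)
  arm <- ifelse(t(x) == 1L, "E", "C")
  imb <- apply(x, 1, function(r) cumsum(2L * r - 1L))
  data.frame(sequence_id = rep(seq_len(count), each = n),
             position = rep(seq_len(n), count),
             arm = as.vector(arm),
             imbalance = as.vector(imb))
}

#' Generate a single randomization sequence
#'
#' Convenience wrapper around [generate_sequences()] returning one sequence
#' with its arm labels and running imbalance.
#'
#' @inheritParams generate_sequences
#' @return A list of class `"rand_seq"` with elements `labels` (character,
#'   `"E"`/`"C"`), `x` (integer 0/1 coding) and `imbalance` (the running
#'   difference between experimental and control counts).
#' @export
generate_sequence <- function(rp, seed = NULL) {
  x <- as.integer(generate_sequences(rp, 1L, seed = seed)[1L, ])
  structure(list(labels = ifelse(x == 1L, "E", "C"), x = x,
                 imbalance = cumsum(2L * x - 1L), rp = rp),
            class = "rand_seq")
}

#' @export
print.rand_seq <- function(x, ...) {
  print(x$rp)
  cat(paste(x$labels, collapse = ""), "\n")
  cat("final imbalance:", x$imbalance[length(x$imbalance)],
      " max |imbalance|:", max(abs(x$imbalance)), "\n")
  invisible(x)
}

#' Stage plan for a group sequential trial
#'
#' Defines the interim-analysis schedule by stage-wise sample sizes.  By
#' default the `n` patients are split into `K` equal stages, which requires
#' `K` to divide `n`; unequal schedules are given explicitly via `sizes`
#' (the placement of extra patients matters in small trials, so no implicit
#' rounding is applied).
#'
#' @param n Maximum sample size.
#' @param K Number of stages (analyses); `K = 3` means two interim analyses
#'   plus a final analysis.
#' @param sizes Optional explicit stage sizes (length `K`, summing to `n`).
#'
#' @return An object of class `"stage_plan"` with elements `sizes` and
#'   `cumulative`.
#' @examples
#' stage_plan(24, 3)
#' stage_plan(17, 4, sizes = c(5, 4, 4, 4))
#' @export
stage_plan <- function(n, K, sizes = NULL) {
  stopifnot(n >= 1, K >= 1)
  if (is.null(sizes)) {
    if (n %% K != 0)
      stop("'K' must divide 'n' for an equal stage plan; supply 'sizes'",
           call. = FALSE)
    sizes <- rep(n / K, K)
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != K || any(sizes < 1) || sum(sizes) != n)
    stop("'sizes' must be ", K, " positive integers summing to ", n,
         call. = FALSE)
  structure(list(n = as.integer(n), K = as.integer(K), sizes = sizes,
                 cumulative = cumsum(sizes)),
            class = "stage_plan")
}

#' @export
print.stage_plan <- function(x, ...) {
  cat("Stage plan: n =", x$n, ", K =", x$K,
      ", sizes =", paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Stage-wise and cumulative allocation counts of a sequence
#'
#' Cuts a randomization sequence by a stage plan and counts the patients per
#' arm within each stage and cumulatively up to each analysis.
#'
#' @param seq A `"rand_seq"` object, a 0/1 integer vector (1 = experimental)
#'   or a single row of a `"rand_seqs"` matrix.
#' @param plan A [stage_plan()] whose sizes sum to the sequence length.
#'
#' @return An object of class `"stage_alloc"`: a list with integer matrices
#'   `stage` and `cumulative`, each with columns `nE` and `nC` and one row
#'   per analysis.
#' @examples
#' # the worked 24-patient example: stages allocate 6:2, 5:3 and 2:6
#' x <- rep(c(1, 0), c(6, 2) )
#' x <- c(x, rep(c(1, 0), c(5, 3)), rep(c(1, 0), c(2, 6)))
#' summarize_stages(x, stage_plan(24, 3))
#' @export
summarize_stages <- function(seq, plan) {
  x <- if (inherits(seq, "rand_seq")) seq$x else as.integer(seq)
  stopifnot(inherits(plan, "stage_plan"))
  if (length(x) != plan$n)
    stop("sequence length (", length(x), ") does not match the stage plan (n = ",
         plan$n, ")", call. = FALSE)
  idx <- rep(seq_len(plan$K), plan$sizes)
  nE <- as.integer(rowsum(x, idx))
  stage <- cbind(nE = nE, nC = plan$sizes - nE)
  cumulative <- cbind(nE = cumsum(nE), nC = plan$cumulative - cumsum(nE))
  structure(list(stage = stage, cumulative = cumulative, plan = plan),
            class = "stage_alloc")
}

#' @export
print.stage_alloc <- function(x, ...) {
  df <- data.frame(stage = seq_len(x$plan$K),
                   nE = x$stage[, "nE"], nC = x$stage[, "nC"],
                   NE = x$cumulative[, "nE"], NC = x$cumulative[, "nC"])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Eligibility of a sequence for a given analysis method and test
#'
#' Applies the exclusion rules under which the stage-wise test statistics are
#' well defined.  Cumulative methods (classic Pocock/O'Brien-Fleming and
#' Lan-DeMets) only require both arms to be represented in the first-stage
#' data (z-test), or at least two patients per arm there (t-test, for the
#' variance estimate).  The inverse normal combination test computes a
#' statistic from each stage separately, so the same condition must hold in
#' every stage.
#'
#' @param alloc A [summarize_stages()] result.
#' @param method `"cumulative"` (classic and Lan-DeMets families) or
#'   `"inct"`.
#' @param test `"z"` or `"t"`.
#'
#' @return A list with `included` (logical) and `reason` (`"ok"` or a string
#'   naming the stage and rule that fired).
#' @export
classify_sequence <- function(alloc, method = c("cumulative", "inct"),
                              test = c("z", "t")) {
  stopifnot(inherits(alloc, "stage_alloc"))
  method <- match.arg(method); test <- match.arg(test)
  min_per_arm <- if (test == "z") 1L else 2L
  if (method == "cumulative") {
    if (min(alloc$cumulative[1L, ]) < min_per_arm)
      return(list(included = FALSE,
                  reason = sprintf("stage 1: fewer than %d patients in one arm",
                                   min_per_arm)))
  } else {
    bad <- which(apply(alloc$stage, 1L, min) < min_per_arm)
    if (length(bad))
      return(list(included = FALSE,
                  reason = sprintf("stage %d: fewer than %d patients in one arm",
                                   bad[1L], min_per_arm)))
  }
  list(included = TRUE, reason = "ok")
}

#' Probability that an initial stage is allocated to a single arm
#'
#' Computes the probability that all of the first `stage_size` patients are
#' assigned to the same arm (either arm counted), the event that makes the
#' first-stage test statistic undefined and forces exclusion of the
#' sequence.  Closed forms are available for complete randomization
#' (\eqn{2 (1/2)^s}), Efron's biased coin (\eqn{(1-p)^{s-1}}) and the random
#' allocation rule (\eqn{2\binom{n-s}{n/2-s}/\binom{n}{n/2}}); every
#' procedure except RPBR can also be evaluated by exhaustive enumeration of
#' all \eqn{2^s} labelled allocation paths with their exact probabilities.
#'
#' @param rp A [rand_spec()].
#' @param stage_size Size \eqn{s} of the initial stage.
#' @param method `"analytic"` (CR, EBC, RAR only) or `"enumerate"`
#'   (any procedure with a deterministic state; capped at `stage_size <= 16`).
#'
#' @return A probability.
#' @examples
#' single_group_stage_probability(rand_spec("cr", n = 24), 8)   # 2 * (1/2)^8
#' @export
single_group_stage_probability <- function(rp, stage_size,
                                           method = c("analytic", "enumerate")) {
  stopifnot(inherits(rp, "rand_spec"), stage_size >= 1, stage_size <= rp$n)
  method <- match.arg(method)
  s <- as.integer(stage_size)
  if (method == "analytic") {
    out <- switch(rp$kind,
      cr  = 2 * 0.5^s,
      ebc = if (s == 1L) 1 else (1 - rp$p)^(s - 1L),
      rar = if (s > rp$n / 2) 0 else
        2 * choose(rp$n - s, rp$n / 2 - s) / choose(rp$n, rp$n / 2),
      stop("no closed form for ", toupper(rp$kind),
           "; use method = \"enumerate\"", call. = FALSE))
    return(out)
  }
  if (rp$kind == "rpbr")
    stop("enumeration is not supported for RPBR (random block lengths)",
         call. = FALSE)
  if (s > 16L)
    stop("enumeration is capped at stage_size <= 16", call. = FALSE)
  ## walk all monochrome-or-not paths?  No: only the two monochrome paths have
  ## positive probability of the event, but their probability depends on the
  ## full allocation law, so evaluate both paths step by step.  For procedures
  ## with deterministic assignments a path may have probability zero.
  path_prob <- function(arm) {      # arm: 1 = all E, 0 = all C
    pr <- 1
    nE <- 0L; blk_nE <- 0L; blk_pos <- 0L
    for (j in seq_len(s)) {
      pE <- alloc_prob_E(rp, j - 1L, nE, blk_nE, blk_pos, rp$l)
      pr <- pr * if (arm == 1L) pE else 1 - pE
      if (pr == 0) return(0)
      nE <- nE + arm
      if (rp$kind == "pbr") {
        blk_nE <- blk_nE + arm; blk_pos <- blk_pos + 1L
        if (blk_pos == rp$l) { blk_pos <- 0L; blk_nE <- 0L }
      }
    }
    pr
  }
  path_prob(1L) + path_prob(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
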