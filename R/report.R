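#' Run a configuration-driven operating-characteristics experiment
#'
#' Evaluates every combination of randomization procedure and design in a
#' configuration, producing one tidy row per (procedure, design, effect
#' size).  z-test designs are evaluated with the exact multivariate normal
#' engine; t-test designs with the trial-simulation engine.  The
#' study's headline tables are projections of this schema.
#'
#' @param config A named list or a path to a JSON (or YAML) file with
#'   components:
#'   \describe{
#'     \item{n, K}{trial size and number of stages;}
#'     \item{rps}{list of argument lists for [rand_spec()] (the `n` is
#'       filled in);}
#'     \item{designs}{list of argument lists for [gs_design()] (`K`, `n`
#'       filled in);}
#'     \item{delta}{effect-size grid (or `list(from, to, by)`);}
#'     \item{n_sequences}{sequences per cell (default 1000);}
#'     \item{n_trials}{trials per sequence for t-test cells (default 2000);}
#'     \item{seed}{master seed (mandatory);}
#'     \item{mode}{`"adjusted"` (default) or `"naive"`;}
#'     \item{scale}{optional factor applied to `n_sequences`/`n_trials`.}
#'   }
#' @param verbose Print one progress line per cell.
#'
#' @return A data frame of class `"gs_result_table"` with columns `rp`,
#'   `method`, `boundary`, `futility`, `test`, `engine`, `delta`, `metric`,
#'   `estimate`, `sd`, `se`, `included`, `excluded`.
#' @examples
#' \donttest{
#' cfg <- list(n = 24, K = 3, seed = 1, n_sequences = 50,
#'             rps = list(list(kind = "pbr", l = 4)),
#'             designs = list(list(method = "ldm", boundary = "obf")),
#'             delta = c(0, 1))
#' run_experiment(cfg, verbose = FALSE)
#' }
#' @export
run_experiment <- function(config, verbose = TRUE) {
  cfg <- load_config(config)
  rows <- list()
  cell <- 0L
  for (ri in seq_along(cfg$rps)) {
    rp <- do.call(rand_spec, c(cfg$rps[[ri]], list(n = cfg$n)))
    for (di in seq_along(cfg$designs)) {
      dargs <- cfg$designs[[di]]
      design <- do.call(gs_design, c(dargs, list(K = cfg$K, n = cfg$n)))
      cell <- cell + 1L
      seed_cell <- (cfg$seed + 7919L * cell) %% .Machine$integer.max
      res <- if (design$test == "z")
        mean_operating_characteristics(rp, design, cfg$delta,
                                       cfg$n_sequences, seed_cell, cfg$mode)
      else
        estimate_power_mc(rp, design, cfg$delta, cfg$n_sequences,
                          cfg$n_trials, seed_cell, cfg$mode)
      lab <- rp_label(rp)
      if (verbose)
        message(sprintf("[%s | %s %s %s %s] included %d / excluded %d",
                        lab, design$method, design$boundary, design$futility,
                        design$test, res$included[1L], res$excluded[1L]))
      rows[[cell]] <- data.frame(
        rp = lab, method = design$method, boundary = design$boundary,
        futility = design$futility, test = design$test,
        engine = if (design$test == "z") "exact" else "mc",
        delta = res$delta,
        metric = ifelse(res$delta == 0, "t1e", "power"),
        estimate = res$mean, sd = res$sd, se = res$se,
        included = res$included, excluded = res$excluded)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  class(out) <- c("gs_result_table", class(out))
  out
}

rp_label <- function(rp) {
  switch(rp$kind,
    cr = "CR", rar = "RAR",
    pbr = sprintf("PBR(%d)", rp$l),
    rpbr = "RPBR",
    ebc = sprintf("EBC(%.3g)", rp$p),
    bsd = sprintf("BSD(%d)", rp$m),
    chen = sprintf("Chen(%.3g,%d)", rp$p, rp$m))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  for (f in c("n", "K", "rps", "designs", "seed"))
    if (is.null(config[[f]]))
      stop("config is missing mandatory field '", f, "'", call. = FALSE)
  if (is.null(config$delta)) config$delta <- 0
  if (is.list(config$delta) && !is.null(config$delta$from))
    config$delta <- seq(config$delta$from, config$delta$to, config$delta$by)
  config$delta <- as.numeric(config$delta)
  config$n_sequences <- config$n_sequences %||% 1000L
  config$n_trials <- config$n_trials %||% 2000L
  config$mode <- config$mode %||% "adjusted"
  if (!is.null(config$scale)) {
    config$n_sequences <- max(1L, as.integer(config$n_sequences * config$scale))
    config$n_trials <- max(2L, as.integer(config$n_trials * config$scale))
  }
  ## JSON may deliver design/rp argument lists as data frames
  as_arg_lists <- function(x) {
    if (is.data.frame(x))
      x <- lapply(seq_len(nrow(x)), function(i)
        Filter(function(v) !is.na(v)[1L], as.list(x[i, , drop = FALSE])))
    lapply(x, as.list)
  }
  config$rps <- as_arg_lists(config$rps)
  config$designs <- as_arg_lists(config$designs)
  config
}

#' Pivot a tidy result table into a manuscript-style layout
#'
#' Reshapes the output of [run_experiment()] into a wide
#' procedure-by-design matrix for a chosen effect size and metric.  Missing
#' cells are rendered as `NA`, never dropped.
#'
#' @param results A `"gs_result_table"`.
#' @param delta Effect size to display.
#' @param metric `"power"` or `"t1e"`.
#' @param file Optional path to also write the layout as CSV.
#'
#' @return A data frame with one row per randomization procedure and one
#'   column per design.
#' @export
export_tables <- function(results, delta = 1.0, metric = "power",
                          file = NULL) {
  stopifnot(inherits(results, "gs_result_table"))
  sub <- results[results$metric == metric &
                   abs(results$delta - delta) < 1e-9, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no cells for metric '", metric, "' at delta = ", delta,
         call. = FALSE)
  sub$design <- paste(sub$method, sub$boundary,
                      ifelse(sub$futility == "none", "",
                             paste0("(", sub$futility, ")")))
  sub$design <- trimws(sub$design)
  rps <- unique(sub$rp); designs <- unique(sub$design)
  wide <- data.frame(rp = rps)
  for (d in designs) {
    v <- rep(NA_real_, length(rps))
    m <- sub[sub$design == d, ]
    v[match(m$rp, rps)] <- m$estimate
    wide[[d]] <- v
  }
  missing <- which(is.na(as.matrix(wide[, -1, drop = FALSE])), arr.ind = TRUE)
  if (nrow(missing))
    warning("missing cells: ",
            paste(sprintf("(%s, %s)", wide$rp[missing[, 1]],
                          designs[missing[, 2]]), collapse = ", "),
            call. = FALSE)
  if (!is.null(file)) utils::write.csv(wide, file, row.names = FALSE)
  wide
}

#' Rule-based suitability report for procedure/design combinations
#'
#' Applies the arithmetic selection rules for pairing restricted
#' randomization procedures with group sequential designs in small samples
#' (equal stage sizes): a maximum tolerated imbalance `m` must stay below
#' the stage size `n/K` for cumulative (Lan-DeMets) analyses and below half
#' the stage size for the inverse normal combination test, because once an
#' imbalance of `m` is reached up to `2m` consecutive assignments can go to
#' the lagging arm; a block length `l` should divide `n/K` for stage-wise
#' balance (required for type I error control with standard, unadjusted
#' boundaries); unrestricted procedures risk single-group stages.
#'
#' @param rps List of [rand_spec()] objects (or a single one).
#' @param n Maximum sample size.
#' @param K Number of equally sized stages; `K` must divide `n`.
#'
#' @return A data frame with one row per procedure and verdict columns
#'   `ldm`, `inct` and `standard_boundaries`, each naming the condition that
#'   fired.
#' @examples
#' framework_summary(list(rand_spec("pbr", n = 24, l = 4),
#'                        rand_spec("bsd", n = 24, m = 3)), n = 24, K = 3)
#' @export
framework_summary <- function(rps, n, K) {
  if (inherits(rps, "rand_spec")) rps <- list(rps)
  if (n %% K != 0)
    stop("the selection framework applies to equal stage sizes only; ",
         "K must divide n", call. = FALSE)
  ns <- n / K
  row_for <- function(rp) {
    lab <- rp_label(rp)
    unrestricted <- "Risk of allocations to a single group"
    low_power <- "Low power; risk of allocations to a single group"
    switch(rp$kind,
      cr = data.frame(rp = lab, ldm = low_power, inct = low_power,
                      standard_boundaries = "T1E not controlled"),
      rar = data.frame(rp = lab, ldm = unrestricted, inct = low_power,
                       standard_boundaries = "T1E not controlled"),
      ebc = data.frame(rp = lab, ldm = unrestricted,
                       inct = paste("Moderate power;", tolower(unrestricted)),
                       standard_boundaries = "T1E not controlled"),
      pbr = data.frame(
        rp = lab,
        ldm = "Suitable",
        inct = if (ns %% rp$l == 0)
          sprintf("l = %d divides n/K = %d: full power", rp$l, ns)
        else sprintf("l = %d does not divide n/K = %d: power loss", rp$l, ns),
        standard_boundaries = if (ns %% rp$l == 0)
          sprintf("l divides n/K: T1E controlled")
        else "l must divide n/K to control T1E: not controlled"),
      rpbr = {
        ok <- all(ns %% rp$block_set == 0)
        data.frame(
          rp = lab,
          ldm = "Suitable",
          inct = if (ok) "all block lengths divide n/K: full power"
                 else "some block length does not divide n/K: power loss",
          standard_boundaries = if (ok) "T1E controlled"
                 else "T1E not controlled")
      },
      bsd = ,
      chen = {
        base <- if (rp$kind == "chen")
          sprintf("Chen(%.3g, %d)", rp$p, rp$m) else sprintf("BSD(%d)", rp$m)
        data.frame(
          rp = lab,
          ldm = if (rp$m < ns)
            sprintf("m = %d < n/K = %d: suitable", rp$m, ns)
          else sprintf("m = %d >= n/K = %d: risk of single-group stage",
                       rp$m, ns),
          inct = if (rp$m < ns / 2)
            sprintf("m = %d < (n/K)/2 = %g: suitable, mild power loss vs 1:1",
                    rp$m, ns / 2)
          else sprintf("m = %d >= (n/K)/2 = %g: not recommended", rp$m, ns / 2),
          standard_boundaries = "T1E not controlled")
      })
  }
  out <- do.call(rbind, lapply(rps, row_for))
  rownames(out) <- NULL
  out
}
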