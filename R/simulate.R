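#' Configure a synthetic cross-over intervention study
#'
#' Assembles and validates the parameters of the synthetic-data generator.
#' The defaults emulate the demonstrator nutritional study: ~33 subjects in a
#' double-blind placebo-controlled cross-over design, parameter blocks for
#' three biological processes (7 oxidation, 18 inflammation, 115 metabolism
#' parameters), an additive standardized treatment effect on every parameter
#' (the axes contain only significantly changed parameters), and two planted
#' responder subgroups: one reacting mainly on the inflammation/oxidation
#' blocks, one mainly on the metabolism block.
#'
#' @param nSubjects number of subjects (default 33).
#' @param blocks named integer vector of per-process parameter counts
#'   (default `c(oxidation = 7, inflammation = 18, metabolism = 115)`).
#' @param fracAffected fraction of each block's parameters carrying a
#'   treatment effect; scalar or named per-block (default 1).
#' @param effectSize standardized mean shift (Cohen's d scale) under
#'   treatment; scalar or named per-block (default 1).
#' @param subgroups named list of responder subgroups, each a list with
#'   `proportion` and a named `multipliers` vector (per-block effect
#'   multipliers).  Defaults: group1 (50%) with multipliers
#'   oxidation 1.5 / inflammation 1.5 / metabolism 0.3; group2 (50%) with
#'   0.3 / 0.3 / 1.5.
#' @param withinBlockCorr equicorrelation of the residual noise of
#'   parameters within a block, in `[0, 1)` (default 0.3).
#' @param subjectSd between-subject random-intercept scale; the intercept is
#'   shared across a subject's arms and timepoints (default 1).
#' @param noiseSd residual scale per observation (default 1).
#' @param nTimepoints timepoints per treatment period (default 2); the
#'   treatment effect acts at post-baseline timepoints only.
#' @param preset `"full"` (the defaults above) or `"no-diet"`, the
#'   alternative axis configuration that excludes diet-derived parameters
#'   (blocks 5 / 15 / 114).
#' @return a validated list of class `SimulationConfig`.
#' @seealso [simulateStudy()], [defaultAxes()]
#' @export
simulationConfig <- function(nSubjects = 33,
                             blocks = c(oxidation = 7, inflammation = 18,
                                        metabolism = 115),
                             fracAffected = 1,
                             effectSize = 1,
                             subgroups = list(
                               group1 = list(proportion = 0.5,
                                             multipliers = c(oxidation = 1.5,
                                                             inflammation = 1.5,
                                                             metabolism = 0.3)),
                               group2 = list(proportion = 0.5,
                                             multipliers = c(oxidation = 0.3,
                                                             inflammation = 0.3,
                                                             metabolism = 1.5))),
                             withinBlockCorr = 0.3,
                             subjectSd = 1,
                             noiseSd = 1,
                             nTimepoints = 2,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "no-diet"))
    if (preset == "no-diet" && missing(blocks))
      blocks <- c(oxidation = 5, inflammation = 15, metabolism = 114)
  }
  if (is.null(names(blocks)) || anyDuplicated(names(blocks)))
    stop("blocks must be a uniquely named vector of parameter counts")
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      return(stats::setNames(rep(as.numeric(x), length(blocks)), names(blocks)))
    miss <- setdiff(names(blocks), names(x))
    if (length(miss))
      stop(what, " lacks value(s) for block(s): ", paste(miss, collapse = ", "))
    as.numeric(x[names(blocks)]) -> v
    stats::setNames(v, names(blocks))
  }
  cfg <- list(nSubjects = as.integer(nSubjects),
              blocks = stats::setNames(as.integer(blocks), names(blocks)),
              fracAffected = expand(fracAffected, "fracAffected"),
              effectSize = expand(effectSize, "effectSize"),
              subgroups = subgroups,
              withinBlockCorr = as.numeric(withinBlockCorr),
              subjectSd = as.numeric(subjectSd),
              noiseSd = as.numeric(noiseSd),
              nTimepoints = as.integer(nTimepoints))
  class(cfg) <- "SimulationConfig"
  msg <- .validateSimConfig(cfg)
  if (length(msg)) stop("invalid simulation config: ", paste(msg, collapse = "; "))
  cfg
}

.validateSimConfig <- function(cfg) {
  msg <- character()
  if (cfg$nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (any(cfg$blocks < 1L)) msg <- c(msg, "block sizes must be positive")
  if (any(cfg$fracAffected < 0 | cfg$fracAffected > 1))
    msg <- c(msg, "fracAffected must lie in [0, 1]")
  if (cfg$withinBlockCorr < 0 || cfg$withinBlockCorr >= 1)
    msg <- c(msg, "withinBlockCorr must lie in [0, 1)")
  if (cfg$subjectSd < 0 || cfg$noiseSd < 0)
    msg <- c(msg, "scales must be >= 0")
  if (cfg$nTimepoints < 1L) msg <- c(msg, "nTimepoints must be >= 1")
  props <- vapply(cfg$subgroups, function(g) as.numeric(g$proportion), 1)
  if (abs(sum(props) - 1) > 1e-8)
    msg <- c(msg, "subgroup proportions must sum to 1")
  for (g in names(cfg$subgroups)) {
    m <- cfg$subgroups[[g]]$multipliers
    miss <- setdiff(names(cfg$blocks), names(m))
    if (length(miss))
      msg <- c(msg, paste0("subgroup '", g, "' lacks multiplier(s) for: ",
                           paste(miss, collapse = ", ")))
  }
  msg
}

#' Generate a synthetic cross-over study with known ground truth
#'
#' Simulates one placebo-controlled cross-over study.  The value for subject
#' *i*, parameter *j*, arm *a*, timepoint *t* is
#' \deqn{v = b_{ij} + \epsilon_{ijat} + [a = \mathrm{treated},\ j\
#'   \mathrm{affected},\ t > t_1]\, d_{B(j)}\, m_{G(i),B(j)}}
#' where \eqn{b_{ij}} is a subject random intercept (shared across arms and
#' timepoints, emulating the within-subject pairing of a cross-over design),
#' \eqn{\epsilon} is equicorrelated within each parameter block, \eqn{d} is
#' the block effect size and \eqn{m} the subject's subgroup multiplier.
#' Identical config + seed yields identical output.
#'
#' @param config a [simulationConfig()] object.
#' @param seed integer seed; all randomness derives from it.
#' @return a list with elements `table` (a [SampleTable-class]) and `truth`
#'   (list with `subgroup` — named subgroup label per subject, `affected` —
#'   named logical per parameter, `config`, `seed`).
#' @examples
#' sim <- simulateStudy(simulationConfig(nSubjects = 8,
#'                                       blocks = c(oxidation = 3)), seed = 1)
#' table(sim$truth$subgroup)
#' @export
simulateStudy <- function(config = simulationConfig(), seed = 1L) {
  if (!inherits(config, "SimulationConfig"))
    stop("config must come from simulationConfig()")
  .withSeed(seed, {
    nb <- config$blocks
    block_of <- rep(names(nb), nb)
    width <- max(2L, nchar(as.character(max(nb))))
    param_ids <- unlist(lapply(names(nb), function(b)
      sprintf("%s_%0*d", b, width, seq_len(nb[[b]]))), use.names = FALSE)
    p <- length(param_ids)

    affected <- unlist(lapply(names(nb), function(b) {
      k <- round(config$fracAffected[[b]] * nb[[b]])
      c(rep(TRUE, k), rep(FALSE, nb[[b]] - k))
    }), use.names = FALSE)
    names(affected) <- param_ids

    n <- config$nSubjects
    subj_ids <- sprintf("s%02d", seq_len(n))
    props <- vapply(config$subgroups, function(g) as.numeric(g$proportion), 1)
    counts <- diff(c(0L, round(cumsum(props) * n)))
    subgroup <- rep(names(config$subgroups), counts)
    names(subgroup) <- subj_ids

    tp_ids <- sprintf("t%d", seq_len(config$nTimepoints))
    grid <- expand.grid(timepoint = tp_ids, arm = c("treated", "control"),
                        subject = subj_ids, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("subject", "arm", "timepoint")]
    nobs <- nrow(grid)

    intercept <- matrix(stats::rnorm(n * p, sd = config$subjectSd), n, p,
                        dimnames = list(subj_ids, param_ids))
    rho <- config$withinBlockCorr
    # equicorrelated block noise: sqrt(rho) * shared + sqrt(1 - rho) * own
    eps <- matrix(stats::rnorm(nobs * p), nobs, p)
    if (rho > 0) {
      shared <- matrix(stats::rnorm(nobs * length(nb)), nobs, length(nb))
      bidx <- match(block_of, names(nb))
      eps <- sqrt(1 - rho) * eps + sqrt(rho) * shared[, bidx, drop = FALSE]
    }
    eps <- eps * config$noiseSd

    values <- intercept[grid$subject, , drop = FALSE] + eps
    is_post <- grid$timepoint != tp_ids[1L] | config$nTimepoints == 1L
    treat_on <- grid$arm == "treated" & is_post
    if (any(treat_on) && any(affected)) {
      mult <- do.call(rbind, lapply(config$subgroups, function(g)
        as.numeric(g$multipliers[names(nb)])))
      dimnames(mult) <- list(names(config$subgroups), names(nb))
      shift <- config$effectSize[block_of] * ifelse(affected, 1, 0)
      rows <- which(treat_on)
      values[rows, ] <- values[rows, ] +
        outer(rep(1, length(rows)), shift) *
        mult[subgroup[grid$subject[rows]], block_of, drop = FALSE]
    }
    colnames(values) <- param_ids

    table <- SampleTable(values, subject_id = grid$subject, arm = grid$arm,
                         timepoint = grid$timepoint)
    list(table = table,
         truth = list(subgroup = subgroup, affected = affected,
                      config = config, seed = as.integer(seed)))
  })
}

#' Default axis definitions matching a simulation config
#'
#' One axis per parameter block.  By default each affected parameter
#' contributes a single `mean_over_time` feature, so the per-axis feature
#' count equals the block's parameter count (e.g. 7 / 18 / 115 for the
#' `"full"` preset, 5 / 15 / 114 for `"no-diet"`); `kind = "both"` instead
#' yields the dual baseline + mean-over-time construction.
#'
#' @param config a [simulationConfig()] object.
#' @param kind feature kind per parameter: `"mean_over_time"` (default),
#'   `"baseline"`, or `"both"`.
#' @return a named list of [AxisDefinition-class], one per block.
#' @export
defaultAxes <- function(config = simulationConfig(),
                        kind = c("mean_over_time", "baseline", "both")) {
  kind <- match.arg(kind)
  nb <- config$blocks
  width <- max(2L, nchar(as.character(max(nb))))
  axes <- lapply(names(nb), function(b) {
    k <- round(config$fracAffected[[b]] * nb[[b]])
    if (k < 1L)
      stop("block '", b, "' has no affected parameters to build an axis from")
    AxisDefinition(b, sprintf("%s_%0*d", b, width, seq_len(k)), kind = kind)
  })
  stats::setNames(axes, names(nb))
}
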