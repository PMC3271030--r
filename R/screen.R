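#' Paired two-sided t test on subject-matched arm values
#'
#' Wrapper around the classical paired t test with the degenerate-input
#' policy used by the screening stage: fewer than 3 complete pairs is an
#' error; zero variance of the within-subject differences yields `p = 1`
#' with a warning (the statistic is undefined, no evidence either way).
#'
#' @param treated,control numeric vectors of per-subject values, paired by
#'   position (same subject order).
#' @return list with `statistic` (t, `NA` in the zero-variance case),
#'   `p.value`, and `meanDifference` (treated - control).
#' @export
pairedTest <- function(treated, control) {
  if (length(treated) != length(control))
    stop("treated and control must be paired by subject (equal length)")
  ok <- stats::complete.cases(treated, control)
  d <- treated[ok] - control[ok]
  if (length(d) < 3L)
    stop("paired test needs at least 3 complete subject pairs (got ",
         length(d), ")")
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences; returning p = 1")
    return(list(statistic = NA_real_, p.value = 1, meanDifference = mean(d)))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       meanDifference = mean(d))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around `stats::p.adjust(method = "BH")`.  Adjusted
#' values are pointwise `>=` the raw p values and invariant to input
#' permutation (up to the same permutation).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, in input order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p values must be numeric")
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p values outside [0, 1] at position(s): ",
         paste(bad, collapse = ", "))
  stats::p.adjust(p, method = "BH")
}

# per-subject per-arm means over all timepoints: list(treated =, control =)
# of subjects x parameters matrices with aligned, sorted subject rows
.subjectArmMeans <- function(table, completeOnly = TRUE) {
  vals <- .sampleValues(table)
  cd <- SummarizedExperiment::colData(table)
  subj <- as.character(cd$subject_id)
  arm <- as.character(cd$arm)
  subjects <- sort(unique(subj))
  if (completeOnly) {
    keep <- vapply(subjects, function(s)
      all(c("treated", "control") %in% arm[subj == s]), TRUE)
    subjects <- subjects[keep]
  }
  per_arm <- function(a) {
    idx <- arm == a & subj %in% subjects
    v <- vals[idx, , drop = FALSE]
    obs <- !is.na(v)
    v[!obs] <- 0
    m <- rowsum(v, subj[idx]) / rowsum(obs + 0, subj[idx])
    m[is.nan(m)] <- NA_real_
    m[subjects, , drop = FALSE]
  }
  list(treated = per_arm("treated"), control = per_arm("control"),
       subjects = subjects)
}

#' Univariate significance screen of all parameters
#'
#' Applies [pairedTest()] per parameter on the per-subject arm means
#' (averaged over timepoints), then [bhAdjust()] across all tested
#' parameters as one family, and flags `q <= alpha`.  This is the screening
#' step that selects which parameters define the health-space axes;
#' alternatively, curated [AxisDefinition-class] lists may be supplied
#' directly and the screen skipped.
#'
#' Parameters that cannot be tested (zero difference variance or too few
#' pairs) are reported with `p = 1` / `NA` and never flagged; a warning is
#' emitted per skipped parameter.
#'
#' @param table a valid cross-over [SampleTable-class].
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return a `data.frame` (one row per parameter) with columns
#'   `parameter_id`, `mean_difference` (treated - control),
#'   `p_value`, `q_value`, `significant`; the `alpha` used is stored as an
#'   attribute.
#' @export
screenParameters <- function(table, alpha = 0.05) {
  stopifnot(methods::is(table, "SampleTable"))
  am <- .subjectArmMeans(table)
  params <- rownames(table)
  res <- lapply(params, function(pm) {
    out <- tryCatch(
      withCallingHandlers(
        pairedTest(am$treated[, pm], am$control[, pm]),
        warning = function(w) {
          warning("parameter '", pm, "': ", conditionMessage(w), call. = FALSE)
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        warning("parameter '", pm, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(out))
      data.frame(parameter_id = pm, mean_difference = NA_real_,
                 p_value = NA_real_, tested = FALSE)
    else
      data.frame(parameter_id = pm, mean_difference = out$meanDifference,
                 p_value = out$p.value, tested = TRUE)
  })
  res <- do.call(rbind, res)
  res$q_value <- NA_real_
  res$q_value[res$tested] <- bhAdjust(res$p_value[res$tested])
  res$significant <- !is.na(res$q_value) & res$q_value <= alpha
  res$tested <- NULL
  attr(res, "alpha") <- alpha
  res
}

#' Build axis definitions from a screen result
#'
#' Keeps, per process, the parameters flagged significant by
#' [screenParameters()] — the data-driven analogue of defining each axis
#' from the significantly changed parameters of its process.
#'
#' @param screen result of [screenParameters()].
#' @param processes named list mapping each process name to its candidate
#'   parameter ids (a parameter may belong to several processes).
#' @param kind feature kind passed to [AxisDefinition()] (default
#'   `"mean_over_time"`; use `"both"` for baseline + mean features).
#' @return named list of [AxisDefinition-class]; processes with no
#'   significant parameter are dropped with a warning.
#' @export
axesFromScreen <- function(screen, processes, kind = "mean_over_time") {
  sig <- screen$parameter_id[screen$significant]
  axes <- list()
  for (nm in names(processes)) {
    keep <- intersect(processes[[nm]], sig)
    if (!length(keep)) {
      warning("process '", nm, "' has no significant parameters; axis dropped")
      next
    }
    axes[[nm]] <- AxisDefinition(nm, keep, kind = kind)
  }
  axes
}

#' @rdname screenParameters
#' @param screen a screen result (for writing).
#' @param path output TSV path.
#' @export
writeScreenResult <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
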