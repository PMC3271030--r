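#' Build the per-axis PLS-DA design from a sample table
#'
#' Collapses the (subject, arm, timepoint) samples of a cross-over study into
#' one row per (subject, arm) and one column per axis feature:
#' \describe{
#'   \item{baseline}{the value at the earliest timepoint of that arm's
#'     period (each cross-over period carries its own baseline).}
#'   \item{mean_over_time}{the arithmetic mean of the subject-arm's values
#'     across all timepoints of the period.}
#' }
#' The class code is `y = 0` for treated and `y = 1` for control rows, the
#' coding that anchors the health-space scaling.  Rows are ordered treated
#' block first, control block second, subjects sorted within each block, so
#' downstream fold assignment is deterministic and independent of the input
#' row order.
#'
#' Missing values: a parameter with more than `maxMissing` missing entries is
#' dropped (all its features) with a warning; remaining missing entries are
#' imputed with the parameter mean computed within the same arm.
#' Subjects lacking one of the two arms are dropped with a warning.
#'
#' @param table a valid [SampleTable-class].
#' @param axis an [AxisDefinition-class]; all its parameters must exist in
#'   `table`.
#' @param maxMissing maximum tolerated fraction of missing entries per
#'   parameter before the parameter is dropped (default 0.2).
#' @return a [FeatureMatrix-class].
#' @examples
#' st <- SampleTable(matrix(c(2, 4, 1, 3), 4, 1, dimnames = list(NULL, "p")),
#'                   subject_id = rep("s1", 4),
#'                   arm = rep(c("treated", "control"), each = 2),
#'                   timepoint = c("t0", "t1", "t0", "t1"))
#' buildFeatureMatrix(st, AxisDefinition("ax", "p", "both"))
#' @export
buildFeatureMatrix <- function(table, axis, maxMissing = 0.2) {
  stopifnot(methods::is(table, "SampleTable"), methods::is(axis, "AxisDefinition"))
  feats <- axis@features
  unknown <- setdiff(unique(feats$parameter), rownames(table))
  if (length(unknown))
    stop("axis '", axis@name, "' names unknown parameter(s): ",
         paste(unknown, collapse = ", "))

  vals <- .sampleValues(table)[, unique(feats$parameter), drop = FALSE]
  cd <- SummarizedExperiment::colData(table)
  subj <- as.character(cd$subject_id)
  arm <- as.character(cd$arm)
  tp <- cd$timepoint

  frac_na <- colMeans(is.na(vals))
  drop <- names(frac_na)[frac_na > maxMissing]
  if (length(drop)) {
    warning("dropping parameter(s) with > ", maxMissing * 100,
            "% missing values: ", paste(drop, collapse = ", "))
    feats <- feats[!feats$parameter %in% drop, , drop = FALSE]
    if (!nrow(feats))
      stop("axis '", axis@name, "' has no usable features after missing-value filtering")
    vals <- vals[, unique(feats$parameter), drop = FALSE]
  }
  # arm-wise mean imputation for the tolerated missing entries
  if (anyNA(vals)) {
    for (a in c("treated", "control")) {
      idx <- arm == a
      block <- vals[idx, , drop = FALSE]
      na_cols <- which(colSums(is.na(block)) > 0)
      for (j in na_cols) {
        m <- mean(block[, j], na.rm = TRUE)
        if (is.nan(m))
          stop("parameter '", colnames(vals)[j],
               "' has no observed values in the ", a, " arm")
        block[is.na(block[, j]), j] <- m
      }
      vals[idx, ] <- block
    }
  }

  subjects <- sort(unique(subj))
  has_arm <- vapply(subjects, function(s)
    all(c("treated", "control") %in% arm[subj == s]), TRUE)
  if (any(!has_arm)) {
    warning("dropping subject(s) without both arms: ",
            paste(subjects[!has_arm], collapse = ", "))
    subjects <- subjects[has_arm]
  }
  if (!length(subjects)) stop("no complete subjects (both arms) in the table")

  grid <- expand.grid(subject = subjects, arm = c("treated", "control"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_ids <- paste(grid$subject, grid$arm, sep = "\r")
  keep <- subj %in% subjects
  key <- paste(subj, arm, sep = "\r")[keep]
  vk <- vals[keep, , drop = FALSE]
  # per-cell means over timepoints
  sums <- rowsum(vk, key)
  counts <- as.vector(table(key)[rownames(sums)])
  meansM <- sums / counts
  # per-cell baseline: earliest timepoint within the (subject, arm) period
  first <- which(!duplicated(key[order(key, cd$timepoint[keep])]))
  ord <- order(key, cd$timepoint[keep])
  baseM <- vk[ord[first], , drop = FALSE]
  rownames(baseM) <- key[ord[first]]

  mrow <- match(cell_ids, rownames(meansM))
  brow <- match(cell_ids, rownames(baseM))
  design <- matrix(NA_real_, nrow(grid), nrow(feats))
  is_base <- feats$kind == "baseline"
  if (any(is_base))
    design[, is_base] <- baseM[brow, feats$parameter[is_base], drop = FALSE]
  if (any(!is_base))
    design[, !is_base] <- meansM[mrow, feats$parameter[!is_base], drop = FALSE]
  colnames(design) <- paste(feats$parameter, feats$kind, sep = ".")
  rownames(design) <- paste(grid$subject, grid$arm, sep = ".")
  methods::new("FeatureMatrix",
               design = design,
               y = as.numeric(grid$arm == "control"),
               subjectIds = grid$subject,
               columnInfo = feats)
}
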