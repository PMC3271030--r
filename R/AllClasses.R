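#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

setOldClass("hclust")

#' SampleTable: measured parameters of a cross-over study
#'
#' A `SampleTable` holds the wide table of plasma parameter values
#' (metabolites, proteins, clinical chemistry) together with per-sample
#' metadata.  It extends [SummarizedExperiment::SummarizedExperiment] with the
#' usual Bioconductor orientation: rows are parameters, columns are samples.
#' One sample is one (subject, arm, timepoint) observation; in a cross-over
#' design every subject contributes samples under both the treated and the
#' control arm.
#'
#' Required `colData` columns:
#' \describe{
#'   \item{subject_id}{character subject identifier}
#'   \item{arm}{factor with levels `treated`, `control`}
#'   \item{timepoint}{ordered factor of within-period timepoints (may be a
#'     single level for studies with one observation per period)}
#' }
#'
#' @seealso [SampleTable()], [validateSampleTable()], [readSampleTable()]
#' @export
setClass("SampleTable", contains = "SummarizedExperiment")

setValidity("SampleTable", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "arm")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if ("arm" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$arm)), c("treated", "control"))
    if (length(bad))
      msg <- c(msg, paste0("arm values must be 'treated' or 'control'; found: ",
                           paste(bad, collapse = ", ")))
  }
  pid <- rownames(object)
  if (is.null(pid) || anyNA(pid))
    msg <- c(msg, "parameter ids (rownames) must be present")
  else if (anyDuplicated(pid))
    msg <- c(msg, paste0("duplicate parameter ids: ",
                         paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' AxisDefinition: the parameterization of one health-space axis
#'
#' Maps one biological process (e.g. "oxidation") to the list of parameters
#' whose values span its axis.  Each feature is a (parameter, kind) pair where
#' `kind` is `"baseline"` (the value at the first timepoint of each treatment
#' period) or `"mean_over_time"` (the mean across all timepoints of the
#' period).  A parameter may carry both kinds, and may appear in several axes
#' (biological processes overlap).
#'
#' @slot name single character, the process name.
#' @slot features `data.frame` with columns `parameter` and `kind`.
#' @seealso [AxisDefinition()], [readAxisDefinitions()], [defaultAxes()]
#' @export
setClass("AxisDefinition",
         representation(name = "character", features = "data.frame"))

setValidity("AxisDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  f <- object@features
  if (!all(c("parameter", "kind") %in% colnames(f)))
    msg <- c(msg, "features must have columns 'parameter' and 'kind'")
  else {
    bad <- setdiff(unique(f$kind), c("baseline", "mean_over_time"))
    if (length(bad))
      msg <- c(msg, paste0("unknown feature kind(s): ", paste(bad, collapse = ", ")))
    key <- paste(f$parameter, f$kind)
    if (anyDuplicated(key))
      msg <- c(msg, paste0("duplicated (parameter, kind) pair(s): ",
                           paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: the per-axis PLS-DA design
#'
#' One row per (subject, arm); columns are the axis features.  The class code
#' is `y = 0` for the treated arm and `y = 1` for the control arm, matching
#' the health-space anchors (treated mean scaled to 0, control mean to 1).
#'
#' @slot design numeric matrix, rows = subject-arm observations.
#' @slot y numeric vector of 0/1 class codes (0 = treated, 1 = control).
#' @slot subjectIds character, one per row.
#' @slot columnInfo `data.frame` with `parameter`, `kind` per design column.
#' @export
setClass("FeatureMatrix",
         representation(design = "matrix", y = "numeric",
                        subjectIds = "character", columnInfo = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@design) != length(object@y))
    msg <- c(msg, "length(y) must equal nrow(design)")
  if (nrow(object@design) != length(object@subjectIds))
    msg <- c(msg, "length(subjectIds) must equal nrow(design)")
  if (ncol(object@design) != nrow(object@columnInfo))
    msg <- c(msg, "columnInfo must describe every design column")
  if (length(object@y) && !all(object@y %in% c(0, 1)))
    msg <- c(msg, "y must be coded 0 (treated) / 1 (control)")
  if (length(msg)) msg else TRUE
})

#' PlsModel: a fitted autoscaled NIPALS PLS1 model
#'
#' Stores the autoscaling constants and the NIPALS weights/loadings of a
#' two-class PLS-DA fit.  Prediction is affine in the raw features:
#' `predict(x) = intercept + sum(coefficientsRaw * x)`.
#'
#' @slot centers,scales per-feature autoscaling constants (sample sd, n-1).
#' @slot zeroVariance logical flag per feature (scaled by 1, not dropped).
#' @slot weights,xLoadings p x A matrices of NIPALS weights W and loadings P.
#' @slot yLoadings length-A vector q.
#' @slot nComponents number of components actually fitted.
#' @slot coefficients regression vector on the autoscaled scale.
#' @slot coefficientsRaw,intercept the same model on the raw feature scale.
#' @slot yMean mean of the class code in the training data.
#' @slot featureNames column names of the training design.
#' @export
setClass("PlsModel",
         representation(centers = "numeric", scales = "numeric",
                        zeroVariance = "logical",
                        weights = "matrix", xLoadings = "matrix",
                        yLoadings = "numeric", nComponents = "integer",
                        coefficients = "numeric", coefficientsRaw = "numeric",
                        intercept = "numeric", yMean = "numeric",
                        featureNames = "character"))

#' DcvResult: out-of-fold scores from double cross-validation
#'
#' The outer loop partitions subjects (both arms of a subject travel
#' together); the inner loop selects the component count.  Every sample
#' receives exactly one out-of-fold (oof) prediction score, produced by a
#' model whose training data excluded that sample's subject.
#'
#' @slot oofScores numeric, one oof prediction score per sample.
#' @slot y the 0/1 class codes.
#' @slot subjectIds per-sample subject ids.
#' @slot outerFold per-sample outer-fold assignment.
#' @slot chosenComponents per-outer-fold selected component count.
#' @slot misclassRate fraction of samples whose score falls on the wrong
#'   side of 0.5.
#' @export
setClass("DcvResult",
         representation(oofScores = "numeric", y = "numeric",
                        subjectIds = "character", outerFold = "integer",
                        chosenComponents = "integer", misclassRate = "numeric"))

setValidity("DcvResult", function(object) {
  msg <- character()
  n <- length(object@oofScores)
  if (length(object@y) != n || length(object@subjectIds) != n ||
      length(object@outerFold) != n)
    msg <- c(msg, "per-sample slots must have equal length")
  if (anyNA(object@oofScores))
    msg <- c(msg, "every sample must have an oof score")
  if (length(object@chosenComponents) && any(object@chosenComponents < 1L))
    msg <- c(msg, "chosenComponents must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ScoreSet: scaled per-sample coordinates in the health space
#'
#' One row per (subject, arm) observation, one column per axis.  Scores are
#' dimensionless: on every axis the treated-group mean is 0 and the
#' control-group mean is 1 by construction (anchor scaling).  Between-axis
#' quantitative comparison is intentionally undefined — the anchors make
#' scores comparable *within* an axis only.
#'
#' @slot scores numeric matrix, samples x axes.
#' @slot subjectId,arm per-row metadata (`arm` has levels treated/control).
#' @export
setClass("ScoreSet",
         representation(scores = "matrix", subjectId = "character",
                        arm = "factor"))

setValidity("ScoreSet", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@subjectId) ||
      nrow(object@scores) != length(object@arm))
    msg <- c(msg, "metadata length must equal nrow(scores)")
  if (!all(levels(object@arm) == c("treated", "control")))
    msg <- c(msg, "arm must be a factor with levels treated, control")
  if (is.null(colnames(object@scores)))
    msg <- c(msg, "scores must carry axis names as colnames")
  if (length(msg)) msg else TRUE
})

#' HealthSpaceModel: the fitted space
#'
#' One entry per axis: its definition, the final refit [PlsModel] (for
#' projecting new samples), the scaling anchors (treated-group and
#' control-group mean raw scores), and the double-CV diagnostics of the
#' training run.
#'
#' @slot axes named list; each element has `definition`, `model`, `anchors`
#'   (numeric `c(treated, control)`), `dcv` ([DcvResult] or NULL) and
#'   `refitAnchorOffset` (refit-vs-oof anchor diagnostic).
#' @slot settings list of fold counts, component cap, seed, score type.
#' @export
setClass("HealthSpaceModel",
         representation(axes = "list", settings = "list"))

#' ResponseSet: per-subject treatment-response vectors
#'
#' One row per complete subject; each entry is the control-arm score minus
#' the treated-arm score on one axis, so a positive value means the treatment
#' moved the subject toward the healthy origin.  `cluster` is NA before
#' clustering and for outliers.
#'
#' @slot responses numeric matrix, subjects x axes.
#' @slot subjectId character, one per row.
#' @slot cluster integer cluster labels (NA = unassigned/outlier).
#' @slot outlier logical outlier flags.
#' @slot dendrogram the `hclust` tree of the last clustering (or NULL).
#' @export
setClass("ResponseSet",
         representation(responses = "matrix", subjectId = "character",
                        cluster = "integer", outlier = "logical",
                        dendrogram = "ANY"))

setValidity("ResponseSet", function(object) {
  msg <- character()
  n <- nrow(object@responses)
  if (length(object@subjectId) != n || length(object@cluster) != n ||
      length(object@outlier) != n)
    msg <- c(msg, "per-subject slots must have equal length")
  if (anyDuplicated(object@subjectId))
    msg <- c(msg, "one record per subject: duplicated subject ids")
  if (length(msg)) msg else TRUE
})
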