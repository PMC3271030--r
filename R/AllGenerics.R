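#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("armLabels", function(x, ...) standardGeneric("armLabels"))

#' @rdname accessors
#' @export
setGeneric("parameterIds", function(x, ...) standardGeneric("parameterIds"))

#' @rdname accessors
#' @export
setGeneric("axisNames", function(x, ...) standardGeneric("axisNames"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x, ...) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("responseMatrix", function(x, ...) standardGeneric("responseMatrix"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("isOutlier", function(x, ...) standardGeneric("isOutlier"))

#' @rdname accessors
#' @export
setGeneric("anchors", function(x, ...) standardGeneric("anchors"))

#' Accessors for healthspace objects
#'
#' Small read-only accessors: `subjectIds()`, `armLabels()`, `parameterIds()`,
#' `axisNames()`, `scoreMatrix()` (samples x axes scaled scores),
#' `responseMatrix()` (subjects x axes response vectors), `clusterLabels()`,
#' `isOutlier()`, and `anchors()` (per-axis treated/control mean raw scores
#' of a [HealthSpaceModel]).
#'
#' @param x a healthspace object.
#' @param ... unused.
#' @return the requested component; see each class's documentation.
#' @name accessors
NULL

#' @rdname accessors
setMethod("subjectIds", "SampleTable",
          function(x) as.character(SummarizedExperiment::colData(x)$subject_id))
#' @rdname accessors
setMethod("subjectIds", "ScoreSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectIds", "ResponseSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectIds", "FeatureMatrix", function(x) x@subjectIds)

#' @rdname accessors
setMethod("armLabels", "SampleTable",
          function(x) factor(as.character(SummarizedExperiment::colData(x)$arm),
                             levels = c("treated", "control")))
#' @rdname accessors
setMethod("armLabels", "ScoreSet", function(x) x@arm)

#' @rdname accessors
setMethod("parameterIds", "SampleTable", function(x) rownames(x))

#' @rdname accessors
setMethod("axisNames", "ScoreSet", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("axisNames", "ResponseSet", function(x) colnames(x@responses))
#' @rdname accessors
setMethod("axisNames", "HealthSpaceModel", function(x) names(x@axes))

#' @rdname accessors
setMethod("scoreMatrix", "ScoreSet", function(x) x@scores)

#' @rdname accessors
setMethod("responseMatrix", "ResponseSet", function(x) x@responses)

#' @rdname accessors
setMethod("clusterLabels", "ResponseSet",
          function(x) stats::setNames(x@cluster, x@subjectId))

#' @rdname accessors
setMethod("isOutlier", "ResponseSet",
          function(x) stats::setNames(x@outlier, x@subjectId))

#' @rdname accessors
setMethod("anchors", "HealthSpaceModel", function(x) {
  do.call(rbind, lapply(x@axes, function(a) a$anchors))
})

setMethod("show", "AxisDefinition", function(object) {
  cat("AxisDefinition '", object@name, "': ", nrow(object@features),
      " feature(s) over ", length(unique(object@features$parameter)),
      " parameter(s)\n", sep = "")
  tab <- table(object@features$kind)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@design), "subject-arm rows x",
      ncol(object@design), "features;",
      sum(object@y == 0), "treated /", sum(object@y == 1), "control\n")
})

setMethod("show", "PlsModel", function(object) {
  cat("PlsModel:", length(object@centers), "features,",
      object@nComponents, "component(s)\n")
  if (any(object@zeroVariance))
    cat("  zero-variance features:", sum(object@zeroVariance), "\n")
})

setMethod("show", "DcvResult", function(object) {
  cat("DcvResult:", length(object@oofScores), "oof scores over",
      length(object@chosenComponents), "outer folds\n")
  cat("  chosen components:", paste(object@chosenComponents, collapse = " "), "\n")
  cat("  misclassification rate:", format(object@misclassRate, digits = 3), "\n")
})

setMethod("show", "ScoreSet", function(object) {
  cat("ScoreSet:", nrow(object@scores), "samples x", ncol(object@scores),
      "axes (", paste(colnames(object@scores), collapse = ", "), ")\n")
  mt <- colMeans(object@scores[object@arm == "treated", , drop = FALSE])
  mc <- colMeans(object@scores[object@arm == "control", , drop = FALSE])
  cat("  treated means:", paste(format(mt, digits = 2), collapse = " "), "\n")
  cat("  control means:", paste(format(mc, digits = 2), collapse = " "), "\n")
})

setMethod("show", "HealthSpaceModel", function(object) {
  cat("HealthSpaceModel with", length(object@axes), "axes:\n")
  for (nm in names(object@axes)) {
    a <- object@axes[[nm]]
    cat("  ", nm, ": ", length(a$model@centers), " features, ",
        a$model@nComponents, " comp; anchors (treated, control) = (",
        format(a$anchors[1], digits = 3), ", ",
        format(a$anchors[2], digits = 3), ")",
        if (!is.null(a$dcv)) paste0("; oof misclass ",
                                    format(a$dcv@misclassRate, digits = 3)),
        "\n", sep = "")
  }
})

setMethod("show", "ResponseSet", function(object) {
  cat("ResponseSet:", nrow(object@responses), "subjects x",
      ncol(object@responses), "axes\n")
  if (any(object@outlier))
    cat("  outliers:", paste(object@subjectId[object@outlier], collapse = ", "), "\n")
  if (!all(is.na(object@cluster))) {
    tab <- table(object@cluster, useNA = "no")
    cat("  clusters:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
})
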