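#' Anchor-scale raw PLS-DA scores to the 0/1 group means
#'
#' The affine map applied simultaneously to all scores of one axis:
#' `s' = (s - mean_treated) / (mean_control - mean_treated)`, so the treated
#' group has mean 0 (the "healthy" origin) and the control group mean 1.
#' The map makes scores comparable within an axis; it deliberately does not
#' make different axes quantitatively comparable.  An anti-separating axis
#' (control mean below treated mean) is sign-flipped by the same map — the
#' anchors canonicalize score orientation.
#'
#' @param raw numeric vector of raw prediction scores.
#' @param treated,control logical masks (or index vectors) selecting each
#'   group's samples; both must be non-empty.
#' @return numeric vector of scaled scores.
#' @export
scaleScores <- function(raw, treated, control) {
  mt <- mean(raw[treated])
  mc <- mean(raw[control])
  if (!length(raw[treated]) || !length(raw[control]) || is.na(mt) || is.na(mc))
    stop("both groups must be non-empty")
  if (mc == mt)
    stop("degenerate axis: treated and control mean scores are equal")
  (raw - mt) / (mc - mt)
}

# internal ScoreSet constructor
.scoreSet <- function(scores, subjectId, arm) {
  methods::new("ScoreSet", scores = scores, subjectId = as.character(subjectId),
               arm = factor(as.character(arm), levels = c("treated", "control")))
}

#' Build a health space from a sample table and axis definitions
#'
#' For every axis: assemble the (subject, arm) feature matrix
#' ([buildFeatureMatrix()]), run autoscaled double cross-validated PLS-DA
#' ([doubleCrossValidate()]), and anchor-scale the resulting out-of-fold
#' prediction scores ([scaleScores()]) so the treated-group mean is 0 and
#' the control-group mean 1.  A final model refit on all data is stored per
#' axis, together with the scaling anchors, so new samples can later be
#' projected into the same space with [projectSamples()].
#'
#' With `scoreType = "refit"` the reported scores come from the all-data
#' refit model instead of double CV (optimistically biased; the default oof
#' scores are the unbiased reading).  An axis whose out-of-fold
#' misclassification rate is near chance triggers an "axis may be
#' uninformative" warning; an axis whose group mean scores coincide is
#' degenerate and fails construction.
#'
#' @param table a valid cross-over [SampleTable-class].
#' @param axes list of [AxisDefinition-class] (one or more; no minimum of 3
#'   is imposed).
#' @param outerFolds,innerFolds,maxComponents double-CV settings, see
#'   [doubleCrossValidate()].
#' @param scoreType `"oof"` (default) or `"refit"`.
#' @param seed master seed; per-axis fold seeds are derived from it.
#' @return list with `model` (a [HealthSpaceModel-class]) and `scores`
#'   (a [ScoreSet-class] satisfying the 0/1 anchor invariant).
#' @examples
#' cfg <- simulationConfig(nSubjects = 12, blocks = c(oxidation = 3),
#'                         nTimepoints = 1)
#' sim <- simulateStudy(cfg, seed = 7)
#' hs <- buildHealthSpace(sim$table, defaultAxes(cfg), outerFolds = 4,
#'                        innerFolds = 3, seed = 7)
#' colMeans(scoreMatrix(hs$scores)[armLabels(hs$scores) == "treated", , drop = FALSE])
#' @export
buildHealthSpace <- function(table, axes, outerFolds = 7L, innerFolds = 5L,
                             maxComponents = 10L,
                             scoreType = c("oof", "refit"), seed = 1L) {
  scoreType <- match.arg(scoreType)
  stopifnot(methods::is(table, "SampleTable"), length(axes) >= 1L)
  viol <- validateSampleTable(table, crossover = FALSE)
  if (nrow(viol))
    stop("invalid sample table: ", paste(viol$detail, collapse = "; "))
  axis_names <- vapply(axes, function(a) a@name, "")
  names(axes) <- axis_names
  seeds <- .childSeeds(seed, length(axes))

  fitted <- vector("list", length(axes))
  score_cols <- vector("list", length(axes))
  ref_ids <- NULL
  ref_subj <- ref_arm <- NULL
  for (i in seq_along(axes)) {
    ax <- axes[[i]]
    fm <- buildFeatureMatrix(table, ax)
    if (is.null(ref_ids)) {
      ref_ids <- rownames(fm@design)
      ref_subj <- fm@subjectIds
      ref_arm <- ifelse(fm@y == 0, "treated", "control")
    } else if (!identical(rownames(fm@design), ref_ids)) {
      stop("axis '", ax@name, "' resolves to a different subject-arm set ",
           "than the preceding axes (uneven missing data?)")
    }
    dcv <- NULL
    if (scoreType == "oof") {
      dcv <- doubleCrossValidate(fm@design, fm@y, fm@subjectIds,
                                 outerFolds = outerFolds,
                                 innerFolds = innerFolds,
                                 maxComponents = maxComponents,
                                 seed = seeds[i])
      if (dcv@misclassRate >= 0.45)
        warning("axis '", ax@name, "': out-of-fold misclassification ",
                format(dcv@misclassRate, digits = 3),
                " is near chance; axis may be uninformative")
      ncomp <- max(1L, as.integer(round(stats::median(dcv@chosenComponents))))
      raw <- dcv@oofScores
    } else {
      ncomp <- .innerSelect(fm@design, fm@y, fm@subjectIds, innerFolds,
                            max(1L, min(maxComponents, ncol(fm@design),
                                        nrow(fm@design) - 2L)))
    }
    refit <- suppressWarnings(fitPls(fm@design, fm@y, ncomp))
    refit_raw <- predict(refit, fm@design)
    if (scoreType == "refit") raw <- refit_raw

    treated <- fm@y == 0
    anchors_used <- c(treated = mean(raw[treated]),
                      control = mean(raw[!treated]))
    anchors_refit <- c(treated = mean(refit_raw[treated]),
                       control = mean(refit_raw[!treated]))
    scaled <- tryCatch(scaleScores(raw, treated, !treated),
                       error = function(e)
                         stop("axis '", ax@name, "': ", conditionMessage(e),
                              call. = FALSE))
    fitted[[i]] <- list(definition = ax, model = refit,
                        anchors = anchors_used, dcv = dcv,
                        refitAnchorOffset = anchors_refit - anchors_used)
    score_cols[[i]] <- scaled
  }

  scores <- do.call(cbind, score_cols)
  dimnames(scores) <- list(ref_ids, axis_names)
  model <- methods::new("HealthSpaceModel",
                        axes = stats::setNames(fitted, axis_names),
                        settings = list(outerFolds = as.integer(outerFolds),
                                        innerFolds = as.integer(innerFolds),
                                        maxComponents = as.integer(maxComponents),
                                        scoreType = scoreType,
                                        seed = as.integer(seed)))
  list(model = model, scores = .scoreSet(scores, ref_subj, ref_arm))
}

#' Project samples into an existing health space
#'
#' Applies each axis's stored autoscaling and refit PLS-DA coefficients to
#' the new table and rescales with the *stored* anchors — nothing is
#' re-estimated, so projected scores live in the original space.  Projecting
#' the training table reproduces the anchor means only approximately when
#' the space was built from out-of-fold scores (the refit-vs-oof offset,
#' reported per axis in the model, is the discrepancy); with
#' `scoreType = "refit"` the reproduction is exact.
#'
#' @param model a [HealthSpaceModel-class].
#' @param table a [SampleTable-class] whose parameters cover every model
#'   feature (missing parameters raise an error naming them).
#' @return a [ScoreSet-class] of projected scores.
#' @export
projectSamples <- function(model, table) {
  stopifnot(methods::is(model, "HealthSpaceModel"),
            methods::is(table, "SampleTable"))
  cols <- lapply(model@axes, function(ax) {
    fm <- buildFeatureMatrix(table, ax$definition)
    raw <- predict(ax$model, fm@design)
    list(ids = rownames(fm@design), subj = fm@subjectIds,
         arm = ifelse(fm@y == 0, "treated", "control"),
         scaled = (raw - ax$anchors[["treated"]]) /
           (ax$anchors[["control"]] - ax$anchors[["treated"]]))
  })
  ids <- cols[[1L]]$ids
  scores <- vapply(cols, function(cc) cc$scaled, numeric(length(ids)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  dimnames(scores) <- list(ids, names(model@axes))
  .scoreSet(scores, cols[[1L]]$subj, cols[[1L]]$arm)
}

#' Export a ScoreSet as TSV
#'
#' Columns: `subject_id`, `arm`, one column per axis (scaled scores).
#'
#' @param scores a [ScoreSet-class].
#' @param path output path.
#' @export
writeScores <- function(scores, path) {
  df <- data.frame(subject_id = scores@subjectId,
                   arm = as.character(scores@arm),
                   scores@scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export double-CV diagnostics as TSV
#'
#' Columns: `sample_id`, `subject_id`, `arm`, `axis`, `oof_score`,
#' `outer_fold`, `chosen_components`.
#'
#' @param model a [HealthSpaceModel-class] built with `scoreType = "oof"`.
#' @param path output path.
#' @export
writeDcvDiagnostics <- function(model, path) {
  rows <- lapply(names(model@axes), function(nm) {
    d <- model@axes[[nm]]$dcv
    if (is.null(d)) return(NULL)
    data.frame(sample_id = names(d@oofScores), subject_id = d@subjectIds,
               arm = ifelse(d@y == 0, "treated", "control"), axis = nm,
               oof_score = unname(d@oofScores), outer_fold = d@outerFold,
               chosen_components = d@chosenComponents[d@outerFold])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("model carries no double-CV diagnostics")
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a HealthSpaceModel as a versioned JSON document
#'
#' The document stores, per axis, the definition, the refit PLS model
#' (autoscaling constants, weights, loadings, coefficients) and the scaling
#' anchors, plus the run settings — everything [projectSamples()] needs.
#'
#' @param model a [HealthSpaceModel-class].
#' @param path file path.
#' @return `loadHealthSpaceModel` returns the reconstructed model;
#'   `saveHealthSpaceModel` returns `path` invisibly.  Double-CV
#'   diagnostics are not serialized.
#' @export
saveHealthSpaceModel <- function(model, path) {
  doc <- list(
    schema = "healthspace-model",
    schema_version = 1L,
    settings = model@settings,
    axes = lapply(model@axes, function(ax) {
      m <- ax$model
      list(name = ax$definition@name,
           features = ax$definition@features,
           anchors = as.list(ax$anchors),
           refit_anchor_offset = as.list(ax$refitAnchorOffset),
           model = list(centers = unname(m@centers), scales = unname(m@scales),
                        zero_variance = unname(m@zeroVariance),
                        weights = m@weights, x_loadings = m@xLoadings,
                        y_loadings = m@yLoadings,
                        n_components = m@nComponents,
                        coefficients = m@coefficients,
                        coefficients_raw = m@coefficientsRaw,
                        intercept = m@intercept, y_mean = m@yMean,
                        feature_names = m@featureNames))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveHealthSpaceModel
#' @export
loadHealthSpaceModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  if (!identical(doc$schema, "healthspace-model"))
    stop("not a health-space model document: ", path)
  axes <- lapply(doc$axes, function(ax) {
    m <- ax$model
    fn <- as.character(m$feature_names)
    p <- length(fn)
    as_mat <- function(x) {
      x <- as.matrix(x)
      if (!length(x)) matrix(0, p, 0) else x
    }
    pls <- methods::new("PlsModel",
                        centers = stats::setNames(as.numeric(m$centers), fn),
                        scales = stats::setNames(as.numeric(m$scales), fn),
                        zeroVariance = stats::setNames(as.logical(m$zero_variance), fn),
                        weights = as_mat(m$weights),
                        xLoadings = as_mat(m$x_loadings),
                        yLoadings = as.numeric(m$y_loadings),
                        nComponents = as.integer(m$n_components),
                        coefficients = as.numeric(m$coefficients),
                        coefficientsRaw = as.numeric(m$coefficients_raw),
                        intercept = as.numeric(m$intercept),
                        yMean = as.numeric(m$y_mean),
                        featureNames = fn)
    def <- AxisDefinition(ax$name, ax$features$parameter, ax$features$kind)
    list(definition = def, model = pls,
         anchors = c(treated = as.numeric(ax$anchors$treated),
                     control = as.numeric(ax$anchors$control)),
         dcv = NULL,
         refitAnchorOffset = c(treated = as.numeric(ax$refit_anchor_offset$treated),
                               control = as.numeric(ax$refit_anchor_offset$control)))
  })
  nm <- vapply(axes, function(a) a$definition@name, "")
  methods::new("HealthSpaceModel", axes = stats::setNames(axes, nm),
               settings = as.list(doc$settings))
}
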