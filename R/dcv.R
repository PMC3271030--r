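#' Double (nested) cross-validated PLS-DA
#'
#' The outer loop partitions *subjects* — both arms of a subject always
#' travel together, so no fold ever trains on one arm of a held-out subject.
#' For each outer fold, an inner k-fold cross-validation over the
#' outer-training subjects selects the component count minimizing the inner
#' misclassification rate (a score `>= 0.5` predicts class 1; ties go to the
#' smallest count).  A model with that count, autoscaled on the
#' outer-training rows only, then predicts the held-out samples, yielding
#' one out-of-fold (oof) prediction score per sample.  These oof scores —
#' not refit-on-all-data scores — are the unbiased coordinates consumed by
#' the health-space scaling.
#'
#' @param X numeric feature matrix, one row per (subject, arm).
#' @param y 0/1 class code per row (0 = treated, 1 = control).
#' @param subjectIds subject id per row; the grouping unit of the outer loop.
#' @param outerFolds,innerFolds fold counts (defaults 7 and 5).
#' @param maxComponents cap on the candidate component counts (default 10;
#'   further capped by fold size and feature count).
#' @param seed integer seed making the fold assignment reproducible.
#' @return a [DcvResult-class].
#' @export
doubleCrossValidate <- function(X, y, subjectIds,
                                outerFolds = 7L, innerFolds = 5L,
                                maxComponents = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  subjectIds <- as.character(subjectIds)
  stopifnot(nrow(X) == length(y), nrow(X) == length(subjectIds))
  if (length(unique(y)) != 2L)
    stop("double cross-validation needs exactly two classes")
  subjects <- sort(unique(subjectIds))
  if (length(subjects) < outerFolds)
    stop("double cross-validation needs at least ", outerFolds,
         " subjects (one per outer fold); got ", length(subjects))

  fold_of <- .withSeed(seed, {
    stats::setNames(sample(rep_len(seq_len(outerFolds), length(subjects))),
                    sample(subjects))
  })
  oof <- rep(NA_real_, nrow(X))
  outer_fold_row <- unname(fold_of[subjectIds])
  chosen <- integer(outerFolds)

  for (k in seq_len(outerFolds)) {
    test_rows <- which(outer_fold_row == k)
    train_rows <- which(outer_fold_row != k)
    if (length(unique(y[train_rows])) != 2L)
      stop("outer fold ", k, " leaves a single-class training set; ",
           "use fewer folds or more subjects")
    chosen[k] <- .innerSelect(X[train_rows, , drop = FALSE], y[train_rows],
                              subjectIds[train_rows], innerFolds,
                              maxComponents)
    fit <- suppressWarnings(
      fitPls(X[train_rows, , drop = FALSE], y[train_rows], chosen[k]))
    chosen[k] <- fit@nComponents
    oof[test_rows] <- predict(fit, X[test_rows, , drop = FALSE])
  }
  methods::new("DcvResult",
               oofScores = stats::setNames(oof, rownames(X)),
               y = y, subjectIds = subjectIds,
               outerFold = as.integer(outer_fold_row),
               chosenComponents = pmax(chosen, 1L),
               misclassRate = mean((oof >= 0.5) != (y == 1)))
}

# Inner CV over subjects of the outer-training set: pooled oof predictions
# per candidate component count; returns the count with minimal
# misclassification (ties -> fewest components).
.innerSelect <- function(X, y, subjectIds, innerFolds, maxComponents) {
  subjects <- sort(unique(subjectIds))
  innerFolds <- min(innerFolds, length(subjects))
  # deterministic inner assignment: subjects are already in sorted order and
  # the outer loop fixed which subjects appear here
  fold_of <- stats::setNames(rep_len(seq_len(innerFolds), length(subjects)),
                             subjects)
  fold_row <- unname(fold_of[subjectIds])
  A <- max(1L, min(maxComponents, ncol(X), nrow(X) - 2L))
  pred <- matrix(NA_real_, nrow(X), A)
  for (k in seq_len(innerFolds)) {
    tr <- which(fold_row != k)
    te <- which(fold_row == k)
    if (!length(te)) next
    if (length(unique(y[tr])) != 2L) next
    fit <- suppressWarnings(fitPls(X[tr, , drop = FALSE], y[tr], A))
    pk <- .plsPredictPerComponent(fit, X[te, , drop = FALSE])
    if (ncol(pk) < A)  # fold supported fewer components: carry the last fit
      pk <- cbind(pk, matrix(pk[, ncol(pk)], length(te), A - ncol(pk)))
    pred[te, ] <- pk
  }
  ok <- !is.na(pred[, 1L])
  if (!any(ok)) return(1L)
  err <- colMeans((pred[ok, , drop = FALSE] >= 0.5) != (y[ok] == 1))
  which.min(err)  # which.min takes the first (= smallest count) on ties
}
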