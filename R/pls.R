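#' Autoscale a feature matrix
#'
#' Centers every column to mean 0 and scales it to unit sample standard
#' deviation (n - 1 denominator).  Zero-variance columns are centered but
#' scaled by 1 and flagged, never dropped, so the column geometry is stable
#' across cross-validation folds.
#'
#' @param X numeric matrix with at least 2 rows.
#' @return list with `X` (scaled matrix), `centers`, `scales`,
#'   `zeroVariance` (logical flag per column).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("autoscaling needs at least 2 rows")
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers, "-")
  scales <- sqrt(colSums(Xc^2) / (n - 1))
  zero <- scales == 0 | !is.finite(scales)
  scales[zero] <- 1
  Xs <- sweep(Xc, 2L, scales, "/")
  list(X = Xs, centers = centers, scales = scales, zeroVariance = zero)
}

#' Fit a two-class PLS-DA model (NIPALS PLS1)
#'
#' Autoscales `X`, centers the 0/1 class code `y`, and runs the NIPALS PLS1
#' deflation: per component the weight vector is `w = E'f / ||E'f||`, scores
#' `t = E w`, x-loadings `p = E't / t't`, y-loading `q = f't / t't`, then
#' `E <- E - t p'` and `f <- f - q t`.  For a single response this update is
#' exact per component (no inner iteration is needed).  Successive score
#' vectors are mutually orthogonal, and with as many components as the rank
#' of `X` the training predictions coincide with ordinary least squares.
#'
#' If the requested component count exceeds what the data support (residual
#' X or weight norm below `tol`), the model is capped with a warning.  A
#' constant `y` yields a 0-component model predicting `mean(y)`.
#'
#' @param X numeric feature matrix (raw scale; autoscaling is internal).
#' @param y numeric class code, 0 = treated / 1 = control (any two-valued
#'   numeric coding works).
#' @param nComponents number of latent components requested.
#' @param tol numerical tolerance declaring a residual direction exhausted
#'   (default 1e-12).
#' @return a [PlsModel-class].
#' @seealso [doubleCrossValidate()]
#' @export
fitPls <- function(X, y, nComponents, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nComponents >= 1)
  sc <- autoscale(X)
  p <- ncol(X)
  ymean <- mean(y)
  E <- sc$X
  f <- y - ymean
  A <- as.integer(nComponents)
  W <- matrix(0, p, 0)
  P <- matrix(0, p, 0)
  q <- numeric(0)
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < tol) break
    w <- w / wn
    t_a <- E %*% w
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(E, t_a) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - t_a %*% t(p_a)
    f <- f - q_a * t_a
    W <- cbind(W, w)
    P <- cbind(P, p_a)
    q <- c(q, q_a)
  }
  nfit <- ncol(W)
  if (nfit < A)
    warning("requested ", A, " components but the data support only ", nfit,
            "; model capped")
  beta <- if (nfit > 0L)
    as.numeric(W %*% solve(crossprod(P, W), q))
  else
    numeric(p)
  beta_raw <- beta / sc$scales
  intercept <- ymean - sum(beta_raw * sc$centers)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  methods::new("PlsModel",
               centers = stats::setNames(sc$centers, fn),
               scales = stats::setNames(sc$scales, fn),
               zeroVariance = stats::setNames(sc$zeroVariance, fn),
               weights = W, xLoadings = P, yLoadings = q,
               nComponents = as.integer(nfit),
               coefficients = beta, coefficientsRaw = beta_raw,
               intercept = intercept, yMean = ymean, featureNames = fn)
}

#' Predict PLS-DA scores for new samples
#'
#' Applies the stored autoscaling and regression vector; the prediction is
#' affine in the raw features,
#' `score(x) = intercept + sum(coefficientsRaw * x)`.
#'
#' @param object a [PlsModel-class].
#' @param newdata numeric matrix (or vector for one sample) with the model's
#'   features in training column order.
#' @param ... unused.
#' @return numeric vector of prediction scores (the quantity later anchored
#'   to 0/1 by [scaleScores()]).
#' @export
setMethod("predict", "PlsModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@centers))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object@centers))
  as.numeric(object@intercept + newdata %*% object@coefficientsRaw)
})

# Cumulative per-component predictions: n x A matrix, column a holding the
# prediction of the a-component truncation. A 0-component model yields a
# single constant column.
.plsPredictPerComponent <- function(model, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  A <- model@nComponents
  Xs <- sweep(sweep(newdata, 2L, model@centers, "-"), 2L, model@scales, "/")
  if (A == 0L)
    return(matrix(model@yMean, nrow(newdata), 1L))
  out <- matrix(NA_real_, nrow(newdata), A)
  R <- crossprod(model@xLoadings, model@weights)  # upper unitriangular
  for (a in seq_len(A)) {
    Wa <- model@weights[, seq_len(a), drop = FALSE]
    beta <- Wa %*% solve(R[seq_len(a), seq_len(a), drop = FALSE],
                         model@yLoadings[seq_len(a)])
    out[, a] <- model@yMean + Xs %*% beta
  }
  out
}

# Training X-scores (for orthogonality checks and diagnostics)
.plsScores <- function(model, X) {
  Xs <- sweep(sweep(as.matrix(X), 2L, model@centers, "-"), 2L, model@scales, "/")
  R <- crossprod(model@xLoadings, model@weights)
  Xs %*% (model@weights %*% solve(R))
}
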