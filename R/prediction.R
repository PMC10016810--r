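#' Standardize features on a training fold
#'
#' Column means and standard deviations (population convention, divisor `n`)
#' are computed on the training rows only and applied to both training and
#' test rows, so no information leaks from the held-out subject.
#' Zero-variance training columns are dropped from both matrices with a
#' warning.
#'
#' @param train_X,test_X numeric matrices with identical columns (`test_X`
#'   may be `NULL`).
#' @return list with `train_Z`, `test_Z`, `center`, `scale`, `dropped`.
#' @export
standardize_fold <- function(train_X, test_X = NULL) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) < 2L) stop("training fold needs at least 2 rows")
  mu <- colMeans(train_X)
  sdv <- sqrt(colMeans(sweep(train_X, 2L, mu)^2))
  keep <- sdv > 0
  if (!any(keep)) stop("all training columns have zero variance")
  dropped <- colnames(train_X)[!keep]
  if (length(dropped)) {
    warning("dropping zero-variance columns: ", paste(dropped, collapse = ", "))
  }
  zt <- sweep(sweep(train_X[, keep, drop = FALSE], 2L, mu[keep]),
              2L, sdv[keep], `/`)
  ztest <- NULL
  if (!is.null(test_X)) {
    test_X <- matrix(test_X, ncol = ncol(train_X),
                     dimnames = list(NULL, colnames(train_X)))
    ztest <- sweep(sweep(test_X[, keep, drop = FALSE], 2L, mu[keep]),
                   2L, sdv[keep], `/`)
  }
  list(train_Z = zt, test_Z = ztest, center = mu[keep], scale = sdv[keep],
       dropped = dropped)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing feature j on
#' all other features with an intercept. Perfectly collinear features
#' (R2 within 1e-10 of 1) are reported as `Inf`. With a single feature all
#' VIFs are 1 by convention. When the system has more features than rows a
#' tiny ridge (1e-8) stabilizes the auxiliary regressions.
#'
#' @param Z numeric matrix of features (columns named).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(Z) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  if (p == 1L) {
    return(stats::setNames(1, colnames(Z)))
  }
  out <- numeric(p)
  n <- nrow(Z)
  for (j in seq_len(p)) {
    yj <- Z[, j]
    Xj <- cbind(1, Z[, -j, drop = FALSE])
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) { # constant column: inflated by definition of the ratio
      out[j] <- Inf
      next
    }
    fit <- tryCatch(qr.coef(qr(Xj), yj), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit) || n <= ncol(Xj)) {
      # rank-deficient or under-determined: ridge-stabilized auxiliary fit
      XtX <- crossprod(Xj) + diag(1e-8, ncol(Xj))
      fit <- solve(XtX, crossprod(Xj, yj))
    }
    rss <- sum((yj - Xj %*% fit)^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(Z))
}

#' Iterative VIF-based feature elimination
#'
#' Repeatedly removes the non-protected feature with the highest VIF until
#' all VIFs are at or below `threshold`. Ties are broken by reverse column
#' order (later-added connectivity features are removed first). If the
#' threshold cannot be reached using only non-protected features, the
#' protected set is returned with a warning.
#'
#' @param Z standardized feature matrix with named columns.
#' @param threshold VIF threshold (> 1).
#' @param protected character vector of feature names never removed.
#' @return character vector of retained feature names, in original column
#'   order.
#' @export
vif_select <- function(Z, threshold, protected = character(0)) {
  stopifnot(threshold > 1)
  Z <- as.matrix(Z)
  keep <- colnames(Z)
  repeat {
    v <- vif(Z[, keep, drop = FALSE])
    removable <- setdiff(keep, protected)
    if (length(removable) == 0L) {
      if (any(v > threshold)) {
        warning("VIF threshold unreachable with non-protected features; ",
                "returning protected set")
      }
      break
    }
    vr <- v[removable]
    if (max(v) <= threshold) break
    if (max(vr) <= threshold) {
      warning("remaining collinearity involves only protected features; ",
              "stopping elimination")
      break
    }
    # highest VIF among removable; ties -> latest column removed first
    worst <- removable[vr == max(vr)]
    drop_name <- worst[length(worst)]
    keep <- setdiff(keep, drop_name)
    if (length(keep) == 1L) break
  }
  colnames(Z)[colnames(Z) %in% keep]
}

#' Fit a ridge regression on standardized features
#'
#' Minimizes `(1/N) ||y - X b||^2 + lambda ||b||^2`; the intercept is handled
#' by centring the target on its training mean, so the coefficients solve the
#' stationarity system `(Z'Z + N * lambda * I) b = Z'y_centred`.
#'
#' @param Z standardized training features.
#' @param y training target.
#' @param lambda nonnegative regularization strength.
#' @return object of class `ridge_model` with `coefficients`, `lambda`,
#'   `y_mean`, `feature_names`.
#' @export
ridge_fit <- function(Z, y, lambda) {
  Z <- as.matrix(Z)
  stopifnot(length(y) == nrow(Z), lambda >= 0)
  n <- nrow(Z)
  ym <- mean(y)
  yc <- y - ym
  A <- crossprod(Z) + diag(n * lambda, ncol(Z))
  beta <- tryCatch(solve(A, crossprod(Z, yc)), error = function(e) {
    stop("singular ridge system (collinear features at lambda = 0); ",
         "use a positive lambda", call. = FALSE)
  })
  structure(
    list(coefficients = stats::setNames(as.numeric(beta), colnames(Z)),
         lambda = lambda, y_mean = ym, feature_names = colnames(Z)),
    class = "ridge_model"
  )
}

#' @param object a `ridge_model`.
#' @param newdata standardized feature matrix.
#' @param ... unused.
#' @rdname ridge_fit
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(object$y_mean + newdata %*% object$coefficients)
}

#' Default logarithmic lambda grid
#'
#' 25 logarithmically spaced values from 1e-3 to 1e3.
#'
#' @return numeric vector.
#' @export
default_lambda_grid <- function() {
  10^seq(-3, 3, length.out = 25)
}

#' Inner leave-one-out search for the ridge penalty
#'
#' For each candidate lambda, computes the leave-one-out mean squared
#' prediction error within the training fold (refitting standardization-free:
#' the features are assumed already standardized on this fold) and returns
#' the lambda with minimal error; ties go to the smallest lambda.
#'
#' @param train_Z standardized training features.
#' @param train_y training target.
#' @param grid nonempty numeric vector of candidate lambdas.
#' @return the selected lambda (scalar).
#' @export
inner_lambda_search <- function(train_Z, train_y, grid = default_lambda_grid()) {
  stopifnot(length(grid) > 0)
  train_Z <- as.matrix(train_Z)
  n <- nrow(train_Z)
  grid <- sort(grid)
  errs <- vapply(grid, function(lam) {
    se <- numeric(n)
    for (i in seq_len(n)) {
      fit <- ridge_fit(train_Z[-i, , drop = FALSE], train_y[-i], lam)
      se[i] <- (train_y[i] - predict(fit, train_Z[i, , drop = FALSE]))^2
    }
    mean(se)
  }, numeric(1))
  grid[which.min(errs)]
}

#' Coefficient of determination anchored on the prediction mean
#'
#' `R2 = 1 - sum((Y - Y')^2) / sum((Y - mean(Y'))^2)`: the denominator is
#' centred on the mean of the *predicted* scores. The conventional variant
#' (denominator centred on `mean(Y)`) is available with
#' `conventional = TRUE` but is never the default.
#'
#' @param Y observed values.
#' @param Yprime predicted values.
#' @param conventional use the textbook denominator instead.
#' @return scalar R-squared (may be negative).
#' @export
r_squared <- function(Y, Yprime, conventional = FALSE) {
  stopifnot(length(Y) == length(Yprime), length(Y) >= 2)
  anchor <- if (conventional) mean(Y) else mean(Yprime)
  den <- sum((Y - anchor)^2)
  if (den == 0) stop("zero denominator in R-squared")
  1 - sum((Y - Yprime)^2) / den
}

#' Leave-one-subject-out prediction with in-fold selection
#'
#' For each patient: standardizes features on the remaining patients, runs
#' VIF elimination (when `vif_threshold` is finite; feature sets 4 and 5),
#' selects the ridge penalty by an inner leave-one-out grid search on the
#' training fold, fits, and predicts the held-out patient. Standardization
#' statistics, VIF decisions and the penalty therefore never see the held-out
#' subject.
#'
#' @param ft a `feature_table`.
#' @param vif_threshold VIF threshold; `Inf` (default) disables selection.
#' @param grid lambda grid for the inner search.
#' @param protected features exempt from VIF elimination; defaults to the
#'   clinical benchmarks `age`, `fma_2w`, `cst_asymmetry` (lesion volume and
#'   connectivity measures remain eligible).
#' @return object of class `prediction_result` with observed/predicted
#'   targets, the prediction-mean R-squared, per-fold selected features,
#'   weights, chosen lambdas, selection counts and fold-averaged weights.
#' @export
loo_predict <- function(ft, vif_threshold = Inf, grid = default_lambda_grid(),
                        protected = c("age", "fma_2w", "cst_asymmetry")) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$X)
  if (n < 3L) stop("leave-one-out prediction needs at least 3 patients")
  feats <- colnames(ft$X)
  protected <- intersect(protected, feats)
  y_pred <- numeric(n)
  sel <- vector("list", n)
  wts <- matrix(NA_real_, n, length(feats), dimnames = list(ft$ids, feats))
  lambdas <- numeric(n)
  for (i in seq_len(n)) {
    if (stats::sd(ft$y[-i]) == 0) {
      stop("degenerate fold: zero-variance target in fold ", i)
    }
    st <- standardize_fold(ft$X[-i, , drop = FALSE],
                           ft$X[i, , drop = FALSE])
    zt <- st$train_Z
    selected <- colnames(zt)
    if (is.finite(vif_threshold)) {
      selected <- vif_select(zt, vif_threshold, protected = protected)
      zt <- zt[, selected, drop = FALSE]
    }
    lam <- inner_lambda_search(zt, ft$y[-i], grid)
    fit <- ridge_fit(zt, ft$y[-i], lam)
    y_pred[i] <- predict(fit, st$test_Z[, selected, drop = FALSE])
    sel[[i]] <- selected
    wts[i, selected] <- fit$coefficients
    lambdas[i] <- lam
  }
  counts <- colSums(!is.na(wts))
  structure(
    list(
      ids = ft$ids,
      y_obs = ft$y,
      y_pred = y_pred,
      r2 = r_squared(ft$y, y_pred),
      set_id = ft$set_id,
      target_kind = ft$target_kind,
      vif_threshold = vif_threshold,
      selected = sel,
      lambda = lambdas,
      weights = wts,
      selection_count = counts,
      weight_mean = colMeans(wts, na.rm = TRUE),
      weight_sd = apply(wts, 2L, stats::sd, na.rm = TRUE)
    ),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> set %d (%s), n = %d, LOO R2 = %.3f\n",
    x$set_id %||% NA, x$target_kind, length(x$y_obs), x$r2
  ))
  invisible(x)
}

#' Sweep VIF thresholds
#'
#' Runs the full leave-one-out prediction at each VIF threshold and reports
#' the accuracy curve. The pipeline's operating threshold is a configuration
#' value and is never auto-selected from this (outer) curve, which would
#' leak test information into the selection.
#'
#' @param ft a `feature_table`.
#' @param thresholds integer thresholds to evaluate (default 5..200).
#' @param grid lambda grid.
#' @param protected protected features (see [loo_predict()]).
#' @return data.frame with columns `threshold`, `r2`, `n_features` (mean
#'   number of retained features per fold).
#' @export
vif_sweep <- function(ft, thresholds = 5:200, grid = default_lambda_grid(),
                      protected = c("age", "fma_2w", "cst_asymmetry")) {
  rows <- lapply(thresholds, function(th) {
    res <- loo_predict(ft, vif_threshold = th, grid = grid,
                       protected = protected)
    data.frame(threshold = th, r2 = res$r2,
               n_features = mean(lengths(res$selected)))
  })
  do.call(rbind, rows)
}
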