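#' Fitter labels from the 30% recovery threshold
#'
#' A patient is a fitter of the proportional recovery rule when the FMA
#' recovery score strictly exceeds 30 percentage points; a score of exactly
#' 30 is labelled non-fitter.
#'
#' @param recovery_scores numeric vector of recovery scores (% points).
#' @return logical vector, `TRUE` = fitter.
#' @export
label_fitters_threshold <- function(recovery_scores) {
  if (any(!is.finite(recovery_scores))) stop("recovery scores must be finite")
  recovery_scores > 30
}

#' Fitter labels by two-group hierarchical clustering
#'
#' Compares each patient's actual recovery (`fma_3m - fma_2w` points) with
#' the expectation of the 70% proportional recovery model
#' (`0.7 * (66 - fma_2w)` points) and splits the cohort in two by
#' agglomerative hierarchical clustering (average linkage by default), cut at
#' two clusters; the cluster with the higher mean actual/expected ratio is
#' labelled fitter.
#'
#' By default patients are clustered on the standardized recovery ratio
#' `actual / expected`, the quantity in which the two recovery patterns are
#' actually separated. Patient-level Spearman distance is degenerate for 2-D
#' points (any two distinct points correlate exactly +/-1), and Euclidean
#' clustering of the raw `(expected, actual)` plane confounds recovery
#' pattern with baseline severity (the fitter/non-fitter boundary is a line
#' through the origin, not a point gap); the plane variant remains available
#' via `coords = "plane"`. The default is validated by its agreement with the
#' 30% threshold rule on separated cohorts.
#'
#' @param expected numeric vector of expected recovery points (> 0).
#' @param actual numeric vector of actually recovered points.
#' @param coords cluster on the standardized recovery `"ratio"` (default) or
#'   on the standardized 2-D `"plane"`.
#' @param method distance for [stats::dist()] (default `"euclidean"`).
#' @param linkage linkage for [stats::hclust()] (default `"average"`).
#' @return logical vector, `TRUE` = fitter.
#' @export
label_fitters_clustering <- function(expected, actual,
                                     coords = c("ratio", "plane"),
                                     method = "euclidean",
                                     linkage = "average") {
  coords <- match.arg(coords)
  stopifnot(length(expected) == length(actual), length(expected) >= 4,
            all(expected > 0))
  pts <- if (coords == "ratio") {
    cbind(ratio = actual / expected)
  } else {
    cbind(expected, actual)
  }
  if (all(apply(pts, 2L, stats::sd) == 0)) {
    warning("all patients identical; returning a single (non-fitter) class")
    return(rep(FALSE, length(expected)))
  }
  z <- scale(pts)
  z[, apply(pts, 2L, stats::sd) == 0] <- 0
  hc <- stats::hclust(stats::dist(z, method = method), method = linkage)
  cl <- stats::cutree(hc, k = 2)
  ratio <- actual / expected
  fitter_cluster <- names(which.max(tapply(ratio, cl, mean)))
  cl == as.integer(fitter_cluster)
}

#' Classification metrics for fitter prediction
#'
#' Positive class = fitter. Ratios with zero denominators are reported as
#' `NA` (missing), never as 0.
#'
#' @param labels_true,labels_pred logical vectors (`TRUE` = fitter).
#' @return object of class `classification_result` with confusion counts and
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
classification_metrics <- function(labels_true, labels_pred) {
  stopifnot(length(labels_true) == length(labels_pred),
            length(labels_true) > 0)
  tp <- sum(labels_true & labels_pred)
  fn <- sum(labels_true & !labels_pred)
  tn <- sum(!labels_true & !labels_pred)
  fp <- sum(!labels_true & labels_pred)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp),
      npv = ratio(tn, tn + fn)
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> TP %d FP %d TN %d FN %d | sens %.3f spec %.3f ppv %.3f npv %.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$ppv, x$npv
  ))
  invisible(x)
}

#' Bootstrap confidence interval for the prediction R-squared
#'
#' Draws `n_draws` subsamples of `subsample` predicted/observed pairs
#' (without replacement by default; 32-of-37-style subsampling), computes the
#' prediction-mean R-squared on each, and reports the empirical 2.5 and 97.5
#' percentiles.
#'
#' @param Y observed targets.
#' @param Yprime predicted targets.
#' @param n_draws number of bootstrap draws (default 10000).
#' @param subsample points per draw (default 32, must be <= `length(Y)`).
#' @param seed RNG seed.
#' @param replace draw with replacement instead.
#' @return list of class `bootstrap_ci` with `point_r2`, `lower`, `upper`,
#'   `n_draws`, `subsample_size`, `seed`.
#' @export
bootstrap_r2_ci <- function(Y, Yprime, n_draws = 10000, subsample = 32,
                            seed = 42L, replace = FALSE) {
  stopifnot(length(Y) == length(Yprime), subsample >= 2)
  if (!replace && subsample > length(Y)) {
    stop("subsample size exceeds the number of predictions")
  }
  r2s <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(length(Y), subsample, replace = replace)
      r_squared(Y[idx], Yprime[idx])
    }, numeric(1))
  })
  qs <- stats::quantile(r2s, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(point_r2 = r_squared(Y, Yprime), lower = qs[1L], upper = qs[2L],
         n_draws = n_draws, subsample_size = subsample, seed = seed),
    class = "bootstrap_ci"
  )
}

#' Spearman correlations with Bonferroni correction
#'
#' Spearman rho (average ranks for ties) of each feature against the target,
#' with p-values from the t approximation and Bonferroni adjustment
#' `p_adj = min(1, m_tests * p_raw)`. Constant features yield `NA` rho.
#'
#' @param features numeric matrix (patients x features, named columns).
#' @param target numeric vector.
#' @param m_tests number of tests for the correction (defaults to the number
#'   of features).
#' @return data.frame with `feature`, `rho`, `p_raw`, `p_adj`.
#' @export
spearman_bonferroni <- function(features, target, m_tests = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(n >= 3, length(target) == n)
  m_tests <- m_tests %||% ncol(features)
  res <- lapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    if (stats::sd(x) == 0 || stats::sd(target) == 0) {
      return(data.frame(feature = colnames(features)[j], rho = NA_real_,
                        p_raw = NA_real_, p_adj = NA_real_))
    }
    rho <- stats::cor(x, target, method = "spearman")
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
    data.frame(feature = colnames(features)[j], rho = rho, p_raw = p,
               p_adj = min(1, m_tests * p))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test (fitters vs non-fitters)
#'
#' Computes the Mann-Whitney U statistic of `group_a`, a tie-corrected
#' standardized z value, and a two-sided p-value. For small samples
#' (`choose(n, n_a) <= max_exact_comb`) the p-value is exact, obtained by
#' enumerating all group assignments; otherwise the tie-corrected normal
#' approximation is used. Both U and z are reported.
#'
#' @param group_a,group_b numeric vectors (nonempty).
#' @param max_exact_comb enumeration budget for the exact p-value.
#' @return list with `u`, `z`, `p`, `exact`.
#' @export
wilcoxon_ranksum <- function(group_a, group_b, max_exact_comb = 20000) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 1, nb >= 1, na + nb >= 2)
  x <- c(group_a, group_b)
  r <- rank(x)
  n <- na + nb
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 <= 0) 0 else (u - mu) / sqrt(sigma2)
  exact <- choose(n, na) <= max_exact_comb
  if (exact) {
    combs <- utils::combn(n, na)
    rs <- colSums(matrix(r[combs], nrow = na))
    us <- rs - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
  } else {
    p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(z))
  }
  list(u = u, z = z, p = p, exact = exact)
}

#' Feature dendrogram on Spearman correlation distance
#'
#' Distance between features f and g is `1 - spearman_rho(f, g)`; average
#' linkage. Constant features are excluded with a warning. Returns the tree
#' and the two feature groups of the first split.
#'
#' @param feature_matrix numeric matrix (patients x features, >= 3 usable
#'   features).
#' @return list with `hclust` (the tree) and `groups` (list of two character
#'   vectors).
#' @export
feature_dendrogram <- function(feature_matrix) {
  feature_matrix <- as.matrix(feature_matrix)
  sds <- apply(feature_matrix, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant features: ",
            paste(colnames(feature_matrix)[sds == 0], collapse = ", "))
    feature_matrix <- feature_matrix[, sds > 0, drop = FALSE]
  }
  if (ncol(feature_matrix) < 3L) stop("need at least 3 non-constant features")
  rho <- stats::cor(feature_matrix, method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = 2)
  list(
    hclust = hc,
    groups = split(names(cl), cl)
  )
}
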