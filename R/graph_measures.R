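#' Names of the connectivity measures, in reporting order
#'
#' Eleven binary-graph measures followed by seven weighted-graph measures.
#' Node-level measures are summarised by their mean and/or median across
#' nodes, yielding one global value each.
#'
#' @return character vector of 18 measure keys.
#' @export
measure_names <- function() {
  c(
    # binary
    "density", "degree_median", "clustering_mean", "clustering_median",
    "flow_mean", "transitivity", "modularity",
    "eigcent_mean", "eigcent_median",
    "betweenness_mean", "betweenness_median",
    # weighted
    "algebraic_connectivity", "eigcent_w_mean", "eigcent_w_median",
    "modularity_w", "global_efficiency_w", "participation_w_mean",
    "quasi_idempotence"
  )
}

#' Human-readable measure labels
#' @return named character vector mapping measure keys to display labels.
#' @export
measure_labels <- function() {
  c(
    density = "Density",
    degree_median = "Median degree",
    clustering_mean = "Mean clustering coefficient",
    clustering_median = "Median clustering coefficient",
    flow_mean = "Mean flow coefficient",
    transitivity = "Transitivity",
    modularity = "Modularity",
    eigcent_mean = "Mean eigenvector centrality",
    eigcent_median = "Median eigenvector centrality",
    betweenness_mean = "Mean betweenness centrality",
    betweenness_median = "Median betweenness centrality",
    algebraic_connectivity = "Algebraic connectivity",
    eigcent_w_mean = "Mean eigenvector centrality (weighted)",
    eigcent_w_median = "Median eigenvector centrality (weighted)",
    modularity_w = "Modularity (weighted)",
    global_efficiency_w = "Global efficiency",
    participation_w_mean = "Participation coefficient",
    quasi_idempotence = "Quasi-idempotence"
  )
}

#' Weighted density of a connectome
#'
#' Mean max-normalized edge weight over all node pairs:
#' `sum_{i<j} (w_ij / w_max) / (N(N-1)/2)`. Reduces to the binary density on
#' 0/1 matrices and is 0 for an all-zero matrix by convention. Used as the
#' target density for density-matched binarization.
#'
#' @param c a `connectome` or symmetric weight matrix.
#' @return real in `[0, 1]`.
#' @export
weighted_density <- function(c) {
  w <- as_connectome_matrix(c)
  wmax <- max(w)
  if (wmax <= 0) return(0)
  n <- nrow(w)
  sum(w[upper.tri(w)] / wmax) / (n * (n - 1) / 2)
}

#' Binarize a connectome to a target density
#'
#' Keeps the `k = round(target_density * N(N-1)/2)` largest-weight edges;
#' ties at the cutoff are broken by lexicographic (i, j) order. Zero-weight
#' pairs never become edges even when `k` would demand it, so the achieved
#' density can fall below the target on sparse matrices.
#'
#' @param c a `connectome` or weight matrix.
#' @param target_density real in `[0, 1]`.
#' @return list of class `binary_graph` with fields `adjacency` (0/1 matrix)
#'   and `threshold_used` (smallest retained weight, `Inf` for empty graph).
#' @export
binarize_to_density <- function(c, target_density) {
  assert_scalar_number(target_density, "target_density", 0, 1)
  w <- as_connectome_matrix(c)
  n <- nrow(w)
  m <- n * (n - 1) / 2
  k <- round(target_density * m)
  ut <- which(upper.tri(w))
  iw <- w[ut]
  pos <- which(iw > 0)
  # order candidate edges by decreasing weight, ties by (i, j) lexicographic,
  # which equals increasing column-major upper-tri position
  ord <- pos[order(-iw[pos], ut[pos])]
  keep <- ord[seq_len(min(k, length(ord)))]
  a <- matrix(0, n, n)
  a[ut[keep]] <- 1
  a <- a + t(a)
  structure(
    list(
      adjacency = a,
      threshold_used = if (length(keep)) min(iw[keep]) else Inf
    ),
    class = "binary_graph"
  )
}

# Build an igraph object from the positive upper-triangle entries of a
# symmetric matrix (symmetry is validated upstream); avoids the dense
# adjacency checks, which dominate when thousands of small connectomes are
# processed.
graph_from_weights <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0)
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  g <- igraph::make_undirected_graph(as.integer(rbind(i, j)), n = n)
  list(g = g, weights = w[ut])
}

# Principal eigenvector of a symmetric nonnegative matrix: nonnegative,
# unit Euclidean norm. For disconnected graphs the vector is supported on the
# component carrying the largest eigenvalue (Perron-Frobenius per component).
principal_eigenvector <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-12] <- 0
  v <- pmax(v, 0)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) return(rep(0, nrow(a)))
  v / nrm
}

# Seeded Louvain with restarts; returns membership of the best-Q partition.
louvain_partition <- function(g, weights = NULL, gamma = 1, seed = 42L,
                              restarts = 10L) {
  best_q <- -Inf
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g, weights = weights, resolution = gamma)
      q <- igraph::modularity(g, igraph::membership(cl), weights = weights)
      if (q > best_q) {
        best_q <- q
        best <- igraph::membership(cl)
      }
    }
  })
  list(membership = as.integer(best), q = best_q)
}

#' Binary graph measures
#'
#' Computes the binary-graph measures of the connectivity suite on a
#' binarized adjacency matrix: density, median degree, Watts-Strogatz local
#' clustering coefficient (mean, median; 0 for degree < 2), mean flow
#' coefficient (per node, the fraction of neighbour pairs not directly
#' connected, i.e. pairs whose shortest interconnection is the 2-path through
#' the node; 0 for degree < 2), transitivity, Newman modularity of a seeded
#' Louvain partition, eigenvector centrality (principal adjacency
#' eigenvector, nonnegative, unit norm; mean, median), and unnormalized
#' shortest-path betweenness centrality (mean, median).
#'
#' Empty graphs return density 0, all node summaries 0 and modularity 0 by
#' documented convention.
#'
#' @param b a `binary_graph` or 0/1 adjacency matrix.
#' @param seed seed for the Louvain restarts.
#' @param restarts number of Louvain restarts (best modularity kept).
#' @return named numeric vector with the 11 binary measure keys.
#' @export
binary_measure_suite <- function(b, seed = 42L, restarts = 10L) {
  a <- if (inherits(b, "binary_graph")) b$adjacency else as.matrix(b)
  n <- nrow(a)
  deg <- rowSums(a)
  n_edges <- sum(a) / 2
  out <- c(
    density = 2 * n_edges / (n * (n - 1)),
    degree_median = stats::median(deg)
  )
  if (n_edges == 0) {
    zero <- c(clustering_mean = 0, clustering_median = 0, flow_mean = 0,
              transitivity = 0, modularity = 0, eigcent_mean = 0,
              eigcent_median = 0, betweenness_mean = 0, betweenness_median = 0)
    return(c(out, zero))
  }
  g <- graph_from_weights(a)$g
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  # flow coefficient: neighbour pairs joined only via the central 2-path
  flow <- ifelse(deg < 2, 0, 1 - cc)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  part <- louvain_partition(g, weights = NULL, seed = seed, restarts = restarts)
  ec <- principal_eigenvector(a)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  c(out,
    clustering_mean = mean(cc),
    clustering_median = stats::median(cc),
    flow_mean = mean(flow),
    transitivity = trans,
    modularity = part$q,
    eigcent_mean = mean(ec),
    eigcent_median = stats::median(ec),
    betweenness_mean = mean(btw),
    betweenness_median = stats::median(btw))
}

#' Weighted graph measures
#'
#' Computes the weighted-graph measures on a connectome: algebraic
#' connectivity (second-smallest eigenvalue of the weighted Laplacian
#' `D - W`), eigenvector centrality of `W` (mean, median), weighted Newman
#' modularity of a seeded Louvain partition (resolution `gamma`), weighted
#' global efficiency (mean over ordered node pairs of inverse shortest-path
#' length with edge lengths `w_max / w_ij`; unreachable pairs contribute 0),
#' mean participation coefficient `1 - sum_m (s_im / s_i)^2` over the Louvain
#' modules (0 for isolated nodes), and quasi-idempotence (Pearson correlation
#' between the node strengths of the max-normalized matrix and of its square;
#' `NA` when either strength vector has zero variance).
#'
#' @param c a `connectome` or weight matrix.
#' @param gamma Louvain resolution parameter.
#' @param seed seed for the Louvain restarts.
#' @param restarts number of Louvain restarts.
#' @return named numeric vector with the 7 weighted measure keys
#'   (`quasi_idempotence` may be `NA`).
#' @export
weighted_measure_suite <- function(c, gamma = 1, seed = 42L, restarts = 10L) {
  w <- as_connectome_matrix(c)
  n <- nrow(w)
  strength <- rowSums(w)
  lap <- diag(strength) - w
  ev <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  algcon <- max(ev[2L], 0)
  wmax <- max(w)
  if (wmax <= 0) {
    return(c(algebraic_connectivity = 0, eigcent_w_mean = 0,
             eigcent_w_median = 0, modularity_w = 0, global_efficiency_w = 0,
             participation_w_mean = 0, quasi_idempotence = NA_real_))
  }
  ecw <- principal_eigenvector(w)
  gw <- graph_from_weights(w)
  part <- louvain_partition(gw$g, weights = gw$weights, gamma = gamma,
                            seed = seed, restarts = restarts)
  geff <- weighted_global_efficiency(w)
  # participation over the weighted Louvain modules
  memb <- part$membership
  pc <- vapply(seq_len(n), function(i) {
    si <- strength[i]
    if (si <= 0) return(0)
    sm <- rowsum(w[i, ], memb)
    1 - sum((sm / si)^2)
  }, numeric(1))
  wn <- w / wmax
  s1 <- rowSums(wn)
  s2 <- rowSums(wn %*% wn)
  qi <- if (stats::sd(s1) == 0 || stats::sd(s2) == 0) NA_real_ else
    stats::cor(s1, s2)
  c(algebraic_connectivity = algcon,
    eigcent_w_mean = mean(ecw),
    eigcent_w_median = stats::median(ecw),
    modularity_w = part$q,
    global_efficiency_w = geff,
    participation_w_mean = mean(pc),
    quasi_idempotence = qi)
}

#' Weighted global efficiency of a connectome
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' edge lengths `w_max / w_ij`; unreachable pairs contribute 0. Identical to
#' the `global_efficiency_w` entry of [weighted_measure_suite()] but cheap to
#' call on its own (no community detection), which matters when it is
#' evaluated for every patient-by-subject lesioned connectome.
#'
#' @param c a `connectome` or weight matrix.
#' @return real >= 0.
#' @export
weighted_global_efficiency <- function(c) {
  w <- as_connectome_matrix(c)
  n <- nrow(w)
  wmax <- max(w)
  if (wmax <= 0) return(0)
  gw <- graph_from_weights(w)
  d <- igraph::distances(gw$g, weights = wmax / gw$weights)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Full measure vector of one connectome
#'
#' Binarizes the connectome to its own weighted density (density-matched
#' binarization) and concatenates the binary and weighted measure suites.
#'
#' @inheritParams weighted_measure_suite
#' @return named numeric vector over [measure_names()].
#' @export
connectome_measures <- function(c, gamma = 1, seed = 42L, restarts = 10L) {
  b <- binarize_to_density(c, weighted_density(c))
  out <- c(binary_measure_suite(b, seed = seed, restarts = restarts),
           weighted_measure_suite(c, gamma = gamma, seed = seed,
                                  restarts = restarts))
  out[measure_names()]
}

#' Average measure vectors across virtually lesioned connectomes
#'
#' Arithmetic mean per measure across the (typically 60) lesioned healthy
#' connectomes of one patient. Missing values (e.g. undefined
#' quasi-idempotence) are excluded pairwise; the number of contributing
#' connectomes per measure is attached as attribute `n_used`.
#'
#' @param per_connectome list of named numeric vectors with identical names.
#' @return named numeric vector of means, with attribute `n_used`.
#' @export
patient_measure_average <- function(per_connectome) {
  if (length(per_connectome) == 0L) stop("empty measure list")
  keys <- names(per_connectome[[1L]])
  for (v in per_connectome) {
    if (!identical(names(v), keys)) stop("measure vectors must share keys")
  }
  mat <- do.call(rbind, per_connectome)
  means <- colMeans(mat, na.rm = TRUE)
  means[colSums(!is.na(mat)) == 0L] <- NA_real_
  structure(means, n_used = colSums(!is.na(mat)))
}
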