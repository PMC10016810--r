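# Independent brute-force oracles for the graph measures, used to validate
# the implementation on exhaustively enumerated small graphs.

# --- simple-path machinery on <= `n` labeled nodes -------------------------
# All simple paths between every ordered pair in the complete graph K_n are
# enumerated once; each path is stored as an edge bitmask so that validity on
# an arbitrary graph is a single bitwise test.

edge_id <- function(i, j, n) {
  # upper-triangle enumeration, column-major (i < j)
  if (i > j) { k <- i; i <- j; j <- k }
  (j - 1) * (j - 2) / 2 + i
}

enumerate_paths <- function(n) {
  nodes <- seq_len(n)
  out <- list()
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) res[[length(res) + 1]] <- c(v[i], p)
    }
    res
  }
  for (s in nodes) for (t in nodes) {
    if (s >= t) next
    inter <- setdiff(nodes, c(s, t))
    for (k in 0:length(inter)) {
      subsets <- if (k == 0) list(integer(0)) else
        utils::combn(inter, k, simplify = FALSE)
      for (sub in subsets) {
        for (p in perms(sub)) {
          path <- c(s, p, t)
          mask <- 0
          for (e in seq_len(length(path) - 1)) {
            mask <- bitwOr(mask, bitwShiftL(1L, edge_id(path[e], path[e + 1], n) - 1L))
          }
          out[[length(out) + 1]] <- list(s = s, t = t, mask = mask,
                                         len = length(path) - 1L,
                                         inner = p)
        }
      }
    }
  }
  out
}

graph_edge_mask <- function(a) {
  n <- nrow(a)
  mask <- 0
  for (j in 2:n) for (i in 1:(j - 1)) {
    if (a[i, j] > 0) mask <- bitwOr(mask, bitwShiftL(1L, edge_id(i, j, n) - 1L))
  }
  mask
}

# betweenness by exhaustive shortest-path enumeration
oracle_betweenness <- function(a, paths = enumerate_paths(nrow(a))) {
  n <- nrow(a)
  gmask <- graph_edge_mask(a)
  btw <- numeric(n)
  valid <- vapply(paths, function(p) bitwAnd(p$mask, gmask) == p$mask, logical(1))
  ps <- paths[valid]
  key <- vapply(ps, function(p) p$s * 100 + p$t, numeric(1))
  for (k in unique(key)) {
    grp <- ps[key == k]
    lens <- vapply(grp, `[[`, numeric(1), "len")
    short <- grp[lens == min(lens)]
    for (p in short) {
      for (v in p$inner) btw[v] <- btw[v] + 1 / length(short)
    }
  }
  btw
}

# transitivity by direct triangle / connected-triple counting
oracle_transitivity <- function(a) {
  n <- nrow(a)
  tri <- 0
  triples <- 0
  for (v in seq_len(n)) {
    nb <- which(a[v, ] > 0)
    if (length(nb) >= 2) {
      pairs <- utils::combn(nb, 2)
      triples <- triples + ncol(pairs)
      tri <- tri + sum(a[pairs[1, ] + (pairs[2, ] - 1) * n] > 0)
    }
  }
  if (triples == 0) 0 else tri / triples
}

# local clustering by neighbour-pair counting
oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- a[nb, nb]
    sum(sub[upper.tri(sub)] > 0) / (k * (k - 1) / 2)
  }, numeric(1))
}

# global efficiency by Floyd-Warshall on explicit length matrix
oracle_efficiency_weighted <- function(w) {
  n <- nrow(w)
  wmax <- max(w)
  if (wmax <= 0) return(0)
  d <- matrix(Inf, n, n)
  d[w > 0] <- wmax / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      upd <- nd < d[i, ]
      d[i, upd] <- nd[upd]
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# all set partitions of n elements (Bell enumeration, recursive)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# Newman modularity of a membership vector on a (possibly weighted) graph
oracle_modularity <- function(w, membership) {
  m2 <- sum(w)
  if (m2 == 0) return(0)
  k <- rowSums(w)
  b <- w - outer(k, k) / m2
  same <- outer(membership, membership, `==`)
  sum(b[same]) / m2
}

# maximal modularity over all partitions (exhaustive)
oracle_max_modularity <- function(w, partitions = all_partitions(nrow(w))) {
  best <- -Inf
  for (p in partitions) {
    memb <- integer(nrow(w))
    for (b in seq_along(p)) memb[p[[b]]] <- b
    best <- max(best, oracle_modularity(w, memb))
  }
  best
}

# characteristic polynomial eigenvalues via Faddeev-LeVerrier + polyroot
oracle_eigenvalues <- function(m) {
  n <- nrow(m)
  coefs <- numeric(n + 1)
  coefs[1] <- 1
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- m %*% M
    c_k <- -sum(diag(M)) / k
    coefs[k + 1] <- c_k
    M <- M + diag(c_k, n)
  }
  # polynomial: x^n + c1 x^(n-1) + ... + cn; polyroot wants ascending order
  r <- polyroot(rev(coefs))
  sort(Re(r))
}

# --- vectorized variants for the exhaustive 6-node sweep -------------------

# Precomputed path tables: per path its edge bitmask, (s,t) pair id, length,
# plus an expansion of inner-node occurrences for betweenness tallies.
make_path_tables <- function(n, paths = enumerate_paths(n)) {
  npairs <- n * (n - 1) / 2
  pair_of <- vapply(paths, function(p) edge_id(p$s, p$t, n), numeric(1))
  masks <- vapply(paths, `[[`, numeric(1), "mask")
  lens <- vapply(paths, `[[`, numeric(1), "len")
  inner_path <- integer(0)
  inner_node <- integer(0)
  for (k in seq_along(paths)) {
    for (v in paths[[k]]$inner) {
      inner_path <- c(inner_path, k)
      inner_node <- c(inner_node, v)
    }
  }
  list(n = n, npairs = npairs, pair = as.integer(pair_of),
       mask = as.integer(masks), len = as.integer(lens),
       max_len = max(lens), inner_path = inner_path, inner_node = inner_node)
}

# betweenness via the precomputed tables: identical semantics to
# oracle_betweenness but one vectorized pass per graph
oracle_betweenness_fast <- function(a, tab) {
  n <- tab$n
  gmask <- graph_edge_mask(a)
  valid <- bitwAnd(tab$mask, gmask) == tab$mask
  # counts of valid paths per (pair, len)
  bin <- tab$pair + tab$npairs * (tab$len - 1L)
  cnt <- matrix(tabulate(bin[valid], tab$npairs * tab$max_len),
                tab$npairs, tab$max_len)
  minlen <- apply(cnt > 0, 1, function(r) if (any(r)) which(r)[1] else 0L)
  # inner-node occurrences on valid paths, binned by (pair, node, len)
  vo <- valid[tab$inner_path]
  bin3 <- tab$pair[tab$inner_path][vo] +
    tab$npairs * (tab$inner_node[vo] - 1L) +
    tab$npairs * n * (tab$len[tab$inner_path][vo] - 1L)
  occ <- array(tabulate(bin3, tab$npairs * n * tab$max_len),
               dim = c(tab$npairs, n, tab$max_len))
  btw <- numeric(n)
  for (pr in which(minlen > 0)) {
    btw <- btw + occ[pr, , minlen[pr]] / cnt[pr, minlen[pr]]
  }
  btw
}

# stacked same-community indicator matrix (partitions x n^2) for vectorized
# exhaustive modularity maximisation
make_partition_matrix <- function(n, partitions = all_partitions(n)) {
  S <- matrix(0, length(partitions), n * n)
  for (i in seq_along(partitions)) {
    memb <- integer(n)
    for (b in seq_along(partitions[[i]])) memb[partitions[[i]][[b]]] <- b
    S[i, ] <- as.numeric(outer(memb, memb, `==`))
  }
  S
}

oracle_max_modularity_fast <- function(w, S) {
  m2 <- sum(w)
  if (m2 == 0) return(0)
  k <- rowSums(w)
  b <- w - outer(k, k) / m2
  max(S %*% as.numeric(b)) / m2
}

# all connected labeled graphs on n nodes, as adjacency matrices
connected_graphs <- function(n) {
  n_edges <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  out <- list()
  for (code in seq_len(2^n_edges) - 1L) {
    bits <- as.integer(intToBits(code))[seq_len(n_edges)]
    a <- matrix(0, n, n)
    a[ut] <- bits
    a <- a + t(a)
    reach <- diag(n) + a
    for (k in seq_len(n)) reach <- (reach %*% (diag(n) + a)) > 0
    if (all(reach)) out[[length(out) + 1]] <- a
  }
  out
}
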