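# Independent brute-force oracles for graphs with few nodes. All of these
# enumerate (simple paths, node triples, vertex subsets) rather than reusing
# any shortest-path or core machinery from the package or igraph.

# adjacency/length matrices from a coexp_network
net_matrices <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  L <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  if (nrow(e) > 0L) {
    for (i in seq_len(nrow(e))) {
      A[e$a[i], e$b[i]] <- A[e$b[i], e$a[i]] <- 1L
      L[e$a[i], e$b[i]] <- L[e$b[i], e$a[i]] <- 1 / abs(e$rho[i])
    }
  }
  list(A = A, L = L)
}

# all simple paths s -> t with their total lengths, by exhaustive DFS
all_simple_paths_oracle <- function(A, L, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(v, visited, len) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- list(path = visited, len = len)
      return()
    }
    for (u in which(A[v, ] == 1L)) {
      if (!(u %in% visited)) walk(u, c(visited, u), len + L[v, u])
    }
  }
  walk(s, s, 0)
  paths
}

# normalized weighted betweenness by shortest-path enumeration
oracle_betweenness <- function(net) {
  m <- net_matrices(net)
  n <- nrow(m$A)
  b <- numeric(n)
  eps <- 1e-9
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      ps <- all_simple_paths_oracle(m$A, m$L, s, t)
      if (length(ps) == 0L) next
      lens <- vapply(ps, `[[`, 1, "len")
      dmin <- min(lens)
      sp <- ps[lens <= dmin + eps]
      sigma <- length(sp)
      for (v in setdiff(seq_len(n), c(s, t))) {
        sv <- sum(vapply(sp, function(p) v %in% p$path, TRUE))
        b[v] <- b[v] + sv / sigma
      }
    }
  }
  if (n > 2L) b <- b / ((n - 1) * (n - 2) / 2)
  stats::setNames(b, net$nodes)
}

# weighted shortest-path distance matrix by path enumeration
oracle_distances <- function(net) {
  m <- net_matrices(net)
  n <- nrow(m$A)
  d <- matrix(Inf, n, n, dimnames = dimnames(m$A))
  diag(d) <- 0
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      ps <- all_simple_paths_oracle(m$A, m$L, s, t)
      if (length(ps) > 0L) {
        d[s, t] <- d[t, s] <- min(vapply(ps, `[[`, 1, "len"))
      }
    }
  }
  d
}

oracle_closeness <- function(net) {
  d <- oracle_distances(net)
  n <- nrow(d)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0L) return(0)
    length(reach) / sum(d[v, reach])
  }, 1)
}

oracle_clustering <- function(net) {
  m <- net_matrices(net)
  n <- nrow(m$A)
  vapply(seq_len(n), function(v) {
    nb <- which(m$A[v, ] == 1L)
    k <- length(nb)
    if (k < 2L) return(0)
    links <- sum(m$A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, 1)
}

oracle_topological_coefficient <- function(net) {
  m <- net_matrices(net)
  n <- nrow(m$A)
  vapply(seq_len(n), function(v) {
    k <- sum(m$A[v, ])
    if (k == 0L) return(0)
    J <- c()
    for (u in setdiff(seq_len(n), v)) {
      shared <- sum(m$A[v, ] == 1L & m$A[u, ] == 1L)
      if (shared > 0L) J <- c(J, shared + m$A[v, u])
    }
    if (length(J) == 0L) return(0)
    mean(J) / k
  }, 1)
}

# triangle triples by brute force over all node triples
oracle_triangles <- function(net) {
  m <- net_matrices(net)
  n <- nrow(m$A)
  out <- list()
  if (n >= 3L) {
    for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      if (m$A[i, j] & m$A[j, k] & m$A[i, k]) {
        out[[length(out) + 1L]] <- sort(net$nodes[c(i, j, k)])
      }
    }
  }
  out
}

# MCODE vertex weight by subset enumeration: the highest k-core of the
# closed neighbourhood is recovered as the union of all vertex subsets whose
# minimum internal degree attains the maximum over subsets
oracle_mcode_weight <- function(net, v, degree_cutoff = 2L) {
  m <- net_matrices(net)
  vi <- which(net$nodes == v)
  if (sum(m$A[vi, ]) < degree_cutoff) return(0)
  closed <- c(vi, which(m$A[vi, ] == 1L))
  nn <- length(closed)
  B <- m$A[closed, closed, drop = FALSE]
  best_k <- -1L
  members <- logical(nn)
  for (mask in 1:(2^nn - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(nn) - 1L)) > 0)
    degs <- rowSums(B[S, S, drop = FALSE])
    mk <- min(degs)
    if (mk > best_k) {
      best_k <- mk
      members <- logical(nn); members[S] <- TRUE
    } else if (mk == best_k) {
      members[S] <- TRUE
    }
  }
  S <- which(members)
  ns <- length(S)
  dens <- if (ns < 2L) 0 else sum(B[S, S]) / (ns * (ns - 1))
  best_k * dens
}

# exhaustive hypergeometric tail: enumerate all draws of size q from a small
# universe and count those overlapping the set by >= k
oracle_hyper_tail <- function(k, set_size, universe_size, q) {
  draws <- utils::combn(universe_size, q)
  inset <- seq_len(set_size)          # wlog the set occupies the first slots
  mean(apply(draws, 2L, function(d) sum(d %in% inset) >= k))
}

# random sign-weighted network, connected via retry; weights from a dyadic
# set so tied path lengths compare exactly
random_connected_net <- function(n, p = 0.4, weights = c(0.25, 0.5, 1)) {
  repeat {
    pairs <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep)) next
    ids <- sprintf("n%02d", seq_len(n))
    rho <- sample(weights, sum(keep), replace = TRUE) *
      sample(c(-1, 1), sum(keep), replace = TRUE)
    net <- coexp_network(ids, data.frame(a = ids[pairs[1L, keep]],
                                         b = ids[pairs[2L, keep]],
                                         rho = rho, p = 0.01))
    g <- as_igraph(net)
    if (igraph::components(g)$no == 1L) return(net)
  }
}
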