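## Global geometric attributes and local node centralities.
##
## Global reachability attributes (diameter, characteristic path length,
## shortest-path counts) are computed on the unweighted graph, as in the
## Cytoscape-style attribute panel. Local centralities that traverse paths
## use edge lengths 1/|rho|: highly correlated miRNAs sit close together,
## regardless of correlation sign.

#' Global topology of a co-expression network
#'
#' Computes: node/edge counts, number of connected components, unweighted
#' diameter (longest shortest path over reachable pairs), number of ordered
#' reachable pairs (`n_shortest_paths`) and its fraction of N(N-1),
#' characteristic path length (mean unweighted distance over reachable
#' ordered pairs), Freeman degree centralization
#' `(N/(N-2)) * (max_degree/(N-1) - density)` (1 for a star, 0 for any
#' degree-regular graph), average neighbour count `2E/N`, density
#' `2E/(N(N-1))`, and heterogeneity `sd(degree)/mean(degree)` (population
#' SD; the coefficient of variation of the degree sequence).
#'
#' @param net A `coexp_network`.
#' @return A list of class `global_topology`.
#' @export
global_topology <- function(net) {
  stopifnot(inherits(net, "coexp_network"))
  N <- length(net$nodes)
  if (N < 2L) stop("global topology needs at least 2 nodes", call. = FALSE)
  E <- nrow(net$edges)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  density <- 2 * E / (N * (N - 1))
  comp <- igraph::components(g)

  d <- igraph::distances(g, weights = NA)   # unweighted
  reach <- is.finite(d) & row(d) != col(d)
  nsp <- sum(reach)
  dia <- if (nsp > 0) max(d[reach]) else 0
  cpl <- if (nsp > 0) mean(d[reach]) else NA_real_

  centralization <- if (N > 2) {
    (N / (N - 2)) * (max(deg) / (N - 1) - density)
  } else 0
  md <- mean(deg)
  heterogeneity <- if (md > 0) sqrt(mean((deg - md)^2)) / md else 0

  structure(list(n_nodes = N,
                 n_edges = E,
                 connected_components = comp$no,
                 diameter = as.integer(dia),
                 n_shortest_paths = as.integer(nsp),
                 shortest_path_fraction = nsp / (N * (N - 1)),
                 characteristic_path_length = cpl,
                 network_centralization = centralization,
                 avg_neighbours = 2 * E / N,
                 density = density,
                 heterogeneity = heterogeneity),
            class = "global_topology")
}

#' @export
print.global_topology <- function(x, ...) {
  cat("global topology:\n")
  cat(sprintf("  nodes %d, edges %d, connected components %d\n",
              x$n_nodes, x$n_edges, x$connected_components))
  cat(sprintf("  diameter %d, shortest paths %d (%.0f%%), characteristic path length %.2f\n",
              x$diameter, x$n_shortest_paths, 100 * x$shortest_path_fraction,
              x$characteristic_path_length))
  cat(sprintf("  centralization %.2f, avg neighbours %.2f, density %.2f, heterogeneity %.2f\n",
              x$network_centralization, x$avg_neighbours, x$density,
              x$heterogeneity))
  invisible(x)
}

#' Per-node centralities and local topology
#'
#' Path-based metrics use edge lengths 1/|rho| (unit lengths on unweighted
#' fixtures). Per node: degree; betweenness (fraction of weighted shortest
#' paths passing through, normalized by (N-1)(N-2)/2); closeness =
#' (number of reachable nodes) / (sum of weighted distances to them), which
#' lies in [0,1] because every edge length is >= 1; unweighted local
#' clustering coefficient (0 for degree < 2); topological coefficient
#' TC(v) = mean over nodes u sharing at least one neighbour with v of
#' J(v,u)/k(v), where J counts shared neighbours plus 1 if u and v are
#' adjacent (0 when no node shares a neighbour); and the mean weighted
#' shortest-path length to reachable nodes (`avg_shortest_path`, 0 with
#' `unreachable = TRUE` for isolated nodes).
#'
#' @param net A `coexp_network`.
#' @return Data.frame with one row per node: `mirna`, `degree`,
#'   `betweenness`, `closeness`, `clustering_coefficient`,
#'   `topological_coefficient`, `avg_shortest_path`, `unreachable`.
#' @export
node_topology <- function(net) {
  stopifnot(inherits(net, "coexp_network"))
  N <- length(net$nodes)
  if (N < 2L) stop("node topology needs at least 2 nodes", call. = FALSE)
  g <- as_igraph(net)
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$length else numeric(0)

  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = w, normalized = TRUE)
  d <- igraph::distances(g, weights = w)
  reach <- is.finite(d) & row(d) != col(d)
  nr <- rowSums(reach)
  sumd <- rowSums(ifelse(reach, d, 0))
  clo <- ifelse(nr > 0, nr / sumd, 0)
  asp <- ifelse(nr > 0, sumd / nr, 0)

  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0

  A <- matrix(0L, N, N, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    A[cbind(net$edges$a, net$edges$b)] <- 1L
    A[cbind(net$edges$b, net$edges$a)] <- 1L
  }
  S <- A %*% A                     # shared-neighbour counts
  tc <- numeric(N)
  for (v in seq_len(N)) {
    partners <- which(S[v, ] > 0 & seq_len(N) != v)
    if (length(partners) == 0L || deg[v] == 0) next
    J <- S[v, partners] + A[v, partners]
    tc[v] <- mean(J) / deg[v]
  }

  data.frame(mirna = net$nodes,
             degree = as.integer(deg),
             betweenness = as.numeric(btw),
             closeness = as.numeric(clo),
             clustering_coefficient = as.numeric(cc),
             topological_coefficient = tc,
             avg_shortest_path = as.numeric(asp),
             unreachable = nr == 0,
             stringsAsFactors = FALSE)
}

#' Top-k nodes per topological index
#'
#' For every topological index, the k highest-valued nodes are listed (ties
#' broken by miRNA id; nodes tied with the k-th value are included and
#' flagged as boundary ties). Also reports which nodes are top-k for at
#' least one index and for more than one.
#'
#' @param reports Data.frame from [node_topology()].
#' @param k Number of top nodes per index.
#' @param indices Index columns to rank (default: all numeric metrics).
#' @return List of class `node_ranking`: `per_index` (named list of
#'   data.frames `mirna`, `value`, `boundary_tie`), `top_any`,
#'   `top_multiple` (character vectors).
#' @export
rank_nodes <- function(reports, k = 5L,
                       indices = c("degree", "betweenness", "closeness",
                                   "clustering_coefficient",
                                   "topological_coefficient")) {
  stopifnot(k >= 1L)
  indices <- intersect(indices, names(reports))
  per <- list()
  for (ix in indices) {
    v <- reports[[ix]]
    ord <- order(-v, reports$mirna)
    kk <- min(k, length(v))
    cut <- v[ord][kk]
    keep <- ord[v[ord] >= cut]
    per[[ix]] <- data.frame(mirna = reports$mirna[keep],
                            value = v[keep],
                            boundary_tie = v[keep] == cut &
                              sum(v >= cut) > kk,
                            stringsAsFactors = FALSE)
  }
  counts <- table(unlist(lapply(per, function(d) unique(d$mirna))))
  structure(list(per_index = per,
                 top_any = sort(names(counts)),
                 top_multiple = sort(names(counts)[counts > 1])),
            class = "node_ranking")
}

#' @export
print.node_ranking <- function(x, ...) {
  for (ix in names(x$per_index)) {
    d <- x$per_index[[ix]]
    cat(ix, ": ", paste(sprintf("%s (%.3g)", d$mirna, d$value), collapse = ", "),
        "\n", sep = "")
  }
  cat("top in >1 index:", paste(x$top_multiple, collapse = ", "), "\n")
  invisible(x)
}

#' Write global and per-node topology reports as TSV
#' @param global A `global_topology` object.
#' @param nodes Data.frame from [node_topology()].
#' @param global_path,nodes_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_topology <- function(global, nodes, global_path, nodes_path) {
  utils::write.table(as.data.frame(unclass(global)), global_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(global_path, nodes_path))
}
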