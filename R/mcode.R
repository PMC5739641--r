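## Molecular Complex Detection (MCODE) on the unweighted topology of a
## co-expression network: vertex weighting by the density of the highest
## k-core of the closed neighbourhood, seeded outward growth, haircut
## post-processing, plus a binomial null for cluster density.

#' MCODE parameter set
#'
#' Published MCODE defaults: degree cutoff 2, node score cutoff 0.2, haircut
#' on, fluff off, maximum growth depth 100.
#'
#' @param degree_cutoff Minimum degree for a node to receive a non-zero
#'   weight (integer >= 2).
#' @param node_score_cutoff Fraction of the seed score a neighbour may fall
#'   short by and still join the complex, in [0,1].
#' @param haircut Remove singly-connected members (iterated to a fixpoint,
#'   i.e. the 2-core of the complex), so a second application is a no-op.
#' @param fluff Include neighbourhoods of members whose neighbourhood
#'   density exceeds `fluff_density_cutoff` (fluffed nodes may overlap
#'   between clusters).
#' @param fluff_density_cutoff Density cutoff used when `fluff = TRUE`.
#' @param max_depth Maximum breadth-first growth depth from the seed.
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.5, max_depth = 100L) {
  stopifnot(degree_cutoff >= 2, node_score_cutoff >= 0, node_score_cutoff <= 1,
            fluff_density_cutoff >= 0, fluff_density_cutoff <= 1, max_depth >= 1)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density_cutoff = fluff_density_cutoff,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

graph_density_simple <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# highest k-core of a graph: subgraph induced by vertices with maximal
# coreness; returns list(k, vids)
highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0L) return(list(k = 0L, vids = integer(0)))
  core <- igraph::coreness(g)
  kmax <- max(core)
  list(k = kmax, vids = which(core == kmax))
}

#' MCODE vertex weights
#'
#' For each node v with degree >= `degree_cutoff`, the highest k-core of the
#' subgraph induced by v's closed neighbourhood is found; the weight is
#' `k_max * density(core)`. Nodes below the degree cutoff score 0. A node
#' inside a clique K_m therefore scores (m-1) * 1.
#'
#' @param net A `coexp_network`.
#' @param params An [mcode_params()] object.
#' @return Named numeric vector of node scores.
#' @export
mcode_weights <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "coexp_network"))
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  scores <- stats::setNames(numeric(length(net$nodes)), igraph::V(g)$name)
  for (v in which(deg >= params$degree_cutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    hk <- highest_kcore(sub)
    core <- igraph::induced_subgraph(sub, hk$vids)
    scores[v] <- hk$k * graph_density_simple(core)
  }
  scores
}

#' MCODE complex detection
#'
#' Complexes are grown from seeds in decreasing weight order (ties broken by
#' miRNA id): starting at the highest-weighted unassigned node, a
#' breadth-first traversal includes unassigned neighbours whose weight is at
#' least `seed_weight * (1 - node_score_cutoff)`, down to `max_depth` levels.
#' Haircut then prunes singly-connected members (iterated, i.e. the 2-core);
#' with `fluff`, dense neighbourhoods of members are appended afterwards.
#' All nodes consumed during growth stay assigned, so complexes are disjoint
#' in membership (up to fluffed nodes). Complexes with fewer than 2
#' surviving members are discarded. Results are sorted by score
#' (density x size) descending, ties by size then seed id.
#'
#' @param net A `coexp_network`.
#' @param params An [mcode_params()] object.
#' @param weights Optional precomputed [mcode_weights()] vector.
#' @return List of class `mcode_result`; each element has `members`, `seed`,
#'   `density`, `score`, `n_edges` and (after
#'   [cluster_density_pvalue()]) `p_value`.
#' @export
mcode_clusters <- function(net, params = mcode_params(), weights = NULL) {
  stopifnot(inherits(net, "coexp_network"))
  g <- as_igraph(net)
  if (is.null(weights)) weights <- mcode_weights(net, params)
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  assigned <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  clusters <- list()

  seed_order <- order(-weights, nodes)
  for (sv in seed_order) {
    seed <- nodes[sv]
    if (assigned[seed]) next
    thr <- weights[sv] * (1 - params$node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- sv
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- integer(0)
      for (u in frontier) {
        for (nb in adj[[u]]) {
          if (!assigned[nb] && weights[nb] >= thr) {
            assigned[nb] <- TRUE
            members <- c(members, nodes[nb])
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (params$haircut) members <- haircut_members(g, nodes, members)
    if (params$fluff) {
      extra <- character(0)
      for (u in members) {
        nbv <- c(which(nodes == u),
                 as.integer(igraph::neighbors(g, which(nodes == u))))
        sub <- igraph::induced_subgraph(g, nbv)
        if (graph_density_simple(sub) > params$fluff_density_cutoff) {
          extra <- c(extra, nodes[nbv])
        }
      }
      members <- sort(unique(c(members, extra)))
    }
    if (length(members) >= 2L) {
      sub <- igraph::induced_subgraph(g, which(nodes %in% members))
      dens <- graph_density_simple(sub)
      clusters[[length(clusters) + 1L]] <-
        list(members = sort(members), seed = seed, density = dens,
             score = dens * length(members),
             n_edges = igraph::ecount(sub), p_value = NA_real_)
    }
  }
  if (length(clusters) > 1L) {
    ord <- order(-vapply(clusters, `[[`, 1, "score"),
                 -vapply(clusters, function(cl) length(cl$members), 1L),
                 vapply(clusters, `[[`, "", "seed"))
    clusters <- clusters[ord]
  }
  structure(clusters, class = "mcode_result")
}

# iterative removal of members with < 2 links inside the complex (2-core of
# the induced subgraph); idempotent by construction
haircut_members <- function(g, nodes, members) {
  repeat {
    if (length(members) < 2L) return(character(0))
    sub <- igraph::induced_subgraph(g, which(nodes %in% members))
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg < 2]
    if (length(drop) == 0L) return(members)
    members <- setdiff(members, drop)
  }
}

#' @export
print.mcode_result <- function(x, ...) {
  cat("MCODE:", length(x), "cluster(s)\n")
  for (i in seq_along(x)) {
    cl <- x[[i]]
    cat(sprintf("  %d: %d miRNAs, density %.3f, score %.3f, seed %s%s\n",
                i, length(cl$members), cl$density, cl$score, cl$seed,
                if (!is.na(cl$p_value)) sprintf(", p %.3g", cl$p_value) else ""))
  }
  invisible(x)
}

#' Significance of a cluster's density
#'
#' Analytic null: the number of edges among the cluster's C(k,2) node pairs
#' is compared against Binomial(C(k,2), p0) with p0 the global network
#' density; p is the upper-tail probability of at least the observed edge
#' count. `method = "permutation"` instead rewires the network
#' degree-preservingly `n_permutations` times and counts how often the
#' members' induced edge count reaches the observed one (add-one
#' permutation p-value); reproducible under `seed`.
#'
#' @param cluster One element of an [mcode_clusters()] result (list with
#'   `members`), or a character vector of member ids.
#' @param net The `coexp_network` the cluster came from.
#' @param method `"binomial"` (default) or `"permutation"`.
#' @param n_permutations Number of rewired graphs (>= 99) for the
#'   permutation null.
#' @param seed Integer seed for the rewiring.
#' @return A p-value in [0,1].
#' @export
cluster_density_pvalue <- function(cluster, net, method = c("binomial", "permutation"),
                                   n_permutations = 999L, seed = 1L) {
  method <- match.arg(method)
  members <- if (is.list(cluster)) cluster$members else as.character(cluster)
  k <- length(members)
  if (k < 2L) stop("cluster must have at least 2 members", call. = FALSE)
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  e_obs <- igraph::ecount(igraph::induced_subgraph(g, which(nodes %in% members)))
  m <- k * (k - 1) / 2
  if (method == "binomial") {
    N <- length(net$nodes)
    p0 <- 2 * nrow(net$edges) / (N * (N - 1))
    return(stats::pbinom(e_obs - 1L, size = m, prob = p0, lower.tail = FALSE))
  }
  if (n_permutations < 99L) stop("need at least 99 permutations", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  vids <- which(nodes %in% members)
  for (b in seq_len(n_permutations)) {
    gp <- igraph::rewire(g, igraph::keeping_degseq(
      niter = max(100L, 10L * igraph::ecount(g))))
    if (igraph::ecount(igraph::induced_subgraph(gp, vids)) >= e_obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_permutations)
}

#' Attach density p-values to every MCODE cluster
#' @inheritParams cluster_density_pvalue
#' @param clusters An `mcode_result`.
#' @return The `mcode_result` with `p_value` filled in.
#' @export
mcode_significance <- function(clusters, net, method = "binomial",
                               n_permutations = 999L, seed = 1L) {
  for (i in seq_along(clusters)) {
    clusters[[i]]$p_value <- cluster_density_pvalue(
      clusters[[i]], net, method = method,
      n_permutations = n_permutations, seed = seed)
  }
  clusters
}

#' Write MCODE clusters as TSV
#' @param clusters An `mcode_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters <- function(clusters, path) {
  df <- data.frame(
    cluster_id = seq_along(clusters),
    seed = vapply(clusters, `[[`, "", "seed"),
    size = vapply(clusters, function(cl) length(cl$members), 1L),
    density = vapply(clusters, `[[`, 1, "density"),
    score = vapply(clusters, `[[`, 1, "score"),
    p_value = vapply(clusters, `[[`, 1, "p_value"),
    members = vapply(clusters, function(cl) paste(cl$members, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
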