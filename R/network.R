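## Significance-gated Spearman co-expression networks.
##
## Correlation p-values come from the t approximation of Spearman's
## statistic, except in very small strata where the t approximation is
## unreliable: there the exact permutation distribution of rho (all n!
## rearrangements, midranks kept) is enumerated instead.

.perm_cache <- new.env(parent = emptyenv())

# all permutations of 1..n as an (n! x n) integer matrix, memoised
perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  permute <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      rest <- permute(v[-i])
      out[[i]] <- cbind(v[i], rest, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  m <- permute(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

#' Pairwise Spearman correlations with significance over a sample stratum
#'
#' Computes the full symmetric Spearman rho matrix (midranks for ties) over
#' the chosen samples and features, with two-sided p-values. For strata with
#' more than `exact_limit` samples, p comes from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df; for `n <= exact_limit`
#' the exact permutation distribution of rho is enumerated (all n!
#' orderings), since the t approximation is unreliable at such sizes.
#' Constant features have undefined correlations; these are recorded as
#' rho = 0, p = 1 with a warning.
#'
#' @param study An `expression_study`.
#' @param features Optional feature subset (default: all features).
#' @param tissue,cohort Optional stratum filters passed to [subset_study()].
#' @param exact_limit Largest stratum size for which exact permutation
#'   p-values are used (default 9).
#' @return A list of class `spearman_corr`: `rho` and `p` (symmetric
#'   matrices, unit diagonal / zero diagonal p), `n` (stratum size),
#'   `method`, `stratum` (label).
#' @export
spearman_matrix <- function(study, features = NULL, tissue = NULL,
                            cohort = NULL, exact_limit = 9L) {
  study <- subset_study(study, tissue = tissue, cohort = cohort,
                        features = features)
  n <- nrow(study$samples)
  if (n < 3L) stop("need at least 3 samples in the stratum", call. = FALSE)
  x <- study$values
  r <- t(apply(x, 1L, rank))            # midranks
  sds <- apply(r, 1L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) in stratum: rho set to 0, p to 1 (",
            paste(utils::head(rownames(x)[const], 3), collapse = ", "),
            if (sum(const) > 3) ", ..." else "", ")", call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(t(r)))
  rho[const, ] <- 0; rho[, const] <- 0
  diag(rho) <- 1
  rho[is.na(rho)] <- 0

  exact <- n <= exact_limit
  if (!exact) {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2L)
    p[abs(rho) >= 1] <- 0
  } else {
    p <- matrix(1, nrow(x), nrow(x))
    P <- perm_matrix(n)
    nf <- nrow(x)
    if (nf >= 2L) {
      for (j in 2L:nf) {
        if (const[j]) next
        Yp <- matrix(r[j, ][P], nrow = nrow(P))
        live <- which(!const[seq_len(j - 1L)])
        if (length(live) == 0L) next
        S <- Yp %*% t(r[live, , drop = FALSE])    # n! x |live| sums of products
        for (kk in seq_along(live)) {
          i <- live[kk]
          obs <- sum(r[i, ] * r[j, ])
          mu <- n * mean(r[i, ]) * mean(r[j, ])
          pv <- mean(abs(S[, kk] - mu) >= abs(obs - mu) - 1e-9)
          p[i, j] <- p[j, i] <- pv
        }
      }
    }
  }
  diag(p) <- 0
  dimnames(p) <- dimnames(rho) <- list(rownames(x), rownames(x))
  stratum <- paste(c(cohort, tissue), collapse = "/")
  structure(list(rho = rho, p = p, n = n,
                 method = if (exact) "exact-permutation" else "t-approximation",
                 stratum = if (nzchar(stratum)) stratum else "all"),
            class = "spearman_corr")
}

#' Build a significance-gated co-expression network
#'
#' Nodes are the supplied miRNA subset (isolated nodes are kept, since
#' connected and assayed miRNAs are counted separately); an undirected edge
#' joins two miRNAs iff their correlation p-value is below `alpha`. Edges
#' carry the Spearman rho as weight and a `direct`/`inverse` sign. No
#' multiple-testing correction is applied to edge p-values by default;
#' `adjust = "BH"` switches the gate to Benjamini-Hochberg q-values across
#' all tested pairs.
#'
#' @param corr A `spearman_corr` object from [spearman_matrix()].
#' @param features Optional node subset (default: all features in `corr`).
#' @param alpha Edge-inclusion threshold in (0,1).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `coexp_network`: list with `nodes` (character),
#'   `edges` (data.frame `a`, `b`, `rho`, `p`, `sign`, endpoints ordered
#'   `a < b`), `stratum`, `alpha`.
#' @export
build_network <- function(corr, features = NULL, alpha = 0.05,
                          adjust = c("none", "BH")) {
  stopifnot(inherits(corr, "spearman_corr"),
            is.numeric(alpha), alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  nodes <- rownames(corr$rho)
  if (!is.null(features)) {
    miss <- setdiff(features, nodes)
    if (length(miss) > 0L) {
      stop("feature(s) absent from correlation table: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    nodes <- features
  }
  rho <- corr$rho[nodes, nodes, drop = FALSE]
  p <- corr$p[nodes, nodes, drop = FALSE]
  ut <- upper.tri(p)
  pv <- p[ut]
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  idx <- which(ut, arr.ind = TRUE)
  keep <- pv < alpha
  a <- nodes[idx[keep, 1L]]
  b <- nodes[idx[keep, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(a = a, b = b,
                      rho = rho[ut][keep],
                      p = pv[keep],
                      sign = ifelse(rho[ut][keep] > 0, "direct", "inverse"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges,
                 stratum = corr$stratum, alpha = alpha),
            class = "coexp_network")
}

#' Construct a co-expression network directly from an edge table
#'
#' Convenience constructor for fixtures and examples; validates the edge
#' invariants (no self-edges, at most one edge per unordered pair, endpoints
#' among nodes).
#'
#' @param nodes Character vector of node ids.
#' @param edges Data.frame with columns `a`, `b` and optionally `rho`, `p`,
#'   `sign` (defaults: rho 1, p 0, sign from rho).
#' @param stratum Label.
#' @return A `coexp_network`.
#' @export
coexp_network <- function(nodes, edges = NULL, stratum = "manual") {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(a = character(0), b = character(0), rho = numeric(0),
                        p = numeric(0), sign = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$rho)) edges$rho <- 1
    if (is.null(edges$p)) edges$p <- 0
    a <- as.character(edges$a); b <- as.character(edges$b)
    if (any(a == b)) stop("self-edges are not allowed", call. = FALSE)
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges$a <- a; edges$b <- b
    if (anyDuplicated(paste(a, b))) {
      stop("duplicate edge(s) on an unordered pair", call. = FALSE)
    }
    if (!all(c(a, b) %in% nodes)) stop("edge endpoint not in node set", call. = FALSE)
    edges$sign <- ifelse(edges$rho > 0, "direct", "inverse")
    edges <- edges[order(edges$a, edges$b),
                   c("a", "b", "rho", "p", "sign"), drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(nodes), edges = edges, stratum = stratum,
                 alpha = NA_real_),
            class = "coexp_network")
}

#' Convert a co-expression network to an igraph graph
#'
#' Edge attributes: `weight` (rho), `absweight` (|rho|), `p`, `sign`, and
#' `length` (1/|rho|, the path length used by the weighted centralities).
#'
#' @param net A `coexp_network`.
#' @return An igraph object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexp_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(net$edges$a, net$edges$b),
                           weight = net$edges$rho,
                           absweight = abs(net$edges$rho),
                           p = net$edges$p,
                           sign = net$edges$sign,
                           length = 1 / abs(net$edges$rho))
  }
  g
}

#' @export
print.coexp_network <- function(x, ...) {
  deg <- network_degrees(x)
  cat("coexp_network [", x$stratum, "]: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(deg > 0), " connected miRNAs)\n", sep = "")
  if (nrow(x$edges) > 0L) {
    cat("  sign: ", sum(x$edges$sign == "direct"), " direct, ",
        sum(x$edges$sign == "inverse"), " inverse\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.coexp_network <- function(object, ...) {
  g <- global_topology(object)
  print(object)
  print(g)
  invisible(g)
}

#' @export
plot.coexp_network <- function(x, ...) {
  g <- as_igraph(x)
  ec <- if (igraph::ecount(g) > 0) {
    ifelse(igraph::E(g)$sign == "direct", "firebrick", "steelblue")
  } else NULL
  igraph::plot.igraph(g, edge.color = ec, vertex.size = 6,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}

network_degrees <- function(net) {
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges$a, net$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Write a network edge list as TSV
#' @param net A `coexp_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#' @param net A `coexp_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file back into a co-expression network
#' @param path GraphML file written by [write_graphml()].
#' @return A `coexp_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    edges <- data.frame(a = el[, 1L], b = el[, 2L],
                        rho = igraph::E(g)$weight,
                        p = if (!is.null(igraph::E(g)$p)) igraph::E(g)$p else 0,
                        stringsAsFactors = FALSE)
  } else edges <- NULL
  coexp_network(nodes, edges, stratum = "graphml")
}
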