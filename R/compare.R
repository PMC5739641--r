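## Cross-condition network comparison: shared/specific nodes and edges,
## preservation and sign concordance against a reference correlation table,
## connected-component motif census, and neighbourhood extraction.

edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  paste(net$edges$a, net$edges$b, sep = "\r")
}

#' Compare two co-expression networks
#'
#' Set algebra on node ids and unordered edge pairs (edge identity is the
#' miRNA-id pair; weights may differ). Among nodes present in both
#' networks, those whose incident edge sets are disjoint between the two
#' networks are reported as `nodes_with_no_shared_links`, and those whose
#' incident edge sets coincide exactly as `nodes_with_all_links_shared`.
#'
#' @param net_a,net_b `coexp_network` objects.
#' @return List of class `network_comparison`.
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "coexp_network"), inherits(net_b, "coexp_network"))
  ka <- edge_keys(net_a); kb <- edge_keys(net_b)
  shared_nodes <- intersect(net_a$nodes, net_b$nodes)
  shared_edges <- intersect(ka, kb)

  inc <- function(keys, node) {
    if (length(keys) == 0L) return(character(0))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    keys[vapply(parts, function(p) node %in% p, TRUE)]
  }
  none_shared <- character(0); all_shared <- character(0)
  for (v in shared_nodes) {
    ia <- inc(ka, v); ib <- inc(kb, v)
    if (length(intersect(ia, ib)) == 0L && (length(ia) + length(ib)) > 0L) {
      none_shared <- c(none_shared, v)
    }
    if (length(ia) > 0L && setequal(ia, ib)) all_shared <- c(all_shared, v)
  }
  unkey <- function(k) {
    if (length(k) == 0L) {
      return(data.frame(a = character(0), b = character(0)))
    }
    m <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    data.frame(a = m[, 1L], b = m[, 2L], stringsAsFactors = FALSE)
  }
  structure(list(shared_nodes = sort(shared_nodes),
                 nodes_only_a = sort(setdiff(net_a$nodes, net_b$nodes)),
                 nodes_only_b = sort(setdiff(net_b$nodes, net_a$nodes)),
                 shared_edges = unkey(sort(shared_edges)),
                 n_shared_edges = length(shared_edges),
                 edges_only_a = length(setdiff(ka, kb)),
                 edges_only_b = length(setdiff(kb, ka)),
                 nodes_with_no_shared_links = sort(none_shared),
                 nodes_with_all_links_shared = sort(all_shared)),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("network comparison:\n")
  cat("  shared nodes:", length(x$shared_nodes),
      "| only A:", length(x$nodes_only_a),
      "| only B:", length(x$nodes_only_b), "\n")
  cat("  shared edges:", x$n_shared_edges,
      "| only A:", x$edges_only_a, "| only B:", x$edges_only_b, "\n")
  cat("  nodes sharing no link:", length(x$nodes_with_no_shared_links),
      "| sharing all links:", length(x$nodes_with_all_links_shared), "\n")
  invisible(x)
}

#' Edge preservation and sign concordance against a reference dataset
#'
#' Re-tests each edge of the query network in an independent reference
#' correlation table: an edge is preserved iff its pair is significant
#' (p < alpha) there, and concordant iff additionally the correlation signs
#' agree. Pairs absent from the reference feature space are unpreserved and
#' counted separately.
#'
#' @param query A `coexp_network`.
#' @param ref_corr A `spearman_corr` computed on the reference data.
#' @param alpha Significance threshold applied in the reference table.
#' @return List with `preserved`, `concordant`, `missing_pairs`, `n_edges`
#'   and the per-edge logical vectors.
#' @export
preservation_vs_reference <- function(query, ref_corr, alpha = 0.05) {
  stopifnot(inherits(query, "coexp_network"), inherits(ref_corr, "spearman_corr"))
  e <- query$edges
  n_edges <- nrow(e)
  feats <- rownames(ref_corr$rho)
  present <- e$a %in% feats & e$b %in% feats
  if (!any(present) && n_edges > 0L) {
    stop("reference correlation table covers no query edge", call. = FALSE)
  }
  preserved <- concordant <- rep(FALSE, n_edges)
  if (any(present)) {
    ii <- cbind(match(e$a[present], feats), match(e$b[present], feats))
    pv <- ref_corr$p[ii]
    rr <- ref_corr$rho[ii]
    preserved[present] <- pv < alpha
    concordant[present] <- preserved[present] & (sign(rr) == sign(e$rho[present]))
  }
  list(preserved = sum(preserved), concordant = sum(concordant),
       missing_pairs = sum(!present), n_edges = n_edges,
       edge_preserved = preserved, edge_concordant = concordant)
}

#' Motif census of a network's connected components
#'
#' Classifies every connected component as `pair` (single edge), `triangle`
#' (K3), `chain` (induced path on >= 3 nodes: two endpoints of degree 1,
#' internal degrees 2) or `other` (anything else, including isolated
#' nodes). Also enumerates all triangles anywhere in the graph and reports
#' the longest chain with its ordered edge-sign sequence, so runs of
#' consecutive inverse correlations can be read off.
#'
#' @param net A `coexp_network`.
#' @return List of class `motif_census`: `components` (data.frame
#'   `component_id`, `class`, `size`, `members`), `counts` (named vector),
#'   `triangles` (list of sorted id triples), `longest_chain` (list with
#'   `members` in path order, `signs`, `length`) or `NULL`.
#' @export
motif_census <- function(net) {
  stopifnot(inherits(net, "coexp_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  nodes <- igraph::V(g)$name

  classes <- character(comp$no); members <- character(comp$no)
  sizes <- integer(comp$no)
  chains <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vids)
    n <- igraph::vcount(sub); m <- igraph::ecount(sub)
    deg <- igraph::degree(sub)
    cls <- if (n == 2L && m == 1L) "pair"
      else if (n == 3L && m == 3L) "triangle"
      else if (n >= 3L && m == n - 1L && sum(deg == 1L) == 2L && all(deg <= 2L)) "chain"
      else "other"
    classes[ci] <- cls
    sizes[ci] <- n
    members[ci] <- paste(sort(nodes[vids]), collapse = ",")
    if (cls == "chain") {
      ends <- sort(igraph::V(sub)$name[deg == 1L])
      path <- igraph::shortest_paths(sub,
        from = which(igraph::V(sub)$name == ends[1L]),
        to = which(igraph::V(sub)$name == ends[2L]), weights = NA)$vpath[[1L]]
      ord <- igraph::V(sub)$name[as.integer(path)]
      sgn <- character(n - 1L)
      for (i in seq_len(n - 1L)) {
        eid <- igraph::get_edge_ids(sub, c(ord[i], ord[i + 1L]))
        sgn[i] <- igraph::E(sub)$sign[eid]
      }
      chains[[length(chains) + 1L]] <- list(members = ord, signs = sgn,
                                            length = as.integer(n))
    }
  }
  tri <- igraph::triangles(g)
  tri_list <- list()
  if (length(tri) > 0L) {
    tm <- matrix(nodes[as.integer(tri)], ncol = 3L, byrow = TRUE)
    tri_list <- lapply(seq_len(nrow(tm)), function(i) sort(tm[i, ]))
    tri_list <- tri_list[order(vapply(tri_list, paste, "", collapse = ","))]
  }
  longest <- NULL
  if (length(chains) > 0L) {
    lens <- vapply(chains, `[[`, 1L, "length")
    best <- which(lens == max(lens))
    # deterministic tie-break: lexicographically first member sequence
    if (length(best) > 1L) {
      best <- best[order(vapply(chains[best],
                                function(chn) paste(chn$members, collapse = ","),
                                ""))][1L]
    }
    longest <- chains[[best]]
  }
  counts <- c(pair = sum(classes == "pair"),
              triangle = sum(classes == "triangle"),
              chain = sum(classes == "chain"),
              other = sum(classes == "other"))
  structure(list(components = data.frame(component_id = seq_len(comp$no),
                                         class = classes, size = sizes,
                                         members = members,
                                         stringsAsFactors = FALSE),
                 counts = counts,
                 triangles = tri_list,
                 longest_chain = longest),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("motif census:", paste(sprintf("%s %d", names(x$counts), x$counts),
                             collapse = ", "), "\n")
  cat("  triangles anywhere:", length(x$triangles), "\n")
  if (!is.null(x$longest_chain)) {
    cat("  longest chain (", x$longest_chain$length, " miRNAs): ",
        paste(x$longest_chain$members, collapse = " - "), "\n  signs: ",
        paste(x$longest_chain$signs, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the neighbourhood of a miRNA
#'
#' Breadth-limited subgraph around a centre node. At the default radius 1
#' the `neighbours` table lists each adjacent miRNA with the rho and sign of
#' its edge to the centre; the induced subnetwork over all nodes within
#' `radius` is returned as well.
#'
#' @param net A `coexp_network`.
#' @param centre miRNA id, must be a node of the network.
#' @param radius Integer >= 1.
#' @return List of class `neighbourhood`: `centre`, `radius`, `neighbours`
#'   (data.frame `mirna`, `rho`, `sign` for radius-1 partners), `subnet`
#'   (a `coexp_network`).
#' @export
neighbourhood <- function(net, centre, radius = 1L) {
  stopifnot(inherits(net, "coexp_network"), radius >= 1L)
  if (!centre %in% net$nodes) stop("unknown centre node: ", centre, call. = FALSE)
  g <- as_igraph(net)
  d <- igraph::distances(g, v = which(igraph::V(g)$name == centre), weights = NA)
  keep <- igraph::V(g)$name[which(d <= radius)]
  e <- net$edges
  inside <- e$a %in% keep & e$b %in% keep
  sub <- coexp_network(keep, if (any(inside)) e[inside, , drop = FALSE] else NULL,
                       stratum = paste0(net$stratum, ":", centre, "@r", radius))
  touch <- e$a == centre | e$b == centre
  nb <- data.frame(mirna = ifelse(e$a[touch] == centre, e$b[touch], e$a[touch]),
                   rho = e$rho[touch], sign = e$sign[touch],
                   stringsAsFactors = FALSE)
  nb <- nb[order(nb$mirna), , drop = FALSE]
  rownames(nb) <- NULL
  structure(list(centre = centre, radius = as.integer(radius),
                 neighbours = nb, subnet = sub),
            class = "neighbourhood")
}

#' @export
print.neighbourhood <- function(x, ...) {
  cat("neighbourhood of", x$centre, "(radius", x$radius, "):",
      nrow(x$neighbours), "direct neighbour(s)\n")
  if (nrow(x$neighbours) > 0L) print(x$neighbours)
  invisible(x)
}

#' Write comparison and census reports as TSV
#' @param census A `motif_census`.
#' @param path Output path for the component table.
#' @return Invisibly, `path`.
#' @export
write_census <- function(census, path) {
  utils::write.table(census$components, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
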