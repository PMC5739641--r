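test_that("vertex weights follow the closed-neighbourhood core density", {
  # isolated and low-degree nodes score 0; K5 members score 4 * 1
  k5 <- make_net(c(letters[1:5], "x"), clique_edges(letters[1:5]))
  w <- mcode_weights(k5)
  expect_equal(unname(w[letters[1:5]]), rep(4, 5))
  expect_equal(unname(w["x"]), 0)

  # pendant attached to the clique still sees the K5 as its highest core...
  k5p <- make_net(c(letters[1:5], "p", "q"),
                  c(clique_edges(letters[1:5]), "a-p", "a-q"))
  w <- mcode_weights(k5p)
  expect_equal(unname(w["a"]), 4)
  # ...but the degree-1 pendants fall under the degree cutoff
  expect_equal(unname(w["p"]), 0)
})

test_that("weights match the subset-enumeration oracle on random graphs", {
  set.seed(77)
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    net <- random_connected_net(n, runif(1, 0.35, 0.6))
    w <- mcode_weights(net)
    orc <- vapply(net$nodes, function(v) oracle_mcode_weight(net, v), 1)
    expect_equal(unname(w), unname(orc), tolerance = 1e-12)
  }
})

test_that("disjoint cliques with pendant noise give exactly the two cliques", {
  a <- sprintf("a%d", 1:4); b <- sprintf("b%d", 1:4)
  net <- make_net(c(a, b, "p1", "p2"),
                  c(clique_edges(a), clique_edges(b),
                    "a2-p1", "b3-p2"))  # pendants pruned by haircut
  cl <- mcode_clusters(net)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]]$members, a)   # ties by size then seed id
  expect_setequal(cl[[2]]$members, b)
  expect_equal(cl[[1]]$density, 1)
  expect_equal(cl[[1]]$score, 4)
  expect_false(any(c("p1", "p2") %in% unlist(lapply(cl, `[[`, "members"))))
})

test_that("equal-weight cliques joined by a bridge grow into one complex", {
  # both cliques' members carry weight 3 >= 3 * (1 - 0.2), so the
  # breadth-first growth legitimately crosses the bridge
  a <- sprintf("a%d", 1:4); b <- sprintf("b%d", 1:4)
  net <- make_net(c(a, b), c(clique_edges(a), clique_edges(b), "a1-b1"))
  cl <- mcode_clusters(net)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c(a, b))
  # a stricter node-score cutoff cannot split equal weights either, but a
  # depth limit of one keeps the far clique out and haircut trims the bridge
  cl1 <- mcode_clusters(net, mcode_params(max_depth = 1))
  expect_setequal(cl1[[1]]$members, a)
})

test_that("clusters are deterministic, disjoint, and survive their own haircut", {
  set.seed(31)
  net <- random_connected_net(8, 0.5)
  c1 <- mcode_clusters(net)
  c2 <- mcode_clusters(net)
  expect_identical(c1, c2)
  members <- unlist(lapply(c1, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  # haircut fixpoint: every member keeps >= 2 links inside its cluster
  g <- as_igraph(net)
  for (cl in c1) {
    sub <- igraph::induced_subgraph(g, which(igraph::V(g)$name %in% cl$members))
    expect_true(all(igraph::degree(sub) >= 2))
    expect_identical(
      mirnet:::haircut_members(g, igraph::V(g)$name, cl$members),
      cl$members)
  }
  # edgeless network: nothing to cluster
  expect_length(mcode_clusters(coexp_network(letters[1:4])), 0L)
})

test_that("density p-values: closed-form binomial and null-consistency", {
  # 5-clique embedded in a background of global density 0.1:
  # p = P(Binom(10, 0.1) >= 10) = 1e-10
  nodes <- sprintf("n%02d", 1:15)
  cl5 <- nodes[1:5]
  extra <- c("n06-n07", "n08-n09", "n10-n11")   # filler to set density
  net0 <- make_net(nodes, c(clique_edges(cl5), extra))
  dens <- 2 * nrow(net0$edges) / (15 * 14)
  p <- cluster_density_pvalue(cl5, net0)
  expect_equal(p, pbinom(9, 10, dens, lower.tail = FALSE))
  net_dense <- make_net(nodes[1:6], clique_edges(nodes[1:6]))
  # in a clique the cluster density equals the global density: p = 1
  expect_equal(cluster_density_pvalue(nodes[1:4], net_dense), 1)
  expect_error(cluster_density_pvalue("n01", net0), "2 members")
  expect_error(cluster_density_pvalue(cl5, net0, method = "permutation",
                                      n_permutations = 10), "99")
})

test_that("permutation and analytic nulls agree within Monte-Carlo error", {
  set.seed(9)
  nodes <- sprintf("m%02d", 1:12)
  pairs <- combn(nodes, 2)
  keep <- runif(ncol(pairs)) < 0.35
  net <- coexp_network(nodes, data.frame(a = pairs[1, keep], b = pairs[2, keep],
                                         rho = 0.8, p = 0.01))
  members <- nodes[1:5]
  pa <- cluster_density_pvalue(members, net)
  pp <- cluster_density_pvalue(members, net, method = "permutation",
                               n_permutations = 499, seed = 2)
  expect_lt(abs(pa - pp), 0.2)
  # permutation p is reproducible under the same seed
  pp2 <- cluster_density_pvalue(members, net, method = "permutation",
                                n_permutations = 499, seed = 2)
  expect_identical(pp, pp2)
})

test_that("planted co-expression modules are recovered from synthetic data", {
  sim <- simulate_study(sim_config(
    n_pairs = 50, n_features = 80, n_de = 0,
    modules = list(list(size = 6, rho_target = 0.9),
                   list(size = 6, rho_target = 0.9, sign_pattern = "mixed")),
    noise_sd = 0.4, seed = 33))
  corr <- spearman_matrix(sim$study, tissue = "tumour")
  net <- build_network(corr, alpha = 0.05, adjust = "BH")
  cl <- mcode_clusters(net)
  jacc <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  hits <- 0
  for (m in c("M1", "M2")) {
    truth <- sim$truth$feature_id[sim$truth$module_id == m]
    best <- max(c(0, vapply(cl, function(ci) jacc(ci$members, truth), 1)))
    if (best >= 0.75) hits <- hits + 1
  }
  expect_gte(hits, 1)
})
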