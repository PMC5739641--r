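test_that("network comparison set algebra on identity and disjoint cases", {
  net <- pvac_style_fixture()
  same <- compare_networks(net, net)
  expect_equal(same$shared_nodes, sort(net$nodes))
  expect_length(same$nodes_only_a, 0L)
  expect_equal(same$n_shared_edges, nrow(net$edges))
  expect_length(same$nodes_with_no_shared_links, 0L)
  # every connected node keeps all its links under identity
  deg <- mirnet:::network_degrees(net)
  expect_setequal(same$nodes_with_all_links_shared, names(deg)[deg > 0])

  # edge-disjoint networks on the same nodes
  a <- make_net(c("x", "y", "z", "w"), c("x-y", "z-w"))
  b <- make_net(c("x", "y", "z", "w"), c("x-z", "y-w"))
  cmp <- compare_networks(a, b)
  expect_equal(cmp$n_shared_edges, 0L)
  expect_setequal(cmp$nodes_with_no_shared_links, c("x", "y", "z", "w"))
  expect_length(cmp$nodes_with_all_links_shared, 0L)
})

test_that("comparison is symmetric up to swapping the a/b fields", {
  a <- make_net(letters[1:6], c("a-b", "b-c", "d-e"))
  b <- make_net(letters[3:8], c("c-d", "d-e", "f-g"))
  ab <- compare_networks(a, b)
  ba <- compare_networks(b, a)
  expect_equal(ab$shared_nodes, ba$shared_nodes)
  expect_equal(ab$nodes_only_a, ba$nodes_only_b)
  expect_equal(ab$nodes_only_b, ba$nodes_only_a)
  expect_equal(ab$n_shared_edges, ba$n_shared_edges)
  expect_equal(ab$nodes_with_no_shared_links, ba$nodes_with_no_shared_links)
})

test_that("counts match hand enumeration on a constructed pair of graphs", {
  a <- make_net(sprintf("v%d", 1:10),
                c("v1-v2", "v2-v3", "v3-v4", "v5-v6", "v7-v8", "v9-v10"))
  b <- make_net(sprintf("v%d", 1:10),
                c("v1-v2", "v3-v4", "v5-v7", "v7-v8", "v9-v10"))
  cmp <- compare_networks(a, b)
  expect_equal(cmp$n_shared_edges, 4L)          # v1-v2, v3-v4, v7-v8, v9-v10
  expect_equal(cmp$edges_only_a, 2L)            # v2-v3, v5-v6
  expect_equal(cmp$edges_only_b, 1L)            # v5-v7
  expect_setequal(cmp$nodes_with_no_shared_links, c("v5", "v6"))
  expect_setequal(cmp$nodes_with_all_links_shared,
                  c("v1", "v4", "v8", "v9", "v10"))
})

test_that("preservation re-tests edges in the reference with sign concordance", {
  sim <- simulate_study(sim_config(n_pairs = 40, n_features = 20, n_de = 0,
                                   modules = list(list(size = 5, rho_target = 0.9)),
                                   noise_sd = 0.4, seed = 12))
  corr <- spearman_matrix(sim$study, tissue = "tumour")
  net <- build_network(corr, alpha = 0.05)

  # self-reference: everything preserved and concordant
  self <- preservation_vs_reference(net, corr, alpha = 0.05)
  expect_equal(self$preserved, nrow(net$edges))
  expect_equal(self$concordant, nrow(net$edges))

  # sign-flipped reference: preserved but nothing concordant
  flipped <- corr; flipped$rho <- -corr$rho
  fl <- preservation_vs_reference(net, flipped, alpha = 0.05)
  expect_equal(fl$preserved, nrow(net$edges))
  expect_equal(fl$concordant, 0L)

  # ordering invariant: concordant <= preserved <= edges
  expect_lte(fl$concordant, fl$preserved)
  expect_lte(fl$preserved, nrow(net$edges))

  # pairs missing from the reference feature space count separately
  sub <- corr
  keep <- rownames(corr$rho)[1:10]
  sub$rho <- corr$rho[keep, keep]; sub$p <- corr$p[keep, keep]
  ms <- preservation_vs_reference(net, sub, alpha = 0.05)
  expect_equal(ms$missing_pairs,
               sum(!(net$edges$a %in% keep & net$edges$b %in% keep)))
})

test_that("an independent replicate cohort preserves planted-module edges", {
  # one generated cohort split into two subject halves: both halves share
  # the planted module structure but carry independent noise and latents
  sim <- simulate_study(sim_config(n_pairs = 80, n_features = 30, n_de = 0,
                                   modules = list(list(size = 6, rho_target = 0.9)),
                                   noise_sd = 0.4, seed = 101))
  st <- sim$study
  subj <- unique(st$samples$subject_id)
  half <- function(sub) {
    keep <- st$samples$subject_id %in% sub
    mirnet:::new_expression_study(st$features, st$samples[keep, , drop = FALSE],
                                  st$values[, keep, drop = FALSE])
  }
  s1 <- half(subj[1:40]); s2 <- half(subj[41:80])
  mod <- sim$truth$feature_id[sim$truth$module_id == "M1"]
  net1 <- build_network(spearman_matrix(s1, tissue = "tumour"), alpha = 0.05)
  corr2 <- spearman_matrix(s2, tissue = "tumour")
  pres <- preservation_vs_reference(net1, corr2, alpha = 0.05)
  inmod <- net1$edges$a %in% mod & net1$edges$b %in% mod
  expect_gte(sum(inmod), 10)
  expect_gte(mean(pres$edge_preserved[inmod]), 0.8)
  expect_true(all(pres$edge_concordant <= pres$edge_preserved))
})

test_that("motif census classifies components and finds the longest chain", {
  expect_equal(unname(motif_census(make_net(c("a", "b", "c"),
                                            clique_edges(c("a", "b", "c"))))$counts),
               c(0, 1, 0, 0))
  net <- pvac_style_fixture()
  cen <- motif_census(net)
  expect_equal(cen$counts[["chain"]], 1L)
  expect_equal(cen$counts[["triangle"]], 2L)
  expect_equal(cen$counts[["pair"]], 2L)
  expect_equal(sum(cen$counts), 5L)                 # conserves component count
  expect_length(cen$triangles, 2L)
  expect_equal(cen$longest_chain$length, 7L)
  expect_equal(cen$longest_chain$members[1], "c1")  # path order from c1 end
  expect_equal(cen$longest_chain$signs,
               ifelse(rep(c(-0.9, 0.8), length.out = 6) > 0,
                      "direct", "inverse"))
  # a star is neither pair, triangle nor chain; singletons fall into other
  star <- make_net(c("h", "a", "b", "c", "s"), c("a-h", "b-h", "c-h"))
  expect_equal(unname(motif_census(star)$counts), c(0, 0, 0, 2))
})

test_that("triangle enumeration matches brute force on random graphs", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    net <- random_connected_net(n, runif(1, 0.4, 0.7))
    cen <- motif_census(net)
    orc <- oracle_triangles(net)
    expect_equal(length(cen$triangles), length(orc))
    expect_setequal(vapply(cen$triangles, paste, "", collapse = ","),
                    vapply(orc, paste, "", collapse = ","))
  }
})

test_that("neighbourhood extraction returns annotated adjacency", {
  net <- pvac_style_fixture()
  nb <- neighbourhood(net, "c2")
  expect_setequal(nb$neighbours$mirna, c("c1", "c3"))
  expect_equal(nrow(nb$subnet$edges), 2L)

  # neighbour table equals the adjacency row of the edge list
  adj <- net$edges[net$edges$a == "c2" | net$edges$b == "c2", ]
  expect_setequal(nb$neighbours$mirna,
                  setdiff(unique(c(adj$a, adj$b)), "c2"))
  expect_equal(sort(nb$neighbours$rho), sort(adj$rho))

  # radius 2 pulls in the next shell including its internal edges
  nb2 <- neighbourhood(net, "c2", radius = 2)
  expect_setequal(nb2$subnet$nodes, c("c1", "c2", "c3", "c4"))

  iso <- make_net(c("a", "b", "x"), "a-b")
  expect_equal(nrow(neighbourhood(iso, "x")$neighbours), 0L)
  star <- make_net(c("h", letters[1:5]), paste0(letters[1:5], "-h"))
  expect_equal(nrow(neighbourhood(star, "h")$neighbours), 5L)
  expect_error(neighbourhood(net, "nope"), "unknown centre")
})
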