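test_that("spearman matrix reproduces hand-computed and monotone cases", {
  vals <- rbind(x = c(1, 2, 3, 4, 5),
                y = c(2, 4, 6, 8, 10),
                yr = c(10, 8, 6, 4, 2),
                z = c(1, 3, 2, 5, 4))
  vals <- cbind(vals, vals)   # 5 pairs (samples just need to exist)
  st <- make_study(vals)
  corr <- spearman_matrix(st, tissue = "normal", exact_limit = 0L)
  expect_equal(diag(corr$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(corr$rho["x", "y"], 1)
  expect_equal(corr$rho["x", "yr"], -1)
  # rank differences d = (0,-1,1,-1,1): rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(corr$rho["x", "z"], 0.8)
  expect_true(isSymmetric(corr$rho))
  expect_true(isSymmetric(corr$p))
})

test_that("t-approximation p-values agree with cor.test", {
  set.seed(3)
  vals <- matrix(rnorm(4 * 24), 4, 24)
  st <- make_study(vals)
  corr <- spearman_matrix(st, tissue = "tumour")   # n = 12 > exact_limit
  expect_equal(corr$method, "t-approximation")
  tum <- st$values[, st$samples$tissue == "tumour"]
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- suppressWarnings(cor.test(tum[i, ], tum[j, ], method = "spearman",
                                    exact = FALSE))
    expect_equal(corr$rho[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(corr$p[i, j], ct$p.value, tolerance = 1e-9)
  }
})

test_that("small strata use the exact permutation null", {
  # independent oracle: enumerate permutations recursively (distinct code
  # path from the package's permutation matrix)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  set.seed(5)
  vals <- matrix(rnorm(3 * 10), 3, 10)
  st <- make_study(vals)
  corr <- spearman_matrix(st, tissue = "normal")   # n = 5 <= 9
  expect_equal(corr$method, "exact-permutation")
  nor <- st$values[, st$samples$tissue == "normal"]
  for (i in 1:2) for (j in (i + 1):3) {
    xr <- rank(nor[i, ]); yr <- rank(nor[j, ])
    obs <- abs(cor(xr, yr))
    null <- vapply(perms(seq_along(yr)),
                   function(pm) cor(xr, yr[pm]), 1)
    expect_equal(corr$p[i, j], mean(abs(null) >= obs - 1e-9),
                 tolerance = 1e-12)
  }
})

test_that("constant features are flagged and contribute no edges", {
  vals <- rbind(flat = rep(3, 10), a = rnorm(10), b = rnorm(10))
  st <- make_study(matrix(vals, 3, 10, dimnames = list(rownames(vals), NULL)))
  expect_warning(corr <- spearman_matrix(st, tissue = NULL), "constant")
  expect_equal(corr$rho["flat", "a"], 0)
  expect_equal(corr$p["flat", "a"], 1)
  net <- build_network(corr, alpha = 0.05)
  expect_false("flat" %in% c(net$edges$a, net$edges$b))
  expect_true("flat" %in% net$nodes)
})

test_that("networks keep isolated nodes, nest across alpha, and respect sign", {
  set.seed(11)
  sim <- simulate_study(sim_config(n_pairs = 30, n_features = 25, n_de = 0,
                                   modules = list(list(size = 5, rho_target = 0.9,
                                                       sign_pattern = "inverse")),
                                   noise_sd = 0.4, seed = 2))
  corr <- spearman_matrix(sim$study, tissue = "tumour")
  n05 <- build_network(corr, alpha = 0.05)
  n01 <- build_network(corr, alpha = 0.01)
  expect_equal(length(n05$nodes), 25L)
  key <- function(net) paste(net$edges$a, net$edges$b)
  expect_true(all(key(n01) %in% key(n05)))
  expect_true(all(n05$edges$a < n05$edges$b))
  expect_equal(n05$edges$sign, ifelse(n05$edges$rho > 0, "direct", "inverse"))
  # inverse-pattern module: all members load with the same (negated) sign,
  # so within-module correlations are positive
  mod <- sim$truth$feature_id[sim$truth$module_id == "M1"]
  inmod <- n05$edges$a %in% mod & n05$edges$b %in% mod
  expect_gte(sum(inmod), 8)
  expect_true(all(n05$edges$sign[inmod] == "direct"))
  # planted module internal density at alpha 0.05
  expect_gte(sum(inmod) / choose(5, 2), 0.8)
  # near-independence: an alpha below any observed p gives an edgeless graph
  tiny <- build_network(corr, alpha = min(corr$p[upper.tri(corr$p)]) * 0.99 +
                          .Machine$double.xmin)
  expect_lte(nrow(tiny$edges), sum(corr$p[upper.tri(corr$p)] == 0))
})

test_that("strictly increasing transforms of one feature leave the network unchanged", {
  set.seed(19)
  vals <- matrix(rnorm(6 * 20, 8), 6, 20)
  st <- make_study(vals)
  corr1 <- spearman_matrix(st, tissue = "tumour")
  st$values[2, ] <- exp(st$values[2, ])           # monotone transform
  st$values[5, ] <- st$values[5, ]^3 + 10
  corr2 <- spearman_matrix(st, tissue = "tumour")
  expect_equal(corr1$rho, corr2$rho)
  expect_equal(corr1$p, corr2$p)
  n1 <- build_network(corr1, alpha = 0.05)
  n2 <- build_network(corr2, alpha = 0.05)
  expect_identical(n1$edges, n2$edges)
})

test_that("BH-gated edge sets are a subset of the raw-p edge sets", {
  set.seed(23)
  sim <- simulate_study(sim_config(n_pairs = 30, n_features = 30, n_de = 0,
                                   modules = list(list(size = 6, rho_target = 0.9)),
                                   noise_sd = 0.4, seed = 8))
  corr <- spearman_matrix(sim$study, tissue = "tumour")
  raw <- build_network(corr, alpha = 0.05)
  bh <- build_network(corr, alpha = 0.05, adjust = "BH")
  key <- function(net) paste(net$edges$a, net$edges$b)
  expect_true(all(key(bh) %in% key(raw)))
  mod <- sim$truth$feature_id[sim$truth$module_id == "M1"]
  expect_gte(sum(bh$edges$a %in% mod & bh$edges$b %in% mod), 10)
})

test_that("edge lists and GraphML round-trip through igraph", {
  net <- pvac_style_fixture()
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".graphml")
  write_edge_list(net, p1)
  expect_equal(nrow(read.delim(p1)), nrow(net$edges))
  write_graphml(net, p2)
  back <- read_graphml(p2)
  expect_setequal(back$nodes, net$nodes)
  expect_equal(nrow(back$edges), nrow(net$edges))
  expect_setequal(paste(back$edges$a, back$edges$b),
                  paste(net$edges$a, net$edges$b))
})
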