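test_that("C-score hits the checkerboard and identical-row anchors", {
  expect_equal(cscore(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(cscore(rbind(c(1, 1, 0), c(1, 1, 0))), 0)
  # swap null preserves both margins
  set.seed(2)
  m <- matrix(rbinom(80, 1, 0.4), 8, 10)
  m2 <- floodnet:::swap_matrix(m, 500)
  expect_equal(rowSums(m2), rowSums(m))
  expect_equal(colSums(m2), colSums(m))
})

test_that("C-score test reports SES consistently and flags degenerate rows", {
  set.seed(3)
  m <- rbind(matrix(rbinom(60, 1, 0.5), 6, 10), 1)  # last row all-present
  expect_warning(res <- cscore_test(m, n_null = 99, seed = 1,
                                    burn_in = 500, thin = 20),
                 "all-present")
  expect_equal(res$ses, (res$observed - res$null_mean) / res$null_sd)
  expect_gte(res$p, 0.01)
})

test_that("network inference applies the |r| and p thresholds exactly", {
  set.seed(5)
  n <- 30
  base <- matrix(rpois(8 * n, 50), 8, n)
  base[2, ] <- base[1, ] * 2L            # proportional pair
  ct <- count_table(base)
  net <- infer_network(ct, r_threshold = 0.6, p_max = 0.01)
  e12 <- net$edges[net$edges$from == "taxon1" & net$edges$to == "taxon2", ]
  expect_equal(nrow(e12), 1)
  expect_equal(e12$sign, "positive")
  expect_gt(e12$r, 0.99)
  # every reported edge satisfies the rule; no qualifying pair is missing
  rel <- relative_abundance(ct)
  r <- cor(t(rel))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  want <- which(upper.tri(r) & abs(r) >= 0.6 & p <= 0.01)
  expect_equal(nrow(net$edges), length(want))
  expect_true(all(abs(net$edges$r) >= 0.6 & net$edges$p <= 0.01))
  expect_error(infer_network(ct, min_samples = 40), "insufficient")
})

test_that("node metrics equal the exhaustive-path oracle on random graphs", {
  for (i in 1:40) {
    n <- sample(4:10, 1)
    a <- rand_adjacency(n, p = runif(1, 0.2, 0.7), seed = 400 + i)
    net <- adjacency_to_network(a)
    got <- node_metrics(net)
    want <- graph_metrics_oracle(a)
    expect_equal(got$degree, want$degree)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
  }
})

test_that("path and complete graphs give the textbook centralities", {
  path3 <- adjacency_to_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  m <- node_metrics(path3)
  expect_equal(m$betweenness[2], 1)
  expect_equal(m$closeness[2], 1)
  k5 <- adjacency_to_network(1 - diag(5))
  expect_true(all(node_metrics(k5)$betweenness == 0))
})

test_that("modularity matches its definitional recomputation and anchors", {
  # two disjoint triangles: component partition has Q = 0.5
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- 1
  a[4, 5] <- a[5, 6] <- a[4, 6] <- 1
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", 1:6), paste0("v", 1:6))
  net <- adjacency_to_network(a)
  mod <- detect_modules(net)
  expect_equal(mod$Q, 0.5, tolerance = 1e-12)
  expect_equal(mod$n_modules, 2)
  expect_equal(modularity_q(net, mod$membership), 0.5, tolerance = 1e-12)
  # single-community partition: Q exactly 0
  expect_equal(modularity_q(net, rep(1, 6)), 0, tolerance = 1e-15)
  # definitional Q equals igraph's Q on random graphs and partitions
  for (i in 1:20) {
    aa <- rand_adjacency(8, 0.4, seed = 900 + i)
    if (sum(aa) == 0) next
    nn <- adjacency_to_network(aa)
    set.seed(i)
    memb <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_q(nn, memb),
                 igraph::modularity(nn$graph, memb), tolerance = 1e-12)
    det <- detect_modules(nn, seed = i)
    expect_equal(det$Q, modularity_q(nn, det$membership), tolerance = 1e-12)
  }
  # edgeless network: singleton modules, Q = 0
  lone <- adjacency_to_network(matrix(0, 3, 3,
                                      dimnames = list(paste0("v", 1:3),
                                                      paste0("v", 1:3))))
  m0 <- detect_modules(lone)
  expect_equal(m0$Q, 0)
  expect_equal(m0$n_modules, 3)
})

test_that("keystone taxa are strict 75th-percentile exceeders on all metrics", {
  # star K1,6: the hub alone exceeds every percentile
  a <- matrix(0, 7, 7)
  a[1, 2:7] <- 1
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", 1:7), paste0("v", 1:7))
  expect_equal(keystone_taxa(adjacency_to_network(a)), "v1")
  # ring: perfect ties, nothing strictly exceeds
  ring <- matrix(0, 6, 6)
  for (i in 1:6) ring[i, i %% 6 + 1] <- 1
  ring <- ring + t(ring)
  dimnames(ring) <- list(paste0("v", 1:6), paste0("v", 1:6))
  expect_length(keystone_taxa(adjacency_to_network(ring)), 0)
  # invariance under node relabeling
  a8 <- rand_adjacency(8, 0.5, seed = 77)
  ks1 <- keystone_taxa(adjacency_to_network(a8))
  perm <- sample(8)
  ap <- a8[perm, perm]
  ks2 <- keystone_taxa(adjacency_to_network(ap))
  expect_setequal(ks1, ks2)
  # tiny networks return empty with a warning
  expect_warning(ks <- keystone_taxa(adjacency_to_network(
    rand_adjacency(3, 1, seed = 1))), "fewer than 4")
  expect_length(ks, 0)
})

test_that("zone summary tallies a hand-built network correctly", {
  # 4 taxa: t1,t2 main-channel; t3,t4 off-channel, by construction
  n <- 20
  zone <- rep(c("main-channel", "off-channel"), each = n / 2)
  h <- sample_hierarchy(paste0("s", 1:n), "montane", "FP1", zone,
                        ifelse(zone == "main-channel", "riffle", "pond"))
  hi <- c(rep(60L, n / 2), rep(10L, n / 2))
  lo <- c(rep(10L, n / 2), rep(60L, n / 2))
  set.seed(8)
  jit <- function(v) pmax(1L, v + sample(-3:3, n, TRUE))
  m <- rbind(t1 = jit(hi), t2 = jit(hi), t3 = jit(lo), t4 = jit(lo))
  colnames(m) <- h$sample_id
  ct <- count_table(m)
  net <- infer_network(ct, r_threshold = 0.6, p_max = 0.01, min_samples = 5)
  zs <- zone_edge_summary(net, h, ct)
  expect_equal(unname(zs$affinity[c("t1", "t2")]),
               rep("main-channel", 2))
  expect_equal(unname(zs$affinity[c("t3", "t4")]),
               rep("off-channel", 2))
  # t1-t2 and t3-t4 positive same-zone; cross pairs negative cross-zone
  expect_equal(unname(zs$edge_tab["positive", "same_zone"]), 2)
  expect_equal(unname(zs$edge_tab["negative", "cross_zone"]), 4)
  expect_equal(zs$pct_positive + zs$pct_negative, 100)
})

test_that("edge rule asserted post-hoc on inferred network objects", {
  sim <- simulate_scenario("n-limited", seed = 5)
  net <- infer_network(sim$counts, r_threshold = 0.6, p_max = 0.01)
  expect_true(all(abs(net$edges$r) >= 0.6))
  expect_true(all(net$edges$p <= 0.01))
  expect_false(any(net$edges$from == net$edges$to))
  expect_false(any(duplicated(net$edges[c("from", "to")])))
})
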