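test_that("REML variance components equal the EMS oracle on balanced designs", {
  hits <- 0
  for (s in c(2, 5, 8, 11)) {
    dat <- balanced_nested_data(a = 5, b = 3, n = 4, seed = s)
    oracle <- ems_nested_oracle(dat$env$y, dat$group, dat$subgroup)
    if (any(oracle < 0)) next   # REML==ANOVA only holds off the boundary
    got <- vca(dat$env, dat$h, "y", log_transform = FALSE,
               levels = c("floodplain", "habitat"))
    expect_equal(got$variance, unname(oracle), tolerance = 1e-6)
    expect_equal(sum(got$percent), 100, tolerance = 1e-9)
    hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("pure-residual data leaves structural components near zero", {
  set.seed(30)
  small <- replicate(30, {
    dat <- balanced_nested_data(a = 5, b = 3, n = 3, sA = 0, sB = 0,
                                sW = 1, seed = sample.int(1e6, 1))
    got <- vca(dat$env, dat$h, "y", log_transform = FALSE,
               levels = c("floodplain", "habitat"))
    all(got$percent[1:2] < 15)
  })
  expect_gte(mean(small), 0.8)
})

test_that("db-MEM eigenvectors are centred, orthogonal, and match hand PCoA", {
  set.seed(41)
  xy <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  mem <- build_dbmem(xy)
  V <- mem$vectors
  expect_equal(unname(colMeans(V)), rep(0, ncol(V)), tolerance = 1e-10)
  expect_equal(unname(crossprod(V)), diag(ncol(V)), tolerance = 1e-10)
  expect_true(all(mem$values > 0))
  # 3 equidistant collinear points: PCoA of the (untruncated) distances
  xy3 <- cbind(c(0, 1, 2), 0)
  mem3 <- build_dbmem(xy3, truncation = 2)
  D <- as.matrix(dist(xy3))
  G <- -0.5 * D^2
  G <- sweep(sweep(G, 1, rowMeans(G)), 2, colMeans(G) - mean(G))
  ev <- eigen(G, symmetric = TRUE)
  keep <- ev$values > 1e-8
  v_hand <- abs(ev$vectors[, keep, drop = FALSE])
  v_hand <- sweep(v_hand, 2, sqrt(colSums(v_hand^2)), "/")
  expect_equal(unname(abs(mem3$vectors)), v_hand, tolerance = 1e-8)
  expect_error(build_dbmem(matrix(1, 3, 2)), "distinct")
})

test_that("on a regular transect the leading MEM has the fewest sign changes", {
  xy <- cbind(seq(0, 100, by = 5), 0)
  mem <- build_dbmem(xy)
  sign_changes <- apply(mem$vectors, 2, function(v)
    sum(diff(sign(v)) != 0))
  expect_equal(unname(which.min(sign_changes)), 1L)
  expect_true(all(diff(sign_changes) >= 0) || sign_changes[1] ==
                min(sign_changes))
})

test_that("forward selection is calibrated and finds a lone true predictor", {
  set.seed(51)
  empty <- replicate(20, {
    Y <- matrix(rnorm(30 * 6), 30, 6)
    X <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
    length(suppressWarnings(
      forward_select_rda(Y, X, n_perm = 99,
                         seed = sample.int(1e6, 1)))$selected) == 0
  })
  expect_gte(mean(empty), 0.85)
  found <- replicate(10, {
    x1 <- rnorm(35)
    X <- data.frame(x1 = x1, x2 = rnorm(35), x3 = rnorm(35))
    Y <- outer(x1, rnorm(5)) + matrix(rnorm(35 * 5, 0, 0.5), 35, 5)
    sel <- suppressWarnings(
      forward_select_rda(Y, X, n_perm = 99, seed = sample.int(1e6, 1)))
    length(sel$selected) >= 1 && sel$selected[1] == "x1"
  })
  expect_gte(mean(found), 0.9)
})

test_that("single-predictor adjusted R2 matches the closed-form RDA", {
  set.seed(52)
  x <- rnorm(25)
  Y <- outer(x, c(1, -0.5, 2)) + matrix(rnorm(75, 0, 0.4), 25, 3)
  sel <- forward_select_rda(Y, data.frame(x = x), n_perm = 199, seed = 1)
  # closed form: R2 = SS(fitted)/SS(total) for the multivariate regression
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  xc <- x - mean(x)
  fitted <- outer(xc, colSums(Yc * xc) / sum(xc^2))
  r2 <- sum(fitted^2) / sum(Yc^2)
  n <- 25
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  expect_equal(sel$adj_r2[1], adj, tolerance = 1e-9)
})

test_that("variance partitioning identities and degenerate cases hold", {
  set.seed(61)
  n <- 40
  E <- matrix(rnorm(n * 2), n)
  S <- matrix(rnorm(n * 2), n)
  Y <- E %*% matrix(rnorm(2 * 5), 2) + matrix(rnorm(n * 5, 0, 0.5), n)
  vp <- varpart_fractions(Y, E, S)
  fr <- vp$fractions
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(fr[["a"]] + fr[["b"]], vp$adj_r2[["env"]], tolerance = 1e-9)
  expect_equal(fr[["b"]] + fr[["c"]], vp$adj_r2[["space"]], tolerance = 1e-9)
  expect_equal(fr[["d"]], 1 - vp$adj_r2[["full"]], tolerance = 1e-9)
  # env-only signal with orthogonal spatial set: c and b near zero
  expect_lt(abs(fr[["c"]]), 0.05)
  expect_lt(abs(fr[["b"]]), 0.05)
  # cross-check against vegan::varpart (its indfract rows are ordered
  # unique-X1, unique-X2, shared, residual)
  vv <- vegan::varpart(Y, E, S)$part$indfract$Adj.R.squared
  expect_equal(unname(fr[c("a", "c", "b", "d")]), vv, tolerance = 1e-9)
  # duplicated predictor sets are rank-deficient by construction
  expect_error(varpart_fractions(Y, E, E), "collinear")
  # near-duplicate: shared fraction carries everything
  S2 <- E + matrix(rnorm(n * 2, 0, 1e-4), n)
  vp2 <- varpart_fractions(Y, E, S2)
  expect_lt(abs(vp2$fractions[["a"]]), 0.02)
  expect_lt(abs(vp2$fractions[["c"]]), 0.02)
})

test_that("vca recovers the configured nested fractions from generated data", {
  cfg <- scenario_config()
  sim <- simulate_scenario(cfg, seed = 77)
  v <- vca(sim$env, sim$hierarchy, "DOC")
  expect_equal(v$component, c("biome", "floodplain", "zone", "habitat",
                              "residual"))
  truth <- cfg$variance_fractions["DOC", ]
  expect_lt(median(abs(v$percent - truth)), 15)
  expect_equal(sum(v$percent), 100, tolerance = 1e-6)
})
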