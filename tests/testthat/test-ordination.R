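test_that("NIPALS matches the eigendecomposition on complete matrices", {
  set.seed(3)
  X <- matrix(rnorm(30 * 6), 30, 6) %*% diag(c(3, 2.5, 2, 1, 1, 0.5))
  fit <- nipals_pca(X, n_axes = 3, center = TRUE, scale. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  for (a in 1:3) {
    expect_equal(abs(fit$loadings[, a]), abs(sv$v[, a]), tolerance = 1e-8)
    expect_equal(abs(fit$scores[, a]), abs(sv$u[, a] * sv$d[a]),
                 tolerance = 1e-7)
    expect_equal(fit$explained[a], sv$d[a]^2 / sum(sv$d^2), tolerance = 1e-8)
  }
  # sign convention: largest |loading| positive
  expect_true(all(apply(fit$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  # orthogonality and ordering
  expect_equal(crossprod(fit$loadings), diag(3), tolerance = 1e-8)
  expect_true(all(diff(fit$explained) <= 1e-10))
})

test_that("rank-1 data loads entirely on the first axis", {
  X <- outer(1:12, c(2, -1, 0.5))
  fit <- nipals_pca(X, n_axes = 2, center = TRUE, scale. = FALSE)
  expect_equal(fit$explained[1], 1, tolerance = 1e-10)
})

test_that("NIPALS tolerates missing cells", {
  set.seed(4)
  X <- matrix(rnorm(40 * 5), 40, 5) %*% diag(c(3, 2, 1, 0.5, 0.5))
  Xm <- X
  Xm[sample(length(X), round(0.05 * length(X)))] <- NA
  fit <- nipals_pca(Xm, n_axes = 2, center = TRUE, scale. = FALSE)
  expect_true(all(is.finite(fit$scores)))
  # reconstruction on observed cells should capture most variance
  rec <- fit$scores %*% t(fit$loadings)
  obs <- !is.na(Xm)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_lt(sum((Xc[obs] - rec[obs])^2) / sum(Xc[obs]^2), 0.25)
})

test_that("group dispersion reproduces hand-placed centroid distances", {
  sc <- rbind(c(0, 0), c(2, 0), c(1, 3), c(5, 5), c(7, 5))
  gd <- group_dispersion(sc, c("g1", "g1", "g1", "g2", "g2"))
  # g1 centroid (1,1): distances sqrt(2), sqrt(2), 2
  expect_equal(unname(gd$distances[1:3]), c(sqrt(2), sqrt(2), 2),
               tolerance = 1e-10)
  expect_equal(unname(gd$distances[4:5]), c(1, 1), tolerance = 1e-10)
  dup <- group_dispersion(rbind(c(1, 1), c(1, 1)), c("a", "a"))
  expect_equal(unname(dup$distances), c(0, 0), tolerance = 1e-12)
})

test_that("NMDS embeds exactly embeddable points with ~zero stress, reproducibly", {
  set.seed(6)
  pts <- matrix(rnorm(16), 8, 2)
  d <- dist(pts)
  fit <- nmds(d, k = 2, n_starts = 5, seed = 3)
  expect_lt(fit$stress, 1e-3)
  fit2 <- nmds(d, k = 2, n_starts = 5, seed = 3)
  expect_identical(fit$scores, fit2$scores)
  expect_true(fit$stress >= 0 && fit$stress <= 1)
  expect_error(nmds(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("ANOSIM matches exhaustive enumeration and the vegan cross-check", {
  set.seed(9)
  pts <- c(0, 0.3, 0.5, 5, 5.2, 5.4) + rnorm(6, 0, 0.01)
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  ex <- anosim(d, g, n_perm = "exact")
  # independent enumeration of all 720 label permutations
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 6), ]
  lower <- which(lower.tri(d))
  rk <- rank(d[lower])
  stat <- function(gg) {
    same <- outer(gg, gg, "==")[lower]
    (mean(rk[!same]) - mean(rk[same])) / (6 * 5 / 4)
  }
  null <- apply(perms, 1, function(pm) stat(g[pm]))
  expect_equal(ex$R, stat(g), tolerance = 1e-12)
  expect_equal(ex$p, mean(null >= ex$R), tolerance = 1e-12)
  vg <- vegan::anosim(as.dist(d), g, permutations = 99)
  expect_equal(ex$R, unname(vg$statistic), tolerance = 1e-10)
  # complete separation
  expect_equal(ex$R, 1)
})

test_that("ANOSIM R is centred near zero under random labels", {
  set.seed(12)
  rs <- replicate(200, {
    d <- as.matrix(dist(rnorm(8)))
    anosim(d, sample(rep(c("a", "b"), 4)), n_perm = 19, seed = 1)$R
  })
  expect_lt(abs(mean(rs)), 0.02)
  expect_true(all(abs(rs) <= 1 + 1e-12))
})

test_that("environmental vectors recover axis-aligned and closed-form fits", {
  set.seed(15)
  sc <- matrix(rnorm(40), 20, 2)
  ef <- envfit_vectors(sc, cbind(v = sc[, 1]), n_perm = 99, seed = 1)
  expect_equal(ef$r2, 1, tolerance = 1e-10)
  expect_gt(abs(ef$axis1), 0.99)
  expect_lt(abs(ef$axis2), 0.1)
  # hand 4-point example against closed-form least squares
  sc4 <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  v <- c(2, 0, 3, -1)
  ef4 <- envfit_vectors(sc4, cbind(v = v), n_perm = 99, seed = 1)
  co <- coef(lm(I(v - mean(v)) ~ 0 + sc4))
  r2 <- summary(lm(v ~ sc4))$r.squared
  expect_equal(ef4$r2, r2, tolerance = 1e-10)
  expect_equal(unname(unlist(ef4[1, c("axis1", "axis2")])),
               unname(co / sqrt(sum(co^2)) * sqrt(r2)), tolerance = 1e-10)
  # constant variable: r2 0, p 1
  efc <- envfit_vectors(sc, cbind(v = rep(1, 20)), n_perm = 99, seed = 1)
  expect_equal(c(efc$r2, efc$p), c(0, 1))
  # cross-check against vegan on a generic variable
  env1 <- cbind(z = rnorm(20))
  efv <- vegan::envfit(sc, env1, permutations = 99)
  expect_equal(envfit_vectors(sc, env1, n_perm = 99, seed = 2)$r2,
               unname(efv$vectors$r), tolerance = 1e-10)
})
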