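test_that("Shannon alpha diversity matches direct evaluation", {
  ct <- count_table(cbind(a = c(10L, 0L, 0L), b = c(5L, 5L, 5L),
                          c = c(50L, 25L, 25L)))
  H <- shannon_alpha(ct)
  expect_equal(unname(H["a"]), 0)
  expect_equal(unname(H["b"]), log(3))
  expect_equal(unname(H["c"]), 1.03972, tolerance = 1e-5)
  # zero-count taxa do not contribute
  ct2 <- count_table(rbind(ct$counts, 0))
  expect_equal(shannon_alpha(ct2), H)
})

test_that("Bray-Curtis agrees with the hand formula and its bounds", {
  ct <- count_table(cbind(x = c(6L, 2L), y = c(2L, 2L)))
  expect_equal(bray_curtis(ct)["x", "y"], 4 / 12)
  same <- count_table(cbind(a = c(3L, 1L), b = c(3L, 1L)))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disjoint <- count_table(cbind(a = c(5L, 0L), b = c(0L, 7L)))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)
  # invariant to taxon order
  ct3 <- rand_count_table(7, 4, seed = 5)
  perm <- sample(7)
  expect_equal(bray_curtis(ct3),
               bray_curtis(count_table(ct3$counts[perm, ],
                                       ct3$taxon_ids[perm])))
})

test_that("pairwise partition reproduces the Baselga worked cases", {
  # A={1,2,3}, B={2,3,4}: a=2, b=c=1 -> sor 1/3 all turnover
  m <- cbind(A = c(1L, 1L, 1L, 0L), B = c(0L, 1L, 1L, 1L))
  bp <- beta_partition(count_table(m), "incidence")
  expect_equal(bp$total["A", "B"], 1 / 3)
  expect_equal(bp$turnover["A", "B"], 1 / 3)
  expect_equal(bp$nestedness["A", "B"], 0)
  # B subset of A (a=2, b=2, c=0): pure nestedness
  m2 <- cbind(A = c(1L, 1L, 1L, 1L), B = c(1L, 1L, 0L, 0L))
  bp2 <- beta_partition(count_table(m2), "incidence")
  expect_equal(bp2$turnover["A", "B"], 0)
  expect_equal(bp2$nestedness["A", "B"], 1 / 3)
  expect_equal(bp2$total["A", "B"], 1 / 3)
  # identical pair
  m3 <- cbind(A = c(2L, 3L), B = c(2L, 3L))
  for (mode in c("incidence", "abundance")) {
    bp3 <- beta_partition(count_table(m3), mode)
    expect_equal(unname(bp3$total["A", "B"]), 0)
  }
})

test_that("partition identity, bounds and symmetry hold on random tables", {
  for (i in 1:25) {
    ct <- rand_count_table(10, 5, lambda = 3, seed = 100 + i)
    for (mode in c("incidence", "abundance")) {
      bp <- beta_partition(ct, mode)
      expect_equal(bp$total, bp$turnover + bp$nestedness, tolerance = 1e-12)
      expect_true(all(bp$total[is.finite(bp$total)] >= -1e-12))
      expect_true(all(bp$total[is.finite(bp$total)] <= 1 + 1e-12))
      expect_equal(bp$total, t(bp$total))
      expect_equal(unname(diag(bp$total)), rep(0, 5))
    }
  }
})

test_that("multi-site statistics equal the set-operation oracle", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(rbinom(5 * 8, 1, 0.5) * rpois(40, 4), 5, 8)
    colnames(m) <- paste0("s", 1:8)
    if (any(colSums(m) == 0)) next
    ct <- count_table(m)
    for (mode in c("incidence", "abundance")) {
      got <- multi_site_beta(ct, mode = mode)
      expect_equal(unname(got), multi_site_oracle(m, mode),
                   tolerance = 1e-12)
    }
  }
  # identical samples: zero; pairwise-disjoint: all turnover
  same <- count_table(matrix(3L, 4, 3))
  expect_equal(unname(multi_site_beta(same, mode = "incidence")),
               c(0, 0, 0))
  disj <- count_table(diag(3L) * 5L)
  got <- multi_site_beta(disj, mode = "incidence")
  expect_equal(unname(got["turnover"]), unname(got["total"]))
  expect_error(multi_site_beta(count_table(matrix(1L, 2, 2))), "3 samples")
})

test_that("taxon and sample contributions are normalised shares of variance", {
  ct <- rand_count_table(8, 5, seed = 31)
  tc <- taxon_contributions(ct)
  expect_equal(sum(tc$scbd), 1, tolerance = 1e-9)
  expect_equal(sum(tc$lcbd), 1, tolerance = 1e-9)
  expect_true(all(tc$scbd >= 0) && all(tc$lcbd >= 0))
  # a taxon constant after the Hellinger transform contributes nothing
  m <- ct$counts
  tot <- colSums(m)
  const <- matrix(round(tot / 4), 1)
  m2 <- rbind(m, const)                  # constant relative share
  tc2 <- taxon_contributions(count_table(m2), transform = "relative")
  expect_lt(tc2$scbd[9], 0.02)
})

test_that("guild fractions are read shares with label validation", {
  ct <- count_table(cbind(s1 = c(34L, 66L), s2 = c(0L, 50L)),
                    c("cy", "ot"),
                    guild = c("other-cyanobacteria", "other"))
  fr <- guild_fractions(ct, "other-cyanobacteria")
  expect_equal(unname(fr), c(0.34, 0))
  expect_equal(unname(guild_fractions(ct, c("other-cyanobacteria",
                                            "other"))), c(1, 1))
  expect_error(guild_fractions(ct, "archaea"), "unknown guild")
})
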