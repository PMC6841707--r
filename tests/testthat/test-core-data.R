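test_that("count table construction validates its invariants", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  ct <- count_table(m, c("a", "b", "c"))
  expect_s3_class(ct, "count_table")
  expect_equal(dim(ct), c(3L, 2L))
  expect_error(count_table(matrix(-1, 1, 1)), "negative")
  expect_error(count_table(matrix(1.5, 1, 1)), "non-integer")
  expect_error(count_table(matrix(1, 2, 1), c("x", "x")), "duplicate")
})

test_that("count table TSV round-trips identically", {
  ct <- rand_count_table(5, 4, seed = 11)
  ct$lineage <- paste0("P", 1:5, ";F", 1:5)
  ct$guild <- c("diatom", "other", "other", "diatom", "other")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(count_table(ct$counts, ct$taxon_ids, ct$lineage,
                                ct$guild), path)
  back <- read_count_table(path)
  expect_identical(unname(back$counts), unname(ct$counts))
  expect_identical(back$lineage, ct$lineage)
  expect_identical(back$guild, ct$guild)
})

test_that("samples-as-rows orientation flag flips the matrix on read", {
  ct <- rand_count_table(3, 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(ct$counts), t(ct$counts))
  writeLines("# orientation: samples-as-rows", path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  back <- read_count_table(path)
  expect_equal(unname(back$counts), unname(ct$counts))
})

test_that("reading malformed counts names the offending column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "a\t3\toops", "b\t1\t2"), path)
  expect_error(read_count_table(path), "s2")
})

test_that("prevalence/read-count filter matches the stated removal rule", {
  # taxon1: 2 of 10 samples, 500 reads -> removed (low prevalence)
  # taxon2: all samples, 19 reads total -> removed (low total)
  # taxon3: all samples, 20 reads total -> retained (boundary)
  m <- rbind(c(250, 250, rep(0, 8)),
             c(rep(2, 9), 1),
             c(rep(2, 10)))
  ct <- count_table(m, c("t1", "t2", "t3"))
  kept <- filter_taxa(ct)
  expect_identical(kept$taxon_ids, "t3")
  # "and" rule removes only taxa failing both conditions
  kept_and <- filter_taxa(ct, rule = "and")
  expect_setequal(kept_and$taxon_ids, c("t1", "t2", "t3"))
  # idempotence
  expect_identical(filter_taxa(kept)$counts, kept$counts)
})

test_that("rarefaction hits depth exactly, drops shallow samples, and is seeded", {
  set.seed(42)
  m <- matrix(rpois(5 * 3, 40), 5, 3)
  m[, 1] <- m[, 1] + 100          # deep sample
  ct <- count_table(m)
  depth <- min(colSums(m))
  r1 <- rarefy(ct, depth, seed = 7)
  expect_true(all(colSums(r1$counts) == depth))
  expect_identical(rarefy(ct, depth, seed = 7)$counts, r1$counts)
  expect_false(identical(rarefy(ct, depth, seed = 8)$counts, r1$counts))
  # a sample one read short of depth is dropped
  shallow <- count_table(cbind(a = c(5L, 5L), b = c(4L, 5L)))
  expect_message(out <- rarefy(shallow, 10, seed = 1), "dropping")
  expect_identical(colnames(out$counts), "a")
  expect_identical(attr(out, "dropped_samples"), "b")
  expect_error(rarefy(shallow, 99), "below depth")
})

test_that("taxon collapse sums counts, conserves totals, and pools unclassified", {
  ct <- count_table(matrix(c(3, 7, 5, 1, 2, 4), 3, 2),
                    c("o1", "o2", "o3"),
                    lineage = c("Cyano;FamA", "Cyano;FamA", "Cyano"),
                    guild = c("other-cyanobacteria", "other-cyanobacteria",
                              "diatom"))
  fam <- collapse_taxa(ct, level = 2)
  expect_setequal(fam$taxon_ids, c("FamA", "unclassified-Cyano"))
  expect_equal(unname(fam$counts["FamA", ]), c(3 + 7, 1 + 2))
  expect_equal(colSums(fam$counts), colSums(ct$counts))
  expect_identical(fam$guild[fam$taxon_ids == "FamA"], "other-cyanobacteria")
  # disagreeing guilds collapse to "mixed"
  ct2 <- count_table(matrix(1:4, 2, 2), c("a", "b"),
                     lineage = c("P;F", "P;F"),
                     guild = c("diatom", "other"))
  expect_identical(collapse_taxa(ct2, 2)$guild, "mixed")
})

test_that("filter -> rarefy -> collapse conserves rarefied totals", {
  ct <- rand_count_table(20, 6, lambda = 60, seed = 3)
  ct$lineage <- paste0("P", rep(1:4, 5), ";F", rep(1:10, 2))
  ct <- count_table(ct$counts, ct$taxon_ids, ct$lineage)
  depth <- min(colSums(ct$counts)) - 10
  out <- collapse_taxa(rarefy(filter_taxa(ct, 0.2, 5), depth, seed = 1), 2)
  expect_true(all(colSums(out$counts) == depth))
})

test_that("sample hierarchy enforces zone/habitat consistency", {
  expect_error(
    sample_hierarchy("s1", "montane", "FP1", "main-channel", "pond"),
    "inconsistent with zone")
  h <- sample_hierarchy(c("s1", "s2"), "montane", "FP1",
                        c("main-channel", "off-channel"),
                        c("riffle", "pond"))
  expect_s3_class(h, "sample_hierarchy")
  expect_error(
    sample_hierarchy(c("s1", "s1"), "montane", "FP1", "main-channel",
                     "riffle"), "duplicate")
})

test_that("flow series validates dates and discharge", {
  expect_error(flow_series("r", as.Date(c("2000-01-02", "2000-01-01")),
                           c(1, 2)), "increasing")
  expect_error(flow_series("r", as.Date(c("2000-01-01", "2000-01-02")),
                           c(1, -2)), "non-negative")
})
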