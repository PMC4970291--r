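test_that("dereplication counts distinct strings per sample and conserves reads", {
  tab <- dereplicate(list(s1 = c("ACGT", "ACGT", "ACGA")))
  expect_equal(unname(pooled_counts(tab)[match("ACGT", tab$seqs)]), 2)
  expect_equal(unname(pooled_counts(tab)[match("ACGA", tab$seqs)]), 1)
  expect_equal(sum(tab$counts), 3)

  shared <- dereplicate(list(a = c("AAAA", "CCCC"), b = c("AAAA")))
  expect_equal(unname(pooled_counts(shared)[match("AAAA", shared$seqs)]), 2)
  expect_equal(dim(shared$counts), c(2L, 2L))
  expect_error(dereplicate(list(a = character(0))), "no sequences")
})

test_that("cross-sample rare-sequence removal retains exactly the abundant sequences", {
  # pooled counts by construction: AAAA = 3, CCCC = 1, GGGG = 1
  tab <- dereplicate(list(s1 = c("AAAA", "AAAA", "AAAA", "CCCC"),
                          s2 = c("GGGG")))
  t2 <- remove_rare(tab, 2)
  expect_equal(unname(t2$table$seqs), "AAAA")
  expect_equal(unname(t2$table$counts[1, ]), c(3L, 0L))
  expect_equal(t2$report$sequences_removed, 2)
  expect_equal(t2$report$reads_removed, 2)
  expect_equal(t2$report$reads_retained + t2$report$reads_removed,
               sum(tab$counts))

  ident <- remove_rare(tab, 1)
  expect_identical(ident$table$counts, tab$counts)

  doubleton <- dereplicate(list(s1 = "TTTT", s2 = "TTTT"))
  gone <- remove_rare(doubleton, 3)
  expect_equal(nrow(gone$table$counts), 0)
  expect_equal(gone$report$reads_removed, 2)
})

test_that("filtering is idempotent and monotone in the threshold", {
  set.seed(31)
  counts <- matrix(rpois(60, 1.2), ncol = 3)
  tab <- make_useq(counts[rowSums(counts) > 0, , drop = FALSE])
  for (t in c(2, 3, 5)) {
    once <- remove_rare(tab, t)$table
    twice <- remove_rare(once, t)$table
    expect_identical(once$counts, twice$counts)
  }
  kept <- lapply(1:4, function(t) names(remove_rare(tab, t)$table$seqs))
  for (t in 1:3) expect_true(all(kept[[t + 1]] %in% kept[[t]]))
})

test_that("rarefaction hits the exact depth and errors on shallow samples", {
  tab <- make_useq(matrix(c(60, 40, 10, 90), ncol = 2))
  r <- rarefy(tab, depth = 100, seed = 1)
  expect_equal(unname(colSums(r$counts)), c(100L, 100L))
  expect_identical(r$counts, tab$counts)  # already at depth: unchanged

  expect_error(rarefy(tab, depth = 101, seed = 1), "S01")

  deep <- make_useq(matrix(c(100, 100), ncol = 1))
  draws <- vapply(1:200, function(s) {
    rarefy(deep, depth = 100, seed = s)$counts[1, 1]
  }, integer(1))
  expect_equal(unique(vapply(1:5, function(s) {
    sum(rarefy(deep, depth = 100, seed = s)$counts)
  }, integer(1))), 100L)
  # hypergeometric mean 50, sd of the mean over 200 draws ~ 0.25
  sigma <- sqrt(100 * 0.25 * 100 / 199) / sqrt(200)
  expect_lt(abs(mean(draws) - 50), 3 * sigma + 1e-9)
})

test_that("rarefaction is deterministic under a fixed seed", {
  tab <- make_useq(matrix(rpois(30, 8) + 1, ncol = 2))
  expect_identical(rarefy(tab, 50, seed = 7)$counts,
                   rarefy(tab, 50, seed = 7)$counts)
})

test_that("the cluster-size spectrum tallies pooled counts and conserves reads", {
  tab <- dereplicate(list(s1 = c("AAAA", "AAAA", "AAAA", "CCCC"),
                          s2 = c("GGGG")))
  sp <- cluster_size_spectrum(tab)
  expect_equal(sp$cluster_size, c(1L, 3L))
  expect_equal(sp$n_clusters, c(2L, 1L))
  expect_equal(sum(sp$cluster_size * sp$n_clusters), sum(tab$counts))

  filtered <- remove_rare(tab, 2)$table
  spf <- cluster_size_spectrum(filtered)
  expect_false(1L %in% spf$cluster_size)
})

test_that("rarefying then filtering never yields more unique sequences than rarefying alone", {
  set.seed(77)
  counts <- matrix(rpois(80, 2), ncol = 2)
  tab <- make_useq(counts[rowSums(counts) > 0, , drop = FALSE])
  r <- rarefy(tab, depth = min(colSums(tab$counts)), seed = 3)
  rf <- remove_rare(r, 2)$table
  expect_lte(nrow(rf$counts), nrow(r$counts))
})
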