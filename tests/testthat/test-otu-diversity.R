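test_that("distance matrices are symmetric with zero diagonal", {
  seqs <- stats::setNames(random_dna(5, 80), paste0("u", 1:5))
  seqs[2] <- seqs[1]
  dm <- pairwise_distances(seqs)
  expect_equal(dm[1, 2], 0)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 5))
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("average-linkage clustering handles the extreme cutoff cases", {
  set.seed(51)
  seqs <- stats::setNames(random_dna(6, 100), paste0("u", 1:6))
  dm <- pairwise_distances(seqs)
  expect_true(all(dm[upper.tri(dm)] > 0.03))
  otus <- cluster_otus(dm, 0.03)
  expect_equal(nrow(otus$counts), 6)

  base <- random_dna(1, 100)
  near <- base
  substr(near, 10, 10) <- chartr("ACGT", "CAAA", substr(base, 10, 10))
  substr(near, 60, 60) <- chartr("ACGT", "GGTC", substr(base, 60, 60))
  pair <- stats::setNames(c(base, near), c("a", "b"))
  dm2 <- pairwise_distances(pair)
  expect_equal(dm2["a", "b"], 0.02)
  expect_equal(nrow(cluster_otus(dm2, 0.03)$counts), 1)
})

test_that("clustering matches a greedy average-linkage oracle on small instances", {
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(5:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.08)
    d <- d + t(d)
    dimnames(d) <- list(paste0("u", 1:n), paste0("u", 1:n))
    cutoff <- runif(1, 0.015, 0.06)
    got <- cluster_otus(d, cutoff)
    membership <- integer(n)
    for (g in seq_along(got$members)) {
      membership[match(got$members[[g]], rownames(d))] <- g
    }
    expect_equal(partition_signature(membership),
                 partition_signature(oracle_average_linkage(d, cutoff)))
  }
})

test_that("clustering conserves read totals and names representatives", {
  refs <- mock_reference_set(length = 150, seed = 61)
  cfg <- sim_config(n_samples = 3, depth = 50, sub_rate = 0.004,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0.1, n_noise_templates = 40, seed = 62)
  tab <- dereplicate(simulate_run(refs, cfg))
  otus <- cluster_otus(pairwise_distances(tab), 0.03, tab)
  expect_equal(sum(otus$counts), sum(tab$counts))
  expect_equal(sort(unlist(otus$members, use.names = FALSE)),
               sort(names(tab$seqs)))
  expect_true(all(otus$representatives %in% tab$seqs))
  expect_true(all(diff(rowSums(otus$counts)) <= 0))
})

test_that("alpha diversity matches closed forms on constructed tables", {
  even <- alpha_diversity(make_otus(matrix(c(50, 50), 2, 1)))
  ps <- even$per_sample
  expect_equal(ps$sobs, 2)
  expect_equal(ps$shannon, log(2))
  expect_equal(ps$invsimpson, 99 / 49)
  expect_equal(ps$chao, 2)  # n1 = 0 so Chao collapses to S_obs

  single <- alpha_diversity(make_otus(matrix(7, 1, 1)))
  expect_equal(single$per_sample$shannon, 0)
  expect_equal(single$per_sample$sobs, 1)

  rare <- alpha_diversity(make_otus(matrix(c(4, 1, 1, 1, 2, 2), ncol = 1)))
  # n1 = 3, n2 = 2: bias-corrected Chao adds 3*2 / (2*3) = 1
  expect_equal(rare$per_sample$chao, 7)

  lone <- alpha_diversity(make_otus(matrix(1, 1, 1)))
  expect_true(is.na(lone$per_sample$invsimpson))

  expect_error(alpha_diversity(make_otus(matrix(c(3, 0), 1, 2))),
               "zero reads")
})

test_that("Shannon and Chao agree with vegan on random tables", {
  set.seed(57)
  counts <- matrix(rpois(40, 3), nrow = 10,
                   dimnames = list(paste0("Otu", 1:10), paste0("S", 1:4)))
  counts[1, ] <- counts[1, ] + 1  # keep every sample non-empty
  div <- alpha_diversity(make_otus(counts))
  veg_sh <- unname(vegan::diversity(t(counts), index = "shannon"))
  expect_equal(div$per_sample$shannon, veg_sh, tolerance = 1e-12)
  veg_chao <- unname(vegan::estimateR(t(counts))["S.chao1", ])
  expect_equal(div$per_sample$chao, veg_chao, tolerance = 1e-12)
})

test_that("Chao-type total-richness estimates behave at the extremes", {
  no_rare <- estimated_total_otus(make_otus(matrix(c(5, 9, 4), 3, 1)))
  expect_equal(no_rare$estimate, no_rare$sobs)

  many_singletons <- make_otus(matrix(c(rep(1, 30), 50, 40), ncol = 1))
  infl <- estimated_total_otus(many_singletons)
  expect_gt(infl$estimate, 5 * infl$sobs)

  refs <- mock_reference_set(length = 120, seed = 71,
                             primer_bias = FALSE)
  cfg <- sim_config(n_samples = 2, depth = 400, sub_rate = 0,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0, seed = 72)
  tab <- dereplicate(simulate_run(refs, cfg))
  otus <- cluster_otus(pairwise_distances(tab), 0.03, tab)
  est <- estimated_total_otus(otus)
  expect_true(all(abs(est$estimate - 21) <= 1.5))
})
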