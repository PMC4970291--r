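tax_refs <- mock_reference_set(length = 150, seed = 81,
                               primer_bias = FALSE)

test_that("nearest-reference assignment labels copies and rejects foreign sequences", {
  hit <- assign_otu(tax_refs$seqs[[3]], tax_refs)
  expect_equal(hit$label, tax_refs$genus[3])
  expect_equal(hit$identity, 100)

  set.seed(82)
  foreign <- random_dna(1, 150)
  miss <- assign_otu(foreign, tax_refs, min_identity = 80)
  expect_equal(miss$label, "unclassified")
  expect_lt(miss$identity, 80)
  expect_error(assign_otu(foreign, tax_refs, min_identity = 0), "0, 100")
})

test_that("nearly all simulated non-chimeric reads map back to their source genus", {
  cfg <- sim_config(n_samples = 2, depth = 150, sub_rate = 0.003,
                    ins_rate = 2e-4, del_rate = 2e-4, chimera_prob = 0,
                    noise_rate = 0, seed = 83)
  run <- simulate_run(tax_refs, cfg)
  tab <- dereplicate(run)
  otus <- cluster_otus(pairwise_distances(tab), 0.03, tab)
  assignments <- assign_otus(otus, tax_refs, min_identity = 80)

  seq_to_otu <- stats::setNames(
    rep(names(otus$members), lengths(otus$members)),
    unlist(otus$members, use.names = FALSE))
  read_seq_id <- names(tab$seqs)[match(
    unlist(run$reads, use.names = FALSE), tab$seqs)]
  read_genus <- assignments$genus[match(seq_to_otu[read_seq_id],
                                        assignments$otu)]
  truth_genus <- tax_refs$genus[match(run$truth$template,
                                      names(tax_refs$seqs))]
  ok <- read_genus == truth_genus
  expect_gte(mean(ok), 0.99)
})

test_that("per-sample genus fractions sum to one and match an even design", {
  cfg <- sim_config(n_samples = 4, depth = 300, sub_rate = 0,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0, seed = 84)
  run <- simulate_run(tax_refs, cfg)
  tab <- dereplicate(run)
  otus <- cluster_otus(pairwise_distances(tab), 0.03, tab)
  assignments <- assign_otus(otus, tax_refs)
  ts <- summarize_relative_abundance(otus, assignments,
                                     drop_nonbacterial = FALSE)
  expect_equal(unname(colSums(ts$per_sample)), rep(1, 4),
               tolerance = 1e-9)
  genera <- unique(tax_refs$genus)
  sigma <- sqrt(0.05 * 0.95 / 1200)
  means <- ts$summary$mean_fraction[match(genera, ts$summary$genus)]
  expect_true(all(abs(means - 0.05) < 3 * sigma + 1e-9))
  expect_equal(ts$unclassified, 0)
})

test_that("under-amplified members are detected far below their design share", {
  biased <- mock_reference_set(length = 150, seed = 81)
  cfg <- sim_config(n_samples = 3, depth = 200, sub_rate = 0,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0, seed = 85)
  run <- simulate_run(biased, cfg)
  tab <- dereplicate(run)
  otus <- cluster_otus(pairwise_distances(tab), 0.03, tab)
  assignments <- assign_otus(otus, biased)
  ts <- summarize_relative_abundance(otus, assignments)
  des <- ts$summary$mean_fraction[ts$summary$genus == "Desulfovibrio"]
  if (length(des) == 0) des <- 0
  expect_lt(des, 0.01)
})

test_that("filtering never increases the unclassified fraction when the noise tail is foreign", {
  refs <- mock_reference_set(length = 150, seed = 86, primer_bias = FALSE)
  cfg <- sim_config(n_samples = 4, depth = 80, sub_rate = 0.003,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0.15, n_noise_templates = 120, seed = 87)
  tab <- dereplicate(simulate_run(refs, cfg))
  frac_at <- function(t) {
    ft <- remove_rare(tab, t)$table
    otus <- cluster_otus(pairwise_distances(ft), 0.03, ft)
    ts <- summarize_relative_abundance(otus, assign_otus(otus, refs))
    ts$unclassified
  }
  u <- vapply(1:3, frac_at, numeric(1))
  expect_true(all(diff(u) <= 0))
  expect_gt(u[1], 0)
})
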