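err_refs <- generate_references(4, length = 150, seed = 41,
                                genus = paste0("Genus", 1:4))

test_that("error rate is zero exactly when every sequence matches a reference", {
  cfg0 <- sim_config(n_samples = 2, depth = 30, sub_rate = 0,
                     ins_rate = 0, del_rate = 0, chimera_prob = 0,
                     noise_rate = 0, seed = 6)
  tab <- dereplicate(simulate_run(err_refs, cfg0))
  rep0 <- error_rate(tab, err_refs)
  expect_equal(rep0$overall, 0)
  expect_equal(unname(rep0$per_sample), c(0, 0))
  expect_equal(rep0$reads_assessed, 60)
})

test_that("per-base arithmetic: 2 errors over 500 aligned bases at count 1", {
  ref <- random_dna(1, 500)
  q <- ref
  substr(q, 100, 100) <- chartr("ACGT", "CAAA", substr(ref, 100, 100))
  substr(q, 300, 300) <- chartr("ACGT", "GGTC", substr(ref, 300, 300))
  refs <- reference_set(c(r1 = ref))
  tab <- make_useq(matrix(1, 1, 1), seqs = q)
  rep1 <- error_rate(tab, refs, exclude_chimeras = FALSE)
  expect_equal(rep1$overall, 2 / 500)
})

test_that("the estimator recovers an injected substitution rate within three standard errors", {
  refs <- mock_reference_set(length = 200, seed = 31)
  cfg <- sim_config(n_samples = 2, depth = 300, sub_rate = 0.014,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0, seed = 17)
  run <- simulate_run(refs, cfg)
  tab <- dereplicate(run)
  est <- error_rate(tab, refs, exclude_chimeras = FALSE)$overall
  n_bases <- 600 * 200
  sigma <- sqrt(0.014 * (1 - 0.014) / n_bases)
  expect_lt(abs(est - 0.014), 3 * sigma)
})

test_that("reference-based bimera flagging detects constructed chimeras", {
  a <- err_refs$seqs[[1]]
  b <- err_refs$seqs[[2]]
  expect_lte(pairwise_identity(a, b), 90)
  chim <- paste0(substr(a, 1, 75), substr(b, 76, 150))
  fc <- flag_chimera(chim, err_refs)
  expect_true(fc$is_chimera)
  expect_equal(fc$left_parent, names(err_refs$seqs)[1])
  expect_equal(fc$right_parent, names(err_refs$seqs)[2])

  expect_false(flag_chimera(a, err_refs)$is_chimera)

  dup <- generate_references(
    3, length = 150, seed = 2,
    divergence_spec = list(list(pair = c(1, 2), identity = 1)))
  undetectable <- paste0(substr(dup$seqs[[1]], 1, 75),
                         substr(dup$seqs[[2]], 76, 150))
  expect_false(flag_chimera(undetectable, dup)$is_chimera)
})

test_that("chimeric reads are excluded from the error rate", {
  a <- err_refs$seqs[[1]]
  b <- err_refs$seqs[[2]]
  chim <- paste0(substr(a, 1, 75), substr(b, 76, 150))
  tab <- make_useq(matrix(c(5, 1), 2, 1), seqs = c(a, chim))
  with_chim <- error_rate(tab, err_refs, exclude_chimeras = FALSE)
  without <- error_rate(tab, err_refs, exclude_chimeras = TRUE)
  expect_gt(with_chim$overall, 0)
  expect_equal(without$overall, 0)
  expect_equal(without$chimeras_excluded, 1)
  expect_equal(without$reads_assessed + without$chimeras_excluded,
               sum(tab$counts))
})

test_that("removing cross-sample singletons lowers the error rate on noisy runs", {
  refs <- mock_reference_set(length = 150, seed = 13)
  cfg <- sim_config(n_samples = 4, depth = 60, sub_rate = 0.003,
                    ins_rate = 2e-4, del_rate = 2e-4, chimera_prob = 0,
                    noise_rate = 0.15, n_noise_templates = 120, seed = 19)
  tab <- dereplicate(simulate_run(refs, cfg))
  all_rate <- error_rate(tab, refs, exclude_chimeras = FALSE)$overall
  t2 <- remove_rare(tab, 2)$table
  filt_rate <- error_rate(t2, refs, exclude_chimeras = FALSE)$overall
  expect_lt(filt_rate, all_rate)
  expect_gte(filt_rate, 0)
  expect_lte(all_rate, 1)
})
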