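test_that("a noise-free run gives identical branches, zero error, and the true OTU count", {
  refs <- mock_reference_set(length = 120, seed = 101,
                             primer_bias = FALSE)
  cfg <- sim_config(n_samples = 4, depth = 150, sub_rate = 0,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0, seed = 102)
  run <- simulate_run(refs, cfg)
  rep <- validate(run, config = pipeline_config(rarefy_depth = 150,
                                                seed = 103))
  expect_equal(nrow(rep$summary), 3)
  expect_equal(rep$summary$error_rate_pct, rep(0, 3))
  # 21 reference templates -> 21 OTUs in every branch
  for (br in rep$branches) expect_equal(nrow(br$otus$counts), 21)
  for (col in c("observed_otus", "chao", "shannon", "invsimpson")) {
    expect_equal(rep$summary[[col]], rep(rep$summary[[col]][1], 3))
  }
  expect_equal(rep$summary$unclassified_pct, rep(0, 3))
})

test_that("validation is deterministic under fixed seeds", {
  refs <- mock_reference_set(length = 120, seed = 104)
  cfg <- sim_config(n_samples = 3, depth = 60, sub_rate = 0.003,
                    ins_rate = 2e-4, del_rate = 2e-4,
                    chimera_prob = 0.01, noise_rate = 0.1,
                    n_noise_templates = 60, seed = 105)
  run <- simulate_run(refs, cfg)
  conf <- pipeline_config(rarefy_depth = 60, seed = 106)
  expect_identical(validate(run, config = conf)$summary,
                   validate(run, config = conf)$summary)
})

test_that("noisy runs order the branches the way filtering should", {
  refs <- mock_reference_set(length = 150, seed = 107)
  cfg <- sim_config(n_samples = 4, depth = 70, sub_rate = 0.003,
                    ins_rate = 2e-4, del_rate = 2e-4,
                    chimera_prob = 0.005, noise_rate = 0.15,
                    n_noise_templates = 150, seed = 108)
  run <- simulate_run(refs, cfg)
  rep <- validate(run, config = pipeline_config(rarefy_depth = 70,
                                                seed = 109))
  expect_true(all(diff(rep$summary$error_rate_pct) <= 0))
  expect_true(all(diff(rep$summary$observed_otus) <= 0))
  expect_true(all(diff(rep$summary$unique_sequences) < 0))
  expect_gt(rep$summary$error_rate_pct[1], rep$summary$error_rate_pct[3])
})

test_that("validation artifacts are written and re-loadable", {
  refs <- mock_reference_set(length = 120, seed = 110,
                             primer_bias = FALSE)
  cfg <- sim_config(n_samples = 2, depth = 40, sub_rate = 0.002,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0.1, n_noise_templates = 30, seed = 111)
  run <- simulate_run(refs, cfg)
  rep <- validate(run, config = pipeline_config(rarefy_depth = 40,
                                                seed = 112))
  dir <- withr::local_tempdir()
  write_validation_report(rep, dir)
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  summ <- utils::read.delim(file.path(dir, "summary.tsv"),
                            comment.char = "#")
  expect_equal(summ$branch, rep$summary$branch)
  back <- read_counts(file.path(dir, "counts.tsv"))
  expect_identical(back$counts, rep$table$counts)
  expect_true(file.exists(file.path(dir, "genus_all.tsv")))
})

test_that("stage failures propagate with the stage name", {
  refs <- mock_reference_set(length = 120, seed = 113)
  cfg <- sim_config(n_samples = 2, depth = 30, sub_rate = 0,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0, seed = 114)
  run <- simulate_run(refs, cfg)
  expect_error(
    validate(run, config = pipeline_config(rarefy_depth = 500)),
    "stage 'rarefy'")
})

test_that("simulated runs written to disk rebuild the same count table", {
  refs <- mock_reference_set(length = 120, seed = 115)
  cfg <- sim_config(n_samples = 2, depth = 25, sub_rate = 0.005,
                    ins_rate = 0, del_rate = 0, chimera_prob = 0,
                    noise_rate = 0, seed = 116)
  run <- simulate_run(refs, cfg)
  dir <- withr::local_tempdir()
  write_run(run, dir)
  reads <- lapply(names(run$reads), function(s) {
    read_fasta(file.path(dir, paste0(s, ".fasta")))
  })
  names(reads) <- names(run$reads)
  expect_identical(dereplicate(reads)$counts, dereplicate(run)$counts)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 50)
})
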