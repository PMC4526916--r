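# Seeded generators: determinism, ground-truth completeness, closed-form
# peak areas, and recovery of planted structure by the downstream modules.

test_that("generators are byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- proteome_spec(4, 12, decoy_modes = c("no_motif", "broken_motif"),
                        seed = 21)
  generate_proteome(spec, out_dir = d1)
  generate_proteome(spec, out_dir = d2)
  for (f in c("proteome.fasta", "proteome_truth.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  rspec <- run_spec(c("a", "b"), c(1, 3), seed = 22)
  generate_run(rspec, atcape1_assay(), out_dir = d1)
  generate_run(rspec, atcape1_assay(), out_dir = d2)
  expect_identical(readBin(file.path(d1, "traces.tsv"), "raw", 1e7),
                   readBin(file.path(d2, "traces.tsv"), "raw", 1e7))
  espec <- expression_spec(n_genes = 40, seed = 23)
  generate_expression(espec, out_dir = d1)
  generate_expression(espec, out_dir = d2)
  expect_identical(readBin(file.path(d1, "expression.tsv"), "raw", 1e7),
                   readBin(file.path(d2, "expression.tsv"), "raw", 1e7))
})

test_that("proteome ground truth is complete and one row per record", {
  sim <- generate_proteome(proteome_spec(5, 17,
    decoy_modes = c("no_motif", "internal_motif", "mutated_cleavage_Y",
                    "broken_motif"), seed = 24))
  expect_equal(length(sim$sequences), 22)
  expect_setequal(sim$truth$id, names(sim$sequences))
  expect_equal(anyDuplicated(sim$truth$id), 0)
  expect_equal(sum(sim$truth$is_true), 5)
  # true precursors end exactly at the motif's terminal Y
  for (id in sim$truth$id[sim$truth$is_true]) {
    seq <- sim$sequences[[id]]
    pep <- sim$truth$peptide[sim$truth$id == id]
    expect_equal(substr(seq, nchar(seq) - 10, nchar(seq)), pep)
  }
  expect_error(proteome_spec(1, 1, min_len = 300, max_len = 200, seed = 1),
               "min_len")
})

test_that("mining recovers generated proteomes with sensitivity and specificity 1", {
  for (mode in c("no_motif", "internal_motif", "mutated_cleavage_Y",
                 "broken_motif")) {
    sim <- generate_proteome(proteome_spec(5, 20, decoy_modes = mode,
                                           seed = 25))
    cands <- mine_proteome(sim$sequences)
    hits <- sim$truth[sim$truth$expected_hit, ]
    expect_setequal(cands$precursor_id, hits$id)
    expect_equal(
      cands$cleavage_competent[match(hits$id, cands$precursor_id)],
      hits$expected_competent, info = mode)
    # true peptides come back verbatim
    trues <- sim$truth[sim$truth$is_true, ]
    expect_equal(cands$peptide[match(trues$id, cands$precursor_id)],
                 trues$peptide, info = mode)
  }
  # zero planted motifs: mining yields nothing
  none <- generate_proteome(proteome_spec(0, 50, seed = 26))
  expect_equal(nrow(mine_proteome(none$sequences)), 0)
})

test_that("noiseless runs hit the closed-form Gaussian area", {
  spec <- run_spec(c("s1", "s2"), c(1, 2), noise_sd = 0, rt_jitter_sd = 0,
                   seed = 27)
  run <- generate_run(spec, atcape1_assay())
  for (r in seq_len(nrow(run$truth$areas))) {
    tr <- extract_xic(run$traces,
                      transition_id = run$truth$areas$transition_id[r],
                      sample_id = run$truth$areas$sample_id[r])
    area <- integrate_peak(tr, baseline = "none")
    expect_equal(area, run$truth$areas$true_area[r], tolerance = 0.02)
  }
  res <- quantify_run(run$traces, atcape1_assay(), "s1",
                      baseline = "none")
  expect_equal(res$relative_ratio, c(1, 2), tolerance = 1e-6)
  expect_error(run_spec("a", 0, seed = 1), "> 0")
  expect_error(run_spec("a", 1, rt_sigma = -1, seed = 1), "rt_sigma")
})

test_that("IS normalization cancels per-sample global scaling", {
  base <- run_spec(c("a", "b"), c(1, 4), noise_sd = 0, rt_jitter_sd = 0,
                   global_scale = c(1, 1), seed = 28)
  scaled <- run_spec(c("a", "b"), c(1, 4), noise_sd = 0, rt_jitter_sd = 0,
                     global_scale = c(1, 10), seed = 28)
  q1 <- quantify_run(generate_run(base, atcape1_assay())$traces,
                     atcape1_assay(), "a")
  q2 <- quantify_run(generate_run(scaled, atcape1_assay())$traces,
                     atcape1_assay(), "a")
  expect_equal(q2$normalized, q1$normalized, tolerance = 1e-9)
  expect_equal(q2$relative_ratio, q1$relative_ratio, tolerance = 1e-9)
  expect_equal(q2$is_area[2], 10 * q1$is_area[2], tolerance = 1e-9)
})

test_that("expression generator plants responses and QC failures exactly", {
  planted <- data.frame(gene = 1:4, condition = "salt",
                        log2fc = c(2, 2, -2, -2))
  spec <- expression_spec(n_genes = 80, planted_responses = planted,
                          qc_low_genes = 4, qc_highcv_genes = 4, seed = 29)
  sim <- generate_expression(spec)
  expect_equal(dim(sim$matrix), c(80, 6 * 3))
  expect_setequal(qc_filter(sim$matrix, sim$metadata),
                  sim$truth$gene[sim$truth$expected_qc_pass])
  de <- call_de(sim$matrix, sim$metadata, c("salt", "control"))
  expect_true(all(de$de_flag[de$gene %in% sprintf("GENE_%04d", 1:4)]))
  # a clean matrix with no planted responses and tiny noise: no calls
  quiet <- generate_expression(expression_spec(n_genes = 40,
                                               noise_sd = 1e-3, seed = 30))
  de0 <- call_de(quiet$matrix, quiet$metadata, c("salt", "control"))
  expect_equal(sum(de0$de_flag), 0)
  expect_error(expression_spec(n_replicates = 1, seed = 1), "replicates")
  expect_error(expression_spec(planted_responses = data.frame(
    gene = "NOPE", condition = "salt", log2fc = 1), seed = 1), "gene")
})
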