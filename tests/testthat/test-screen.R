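# Expression screen: QC semantics, DE calling, specificity classes and the
# qPCR transform.

# small handmade matrix helpers
meta_for <- function(stresses, n_rep = 3, time_h = 12) {
  g <- expand.grid(replicate = seq_len(n_rep), stress = stresses,
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_r%d", g$stress, g$replicate),
             stress = g$stress, tissue = "root", time_h = time_h,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

test_that("qc_filter implements the 'any time point' keep rule", {
  meta <- meta_for(c("control", "salt"))
  m <- rbind(
    low      = rep(50, 6),                      # below floor everywhere
    good_one = c(1000, 1200, 1100, 100, 500, 2000),  # CV ~9% then ~83%
    noisy    = c(100, 900, 2000, 80, 700, 1800))     # high CV everywhere
  colnames(m) <- meta$sample_id
  kept <- qc_filter(m, meta)
  expect_true("good_one" %in% kept)     # one clean time point suffices
  expect_false("low" %in% kept)
  expect_false("noisy" %in% kept)
  # single-replicate conditions are skipped with a warning
  meta1 <- meta_for(c("control", "salt"), n_rep = 1)
  m1 <- matrix(1000, 1, 2, dimnames = list("g", meta1$sample_id))
  # one warning per single-replicate condition (two here)
  expect_warning(expect_warning(k1 <- qc_filter(m1, meta1),
                                "single replicate"))
  expect_equal(length(k1), 0)
})

test_that("call_de combines the fold-change and p-value rules", {
  meta <- meta_for(c("control", "salt"), n_rep = 4)
  withr::with_seed(41, {
    up <- 2^(10 + c(rep(0, 4), rep(2, 4)) + rnorm(8, 0, 0.1))
    flat <- 2^(10 + rnorm(8, 0, 0.1))
    # FC below threshold no matter how significant
    weak <- 2^(10 + c(rep(0, 4), rep(log2(1.4), 4)) + rnorm(8, 0, 0.02))
  })
  m <- rbind(up = up, flat = flat, weak = weak)
  colnames(m) <- meta$sample_id
  de <- call_de(m, meta, c("salt", "control"), normalize = FALSE)
  expect_true(de$de_flag[de$gene == "up"])
  expect_equal(de$direction[de$gene == "up"], "up")
  expect_false(de$de_flag[de$gene == "flat"])
  expect_false(de$de_flag[de$gene == "weak"])
  # identical zero-variance groups: FC 1, p 1 by convention
  ident <- matrix(500, 1, 8, dimnames = list("same", meta$sample_id))
  d0 <- call_de(ident, meta, c("salt", "control"), normalize = FALSE)
  expect_equal(d0$fold_change, 1)
  expect_equal(d0$p_value, 1)
  expect_false(d0$de_flag)
})

test_that("normalization cancels per-sample scale factors", {
  meta <- meta_for(c("control", "salt"))
  withr::with_seed(42, {
    base <- rnorm(50, 10, 1)            # gene-level spread
    m <- 2^(matrix(base, 50, 6) + matrix(rnorm(50 * 6, 0, 0.15), 50, 6))
    dimnames(m) <- list(sprintf("g%02d", 1:50), meta$sample_id)
  })
  skewed <- sweep(m, 2, c(1, 1, 1, 7, 7, 7), `*`)
  de <- call_de(skewed, meta, c("salt", "control"))
  expect_lt(max(abs(log2(de$fold_change))), 1)
  expect_equal(sum(de$de_flag), 0)
})

test_that("the DE set is monotone in both thresholds", {
  sim <- generate_expression(expression_spec(
    n_genes = 60,
    planted_responses = data.frame(gene = 1:6, condition = "salt",
                                   log2fc = seq(0.4, 2.4, 0.4)),
    seed = 43))
  base <- call_de(sim$matrix, sim$metadata, c("salt", "control"))
  for (fc in c(1.2, 1.5, 2, 3)) {
    for (p in c(0.1, 0.05, 0.01)) {
      cfg <- screen_config(fc_threshold = fc, p_threshold = p)
      de <- call_de(sim$matrix, sim$metadata, c("salt", "control"),
                    config = cfg)
      stricter <- call_de(sim$matrix, sim$metadata, c("salt", "control"),
                          config = screen_config(fc_threshold = fc + 0.5,
                                                 p_threshold = p / 2))
      expect_true(all(stricter$gene[stricter$de_flag] %in%
                      de$gene[de$de_flag]))
    }
  }
  expect_true(TRUE)  # loop assertions above
})

test_that("specificity classification follows the salt-panel logic", {
  panel <- expand.grid(
    gene = c("saltonly", "salt_plus1", "multi", "quiet", "othersonly"),
    stress = c("salt", "osmotic", "drought", "cold", "oxidative"),
    stringsAsFactors = FALSE)
  panel$de_flag <- with(panel, (gene == "saltonly" & stress == "salt") |
    (gene == "salt_plus1" & stress %in% c("salt", "cold")) |
    (gene == "multi" & stress %in% c("salt", "osmotic", "drought")) |
    (gene == "othersonly" & stress == "cold"))
  cls <- classify_specificity(panel)
  got <- setNames(cls$specificity_class, cls$gene)
  expect_equal(got[["saltonly"]], "salt_specific")
  expect_equal(got[["salt_plus1"]], "salt_specific")  # limit = 1 other
  expect_equal(got[["multi"]], "multi_stress")
  expect_equal(got[["quiet"]], "non_responsive")
  expect_equal(got[["othersonly"]], "non_responsive")
  # stricter limit: salt + 1 other becomes multi_stress
  cls0 <- classify_specificity(panel,
                               screen_config(specificity_stress_limit = 0))
  got0 <- setNames(cls0$specificity_class, cls0$gene)
  expect_equal(got0[["salt_plus1"]], "multi_stress")
  # row order invariance
  shuf <- panel[rev(seq_len(nrow(panel))), ]
  expect_equal(classify_specificity(shuf), cls)
  # missing salt condition is rejected
  expect_error(classify_specificity(panel[panel$stress != "salt", ]),
               "salt")
})

test_that("relative transcript transform is scaled 2^-dCt", {
  expect_equal(relative_transcript(20, 20), 1000)
  expect_equal(relative_transcript(21, 20), 500)
  expect_equal(relative_transcript(18, 20), 4000)
  expect_equal(relative_transcript(c(20, 21), 20), c(1000, 500))
  expect_error(relative_transcript(NA, 20), "finite")
})
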