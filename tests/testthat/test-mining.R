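# Motif finding, local alignment, identity and ranking.

test_that("C-terminal motif finding reproduces the published junctions", {
  # wild-type CNYD junction: hit, cleavage competent
  wt <- find_cterm_motif(paste0(strrep("M", 30), "CNYDPAGNYIGARPY"))
  expect_equal(wt$peptide, "PAGNYIGARPY")
  expect_true(wt$cleavage_competent)
  expect_equal(wt$end - wt$start, 10)
  expect_equal(wt$cleavage_site, wt$start - 1)
  # mutated CNAD junction: still a hit, flagged incompetent
  mut <- find_cterm_motif(paste0(strrep("M", 30), "CNADPAGNYIGARPY"))
  expect_equal(mut$peptide, "PAGNYIGARPY")
  expect_false(mut$cleavage_competent)
  # terminal Y -> A breaks the peptide pattern: no candidate
  expect_null(find_cterm_motif(paste0(strrep("M", 30), "CNYDPAGNYIGARPA")))
  # short protein: no candidate, not an error
  expect_null(find_cterm_motif("CNYDPAGNYIGARP"))
})

test_that("terminal slack controls how far from the end the motif may sit", {
  seq <- paste0(strrep("M", 30), "CNYDPAGNYIGARPY", "KLM")
  expect_null(find_cterm_motif(seq))
  hit <- find_cterm_motif(seq, motif_spec(terminal_slack = 3))
  expect_equal(hit$peptide, "PAGNYIGARPY")
  expect_equal(hit$end, nchar(seq) - 3)
})

test_that("mutating the critical Y flips competence and nothing else", {
  withr::with_seed(11, {
    sim <- generate_proteome(proteome_spec(6, 0, seed = 12))
    for (id in names(sim$sequences)) {
      seq <- sim$sequences[[id]]
      a <- find_cterm_motif(precursor_protein(id, seq))
      expect_true(a$cleavage_competent)
      pos <- a$cleavage_site - 1  # critical position 3 of CNYx
      mut <- paste0(substr(seq, 1, pos - 1), "A",
                    substr(seq, pos + 1, nchar(seq)))
      b <- find_cterm_motif(precursor_protein(id, mut))
      expect_false(b$cleavage_competent)
      b$cleavage_competent <- TRUE
      b$cleavage_signal <- a$cleavage_signal
      expect_identical(a, b)
    }
  })
})

test_that("found peptides always satisfy the peptide pattern", {
  withr::with_seed(13, {
    sim <- generate_proteome(proteome_spec(10, 40,
      decoy_modes = c("no_motif", "mutated_cleavage_Y"), seed = 14))
    for (id in names(sim$sequences)) {
      cand <- find_cterm_motif(precursor_protein(id, sim$sequences[[id]]))
      if (!is.null(cand))
        expect_match(cand$peptide, "^P.GN.....PY$")
    }
  })
})

test_that("local alignment score matches trivial closed forms", {
  bl <- blosum62
  self <- sum(diag(bl[strsplit("PAGNYIGARPY", "")[[1]],
                      strsplit("PAGNYIGARPY", "")[[1]]]))
  expect_equal(local_align_score("PAGNYIGARPY", "PAGNYIGARPY"), self)
  # single-residue case: the matrix entry if positive, else 0
  expect_equal(local_align_score("A", "W"), max(bl["A", "W"], 0))
  expect_equal(local_align_score("W", "W"), max(bl["W", "W"], 0))
  expect_error(local_align_score("ABJZ", "W"), "position 2")
})

test_that("local alignment equals the naive DP oracle on random pairs", {
  withr::with_seed(15, {
    for (k in 1:25) {
      a <- random_peptide(5, 50)
      b <- random_peptide(5, 50)
      expect_equal(local_align_score(a, b),
                   naive_sw_score(a, b, blosum62),
                   info = paste(a, b))
      expect_equal(local_align_score(a, b), local_align_score(b, a))
    }
  })
})

test_that("percent identity counts positions", {
  expect_equal(percent_identity("PAGNYIGARPY", "PAGNYIGARPY"), 100)
  # the printed internal standard differs at three positions (3, 4, 10)
  expect_equal(percent_identity("PAGNYIGARPY", "PAAAYIGARAY"),
               100 * 8 / 11, tolerance = 1e-9)
  # hand count for the AtCAPE2 / AtCAPE4 pair: mismatches at 5 and 9
  expect_equal(percent_identity("PPGNWVGEWPY", "PPGNYVGEKPY"),
               100 * 9 / 11, tolerance = 1e-9)
  expect_error(percent_identity("PAGNY", "PA"), "equal length")
})

test_that("ranking is by descending identity with id tie-break", {
  cands <- data.frame(
    precursor_id = c("B", "A", "C"),
    peptide = c("PAGNYIGARPY", "PAAAYIGARAY", "PAGNYIGARPY"),
    stringsAsFactors = FALSE)
  r <- rank_candidates(cands, "PAGNYIGARPY")
  expect_equal(r$precursor_id, c("B", "C", "A"))
  expect_equal(r$identity_to_reference[1], 100)
  # brute-force identity table over the nine published peptides
  cat9 <- atcape_catalog()
  ref <- "PAGNYIGARPY"
  brute <- vapply(cat9$peptide, function(p)
    100 * sum(strsplit(p, "")[[1]] == strsplit(ref, "")[[1]]) / 11,
    numeric(1))
  ranked <- rank_candidates(
    data.frame(precursor_id = cat9$gene, peptide = cat9$peptide),
    ref)
  ord <- order(-brute, cat9$gene)
  expect_equal(ranked$precursor_id, cat9$gene[ord])
  expect_equal(ranked$identity_to_reference, as.numeric(brute[ord]))
})

test_that("mine_proteome applies motif, prefilter and ranking", {
  withr::with_seed(16, {
    seqs <- table1_fixture(n_decoys = 60, seed = 17)
    cands <- mine_proteome(seqs, reference_peptide = "PAGNYIGARPY")
    expect_equal(nrow(cands), 9)
    expect_equal(cands$precursor_id[1], "AT4G33730")
    expect_true(all(cands$cleavage_competent))
    # pattern position 1 changed to W: nothing matches
    none <- mine_proteome(seqs, motif_spec(peptide_pattern = "WxGNxxxxxPY"))
    expect_equal(nrow(none), 0)
    # homology prefilter: a strict threshold keeps only the query itself
    sub <- seqs[1:5]
    q <- unname(sub[1])
    self_score <- local_align_score(q, q)
    pre <- mine_proteome(sub, query = q, score_threshold = self_score)
    expect_equal(pre$precursor_id, names(sub)[1])
    expect_equal(pre$homology_score, self_score)
  })
  expect_warning(empty <- mine_proteome(character(0)), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("mining a FASTA file round-trips through Biostrings", {
  withr::with_seed(18, {
    dir <- withr::local_tempdir()
    sim <- generate_proteome(proteome_spec(3, 10, seed = 19), out_dir = dir)
    expect_true(file.exists(sim$fasta_path))
    cands <- mine_proteome(sim$fasta_path)
    expect_setequal(cands$precursor_id,
                    sim$truth$id[sim$truth$expected_hit])
  })
})
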