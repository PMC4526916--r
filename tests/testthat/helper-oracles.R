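# Independent oracles used across the suite.

# Naive full-matrix Smith-Waterman with affine gaps (gap of length L costs
# gap_open + L * gap_extend). Deliberately written as the textbook
# three-matrix recurrence in plain R, independent of the package's
# compiled implementation.
naive_sw_score <- function(a, b, S, gap_open = 10, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(min_len = 5, max_len = 30)
  paste(sample(AA20, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")

# Build a deterministic proteome embedding each of the nine published CAPE
# peptides as a C-terminus behind a CNYD block, plus motif-free decoys.
table1_fixture <- function(n_decoys = 60, seed = 101) {
  cat9 <- atcape_catalog()
  sim <- generate_proteome(proteome_spec(0, n_decoys,
                                         decoy_modes = "no_motif",
                                         seed = seed))
  withr::with_seed(seed + 1, {
    trues <- vapply(seq_len(nrow(cat9)), function(i) {
      body <- paste(sample(AA20, 120, replace = TRUE), collapse = "")
      paste0(body, "CNYD", cat9$peptide[i])
    }, "")
  })
  names(trues) <- cat9$gene
  c(trues, sim$sequences)
}

# Analytic Gaussian trace on a regular grid.
gaussian_trace <- function(amplitude, sigma, center = 300, half = NULL,
                           dt = 1) {
  if (is.null(half)) half <- 6 * sigma
  rt <- seq(center - half, center + half, by = dt)
  data.frame(rt_sec = rt,
             intensity = amplitude * exp(-(rt - center)^2 / (2 * sigma^2)))
}
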