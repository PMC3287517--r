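# Shared test fixtures, all built in code.

# The published four-species sample sheet (key TCAG, 6-bp MIDs, V1-V2
# universal primers).
weevil_sheet <- function() {
  validate_sample_sheet(data.frame(
    sample = c("O_salicicola", "O_rugosostriatus", "O_sulcatus",
               "O_armadillo"),
    key = "TCAG",
    mid_fwd = c("ATCGCG", "ATAGCC", "CCATAG", "CTTGAG"),
    mid_rev = c("CGCGAT", "GGCTAT", "CTATGG", "CTCAAG"),
    primer_fwd = "MGAGTTTGATCCTGGCTCAG",
    primer_rev = "GCTGCCTCCCGTAGGAGT",
    stringsAsFactors = FALSE))
}

# A sheet with a non-degenerate primer, for byte-exact consensus oracles.
plain_sheet <- function(n = 2L) {
  validate_sample_sheet(data.frame(
    sample = paste0("s", seq_len(n)),
    key = "TCAG",
    mid_fwd = c("ATCGCG", "CCATAG", "ATAGCC", "CTTGAG")[seq_len(n)],
    mid_rev = c("CGCGAT", "CTATGG", "GGCTAT", "CTCAAG")[seq_len(n)],
    primer_fwd = "AGAGTTTGATCCTGGCTCAG",
    primer_rev = "GCTGCCTCCCGTAGGAGT",
    stringsAsFactors = FALSE))
}

rand_dna <- function(n) amplitag:::random_dna(n)

# Substitute exactly k distinct interior positions.
substitute_k <- function(seq, k, interior = TRUE) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- if (interior) 2:(length(ch) - 1L) else seq_along(ch)
  pos <- sample(cand, k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Simple read data.frame constructor.
make_reads <- function(bases, ids = sprintf("r%03d", seq_along(bases)),
                       qual = 35L) {
  amplitag:::read_frame(ids, bases,
                        lapply(nchar(bases), function(n) rep(qual, n)))
}

# Independent ends-free affine-gap alignment oracle (naive full-matrix DP,
# max score over last row/column; used to cross-check the package aligner).
oracle_overlap_score <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ac); m <- length(bc); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (ac[i] == bc[j]) 1 else -1
      prev <- if (i == 1 || j == 1) 0 else max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- prev + s
      if (i > 1) X[i + 1, j + 1] <- max(M[i, j + 1] - 2.5, X[i, j + 1] - 0.5)
      if (j > 1) Y[i + 1, j + 1] <- max(M[i + 1, j] - 2.5, Y[i + 1, j] - 0.5)
    }
  }
  max(M[n + 1, 2:(m + 1)], M[2:(n + 1), m + 1])
}

# Reference counts fixture (per-OTU read counts of the four-species 454
# survey), shipped under extdata.
counts_fixture <- function() {
  read.delim(system.file("extdata", "otiorhynchus_otu_counts.tsv",
                         package = "amplitag"), stringsAsFactors = FALSE)
}
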