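# OTU construction and the abundance table: identity, clustering, consensus,
# tag stripping and the printed-percentage worked examples.

test_that("pairwise_identity matches constructed cases and the DP oracle", {
  a <- rand_dna(100)
  expect_equal(pairwise_identity(a, a), 1.0)
  set.seed(41)
  b <- substitute_k(a, 5)
  expect_equal(pairwise_identity(a, b), 0.95)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  # alignment scores agree with an independent naive DP on random pairs
  for (i in 1:25) {
    x <- rand_dna(sample(5:40, 1))
    y <- if (i %% 2) rand_dna(sample(5:40, 1)) else substitute_k(x, 2)
    expect_equal(.overlap_align(x, y)$score, oracle_overlap_score(x, y),
                 info = paste(x, y))
  }
  expect_equal(.overlap_align("ACGT", "TGCA")$score,
               oracle_overlap_score("ACGT", "TGCA"))
})

test_that("identity is containment-aware", {
  cons <- rand_dna(400)
  read <- substr(cons, 30, 360)           # exact substring
  expect_equal(pairwise_identity(read, cons), 1.0)
  # unrelated sequences share at best a trivial overlap
  expect_lt(pairwise_identity(rand_dna(300), rand_dna(300)), 0.5)
})

test_that("greedy centroid clustering respects the identity threshold", {
  set.seed(43)
  base <- rand_dna(300)
  near <- substitute_k(base, 15)          # 95% identity
  contigs <- data.frame(bases = c(base, near), support = c(10L, 5L),
                        sample = "s", stringsAsFactors = FALSE)
  cl <- cluster_contigs(contigs, identity_threshold = 0.97)
  expect_equal(length(unique(cl$cluster)), 2L)
  cl <- cluster_contigs(contigs, identity_threshold = 0.90)
  expect_equal(length(unique(cl$cluster)), 1L)
  # byte-identical contigs always merge
  dup <- data.frame(bases = c(base, base), support = c(3L, 2L),
                    sample = "s", stringsAsFactors = FALSE)
  expect_equal(length(unique(cluster_contigs(dup, 0.97)$cluster)), 1L)
  expect_equal(nrow(cluster_contigs(contigs[0, ], 0.97)), 0L)
})

test_that("cluster consensus takes the support-weighted majority", {
  base <- rand_dna(120)
  v1 <- base
  substr(v1, 50, 50) <- "A"
  v2 <- base
  substr(v2, 50, 50) <- "C"
  # 2:1 support on A wins the split column
  cc <- data.frame(bases = c(v1, v1, v2), support = c(1L, 1L, 1L),
                   stringsAsFactors = FALSE)
  cons <- consensus_of_cluster(cc)
  expect_equal(substr(cons, 50, 50), "A")
  # equal support gives the IUPAC tie code (A/C -> M)
  cc <- data.frame(bases = c(v1, v2), support = c(1L, 1L),
                   stringsAsFactors = FALSE)
  expect_equal(substr(consensus_of_cluster(cc), 50, 50), "M")
  # singleton cluster returns its centroid unchanged
  expect_equal(consensus_of_cluster(cc[1, , drop = FALSE]), v1)
})

test_that("strip_tag_primer removes identifier and primer symmetrically", {
  sheet <- weevil_sheet()
  tag <- as.list(sheet[sheet$sample == "O_sulcatus", ])
  insert <- rand_dna(450)
  set.seed(44)
  cons <- full_amplicon(insert, tag)      # M realised to a concrete base
  out <- strip_tag_primer(cons, tag)
  expect_equal(as.character(out), insert)
  expect_true(attr(out, "stripped")$five_prime)
  expect_true(attr(out, "stripped")$three_prime)
  # 480-base consensus with only the 30-base 5' prefix -> 450-base insert
  cons5 <- paste0("TCAG", tag$mid_fwd, "CGAGTTTGATCCTGGCTCAG",
                  substr(insert, 1, 450))
  out <- strip_tag_primer(cons5, tag)
  expect_equal(nchar(out), nchar(cons5) - 30L)
  # already stripped: unchanged plus warning
  expect_warning(out2 <- strip_tag_primer(insert, tag), "not found")
  expect_equal(as.character(out2), insert)
  # strip/length law over random inserts
  for (i in 1:10) {
    ins <- rand_dna(sample(200:500, 1))
    cons <- paste0("TCAG", tag$mid_fwd, "AGAGTTTGATCCTGGCTCAG", ins)
    expect_equal(nchar(strip_tag_primer(cons, tag)),
                 nchar(cons) - 10L - nchar(tag$primer_fwd))
  }
})

test_that("build_table reproduces the published percentage arithmetic", {
  counts <- counts_fixture()
  tab <- build_table(counts)
  pick <- function(otu) tab$pct_of_total[tab$otu_id == otu]
  expect_identical(pick("JN563736"), 90.83)   # 5516 / 6073
  expect_identical(pick("JN563751"), 90.87)   # 7800 / 8584
  expect_identical(pick("JN563760"), 99.16)   # 6358 / 6412
  expect_identical(pick("JN563763"), 93.49)   # 5900 / 6311
  # per-sample percentages sum to 100 within rounding tolerance
  sums <- tapply(tab$pct_of_total, tab$sample, sum)
  expect_true(all(abs(sums - 100) <= 0.05))
  # read counts sum to the sample totals
  expect_equal(as.vector(tapply(tab$read_count, tab$sample, sum)[
    c("O_salicicola", "O_rugosostriatus", "O_sulcatus", "O_armadillo")]),
    c(6073, 8584, 6412, 6311))
  # single OTU -> 100.00
  one <- build_table(data.frame(sample = "s", otu_id = "x",
                                read_count = 7L))
  expect_equal(one$pct_of_total, 100)
  expect_error(build_table(counts[0, ]), "no OTUs")
})

test_that("dominant_fraction aggregates subsets across samples", {
  counts <- counts_fixture()
  tab <- build_table(counts)
  expect_equal(dominant_fraction(tab, unique(tab$otu_id)), 100)
  expect_error(dominant_fraction(tab, "NOT_AN_OTU"), "not in table")
  subset <- counts$otu_id[counts$match_group %in%
                            c("rickettsia", "blochmannia_like")]
  frac <- dominant_fraction(tab, subset)
  expect_equal(frac, 100 * 25942 / 27380, tolerance = 1e-12)
  expect_gt(frac, 90)
})

test_that("re-mapping counts reads against their best OTU", {
  set.seed(45)
  o1 <- rand_dna(450)
  o2 <- rand_dna(450)
  otus <- data.frame(otu_id = c("a", "b"), bases = c(o1, o2), sample = "s",
                     read_count = c(0L, 0L), stringsAsFactors = FALSE)
  reads <- make_reads(c(substr(o1, 10, 420), substr(o2, 1, 400),
                        substitute_k(substr(o1, 1, 430), 8),
                        rand_dna(430)))
  counts <- map_reads_to_otus(reads, otus, min_identity = 0.90)
  expect_equal(as.integer(counts), c(2L, 1L))
  expect_equal(attr(counts, "unmapped"), 1L)
})
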