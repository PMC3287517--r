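# Window-match seed-extension assembly: seeds, window matching, greedy
# extension, budget and the zero-noise template oracle.

zero_noise_pool <- function(sheet, templates, abundances, n, seed) {
  prof <- community_profile(sheet$sample[1], abundances, n)
  sim <- simulate_community(prof, templates, sheet,
                            error_model(sub_rate = 0, hp_indel_base = 0),
                            rng_seed = seed)
  dmx <- demultiplex(sim$reads, sheet)
  list(pool = dmx$pools[[sheet$sample[1]]], truth = sim$truth)
}

test_that("detect_seeds filters by anchor and length, longest first", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  prefix <- paste0("TCAG", tag$mid_fwd, tag$primer_fwd)
  set.seed(2)
  lens <- c(250, 300, 220, 280, 250)
  bases <- vapply(lens, function(n) paste0(prefix, rand_dna(n)), "")
  pool <- make_reads(c(bases, rand_dna(260), paste0(prefix, rand_dna(100))))
  seeds <- detect_seeds(pool, tag, wimseex_params())
  expect_equal(length(seeds), 5L)             # unanchored + short excluded
  expect_equal(nchar(pool$bases[seeds]),
               sort(nchar(bases), decreasing = TRUE))
  # equal lengths (the two 250 bp reads) tie-break by id ascending
  expect_equal(pool$id[seeds[3:4]], sort(pool$id[c(1, 5)]))
  # a pool whose longest anchored read is below min_seed_size gives nothing
  short <- make_reads(paste0(prefix, rand_dna(150)))
  expect_equal(detect_seeds(short, tag, wimseex_params()), integer(0))
  # the default anchor is key + 20 primer bases (24 bp + MID in between)
  expect_equal(nchar(amplitag:::anchor_pattern(tag, wimseex_params())),
               4L + 6L + 20L)
})

test_that("window_match finds the leftmost qualifying offset", {
  p <- wimseex_params()
  win <- rand_dna(60)
  read <- paste0(rand_dna(25), win, rand_dna(40))
  expect_equal(window_match(win, read, p), 25L)
  # a 59-base suffix-prefix overlap is not a 60-base window match
  contig <- paste0(rand_dna(300), win)
  read59 <- paste0(substr(win, 2, 60), rand_dna(80))
  expect_true(is.na(window_match(win, read59, p)))
  # 1 mismatch allowed at 0.98 identity (59/60 >= 0.98)
  win_mm <- win
  substr(win_mm, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                    substr(win, 30, 30))[1]
  read_mm <- paste0(win_mm, rand_dna(40))
  expect_true(is.na(window_match(win, read_mm, p)))
  p98 <- wimseex_params(min_window_identity = 0.98)
  expect_equal(window_match(win, read_mm, p98), 0L)
  # matches that do not extend past the contig end are rejected
  expect_true(is.na(window_match(win, win, p)))
})

test_that("extend merges overlapping reads by majority consensus", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  p <- wimseex_params(min_seed_size = 100)
  left <- paste0("TCAG", tag$mid_fwd, tag$primer_fwd, rand_dna(170))
  right <- paste0(substr(left, nchar(left) - 59, nchar(left)), rand_dna(80))
  pool <- make_reads(c(left, right))
  res <- extend_seed(1L, pool, p)
  expect_equal(res$bases, paste0(left, substr(right, 61, 140)))
  expect_equal(res$support, 2L)
  # seed with no matching reads stays a singleton
  lone <- make_reads(c(left, rand_dna(200)))
  res <- extend_seed(1L, lone, p)
  expect_equal(res$bases, left)
  expect_equal(res$support, 1L)
})

test_that("error-free tiled reads reassemble the full template amplicon", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  template <- rand_dna(450)
  amp <- full_amplicon(template, tag)
  starts <- seq(1, nchar(amp) - 249, by = 10)[1:20]
  tiles <- substring(amp, starts, pmin(starts + 249, nchar(amp)))
  pool <- make_reads(tiles)
  res <- extend_seed(1L, pool, wimseex_params(min_seed_size = 200))
  expect_equal(res$bases, substr(amp, 1, max(starts) + 249))
  expect_equal(res$support, 20L)
})

test_that("zero-noise assembly equals the template amplicons exactly", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  set.seed(31)
  for (rep in 1:4) {
    nt <- sample(2:4, 1)
    templates <- setNames(replicate(nt, rand_dna(450)), paste0("T", 1:nt))
    ab <- runif(nt, 0.2, 1)
    zp <- zero_noise_pool(sheet, templates, setNames(ab / sum(ab),
                                                     names(templates)),
                          sample(300:700, 1), seed = rep)
    ctg <- assemble_tag(zp$pool, tag, wimseex_params())
    amps <- vapply(names(templates), function(t) {
      full_amplicon(templates[[t]], tag)
    }, character(1))
    expect_setequal(ctg$bases, unname(amps))
    truth_counts <- table(zp$truth$template_id)
    for (t in names(templates)) {
      expect_equal(ctg$support[ctg$bases == amps[[t]]],
                   unname(truth_counts[[t]]))
    }
  }
})

test_that("reads are consumed by at most one contig", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  set.seed(5)
  templates <- c(T1 = rand_dna(450), T2 = rand_dna(450))
  zp <- zero_noise_pool(sheet, templates, c(T1 = 0.9, T2 = 0.1), 500, 17)
  ctg <- assemble_tag(zp$pool, tag, wimseex_params())
  members <- unlist(ctg$members)
  expect_equal(anyDuplicated(members), 0L)
  expect_equal(sum(ctg$support), nrow(zp$pool))
  # support ratio approximately 9:1
  expect_equal(ctg$support[1] / sum(ctg$support), 0.9, tolerance = 0.05)
})

test_that("the assembly budget stops seeding once exhausted", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  set.seed(6)
  templates <- c(T1 = rand_dna(450), T2 = rand_dna(450))
  zp <- zero_noise_pool(sheet, templates, c(T1 = 0.5, T2 = 0.5), 400, 19)
  # budget of one read's length: exactly one seed is processed
  p_small <- wimseex_params(max_bases = 501, min_support = 1)
  ctg <- assemble_tag(zp$pool, tag, p_small)
  expect_equal(nrow(ctg), 1L)
  # both templates assemble under the default budget
  ctg <- assemble_tag(zp$pool, tag, wimseex_params())
  expect_equal(nrow(ctg), 2L)
  # empty pool gives an empty contig set
  expect_equal(nrow(assemble_tag(zp$pool[0, ], tag, wimseex_params())), 0L)
})

test_that("assembly is deterministic for a fixed pool order", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  set.seed(7)
  templates <- c(T1 = rand_dna(450), T2 = rand_dna(450))
  prof <- community_profile("s1", c(T1 = 0.7, T2 = 0.3), 300)
  sim <- simulate_community(prof, templates, sheet, error_model(),
                            rng_seed = 23)
  pool <- demultiplex(sim$reads, sheet)$pools$s1
  a <- assemble_tag(pool, tag, wimseex_params())
  b <- assemble_tag(pool, tag, wimseex_params())
  expect_identical(a, b)
})

test_that("noisy contigs stay near-identical to their template", {
  sheet <- plain_sheet(1)
  tag <- as.list(sheet[1, ])
  set.seed(8)
  templates <- c(T1 = rand_dna(450))
  prof <- community_profile("s1", c(T1 = 1), 600)
  sim <- simulate_community(prof, templates, sheet,
                            error_model(sub_rate = 0.004), rng_seed = 29)
  pool <- demultiplex(sim$reads, sheet)$pools$s1
  ctg <- assemble_tag(pool, tag,
                      wimseex_params(min_window_identity = 0.95))
  amp <- full_amplicon(templates[["T1"]], tag)
  expect_gte(pairwise_identity(ctg$bases[1], amp), 0.99)
})

test_that("parameter invariants are enforced", {
  expect_error(wimseex_params(min_seed_size = 50, window_size = 60))
  expect_error(wimseex_params(window_size = 4))
  expect_error(wimseex_params(max_bases = 100))
  expect_error(wimseex_params(min_window_identity = 0))
})
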