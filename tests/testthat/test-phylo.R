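# Nearest-reference search, distances, neighbour joining, Fitch parsimony
# and exhaustive placement, cross-checked against ape and phangorn.

random_alignment <- function(tips, len = 40) {
  setNames(replicate(length(tips), rand_dna(len)), tips)
}

test_that("best_hit returns the closest reference with tie-breaking", {
  set.seed(51)
  refs <- data.frame(accession = c("ACC2", "ACC1", "ACC3"),
                     label = c("two", "one", "three"),
                     bases = c(rand_dna(450), rand_dna(450), rand_dna(450)),
                     stringsAsFactors = FALSE)
  hit <- best_hit(refs$bases[3], refs)
  expect_equal(hit$accession, "ACC3")
  expect_equal(hit$identity, 1.0)
  # 5 vs 20 mismatches: closer reference wins, identity = 445/450
  q <- substitute_k(refs$bases[2], 5)
  refs2 <- refs
  refs2$bases[1] <- substitute_k(refs$bases[2], 20)
  hit <- best_hit(q, refs2)
  expect_equal(hit$accession, "ACC1")
  expect_equal(hit$identity, 445 / 450, tolerance = 0.005)
  # byte-identical references: lexicographically smaller accession
  refs3 <- data.frame(accession = c("B", "A"), label = c("b", "a"),
                      bases = rep(refs$bases[1], 2), stringsAsFactors = FALSE)
  expect_equal(best_hit(refs$bases[1], refs3)$accession, "A")
  expect_error(best_hit("ACGT", refs[0, ]), "empty")
})

test_that("distance_matrix computes pairwise-deletion p and JC69", {
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAA")
  d <- distance_matrix(aln, model = "p")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.1)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # 2 diffs over 100 ungapped columns
  x <- rand_dna(100)
  set.seed(52)
  y <- substitute_k(x, 2)
  aln <- c(a = x, b = y, c = x)
  expect_equal(distance_matrix(aln, "p")["a", "b"], 0.02)
  # JC69 correction: -(3/4) log(1 - 4 * 0.02 / 3)
  expect_equal(distance_matrix(aln, "jc69")["a", "b"],
               -0.75 * log(1 - 0.08 / 3), tolerance = 1e-12)
  # gap/ambiguous columns are dropped per pair
  aln <- c(a = "AC-TACGTAC", b = "ACGTACGTAC", c = "ACNTACGTAC")
  expect_equal(distance_matrix(aln, "p")["a", "b"], 0)
  # saturated pairs are flagged under jc69
  aln <- c(a = "AAAAAAAAAA", b = "CCCCCCCCCC", c = "AAAAAAAAAA")
  expect_warning(d <- distance_matrix(aln, "jc69"), "undefined")
  expect_true(is.na(d["a", "b"]))
  # agreement with ape on diverged copies of one sequence (below JC69
  # saturation)
  skip_if_not_installed("ape")
  set.seed(53)
  base <- rand_dna(60)
  aln <- setNames(vapply(c(0, 3, 6, 9, 12), function(k) {
    if (k == 0) base else substitute_k(base, k)
  }, character(1)), letters[1:5])
  d1 <- distance_matrix(aln, "jc69")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln), "")))
  d2 <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                pairwise.deletion = TRUE))
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-9)
})

test_that("neighbour joining has the 3-taxon closed form", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("NJ inverts additive matrices exactly", {
  skip_if_not_installed("ape")
  set.seed(54)
  for (i in 1:20) {
    nt <- sample(4:12, 1)
    tr <- ape::rtree(nt, br = function(n) runif(n, 0.05, 1))
    dm <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
                      - dm)), 1e-9)
  }
})

test_that("NJ agrees with ape::nj on noisy matrices", {
  skip_if_not_installed("ape")
  set.seed(55)
  for (i in 1:5) {
    nt <- sample(5:9, 1)
    tr <- ape::rtree(nt, br = function(n) runif(n, 0.1, 1))
    dm <- ape::cophenetic.phylo(tr)
    noise <- matrix(runif(nt * nt, 0, 0.01), nt)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    dm <- dm + noise
    expect_equal(ape::dist.topo(neighbor_joining(dm), ape::nj(as.dist(dm))),
                 0, ignore_attr = TRUE)
  }
})

test_that("fitch_score counts state changes per column", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  aln <- c(a = "A", b = "A", c = "C", d = "C")
  expect_equal(fitch_score(tr, aln), 1L)
  expect_equal(fitch_score(tr, c(a = "AAA", b = "AAA", c = "AAA",
                                 d = "AAA")), 0L)
  # gaps and N are wildcards and never force a change
  expect_equal(fitch_score(tr, c(a = "A", b = "-", c = "N", d = "A")), 0L)
  expect_error(fitch_score(tr, c(a = "A", b = "A", c = "C")), "leaf")
})

test_that("fitch_score equals exhaustive enumeration and phangorn", {
  # brute force over all internal-state assignments on a 5-leaf tree
  brute_fitch <- function(tree, aln) {
    tr <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    ncols <- nchar(aln[[1]])
    total <- 0L
    states <- c("A", "C", "G", "T")
    sets <- amplitag:::IUPAC_SETS
    for (col in seq_len(ncols)) {
      leaf_sets <- lapply(tr$tip.label, function(l) {
        ch <- substr(aln[[l]], col, col)
        if (ch %in% names(sets)) sets[[ch]] else states
      })
      names(leaf_sets) <- tr$tip.label
      internal <- (length(tr$tip.label) + 1):(length(tr$tip.label) + tr$Nnode)
      grid <- do.call(expand.grid,
                      c(rep(list(states), length(internal)),
                        stringsAsFactors = FALSE))
      best <- Inf
      for (g in seq_len(nrow(grid))) {
        assign_state <- function(node) {
          if (node <= length(tr$tip.label)) NULL
          else grid[g, node - length(tr$tip.label)]
        }
        cost <- 0L
        for (e in seq_len(nrow(tr$edge))) {
          up <- assign_state(tr$edge[e, 1])
          dn <- tr$edge[e, 2]
          if (dn <= length(tr$tip.label)) {
            if (!(up %in% leaf_sets[[tr$tip.label[dn]]])) cost <- cost + 1L
          } else if (up != grid[g, dn - length(tr$tip.label)]) {
            cost <- cost + 1L
          }
        }
        best <- min(best, cost)
      }
      total <- total + best
    }
    total
  }
  set.seed(56)
  tr <- ape::unroot(ape::rtree(5))
  aln <- random_alignment(tr$tip.label, 10)
  expect_equal(fitch_score(tr, aln), brute_fitch(tr, aln))
  skip_if_not_installed("phangorn")
  for (i in 1:10) {
    nt <- sample(4:10, 1)
    tr <- ape::unroot(ape::rtree(nt))
    aln <- random_alignment(tr$tip.label, 30)
    ph <- phangorn::phyDat(t(vapply(strsplit(aln, ""), identity,
                                    character(30))), type = "DNA")
    expect_equal(fitch_score(tr, aln),
                 as.integer(phangorn::fitch(tr, ph)))
  }
})

test_that("parsimony placement is exhaustive-minimal and deterministic", {
  set.seed(57)
  # query identical to a leaf lands on that leaf's pendant branch
  tr <- ape::unroot(ape::rtree(6))
  aln <- random_alignment(tr$tip.label, 80)
  pl <- parsimony_place(aln[["t4"]], tr, aln)
  expect_equal(pl$scores$child_label[pl$best_edge], "t4")
  # the returned branch minimises the full audit list
  expect_true(all(pl$scores$score[pl$best_edge] <= pl$scores$score))
  # 2-leaf tree has a single branch
  tr2 <- ape::read.tree(text = "(x:1,y:1);")
  aln2 <- c(x = "ACGTACGT", y = "ACCTACGT")
  pl2 <- parsimony_place("ACGTACGT", tr2, aln2)
  expect_equal(nrow(pl2$scores), nrow(tr2$edge))
  # agreement with phangorn scoring on every candidate branch
  skip_if_not_installed("phangorn")
  for (i in 1:5) {
    tr <- ape::unroot(ape::rtree(sample(6:10, 1)))
    aln <- random_alignment(tr$tip.label, 60)
    q <- substitute_k(aln[[sample(tr$tip.label, 1)]], 4)
    pl <- parsimony_place(q, tr, aln)
    full <- c(aln, QUERY = pl$aligned_query)
    ph <- phangorn::phyDat(t(vapply(strsplit(full, ""), identity,
                                    character(nchar(full[[1]])))),
                           type = "DNA")
    oracle <- vapply(seq_len(nrow(tr$edge)), function(e) {
      t2 <- amplitag:::attach_tip(stats::reorder(tr, "cladewise"), e, "QUERY")
      as.integer(phangorn::fitch(t2, ph))
    }, integer(1))
    expect_equal(pl$scores$score, oracle)
    expect_equal(pl$best_edge, which.min(oracle))
  }
})

test_that("newick I/O round-trips topology and branch lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a:1,b:2,(c:3,d:4):5);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("a", "b", "c", "d"))
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_equal(ape::dist.topo(tr, tr2), 0, ignore_attr = TRUE)
  expect_lt(max(abs(sort(tr$edge.length) - sort(tr2$edge.length))), 1e-6)
  writeLines("(a:1,b:2", f)
  expect_error(read_newick(f), "malformed|parse")
})
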