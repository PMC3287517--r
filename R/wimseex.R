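## Window Match Seed Extension (WiMSeEx) consensus assembly.
##
## Greedy per-tag assembly anchored on the key + primer prefix: the longest
## anchored read of at least `min_seed_size` bp seeds a contig, which grows
## 3'-ward one window-advance per round by the column-wise majority base over
## the overhangs of all reads whose sequence matches the contig's terminal
## window. Reads are consumed exclusively by the first contig they support;
## reads fully contained in a finished contig are consumed as supporting
## members as well, and a final majority-vote polish over a capped subsample
## of the members corrects residual errors carried in from the seed read.

#' WiMSeEx assembly parameters
#'
#' @param min_seed_size Minimum seed read length (bp).
#' @param window_size Terminal window length (bp).
#' @param anchor_len_primer Bases of the forward primer included in the seed
#'   anchor (after key and MID).
#' @param max_bases Assembly budget; each per-tag run stops once this much
#'   sequence data has been used (see `budget_mode`).
#' @param min_window_identity Minimum identity of a window match (1.0 =
#'   exact).
#' @param min_support Contigs supported by fewer reads are discarded.
#' @param anchor_mode `"key"`: seeds must match key + MID + primer prefix
#'   (the pool is per-tag, so the MID is known); `"mid"`: MID + primer only.
#' @param budget_mode `"consumed_reads"`: budget counts the summed length of
#'   consumed reads (default); `"contig_bases"`: counts assembled contig
#'   bases instead.
#' @param polish Apply the final majority-vote polish.
#' @param polish_cap Maximum number of member reads used for polishing
#'   (evenly subsampled; the majority vote saturates quickly).
#' @return An object of class `wimseex_params`.
#' @export
wimseex_params <- function(min_seed_size = 200L, window_size = 60L,
                           anchor_len_primer = 20L, max_bases = 500000L,
                           min_window_identity = 1.0, min_support = 2L,
                           anchor_mode = c("key", "mid"),
                           budget_mode = c("consumed_reads", "contig_bases"),
                           polish = TRUE, polish_cap = 300L) {
  anchor_mode <- match.arg(anchor_mode)
  budget_mode <- match.arg(budget_mode)
  stopifnot(min_seed_size >= window_size, window_size >= 8L,
            max_bases > min_seed_size,
            min_window_identity > 0, min_window_identity <= 1,
            min_support >= 1L, anchor_len_primer >= 0L, polish_cap >= 1L)
  structure(list(min_seed_size = as.integer(min_seed_size),
                 window_size = as.integer(window_size),
                 anchor_len_primer = as.integer(anchor_len_primer),
                 max_bases = as.integer(max_bases),
                 min_window_identity = min_window_identity,
                 min_support = as.integer(min_support),
                 anchor_mode = anchor_mode, budget_mode = budget_mode,
                 polish = polish, polish_cap = as.integer(polish_cap)),
            class = "wimseex_params")
}

## The seed anchor pattern for a tag (IUPAC; matched against read prefixes).
anchor_pattern <- function(tag, params) {
  primer_part <- substr(tag$primer_fwd, 1L,
                        min(params$anchor_len_primer, nchar(tag$primer_fwd)))
  if (params$anchor_mode == "key") {
    paste0(tag$key, tag$mid_fwd, primer_part)
  } else {
    paste0(tag$mid_fwd, primer_part)
  }
}

#' Detect seed reads in a per-tag pool
#'
#' Returns the indices of reads of length at least `min_seed_size` whose
#' prefix matches the seed anchor (key + MID + first `anchor_len_primer`
#' primer bases, IUPAC-aware), sorted by length descending then id ascending.
#'
#' @param pool Forward-frame read data.frame (one demultiplexed tag).
#' @param tag The pool's sample-sheet row.
#' @param params [wimseex_params()].
#' @return Integer vector of row indices into `pool` (may be empty).
#' @export
detect_seeds <- function(pool, tag, params = wimseex_params()) {
  if (nrow(pool) == 0L) return(integer(0))
  anc <- anchor_pattern(tag, params)
  len <- nchar(pool$bases)
  cand <- which(len >= params$min_seed_size & len >= nchar(anc))
  if (!length(cand)) return(integer(0))
  ok <- grepl(paste0("^", iupac_regex(anc)), pool$bases[cand])
  cand <- cand[ok]
  cand[order(-len[cand], pool$id[cand], method = "radix")]
}

#' Match a contig's terminal window against a read
#'
#' Finds the leftmost position in `read` where the window aligns with
#' identity at least `min_window_identity` such that the read extends past
#' the contig 3' end.
#'
#' @param contig_end The contig's terminal window (length `window_size`;
#'   may contain IUPAC codes from majority-vote ties).
#' @param read Read sequence (character scalar).
#' @param params [wimseex_params()].
#' @return 0-based offset of the window in the read, or `NA` for no match.
#' @export
window_match <- function(contig_end, read, params = wimseex_params()) {
  w <- params$window_size
  if (nchar(contig_end) != w) {
    stop("contig_end must have length window_size", call. = FALSE)
  }
  if (nchar(read) <= w) return(NA_integer_)
  mm <- max_window_mismatches(params)
  m <- Biostrings::matchPattern(contig_end,
                                Biostrings::DNAString(read),
                                max.mismatch = mm, with.indels = FALSE,
                                fixed = FALSE)
  st <- BiocGenerics::start(m)
  st <- st[st + w - 1L < nchar(read)]   # must extend past the window
  if (!length(st)) return(NA_integer_)
  min(st) - 1L
}

max_window_mismatches <- function(params) {
  floor((1 - params$min_window_identity) * params$window_size + 1e-9)
}

## Column-wise majority vote over equal-anchored strings.
## votes: character vector of strings; starts: 1-based column of each
## string's first base; columns `from..to` are voted on. N never outvotes a
## concrete base; ties between concrete bases give the IUPAC code.
vote_columns <- function(votes, starts, from, to) {
  out <- character(to - from + 1L)
  ends <- starts + nchar(votes) - 1L
  for (col in from:to) {
    cover <- which(starts <= col & ends >= col)
    ch <- substr(votes[cover], col - starts[cover] + 1L,
                 col - starts[cover] + 1L)
    ch <- ch[ch %in% c("A", "C", "G", "T")]
    if (!length(ch)) { out[col - from + 1L] <- "N"; next }
    tab <- table(ch)
    top <- names(tab)[tab == max(tab)]
    out[col - from + 1L] <- if (length(top) == 1L) top else
      iupac_code_for(top)
  }
  paste(out, collapse = "")
}

#' Extend a seed read into a contig
#'
#' The greedy WiMSeEx loop: repeatedly take the contig's terminal
#' `window_size` bases, collect every unconsumed pool read with a
#' [window_match()], and advance the contig by at most one window length
#' using the column-wise majority base over all matched reads' overhangs.
#' A read is consumed the first round it matches. After extension, reads
#' fully contained in the contig are consumed as members, and the contig is
#' polished by a majority vote over (a capped subsample of) its members.
#'
#' @param seed_idx Row index of the seed read in `pool`.
#' @param pool Forward-frame read data.frame.
#' @param params [wimseex_params()].
#' @param consumed Logical vector marking reads already used by other
#'   contigs.
#' @return A list with `bases`, `members` (row indices, seed first),
#'   `support` and the updated `consumed` vector.
#' @export
extend_seed <- function(seed_idx, pool, params = wimseex_params(),
                        consumed = rep(FALSE, nrow(pool))) {
  w <- params$window_size
  mm <- max_window_mismatches(params)
  contig <- pool$bases[seed_idx]
  consumed[seed_idx] <- TRUE
  members <- seed_idx
  offsets <- 1L
  lens <- nchar(pool$bases)
  pool_set <- NULL   # built lazily; only needed if anything can extend
  # pending overhangs: absolute start column + string
  pend_start <- integer(0)
  pend_seq <- character(0)

  repeat {
    L <- nchar(contig)
    win <- substr(contig, L - w + 1L, L)
    avail <- which(!consumed & lens > w)
    if (length(avail)) {
      if (is.null(pool_set)) pool_set <- Biostrings::DNAStringSet(pool$bases)
      m <- Biostrings::vmatchPattern(win, pool_set[avail],
                                     max.mismatch = mm, with.indels = FALSE,
                                     fixed = FALSE)
      st <- vapply(BiocGenerics::start(m), function(s) {
        if (length(s)) min(s) else NA_integer_
      }, integer(1))
      ok <- !is.na(st) & (st + w - 1L) < lens[avail]
      new_idx <- avail[ok]
      if (length(new_idx)) {
        st_new <- st[ok]
        consumed[new_idx] <- TRUE
        members <- c(members, new_idx)
        offsets <- c(offsets, L - w + 1L - (st_new - 1L))
        pend_start <- c(pend_start, rep.int(L + 1L, length(new_idx)))
        pend_seq <- c(pend_seq,
                      substring(pool$bases[new_idx], st_new + w, lens[new_idx]))
      }
    }
    if (!length(pend_seq)) break
    cover_end <- max(pend_start + nchar(pend_seq) - 1L)
    if (cover_end <= L) break
    ext_len <- min(w, cover_end - L)
    ext <- vote_columns(pend_seq, pend_start, L + 1L, L + ext_len)
    contig <- paste0(contig, ext)
    keep <- (pend_start + nchar(pend_seq) - 1L) > nchar(contig)
    pend_start <- pend_start[keep]
    pend_seq <- pend_seq[keep]
  }

  # Containment sweep: unconsumed reads whose prefix window matches inside
  # the contig and whose full length fits are supporting members too. The
  # contig still carries the seed read's own errors at this point (polish
  # comes last), so containment always tolerates at least one mismatch and
  # a few bases of homopolymer length slack.
  avail <- which(!consumed)
  if (length(avail)) {
    cl <- nchar(contig)
    contig_subject <- Biostrings::DNAString(contig)
    for (i in avail) {
      pw <- min(w, lens[i])
      pat <- substr(pool$bases[i], 1L, pw)
      mmi <- max(1L, floor((1 - params$min_window_identity) * pw + 1e-9))
      m <- Biostrings::matchPattern(pat, contig_subject, max.mismatch = mmi,
                                    with.indels = FALSE, fixed = FALSE)
      st <- BiocGenerics::start(m)
      if (!length(st)) next
      slack <- max(3L, ceiling((1 - params$min_window_identity) * lens[i]))
      st <- st[st - 1L + lens[i] <= cl + slack]
      if (!length(st)) next
      consumed[i] <- TRUE
      members <- c(members, i)
      offsets <- c(offsets, min(st))
    }
  }

  if (params$polish && length(members) > 1L) {
    contig <- polish_contig(contig, pool$bases[members], offsets,
                            cap = params$polish_cap)
  }
  list(bases = contig, members = members, support = length(members),
       consumed = consumed)
}

## Majority-vote polish of a contig against its member reads.
## Members aligning gaplessly at their recorded offset take the fast path;
## the rest are globally aligned to the contig so that member insertions and
## deletions relative to the contig vote too (a column whose majority is a
## gap is dropped; a junction where most covering members carry an insertion
## gains the majority inserted base).
polish_contig <- function(contig, member_bases, offsets, cap = 300L,
                          weights = NULL) {
  n <- length(member_bases)
  if (is.null(weights)) weights <- rep.int(1L, n)
  if (n > cap) {
    keep <- unique(round(seq(1L, n, length.out = cap)))
    member_bases <- member_bases[keep]
    offsets <- offsets[keep]
    weights <- weights[keep]
    n <- length(keep)
  }
  aligned <- lapply(seq_len(n), function(i) {
    project_onto_reference(member_bases[i], contig, offsets[i])
  })
  consensus_from_projections(contig, aligned, weights)
}

## Project one sequence onto reference coordinates.
## Returns list(cols = named character: per covered reference column a base
## or "-", first, last, insertions = list(pos -> string)). Fast path when
## the sequence matches the reference gaplessly at `offset`.
project_onto_reference <- function(seq, ref, offset = NA_integer_) {
  L <- nchar(seq)
  if (!is.na(offset) && offset >= 1L && offset + L - 1L <= nchar(ref) &&
      substr(ref, offset, offset + L - 1L) == seq) {
    return(list(first = offset, last = offset + L - 1L,
                cols = strsplit(seq, "", fixed = TRUE)[[1]],
                insertions = list()))
  }
  al <- .overlap_align(seq, ref)
  if (al$cols == 0L) {
    return(list(first = 1L, last = 1L, cols = "-", insertions = list()))
  }
  p <- strsplit(al$p_aln, "", fixed = TRUE)[[1]]
  s <- strsplit(al$s_aln, "", fixed = TRUE)[[1]]
  first <- al$s_start
  last <- al$s_end
  ref_pos <- first - 1L + cumsum(s != "-")
  cols <- rep(NA_character_, last - first + 1L)
  insertions <- list()
  for (k in seq_along(p)) {
    rp <- ref_pos[k]
    if (s[k] != "-") {
      cols[rp - first + 1L] <- p[k]
    } else if (p[k] != "-" && rp >= first && rp < last) {
      key <- as.character(rp)   # insertion after reference column rp
      insertions[[key]] <- paste0(if (is.null(insertions[[key]])) "" else
        insertions[[key]], p[k])
    }
  }
  cols[is.na(cols)] <- "-"
  list(first = first, last = last, cols = cols, insertions = insertions)
}

## Weighted column-wise consensus over projections onto a reference.
## Per column the top-weight symbol wins; base-vs-base ties give the IUPAC
## code; a strict gap majority drops the column; a strict insertion majority
## (over members spanning the junction) inserts the majority string.
consensus_from_projections <- function(ref, projections, weights) {
  L <- nchar(ref)
  nsym <- 6L  # A C G T N -
  sym <- c("A", "C", "G", "T", "N", "-")
  counts <- matrix(0, nrow = nsym, ncol = L, dimnames = list(sym, NULL))
  span_w <- numeric(L)   # weight of members covering each junction col->col+1
  ins_tab <- list()
  for (i in seq_along(projections)) {
    pr <- projections[[i]]
    wgt <- weights[i]
    idx <- pr$first:pr$last
    m <- match(pr$cols, sym)
    ok <- !is.na(m) & idx <= L
    mm <- cbind(m[ok], idx[ok])
    counts[mm] <- counts[mm] + wgt
    if (pr$last > pr$first) {
      cols <- pr$first:(pr$last - 1L)
      cols <- cols[cols >= 1L & cols <= L]
      span_w[cols] <- span_w[cols] + wgt
    }
    for (key in names(pr$insertions)) {
      if (is.null(ins_tab[[key]])) ins_tab[[key]] <- list(w = numeric(0),
                                                          s = character(0))
      ins_tab[[key]]$w <- c(ins_tab[[key]]$w, wgt)
      ins_tab[[key]]$s <- c(ins_tab[[key]]$s, pr$insertions[[key]])
    }
  }
  out <- character(0)
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (col in seq_len(L)) {
    cc <- counts[, col]
    if (sum(cc) == 0) {          # uncovered: keep the reference base
      out <- c(out, ref_chars[col])
    } else {
      base_cc <- cc[c("A", "C", "G", "T")]
      if (cc[["-"]] > sum(cc) - cc[["-"]]) {
        # strict gap majority: drop this column
      } else if (any(base_cc > 0)) {
        top <- names(base_cc)[base_cc == max(base_cc)]
        out <- c(out, if (length(top) == 1L) top else iupac_code_for(top))
      } else {
        out <- c(out, "N")
      }
    }
    key <- as.character(col)
    it <- ins_tab[[key]]
    if (!is.null(it) && sum(it$w) > span_w[col] / 2 && span_w[col] > 0) {
      tab <- tapply(it$w, it$s, sum)
      top <- names(tab)[tab == max(tab)]
      out <- c(out, sort(top)[1L])
    }
  }
  paste(out, collapse = "")
}

#' Assemble all contigs for one tag
#'
#' Repeatedly picks the next unused seed (see [detect_seeds()]), extends it
#' ([extend_seed()]) and subtracts the consumed reads from the pool, until no
#' seeds remain or the assembly budget is exhausted (checked between seeds).
#' Contigs with fewer than `min_support` members are discarded.
#'
#' @param pool Forward-frame read data.frame for one tag.
#' @param tag The pool's sample-sheet row.
#' @param params [wimseex_params()].
#' @param sample Sample name recorded on the contigs (defaults to
#'   `tag$sample`).
#' @return A data.frame of contigs (`contig_id`, `bases`, `support`,
#'   `sample`, list column `members` of read ids) sorted by support
#'   descending.
#' @export
assemble_tag <- function(pool, tag, params = wimseex_params(),
                         sample = tag$sample) {
  empty <- data.frame(contig_id = character(0), bases = character(0),
                      support = integer(0), sample = character(0),
                      stringsAsFactors = FALSE)
  empty$members <- I(list())
  if (nrow(pool) == 0L) return(empty)
  consumed <- rep(FALSE, nrow(pool))
  used_bases <- 0L
  contigs <- list()
  repeat {
    if (used_bases >= params$max_bases) break
    seeds <- detect_seeds(pool[, , drop = FALSE], tag, params)
    seeds <- seeds[!consumed[seeds]]
    if (!length(seeds)) break
    res <- extend_seed(seeds[1L], pool, params, consumed)
    consumed <- res$consumed
    used_bases <- used_bases +
      if (params$budget_mode == "consumed_reads") {
        sum(nchar(pool$bases[res$members]))
      } else {
        nchar(res$bases)
      }
    contigs[[length(contigs) + 1L]] <-
      list(bases = res$bases, support = res$support,
           members = pool$id[res$members])
  }
  if (!length(contigs)) return(empty)
  support <- vapply(contigs, `[[`, integer(1), "support")
  keep <- which(support >= params$min_support)
  if (!length(keep)) return(empty)
  ord <- keep[order(-support[keep],
                    vapply(contigs[keep], `[[`, character(1), "bases"),
                    method = "radix")]
  out <- data.frame(
    contig_id = sprintf("%s_contig%03d", sample, seq_along(ord)),
    bases = vapply(contigs[ord], `[[`, character(1), "bases"),
    support = support[ord], sample = sample, stringsAsFactors = FALSE)
  out$members <- I(lapply(contigs[ord], `[[`, "members"))
  rownames(out) <- NULL
  out
}
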