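## Sample assignment by exact key + MID matching.
##
## Only reads that exactly match the 4-base library key and one of the
## sample sheet's 6-base MIDs (either orientation) and whose primer follows
## (IUPAC-aware) are assigned; everything else is data, not an error, and
## lands in the UNASSIGNED pool. All reported spans are 0-based half-open
## intervals on the read as given.

#' Mean-quality / N-count read filter
#'
#' `TRUE` iff the mean Phred quality is at least `min_mean_q` (vacuously true
#' when no qualities are present) and the number of N bases is at most
#' `max_n`.
#'
#' @param read One-row read data.frame or a list with `bases` and `quals`.
#' @param min_mean_q Minimum mean Phred quality.
#' @param max_n Maximum number of N bases.
#' @return Logical scalar.
#' @export
quality_filter <- function(read, min_mean_q = 20, max_n = 0L) {
  quals <- read$quals
  if (is.list(quals) && length(quals) == 1L) quals <- quals[[1]]
  q_ok <- is.null(quals) || length(quals) == 0L ||
    mean(quals) >= min_mean_q
  n_ok <- lengths(regmatches(read$bases,
                             gregexpr("N", read$bases, fixed = TRUE))) <= max_n
  q_ok && n_ok
}

## Build the MID lookup used by assignment: one entry per (mid, orientation).
mid_lookup <- function(sheet) {
  data.frame(mid = c(sheet$mid_fwd, sheet$mid_rev),
             sample = rep(sheet$sample, 2L),
             orientation = rep(c("fwd", "rev"), each = nrow(sheet)),
             row = rep(seq_len(nrow(sheet)), 2L),
             stringsAsFactors = FALSE)
}

na_spans <- function() {
  list(key_span = c(NA_integer_, NA_integer_),
       mid_span = c(NA_integer_, NA_integer_),
       primer_span = c(NA_integer_, NA_integer_),
       insert_start = NA_integer_)
}

#' Assign one read to a sample
#'
#' Requires a 0-mismatch match of the key at position 0 and of a sheet MID at
#' positions 4..9; the orientation implied by the MID (forward or reverse
#' column) must then be confirmed by an IUPAC-aware match of the
#' corresponding primer (at most `primer_mismatches` mismatches). Reads
#' already in forward frame that instead end with the reverse-complemented
#' reverse tag (`revcomp(key + mid_rev + primer_rev)`) are recognised via
#' their 3' tail when `allow_tail` is `TRUE`, which makes demultiplexing
#' idempotent on its own forward-frame output pools.
#'
#' @param bases Read sequence (character scalar).
#' @param sheet Validated sample sheet.
#' @param primer_mismatches Maximum primer mismatches (default 0).
#' @param allow_tail Also recognise forward-frame reads by their 3' reverse
#'   tag.
#' @return A list with `sample` (or `"UNASSIGNED"`), `orientation`
#'   (`"fwd"`, `"rev"` or `NA`), 0-based half-open `key_span`, `mid_span`,
#'   `primer_span`, and `insert_start`.
#' @export
#' @examples
#' sheet <- read_sample_sheet(system.file("extdata", "samples.tsv",
#'                                        package = "amplitag"))
#' assign_read(paste0("TCAGCCATAGAGAGTTTGATCCTGGCTCAG", "ACGTACGT"), sheet)
assign_read <- function(bases, sheet, primer_mismatches = 0L,
                        allow_tail = TRUE) {
  lk <- mid_lookup(sheet)
  unassigned <- c(list(sample = "UNASSIGNED", orientation = NA_character_),
                  na_spans())
  n <- nchar(bases)
  if (n >= 10L) {
    mid <- substr(bases, 5L, 10L)
    hit <- which(lk$mid == mid)
    if (length(hit) == 1L) {   # sheet invariants guarantee uniqueness
      row <- sheet[lk$row[hit], , drop = FALSE]
      ori <- lk$orientation[hit]
      primer <- if (ori == "fwd") row$primer_fwd else row$primer_rev
      pl <- nchar(primer)
      if (substr(bases, 1L, 4L) == row$key && n >= 10L + pl) {
        mm <- iupac_mismatches(primer, substr(bases, 11L, 10L + pl))
        if (mm <= primer_mismatches) {
          return(list(sample = row$sample, orientation = ori,
                      key_span = c(0L, 4L), mid_span = c(4L, 10L),
                      primer_span = c(10L, 10L + pl),
                      insert_start = 10L + pl))
        }
      }
    }
  }
  if (allow_tail) {
    for (i in seq_len(nrow(sheet))) {
      row <- sheet[i, , drop = FALSE]
      tail_pat <- reverse_complement(paste0(row$key, row$mid_rev,
                                            row$primer_rev))
      tl <- nchar(tail_pat)
      if (n >= tl &&
          iupac_mismatches(tail_pat,
                           substr(bases, n - tl + 1L, n)) <= primer_mismatches) {
        pl <- nchar(row$primer_rev)
        # tail layout (0-based): revcomp(primer_rev), revcomp(mid), revcomp(key)
        return(list(sample = row$sample, orientation = "fwd",
                    key_span = c(n - 4L, n),
                    mid_span = c(n - 10L, n - 4L),
                    primer_span = c(n - tl, n - 10L),
                    insert_start = 0L))
      }
    }
  }
  unassigned
}

#' Demultiplex a read set into per-sample pools
#'
#' Partitions every input read into exactly one pool: a sample, `UNASSIGNED`
#' or `QC_FAIL`. Reads failing [quality_filter()] go to `QC_FAIL` before any
#' matching. Reverse-orientation reads are reverse-complemented into forward
#' frame (qualities reversed) after span recording.
#'
#' @param reads Read data.frame ([read_fastq()] / [read_fasta()]).
#' @param sheet Validated sample sheet.
#' @param min_mean_q,max_n Quality-filter settings (see [quality_filter()]).
#' @param primer_mismatches Maximum primer mismatches for assignment.
#' @return A list with
#'   `pools` (named list of forward-frame read data.frames, one per sample
#'   plus `UNASSIGNED` and `QC_FAIL`),
#'   `assignments` (per-read data.frame: `read_id`, `category`,
#'   `orientation`, `insert_start`), and
#'   `summary` (data.frame of `category`, `count`).
#' @export
demultiplex <- function(reads, sheet, min_mean_q = 20, max_n = 0L,
                        primer_mismatches = 0L) {
  sheet <- validate_sample_sheet(sheet)
  n <- nrow(reads)
  category <- rep("UNASSIGNED", n)
  orientation <- rep(NA_character_, n)
  insert_start <- rep(NA_integer_, n)

  qc_ok <- vapply(seq_len(n), function(i) {
    quality_filter(list(bases = reads$bases[i], quals = reads$quals[[i]]),
                   min_mean_q = min_mean_q, max_n = max_n)
  }, logical(1))
  category[!qc_ok] <- "QC_FAIL"

  # Vectorised 5' matching for the QC-passed reads.
  lk <- mid_lookup(sheet)
  idx <- which(qc_ok)
  if (length(idx)) {
    mid <- substr(reads$bases[idx], 5L, 10L)
    key <- substr(reads$bases[idx], 1L, 4L)
    hit <- match(mid, lk$mid)
    for (h in sort(unique(hit[!is.na(hit)]))) {
      sel <- idx[!is.na(hit) & hit == h]
      row <- sheet[lk$row[h], , drop = FALSE]
      ori <- lk$orientation[h]
      primer <- if (ori == "fwd") row$primer_fwd else row$primer_rev
      pl <- nchar(primer)
      sel <- sel[key[match(sel, idx)] == row$key &
                   nchar(reads$bases[sel]) >= 10L + pl]
      if (!length(sel)) next
      seg <- substr(reads$bases[sel], 11L, 10L + pl)
      ok <- if (primer_mismatches == 0L) {
        grepl(paste0("^", iupac_regex(primer), "$"), seg)
      } else {
        iupac_mismatches(primer, seg) <= primer_mismatches
      }
      sel <- sel[ok]
      if (!length(sel)) next
      category[sel] <- row$sample
      orientation[sel] <- ori
      insert_start[sel] <- 10L + pl
    }
    # 3'-tail rescue for forward-frame reverse reads (idempotence on pools).
    rest <- idx[category[idx] == "UNASSIGNED"]
    if (length(rest)) {
      for (i in seq_len(nrow(sheet))) {
        row <- sheet[i, , drop = FALSE]
        tail_pat <- reverse_complement(paste0(row$key, row$mid_rev,
                                              row$primer_rev))
        tl <- nchar(tail_pat)
        cand <- rest[nchar(reads$bases[rest]) >= tl]
        if (!length(cand)) next
        seg <- substr(reads$bases[cand],
                      nchar(reads$bases[cand]) - tl + 1L,
                      nchar(reads$bases[cand]))
        ok <- if (primer_mismatches == 0L) {
          grepl(paste0("^", iupac_regex(tail_pat), "$"), seg)
        } else {
          iupac_mismatches(tail_pat, seg) <= primer_mismatches
        }
        cand <- cand[ok]
        if (!length(cand)) next
        category[cand] <- row$sample
        orientation[cand] <- "fwd"
        insert_start[cand] <- 0L
        rest <- setdiff(rest, cand)
      }
    }
  }

  # Emit pools; reverse reads flipped into forward frame.
  pools <- list()
  for (s in c(sheet$sample, "UNASSIGNED", "QC_FAIL")) {
    sel <- which(category == s)
    pool <- reads[sel, , drop = FALSE]
    flip <- which(!is.na(orientation[sel]) & orientation[sel] == "rev")
    if (length(flip)) {
      pool$bases[flip] <- reverse_complement(pool$bases[flip])
      pool$quals[flip] <- lapply(pool$quals[flip], rev)
    }
    rownames(pool) <- NULL
    pools[[s]] <- pool
  }
  summary <- data.frame(category = names(pools),
                        count = vapply(pools, nrow, integer(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  assignments <- data.frame(read_id = reads$id, category = category,
                            orientation = orientation,
                            insert_start = insert_start,
                            stringsAsFactors = FALSE)
  list(pools = pools, assignments = assignments, summary = summary)
}
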