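## From contigs to consensus OTUs and the per-sample abundance table:
## greedy centroid clustering at a 16S-style identity radius, support-weighted
## consensus extraction, identifier/primer stripping, and read counting either
## by contig membership or by re-mapping every demultiplexed read.

#' Pairwise sequence identity
#'
#' Global alignment with cost-free terminal gaps (ends-free / overlap
#' Needleman-Wunsch) under match +1, mismatch -1, gap open 2 and gap
#' extension 0.5; identity is the fraction of matching columns among the
#' alignment columns, terminal gaps excluded.
#'
#' @param a,b Non-empty DNA strings. `b` may be a character vector, in which
#'   case `a` is aligned against each element.
#' @return Numeric identity fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")  # 1
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || any(!nzchar(b))) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  .overlap_identity_many(b, a)
}

#' Greedy centroid clustering of contigs
#'
#' Contigs are sorted by support descending (sequence as tie-break); each
#' joins the first existing centroid with [pairwise_identity()] at or above
#' the threshold, otherwise it founds a new cluster. Deterministic.
#'
#' @param contigs Contig data.frame ([assemble_tag()]).
#' @param identity_threshold Identity radius (default 0.97, the conventional
#'   16S OTU radius).
#' @return `contigs` reordered by support with an added integer `cluster`
#'   column; cluster 1 is the most supported centroid's cluster.
#' @export
cluster_contigs <- function(contigs, identity_threshold = 0.97) {
  if (nrow(contigs) == 0L) {
    contigs$cluster <- integer(0)
    return(contigs)
  }
  ord <- order(-contigs$support, contigs$bases, method = "radix")
  contigs <- contigs[ord, , drop = FALSE]
  rownames(contigs) <- NULL
  centroid_idx <- integer(0)
  cluster <- integer(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    placed <- FALSE
    for (ci in seq_along(centroid_idx)) {
      idy <- pairwise_identity(contigs$bases[i],
                               contigs$bases[centroid_idx[ci]])
      if (idy >= identity_threshold) {
        cluster[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroid_idx <- c(centroid_idx, i)
      cluster[i] <- length(centroid_idx)
    }
  }
  contigs$cluster <- cluster
  contigs
}

#' Consensus sequence of one cluster
#'
#' Centroid-anchored alignment: every member is pairwise-aligned to the
#' centroid (the highest-support contig) and the columns are merged; each
#' column takes the support-weighted majority base, ties give the IUPAC
#' ambiguity code, and columns with a strict gap majority are dropped.
#'
#' @param cluster_contigs Data.frame of the cluster's contigs (`bases`,
#'   `support`).
#' @return The consensus DNA string.
#' @export
consensus_of_cluster <- function(cluster_contigs) {
  if (nrow(cluster_contigs) == 0L) stop("empty cluster", call. = FALSE)
  ord <- order(-cluster_contigs$support, cluster_contigs$bases,
               method = "radix")
  cluster_contigs <- cluster_contigs[ord, , drop = FALSE]
  centroid <- cluster_contigs$bases[1L]
  if (nrow(cluster_contigs) == 1L) return(centroid)
  projections <- lapply(cluster_contigs$bases, project_onto_reference,
                        ref = centroid)
  consensus_from_projections(centroid, projections,
                             cluster_contigs$support)
}

#' Strip the sequence identifier and primer from a consensus
#'
#' Removes the leading key + forward MID + forward primer when present
#' (primer matched IUPAC-aware), and symmetrically the 3' tail
#' `revcomp(key + mid_rev + primer_rev)` that fully extended contigs carry.
#' If a prefix/tail is absent the sequence is returned unchanged with a
#' warning flag in the `stripped` attribute.
#'
#' @param seq Consensus DNA string.
#' @param tag Sample-sheet row.
#' @param max_mismatch Residual consensus errors tolerated when recognising
#'   the prefix/tail (IUPAC-aware).
#' @return The stripped sequence, with attribute `stripped` =
#'   `list(five_prime =, three_prime =)` flags.
#' @export
strip_tag_primer <- function(seq, tag, max_mismatch = 1L) {
  five <- FALSE
  three <- FALSE
  pre_len <- 10L + nchar(tag$primer_fwd)
  if (nchar(seq) > pre_len) {
    prefix <- paste0(tag$key, tag$mid_fwd, tag$primer_fwd)
    if (iupac_mismatches(prefix, substr(seq, 1L, pre_len)) <= max_mismatch) {
      seq <- substring(seq, pre_len + 1L)
      five <- TRUE
    }
  }
  tail_pat <- reverse_complement(paste0(tag$key, tag$mid_rev,
                                        tag$primer_rev))
  tl <- nchar(tail_pat)
  if (nchar(seq) > tl) {
    n <- nchar(seq)
    if (iupac_mismatches(tail_pat, substr(seq, n - tl + 1L, n)) <=
        max_mismatch) {
      seq <- substr(seq, 1L, n - tl)
      three <- TRUE
    }
  }
  if (!five) {
    warning("5' key+MID+primer prefix not found; sequence left unchanged",
            call. = FALSE)
  }
  structure(seq, stripped = list(five_prime = five, three_prime = three))
}

#' Build consensus OTUs for one sample
#'
#' Clusters the sample's contigs, extracts one consensus per cluster, strips
#' the tag/primer, and attaches membership read counts (summed contig
#' support per cluster).
#'
#' @param contigs Contig data.frame for one sample.
#' @param tag The sample-sheet row.
#' @param identity_threshold Clustering radius (see [cluster_contigs()]).
#' @return Data.frame `otu_id`, `bases`, `sample`, `read_count`, sorted by
#'   read count descending.
#' @export
make_otus <- function(contigs, tag, identity_threshold = 0.97) {
  sample <- if (nrow(contigs)) contigs$sample[1L] else tag$sample
  cl <- cluster_contigs(contigs, identity_threshold)
  if (nrow(cl) == 0L) {
    return(data.frame(otu_id = character(0), bases = character(0),
                      sample = character(0), read_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(cl, cl$cluster), function(cc) {
    cons <- consensus_of_cluster(cc)
    cons <- suppressWarnings(strip_tag_primer(cons, tag))
    data.frame(bases = as.character(cons), sample = sample,
               read_count = sum(cc$support), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$read_count, out$bases, method = "radix"), ,
             drop = FALSE]
  out <- data.frame(otu_id = sprintf("%s_OTU%02d", sample,
                                     seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Re-map reads to OTU consensus sequences
#'
#' Assigns every read to its best OTU by [pairwise_identity()], requiring at
#' least `min_identity`; reads below the threshold stay unmapped.
#'
#' @param reads Forward-frame read data.frame (one sample's pool).
#' @param otus OTU data.frame for the same sample ([make_otus()]).
#' @param min_identity Minimum identity for a read to count (default 0.90).
#' @return Integer vector of per-OTU read counts (named by `otu_id`);
#'   attribute `unmapped` holds the number of unassigned reads.
#' @export
map_reads_to_otus <- function(reads, otus, min_identity = 0.90) {
  counts <- stats::setNames(integer(nrow(otus)), otus$otu_id)
  if (nrow(reads) == 0L || nrow(otus) == 0L) {
    attr(counts, "unmapped") <- nrow(reads)
    return(counts)
  }
  ids <- matrix(0, nrow = nrow(reads), ncol = nrow(otus))
  for (j in seq_len(nrow(otus))) {
    ids[, j] <- .overlap_identity_many(reads$bases, otus$bases[j])
  }
  best <- max.col(ids, ties.method = "first")
  ok <- ids[cbind(seq_len(nrow(reads)), best)] >= min_identity
  tab <- table(factor(best[ok], levels = seq_len(nrow(otus))))
  counts[] <- as.integer(tab)
  attr(counts, "unmapped") <- sum(!ok)
  counts
}

#' Build the per-sample OTU abundance table
#'
#' @param otus Data.frame with `sample`, `otu_id`, `read_count` and
#'   optionally `closest_match`.
#' @param totals Optional named vector of per-sample read totals used as the
#'   percentage denominator (e.g. assigned-read totals in re-mapping mode);
#'   defaults to the per-sample sum of `read_count`.
#' @return Data.frame `sample`, `otu_id`, `read_count`, `pct_of_total`
#'   (percent, 2 decimals), `closest_match`; rows sorted per sample by read
#'   count descending.
#' @export
#' @examples
#' build_table(data.frame(sample = "s", otu_id = c("a", "b"),
#'                        read_count = c(90, 10)))
build_table <- function(otus, totals = NULL) {
  if (nrow(otus) == 0L) stop("no OTUs to tabulate", call. = FALSE)
  if (is.null(otus$closest_match)) otus$closest_match <- NA_character_
  sums <- tapply(otus$read_count, otus$sample, sum)
  if (is.null(totals)) {
    totals <- sums
  } else {
    missing <- setdiff(names(sums), names(totals))
    if (length(missing)) {
      stop("totals missing for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(totals[names(sums)] <= 0)) {
    stop("sample total of 0 reads", call. = FALSE)
  }
  out <- otus[, c("sample", "otu_id", "read_count", "closest_match")]
  out$pct_of_total <- round(100 * out$read_count /
                              as.numeric(totals[out$sample]), 2L)
  out <- out[order(out$sample, -out$read_count, out$otu_id,
                   method = "radix"),
             c("sample", "otu_id", "read_count", "pct_of_total",
               "closest_match")]
  rownames(out) <- NULL
  out
}

#' Combined abundance of an OTU subset
#'
#' Sum of the subset's read counts across the given samples as a percentage
#' of all read counts across those samples.
#'
#' @param table OTU table ([build_table()]).
#' @param otu_subset Character vector of `otu_id`s.
#' @param samples Samples to include (default: all).
#' @return Percentage in `[0, 100]`.
#' @export
dominant_fraction <- function(table, otu_subset, samples = NULL) {
  if (nrow(table) == 0L) stop("empty OTU table", call. = FALSE)
  if (!is.null(samples)) table <- table[table$sample %in% samples, ,
                                        drop = FALSE]
  if (nrow(table) == 0L) stop("no rows for requested samples", call. = FALSE)
  bad <- setdiff(otu_subset, table$otu_id)
  if (length(bad)) {
    stop("otu_subset not in table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  100 * sum(table$read_count[table$otu_id %in% otu_subset]) /
    sum(table$read_count)
}
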