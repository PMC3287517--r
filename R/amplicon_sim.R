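## 454-style multitag amplicon read simulation with known ground truth.
##
## Reads emulate GS FLX Titanium amplicon sequencing of ~450 bp 16S rDNA
## fragments: every read starts with the 4-base library key, a 6-base
## multiplex identifier (MID) and the PCR primer, followed by the insert
## (forward reads) or its reverse complement read from the B-adaptor end
## (reverse reads). Sequencing noise is dominated by homopolymer
## insertions/deletions whose probability grows with run length.

#' 454 error model
#'
#' @param sub_rate Per-base substitution probability.
#' @param hp_indel_base Per-homopolymer indel probability at run length 1.
#' @param hp_scale Multiplicative factor per extra base of run length; the
#'   effective per-run indel probability is
#'   `min(0.5, hp_indel_base * hp_scale^(k-1))` for a run of length `k`.
#' @param len_mean,len_sd Mean and SD (bp) of the sequenced insert length
#'   (the template portion of the read, excluding key+MID+primer).
#' @param rev_read_frac Fraction of reads sequenced from the reverse
#'   (B-adaptor) end.
#' @return An object of class `error_model`.
#' @export
#' @examples
#' error_model()                       # GS FLX Titanium-like defaults
#' error_model(sub_rate = 0, hp_indel_base = 0)  # noise-free
error_model <- function(sub_rate = 0.004, hp_indel_base = 0.01,
                        hp_scale = 1.6, len_mean = 430, len_sd = 25,
                        rev_read_frac = 0.5) {
  stopifnot(sub_rate >= 0, sub_rate <= 1,
            hp_indel_base >= 0, hp_indel_base <= 1,
            hp_scale >= 0, len_mean > 0, len_sd >= 0,
            rev_read_frac >= 0, rev_read_frac <= 1)
  structure(list(sub_rate = sub_rate, hp_indel_base = hp_indel_base,
                 hp_scale = hp_scale, len_mean = len_mean, len_sd = len_sd,
                 rev_read_frac = rev_read_frac),
            class = "error_model")
}

#' Community profile for one tagged sample
#'
#' @param sample Sample name (must match a sample-sheet row).
#' @param members Named numeric vector of relative abundances (template id ->
#'   abundance); must sum to 1 within 1e-9.
#' @param n_reads Number of reads to simulate for this sample.
#' @return An object of class `community_profile`.
#' @export
community_profile <- function(sample, members, n_reads) {
  if (is.null(names(members)) || any(!nzchar(names(members)))) {
    stop("members must be a named abundance vector", call. = FALSE)
  }
  if (any(members < 0) || abs(sum(members) - 1) > 1e-9) {
    stop("relative abundances must be nonnegative and sum to 1 (got ",
         format(sum(members)), ") for sample ", sample, call. = FALSE)
  }
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) {
    stop("n_reads must be a positive integer", call. = FALSE)
  }
  structure(list(sample = sample, members = members, n_reads = n_reads),
            class = "community_profile")
}

#' Build one tagged amplicon sequence
#'
#' Forward: `key + mid_fwd + primer_fwd + template`; reverse:
#' `key + mid_rev + primer_rev + reverse_complement(template)`. IUPAC codes
#' in the primer are resolved to a concrete base uniformly at random
#' (degenerate primer pools anneal all variants). Titanium A/B adaptors are
#' not emitted; the sequencer strips them before the key.
#'
#' @param template Insert DNA (concrete bases).
#' @param tag One sample-sheet row (list or single-row data.frame).
#' @param orientation `"fwd"` or `"rev"`.
#' @return The amplicon DNA string.
#' @export
build_amplicon <- function(template, tag, orientation = c("fwd", "rev")) {
  orientation <- match.arg(orientation)
  if (!is.character(template) || length(template) != 1L ||
      !nzchar(template)) {
    stop("template must be a non-empty DNA string", call. = FALSE)
  }
  if (orientation == "fwd") {
    paste0(tag$key, tag$mid_fwd, resolve_iupac(tag$primer_fwd), template)
  } else {
    paste0(tag$key, tag$mid_rev, resolve_iupac(tag$primer_rev),
           reverse_complement(template))
  }
}

#' Full forward-frame amplicon including the reverse-tag tail
#'
#' The complete molecule between the Titanium adaptors, read in forward
#' frame: `key + mid_fwd + primer_fwd + template +
#' revcomp(primer_rev) + revcomp(mid_rev) + revcomp(key)`. This is what a
#' fully extended per-tag contig converges to when both read orientations
#' are present.
#'
#' @inheritParams build_amplicon
#' @param resolve_primer Resolve IUPAC codes in the forward primer (random);
#'   set `FALSE` to keep ambiguity codes.
#' @return DNA string.
#' @export
full_amplicon <- function(template, tag, resolve_primer = TRUE) {
  pf <- if (resolve_primer) resolve_iupac(tag$primer_fwd) else tag$primer_fwd
  paste0(tag$key, tag$mid_fwd, pf, template,
         reverse_complement(paste0(tag$key, tag$mid_rev, tag$primer_rev)))
}

#' Apply 454-style sequencing noise to a sequence
#'
#' Each base is substituted with probability `sub_rate` (uniformly over the
#' three alternatives); then each maximal homopolymer run of length `k`
#' gains or loses one base (equiprobably) with probability
#' `min(0.5, hp_indel_base * hp_scale^(k-1))`.
#'
#' @param seq DNA string.
#' @param model An [error_model()].
#' @param rng_seed Optional integer; when given, the result is a
#'   deterministic function of `(seq, model, rng_seed)`.
#' @return The mutated DNA string.
#' @export
mutate_seq <- function(seq, model, rng_seed = NULL) {
  if (!inherits(model, "error_model")) {
    stop("model must be an error_model", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (model$sub_rate == 0 && model$hp_indel_base == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (model$sub_rate > 0) {
    hit <- which(stats::runif(length(chars)) < model$sub_rate)
    for (i in hit) {
      alts <- setdiff(c("A", "C", "G", "T"), chars[i])
      chars[i] <- alts[sample.int(length(alts), 1L)]
    }
  }
  if (model$hp_indel_base > 0) {
    r <- rle(chars)
    k <- r$lengths
    p <- pmin(0.5, model$hp_indel_base * model$hp_scale^(k - 1))
    ind <- stats::runif(length(k)) < p
    if (any(ind)) {
      newlen <- k
      ins <- stats::runif(sum(ind)) < 0.5
      newlen[ind] <- k[ind] + ifelse(ins, 1L, -1L)
      newlen[newlen < 0L] <- 0L
      chars <- rep.int(r$values, newlen)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a multitag 454 amplicon run
#'
#' For each community profile, `n_reads` reads are generated: the template is
#' chosen by relative abundance, the insert trimmed to a length drawn from
#' `Normal(len_mean, len_sd)` clipped to `[100, template length]`, the
#' orientation is reverse with probability `rev_read_frac`, and the tagged
#' amplicon is built and mutated. The output order is shuffled across samples
#' deterministically by `rng_seed`, and a truth table maps every read id to
#' its sample, template and orientation.
#'
#' @param profiles List of [community_profile()] objects.
#' @param templates Named character vector of template sequences, or a
#'   data.frame as returned by [read_fasta()].
#' @param sheet Validated sample sheet (one row per profile sample).
#' @param model An [error_model()].
#' @param rng_seed Integer seed; identical inputs give byte-identical output.
#' @param base_qual Constant Phred quality assigned to simulated bases.
#' @return `list(reads = <read data.frame>, truth = <data.frame with
#'   read_id, sample, template_id, orientation>)`.
#' @export
simulate_community <- function(profiles, templates, sheet, model = error_model(),
                               rng_seed = 1L, base_qual = 34L) {
  if (inherits(profiles, "community_profile")) profiles <- list(profiles)
  if (is.data.frame(templates)) {
    templates <- stats::setNames(templates$bases, templates$id)
  }
  sheet <- validate_sample_sheet(sheet)
  total <- sum(vapply(profiles, function(p) p$n_reads, integer(1)))
  if (total == 0L) stop("total read count is 0", call. = FALSE)
  for (p in profiles) {
    missing <- setdiff(names(p$members), names(templates))
    if (length(missing)) {
      stop("profile ", p$sample, " references unknown template(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (!p$sample %in% sheet$sample) {
      stop("profile sample not in sample sheet: ", p$sample, call. = FALSE)
    }
  }
  set.seed(rng_seed)
  bases <- character(total)
  sam <- character(total)
  tmpl <- character(total)
  ori <- character(total)
  i <- 0L
  for (p in profiles) {
    tag <- as.list(sheet[sheet$sample == p$sample, , drop = FALSE])
    ids <- names(p$members)
    pick <- if (length(ids) == 1L) rep.int(1L, p$n_reads) else
      sample.int(length(ids), p$n_reads, replace = TRUE, prob = p$members)
    lens <- round(stats::rnorm(p$n_reads, model$len_mean, model$len_sd))
    orient <- ifelse(stats::runif(p$n_reads) < model$rev_read_frac,
                     "rev", "fwd")
    for (j in seq_len(p$n_reads)) {
      t_id <- ids[pick[j]]
      t_seq <- templates[[t_id]]
      L <- max(100L, min(nchar(t_seq), lens[j]))
      insert <- if (orient[j] == "fwd") {
        substr(t_seq, 1L, L)
      } else {
        substr(t_seq, nchar(t_seq) - L + 1L, nchar(t_seq))
      }
      amp <- build_amplicon(insert, tag, orient[j])
      i <- i + 1L
      bases[i] <- mutate_seq(amp, model)
      sam[i] <- p$sample
      tmpl[i] <- t_id
      ori[i] <- orient[j]
    }
  }
  ord <- sample.int(total)
  bases <- bases[ord]; sam <- sam[ord]; tmpl <- tmpl[ord]; ori <- ori[ord]
  ids <- sprintf("read_%06d", seq_len(total))
  quals <- lapply(nchar(bases), function(n) rep.int(as.integer(base_qual), n))
  list(reads = read_frame(ids, bases, quals),
       truth = data.frame(read_id = ids, sample = sam, template_id = tmpl,
                          orientation = ori, stringsAsFactors = FALSE))
}
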