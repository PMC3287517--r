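## Readers/writers for the external formats the pipeline touches.
## No science here: parsing is total (every record is returned or raises a
## located error) and round-trips are bit-faithful on id, bases and qualities.
##
## Reads are represented as a data.frame with columns
##   id    - character, unique within a file
##   bases - character, uppercase DNA over {A,C,G,T,N}
##   quals - list column of integer Phred scores (NULL per element for FASTA)

## Construct the canonical read data.frame.
read_frame <- function(id, bases, quals = NULL) {
  if (is.null(quals)) quals <- vector("list", length(id))
  data.frame(id = id, bases = bases,
             quals = I(quals), stringsAsFactors = FALSE)
}

check_read_ids <- function(ids, path) {
  if (any(!nzchar(ids))) stop("empty read id in ", path, call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate read id(s) in ", path, ": ",
         paste(unique(dup)[seq_len(min(3, length(unique(dup))))],
               collapse = ", "), call. = FALSE)
  }
}

#' Read a FASTQ file
#'
#' Strict 4-line-record FASTQ with Phred+33 qualities. Malformed records
#' raise an error naming the offending line. Bases are uppercased and U is
#' mapped to T; characters outside `A,C,G,T,N` are an error.
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return A data.frame with columns `id`, `bases` and list column `quals`
#'   (integer Phred scores), in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) return(read_frame(character(0), character(0)))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ ", path, ": ", length(lines),
         " lines is not a multiple of 4 (near line ",
         4L * (length(lines) %/% 4L) + 1L, ")", call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ ", path, ": missing '@' header at line ",
         idx[bad[1L]], call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ ", path, ": missing '+' separator at line ",
         idx[bad[1L]] + 2L, call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ ", path, ": sequence/quality length mismatch at line ",
         idx[bad[1L]] + 3L, call. = FALSE)
  }
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) {
    stop("malformed FASTQ ", path, ": empty sequence at line ",
         idx[bad[1L]] + 1L, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  check_read_ids(ids, path)
  bases <- vapply(seq_along(seqs), function(i) {
    tryCatch(normalize_dna(seqs[i]),
             error = function(e) {
               stop("malformed FASTQ ", path, " at line ", idx[i] + 1L, ": ",
                    conditionMessage(e), call. = FALSE)
             })
  }, character(1))
  qlist <- lapply(quals, function(q) {
    as.integer(utf8ToInt(q)) - 33L
  })
  bad <- which(vapply(qlist, function(q) any(q < 0L | q > 93L), logical(1)))
  if (length(bad)) {
    stop("malformed FASTQ ", path, ": quality character out of Phred+33 ",
         "range at line ", idx[bad[1L]] + 3L, call. = FALSE)
  }
  read_frame(ids, bases, qlist)
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated; record order is preserved; bases
#' are uppercased with U mapped to T.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param alphabet Allowed characters after normalisation; defaults to the
#'   read alphabet. Pass `names(IUPAC_SETS)` for reference sets that may
#'   contain ambiguity codes.
#' @return A data.frame with columns `id`, `bases`, `desc` (remainder of the
#'   header line) and an all-`NULL` `quals` list column.
#' @export
read_fasta <- function(path, alphabet = c("A", "C", "G", "T", "N")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- read_frame(character(0), character(0))
    out$desc <- character(0)
    return(out)
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA ", path, ": sequence before first header (line 1)",
         call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  hdr <- substring(lines[is_hdr], 2L)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 paste, character(1), collapse = "")
  # records with no sequence lines at all
  full <- character(length(ids))
  full[as.integer(names(seqs))] <- seqs
  empty <- which(!nzchar(full))
  if (length(empty)) {
    stop("malformed FASTA ", path, ": record '", ids[empty[1L]],
         "' has no sequence", call. = FALSE)
  }
  check_read_ids(ids, path)
  bases <- vapply(seq_along(full), function(i) {
    tryCatch(normalize_dna(full[i], alphabet = alphabet),
             error = function(e) {
               stop("malformed FASTA ", path, " record '", ids[i], "': ",
                    conditionMessage(e), call. = FALSE)
             })
  }, character(1))
  out <- read_frame(ids, bases)
  out$desc <- desc
  out
}

#' Write reads as FASTA
#'
#' @param reads Read data.frame (see [read_fasta()]); a `desc` column, if
#'   present, is appended to headers.
#' @param path Output path.
#' @param width Sequence line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(reads, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) == 0L) return(invisible(path))
  hdr <- paste0(">", reads$id)
  if (!is.null(reads$desc)) {
    has <- nzchar(reads$desc)
    hdr[has] <- paste(hdr[has], reads$desc[has])
  }
  out <- character(0)
  for (i in seq_len(nrow(reads))) {
    s <- reads$bases[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, hdr[i], substring(s, starts, pmin(starts + width - 1L,
                                                    nchar(s))))
  }
  writeLines(out, con)
  invisible(path)
}

#' Write reads as FASTQ (Phred+33)
#'
#' Every read must carry a quality vector of the same length as its bases.
#'
#' @inheritParams write_fasta
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  has_q <- vapply(reads$quals, function(q) !is.null(q), logical(1))
  if (nrow(reads) > 0L && !all(has_q)) {
    stop("cannot write FASTQ: read(s) without qualities, e.g. ",
         reads$id[which(!has_q)[1L]], call. = FALSE)
  }
  bad <- which(vapply(seq_len(nrow(reads)), function(i) {
    length(reads$quals[[i]]) != nchar(reads$bases[i])
  }, logical(1)))
  if (length(bad)) {
    stop("quality length differs from sequence length for read ",
         reads$id[bad[1L]], call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) == 0L) return(invisible(path))
  qstr <- vapply(reads$quals, function(q) intToUtf8(q + 33L), character(1))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$bases,
                             "+", qstr)), con)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Tab-separated with the exact header
#' `sample  key  mid_fwd  mid_rev  primer_fwd  primer_rev`. The key must be
#' 4 bp, MIDs 6 bp and unique across rows in both orientations (forward and
#' reverse MID columns jointly), and primers non-empty IUPAC DNA.
#'
#' @param path Path to the TSV sample sheet.
#' @return A validated data.frame, one row per sample.
#' @export
#' @examples
#' sheet <- read_sample_sheet(system.file("extdata", "samples.tsv",
#'                                        package = "amplitag"))
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#'
#' @param df Data.frame with the sample-sheet columns.
#' @return The normalised data.frame (sequences uppercased).
#' @export
validate_sample_sheet <- function(df) {
  want <- c("sample", "key", "mid_fwd", "mid_rev", "primer_fwd", "primer_rev")
  if (!identical(names(df)[seq_along(want)], want)) {
    stop("sample sheet header must be: ", paste(want, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("sample sheet has no rows", call. = FALSE)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample name(s) in sample sheet", call. = FALSE)
  }
  for (col in c("key", "mid_fwd", "mid_rev")) {
    df[[col]] <- vapply(seq_len(nrow(df)), function(i) {
      normalize_dna(df[[col]][i], alphabet = c("A", "C", "G", "T"),
                    what = paste0(col, " for sample ", df$sample[i]))
    }, character(1))
  }
  for (col in c("primer_fwd", "primer_rev")) {
    df[[col]] <- vapply(seq_len(nrow(df)), function(i) {
      normalize_dna(df[[col]][i], alphabet = names(IUPAC_SETS),
                    what = paste0(col, " for sample ", df$sample[i]))
    }, character(1))
  }
  if (any(nchar(df$key) != 4L)) {
    stop("key must be 4 bp for every sample", call. = FALSE)
  }
  if (any(nchar(df$mid_fwd) != 6L) || any(nchar(df$mid_rev) != 6L)) {
    stop("MIDs must be 6 bp for every sample", call. = FALSE)
  }
  mids <- c(df$mid_fwd, df$mid_rev)
  if (anyDuplicated(mids)) {
    stop("MIDs must be unique across samples in both orientations; ",
         "duplicated: ", paste(unique(mids[duplicated(mids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$primer_fwd)) || any(!nzchar(df$primer_rev))) {
    stop("primers must be non-empty", call. = FALSE)
  }
  df
}
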