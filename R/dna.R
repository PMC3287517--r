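## Low-level DNA string utilities shared by all pipeline stages.
## Sequences are plain uppercase character scalars over the IUPAC alphabet;
## reads proper are restricted to {A,C,G,T,N}.

# Allowed bases per IUPAC code (U is normalised to T on input).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# Bit encoding A=1 C=2 G=4 T=8; ambiguity codes are unions. Used by Fitch.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L, `-` = 15L, `?` = 15L
)

# Inverse map from a bit set of {A,C,G,T} back to the IUPAC letter.
BITS_TO_IUPAC <- character(15)
for (.code in c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                "V", "H", "D", "B", "N")) {
  BITS_TO_IUPAC[IUPAC_BITS[[.code]]] <- .code
}
rm(.code)

#' Normalise a DNA string
#'
#' Uppercases, maps U to T, and checks every character against the allowed
#' alphabet.
#'
#' @param x Character scalar.
#' @param alphabet Characters accepted after normalisation. Defaults to the
#'   strict read alphabet `A,C,G,T,N`; pass `names(IUPAC_SETS)` to accept the
#'   full IUPAC ambiguity alphabet (as in primers).
#' @param what Label used in error messages.
#' @return The normalised string.
#' @keywords internal
normalize_dna <- function(x, alphabet = c("A", "C", "G", "T", "N"),
                          what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), alphabet)
  if (length(bad)) {
    stop(what, " contains disallowed character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' IUPAC-aware reverse complement of a DNA string (ambiguity codes map onto
#' the complement of their base sets, e.g. M to K).
#'
#' @param x Character scalar (or vector) of DNA.
#' @return Reverse-complemented string(s).
#' @export
#' @examples
#' reverse_complement("ACGT")   # "ACGT"
#' reverse_complement("TCAGM")  # "KCTGA"
reverse_complement <- function(x) {
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Test a text against an IUPAC pattern
#'
#' `TRUE` iff every base of `text` is contained in the corresponding pattern
#' code's allowed set. Both strings must have equal length.
#'
#' @param pattern IUPAC DNA string (may contain ambiguity codes).
#' @param text Concrete DNA string over `A,C,G,T` (N in the text matches only
#'   an N/ambiguity code that covers all four bases).
#' @return Logical scalar.
#' @export
#' @examples
#' iupac_match("MGAG", "AGAG")  # TRUE, M = A/C
iupac_match <- function(pattern, text) {
  if (nchar(pattern) != nchar(text)) {
    stop("pattern and text must have equal length", call. = FALSE)
  }
  iupac_mismatches(pattern, text) == 0L
}

## Number of positions of `text` not covered by `pattern`'s IUPAC sets.
## Vectorised over `text`; all texts must have nchar(pattern) characters.
iupac_mismatches <- function(pattern, text) {
  pb <- IUPAC_BITS[strsplit(pattern, "", fixed = TRUE)[[1]]]
  if (anyNA(pb)) stop("pattern contains non-IUPAC characters", call. = FALSE)
  tl <- strsplit(text, "", fixed = TRUE)
  vapply(tl, function(ch) {
    tb <- IUPAC_BITS[ch]
    tb[is.na(tb)] <- 0L
    sum(bitwAnd(pb, tb) != tb | tb == 0L)
  }, integer(1))
}

## Translate an IUPAC pattern into a regular expression character-class form.
iupac_regex <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c1) {
    set <- IUPAC_SETS[[c1]]
    if (is.null(set)) stop("non-IUPAC character in pattern: ", c1,
                           call. = FALSE)
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Resolve IUPAC ambiguity codes to concrete bases
#'
#' Each ambiguity code is replaced by one of its allowed bases drawn uniformly
#' at random (degenerate primer pools anneal all variants).
#'
#' @param x IUPAC DNA string.
#' @return DNA string over `A,C,G,T`.
#' @export
resolve_iupac <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  amb <- which(!ch %in% c("A", "C", "G", "T"))
  for (i in amb) {
    set <- IUPAC_SETS[[ch[i]]]
    if (is.null(set)) stop("non-IUPAC character: ", ch[i], call. = FALSE)
    ch[i] <- set[sample.int(length(set), 1L)]
  }
  paste(ch, collapse = "")
}

## IUPAC code for a set of concrete bases (ties in majority votes).
iupac_code_for <- function(bases) {
  bits <- sum(IUPAC_BITS[unique(bases)])
  BITS_TO_IUPAC[bits]
}

## Random DNA of length n (test/simulation helper).
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
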