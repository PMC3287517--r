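## Desk-scale phylogenetic placement: nearest-reference classification,
## pairwise-deletion p/JC69 distances, Saitou-Nei neighbour joining, Fitch
## small parsimony and exhaustive parsimony insertion of a query sequence
## into a fixed reference tree. Trees are `ape` "phylo" objects throughout;
## the NJ, distance and parsimony computations are implemented here (ape and
## phangorn serve as independent cross-checks in the test suite).

#' Nearest reference by pairwise identity
#'
#' @param query DNA string.
#' @param refs Reference data.frame with columns `accession` and `bases`
#'   (e.g. from [read_reference_fasta()]).
#' @return List with `accession`, `identity` (fraction), and `label` if the
#'   refs carry one. Ties are broken by lexicographically smaller accession.
#' @export
best_hit <- function(query, refs) {
  if (is.null(refs) || nrow(refs) == 0L) {
    stop("reference set is empty", call. = FALSE)
  }
  ids <- pairwise_identity(query, refs$bases)
  best <- which(ids == max(ids))
  best <- best[order(refs$accession[best], method = "radix")][1L]
  list(accession = refs$accession[best], identity = ids[best],
       label = if (!is.null(refs$label)) refs$label[best] else NA_character_)
}

#' Read a reference FASTA with labels and optional groups
#'
#' Headers are parsed as `>accession free-text label ... [group=<name>]`.
#'
#' @param path FASTA path (IUPAC alphabet and gaps allowed).
#' @return Data.frame `accession`, `label`, `group`, `bases`.
#' @export
read_reference_fasta <- function(path) {
  fa <- read_fasta(path, alphabet = c(names(IUPAC_SETS), "-"))
  group <- ifelse(grepl("group=", fa$desc),
                  sub(".*group=(\\S+).*", "\\1", fa$desc), NA_character_)
  label <- trimws(sub("group=\\S+", "", fa$desc))
  data.frame(accession = fa$id, label = label, group = group,
             bases = fa$bases, stringsAsFactors = FALSE)
}

#' Pairwise-deletion distance matrix from an alignment
#'
#' For each pair, columns where either sequence has a gap or an ambiguous
#' base are ignored; `p` is the proportion of differing remaining columns
#' and `jc69` applies the Jukes-Cantor correction `-(3/4) log(1 - 4p/3)`.
#' Pairs with `p >= 0.75` under `jc69` are flagged `NA` with a warning.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (at least 3).
#' @param model `"jc69"` (default) or `"p"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, model = c("jc69", "p")) {
  model <- match.arg(model)
  n <- length(alignment)
  if (n < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  if (is.null(names(alignment))) stop("alignment must be named", call. = FALSE)
  chars <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  valid <- matrix(chars %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  flagged <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- valid[i, ] & valid[j, ]
      if (!any(use)) {
        stop("no comparable columns between ", names(alignment)[i], " and ",
             names(alignment)[j], call. = FALSE)
      }
      p <- sum(chars[i, use] != chars[j, use]) / sum(use)
      dij <- if (model == "p") {
        p
      } else if (p >= 0.75) {
        flagged <- TRUE
        NA_real_
      } else {
        -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (flagged) {
    warning("p >= 0.75 for at least one pair; JC69 distance undefined (NA)",
            call. = FALSE)
  }
  d
}

#' Neighbour joining
#'
#' Saitou-Nei agglomeration: iteratively joins the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` with the standard branch-length
#' formulas. Negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch; `Q` ties are broken by the smallest `(i, j)`
#' pair in matrix order. Exact on additive matrices.
#'
#' @param dm Symmetric distance matrix with labelled rows/columns (at least
#'   3 taxa, zero diagonal, no `NA`).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) stop("distance matrix must be labelled",
                                  call. = FALSE)
  if (anyNA(dm)) stop("distance matrix contains NA", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-8 || any(abs(diag(dm)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  if (any(dm < 0)) stop("distances must be nonnegative", call. = FALSE)
  labs <- rownames(dm)
  node <- labs          # newick fragment per active node
  D <- dm
  while (length(node) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    # smallest (i, j), i < j, in current matrix order
    hit <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_node <- sprintf("(%s:%.15g,%s:%.15g)", node[i], bi, node[j], bj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "..new..")
    D <- D2
    node <- c(node[keep], new_node)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b1 <- max(0, (d12 + d13 - d23) / 2)
  b2 <- max(0, (d12 + d23 - d13) / 2)
  b3 <- max(0, (d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 node[1], b1, node[2], b2, node[3], b3)
  ape::read.tree(text = txt)
}

## Encode aligned sequences as bit-state integer matrices for Fitch.
## Gaps, N and any ambiguity code become (partial) wildcards.
encode_states <- function(alignment) {
  chars <- strsplit(alignment, "", fixed = TRUE)
  lapply(chars, function(ch) {
    b <- IUPAC_BITS[ch]
    b[is.na(b)] <- 15L
    unname(b)
  })
}

#' Fitch small-parsimony score
#'
#' Minimum number of state changes over all alignment columns on the given
#' (binary) tree topology. Gaps and N are missing data (full wildcards) and
#' never force a change.
#'
#' @param tree A `phylo` tree (rooted or unrooted, binary).
#' @param alignment Named character vector of equal-length aligned sequences
#'   covering every tip label.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, alignment) {
  missing <- setdiff(tree$tip.label, names(alignment))
  if (length(missing)) {
    stop("no sequence for leaf/leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr <- tree
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE)
  }
  if (!ape::is.binary(tr)) {
    stop("tree must be binary", call. = FALSE)
  }
  tr <- stats::reorder(tr, "postorder")
  ntip <- length(tr$tip.label)
  enc <- encode_states(alignment[tr$tip.label])
  ncol <- length(enc[[1L]])
  states <- vector("list", ntip + tr$Nnode)
  states[seq_len(ntip)] <- enc
  score <- integer(ncol)
  parents <- tr$edge[, 1L]
  children <- tr$edge[, 2L]
  for (nd in unique(parents)) {
    ch <- children[parents == nd]
    s <- states[[ch[1L]]]
    for (k in ch[-1L]) {
      inter <- bitwAnd(s, states[[k]])
      zero <- inter == 0L
      score <- score + zero
      s <- ifelse(zero, bitwOr(s, states[[k]]), inter)
    }
    states[[nd]] <- s
  }
  sum(score)
}

## Attach a new tip to edge `edge_idx` of a phylo tree (topology surgery).
attach_tip <- function(tree, edge_idx, label) {
  ntip <- length(tree$tip.label)
  E <- tree$edge
  # renumber: internal nodes shift by 1 to make room for the new tip
  E[E > ntip] <- E[E > ntip] + 1L
  new_tip <- ntip + 1L
  w <- ntip + 1L + tree$Nnode + 1L   # id of the new internal node
  u <- E[edge_idx, 1L]; v <- E[edge_idx, 2L]
  E[edge_idx, ] <- c(u, w)
  E <- rbind(E, c(w, v), c(w, new_tip))
  el <- tree$edge.length
  if (!is.null(el)) {
    half <- el[edge_idx] / 2
    el[edge_idx] <- half
    el <- c(el, half, 0)
  }
  out <- list(edge = E, tip.label = c(tree$tip.label, label),
              Nnode = tree$Nnode + 1L, edge.length = el)
  class(out) <- "phylo"
  stats::reorder(out, "cladewise")
}

#' Parsimony placement of a query sequence
#'
#' The query is profile-aligned against the consensus of the reference
#' alignment, attached in turn to every branch of the reference tree, and
#' scored with [fitch_score()]; the branch minimising the score wins (ties
#' go to the branch occurring first in preorder). Exhaustive, hence exact at
#' this scale.
#'
#' @param query DNA string (unaligned).
#' @param tree Reference `phylo` tree over the alignment's sequence names.
#' @param ref_alignment Named character vector of equal-length aligned
#'   reference sequences.
#' @param query_label Tip label given to the query.
#' @return List with `best_edge` (index into `scores`), `scores` (data.frame
#'   `edge`, `parent`, `child`, `child_label`, `score` in preorder), and
#'   `aligned_query`.
#' @export
parsimony_place <- function(query, tree, ref_alignment,
                            query_label = "QUERY") {
  tr <- stats::reorder(tree, "cladewise")
  aligned_query <- align_to_alignment(query, ref_alignment)
  aln <- c(ref_alignment,
           stats::setNames(aligned_query, query_label))
  nedge <- nrow(tr$edge)
  scores <- integer(nedge)
  for (e in seq_len(nedge)) {
    scores[e] <- fitch_score(attach_tip(tr, e, query_label), aln)
  }
  ntip <- length(tr$tip.label)
  child <- tr$edge[, 2L]
  tab <- data.frame(edge = seq_len(nedge), parent = tr$edge[, 1L],
                    child = child,
                    child_label = ifelse(child <= ntip,
                                         tr$tip.label[child], ""),
                    score = scores, stringsAsFactors = FALSE)
  list(best_edge = which.min(scores), scores = tab,
       aligned_query = aligned_query)
}

#' Project a query into an existing alignment's columns
#'
#' The query is globally aligned to the (degapped) majority consensus of the
#' alignment; its bases are then placed into the corresponding alignment
#' columns. Query insertions relative to the consensus are dropped;
#' uncovered columns become gaps.
#'
#' @param query DNA string.
#' @param ref_alignment Named character vector of aligned sequences.
#' @return The aligned query string (same length as the alignment columns).
#' @export
align_to_alignment <- function(query, ref_alignment) {
  chars <- do.call(rbind, strsplit(ref_alignment, "", fixed = TRUE))
  ncol <- ncol(chars)
  cons <- vapply(seq_len(ncol), function(j) {
    col <- chars[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) return("-")
    tab <- table(col)
    sort(names(tab)[tab == max(tab)])[1L]
  }, character(1))
  keep <- which(cons != "-")
  cons_str <- paste(cons[keep], collapse = "")
  pr <- project_onto_reference(query, cons_str)
  out <- rep("-", ncol)
  idx <- pr$first:pr$last
  out[keep[idx]] <- pr$cols
  paste(out, collapse = "")
}

#' Write / read Newick trees
#'
#' Thin wrappers around `ape::write.tree` / `ape::read.tree` that round-trip
#' topology and branch lengths (at least 6 decimals) and turn malformed
#' input into an error.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick in ", path, call. = FALSE)
  tr
}
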