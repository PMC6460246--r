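#' Construct a multiple sequence alignment object
#'
#' Rows are gapped residue strings of equal length; `-` marks a gap. Every
#' column must contain at least one residue and row ids must be unique.
#'
#' @param id character vector of row ids.
#' @param aligned character vector of gapped residue strings.
#' @return An object of class `msa` with fields `id`, `aligned`, `n_rows`,
#'   `n_columns`.
#' @export
msa <- function(id, aligned) {
  id <- as.character(id); aligned <- toupper(as.character(aligned))
  if (length(id) != length(aligned)) stop("id and aligned lengths differ")
  if (anyDuplicated(id)) stop("duplicate row ids in alignment")
  w <- unique(nchar(aligned))
  if (length(w) > 1) stop("alignment rows have unequal lengths")
  n_col <- if (length(aligned)) w else 0L
  if (length(aligned)) {
    m <- msa_matrix_chr(aligned)
    if (any(colSums(m != "-") == 0)) stop("alignment contains all-gap columns")
  }
  structure(list(id = id, aligned = aligned,
                 n_rows = length(id), n_columns = n_col),
            class = "msa")
}

msa_matrix_chr <- function(aligned) {
  matrix(unlist(strsplit(aligned, "", fixed = TRUE), use.names = FALSE),
         nrow = length(aligned), byrow = TRUE)
}

#' Character matrix view of an alignment
#' @param x an [msa].
#' @return A rows x columns character matrix with row names set to ids.
#' @export
msa_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  m <- msa_matrix_chr(x$aligned)
  rownames(m) <- x$id
  m
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", x$n_rows, " rows x ", x$n_columns, " columns\n", sep = "")
  n <- min(x$n_rows, 6L)
  for (i in seq_len(n))
    cat(sprintf("  %-20s %s\n", x$id[i], substr(x$aligned[i], 1, 50)))
  if (x$n_rows > n) cat("  ...\n")
  invisible(x)
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' @param path input file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return An [msa].
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    id <- sub("[[:space:]].*$", "", names(ss))
    msa(id, toupper(as.character(ss)))
  } else {
    al <- seqinr::read.alignment(path, format = "clustal")
    msa(al$nam, toupper(unlist(al$seq)))
  }
}

#' Write a multiple alignment
#'
#' @param x an [msa].
#' @param path output file.
#' @param format `"fasta"` or `"clustal"`.
#' @param width wrap width.
#' @export
write_msa <- function(x, path, format = c("fasta", "clustal"), width = 60L) {
  stopifnot(inherits(x, "msa"))
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(x$aligned)
    names(ss) <- x$id
    Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("CLUSTAL W multiple sequence alignment\n", con)
    namew <- max(nchar(x$id)) + 3
    for (start in seq(1, max(x$n_columns, 1), by = width)) {
      for (i in seq_len(x$n_rows))
        writeLines(sprintf("%-*s%s", namew, x$id[i],
                           substr(x$aligned[i], start,
                                  min(start + width - 1, x$n_columns))), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

# p-distance between two gapped rows under pairwise deletion
row_p_distance <- function(ca, cb) {
  shared <- ca != "-" & cb != "-"
  n <- sum(shared)
  if (n == 0) return(NA_real_)
  sum(ca[shared] != cb[shared]) / n
}

#' Progressive multiple sequence alignment
#'
#' A deliberately simple progressive aligner: the guide tree is a
#' neighbor-joining tree on p-distances taken from all pairwise global
#' alignments, and profiles are merged leaf-to-root by profile--profile
#' global alignment with sum-of-pairs (expected substitution) scoring. No
#' iterative refinement is performed; externally computed alignments can be
#' supplied to downstream stages instead via [read_msa].
#'
#' @param seqs a protein [seq_set] with at least two sequences.
#' @param scheme a [scoring_scheme].
#' @return An [msa] whose rows, after removing gaps, reproduce the input
#'   sequences exactly (input order preserved).
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(inherits(seqs, "seq_set"))
  n <- length(seqs)
  if (n < 2) stop("progressive alignment needs at least 2 sequences")
  if (n == 2) {
    al <- global_align(seqs$seq[[1]], seqs$seq[[2]], scheme)
    return(msa(seqs$id, c(al$aligned_query, al$aligned_subject)))
  }
  # guide distances from pairwise global alignments
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- global_align(seqs$seq[[i]], seqs$seq[[j]], scheme)
    ca <- strsplit(al$aligned_query, "")[[1]]
    cb <- strsplit(al$aligned_subject, "")[[1]]
    d[i, j] <- d[j, i] <- row_p_distance(ca, cb)
  }
  guide <- neighbor_joining(d)
  merge_order_align(seqs, guide, scheme)
}

aa20 <- function() PROTEIN_ALPHABET[PROTEIN_ALPHABET != "X"]

profile_of <- function(rows) {
  # 20 x L frequency matrix; gaps (and X) carry no mass
  m <- msa_matrix_chr(rows)
  aas <- aa20()
  f <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = aas))
    as.numeric(tab) / nrow(m)
  }, numeric(20))
  rownames(f) <- aas
  f
}

merge_two <- function(rows1, rows2, scheme) {
  aas <- aa20()
  sub <- scheme$submat[aas, aas]
  res <- cpp_profile_align(profile_of(rows1), profile_of(rows2), sub,
                           scheme$gap_open, scheme$gap_extend)
  expand <- function(rows, idx) {
    m <- msa_matrix_chr(rows)
    out <- matrix("-", nrow(m), length(idx))
    out[, idx != 0] <- m[, idx[idx != 0], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  c(expand(rows1, res$idx1), expand(rows2, res$idx2))
}

merge_order_align <- function(seqs, guide, scheme) {
  # post-order merge over the (unrooted) guide tree, rooted at ape's root node
  edge <- guide$edge
  ntip <- length(guide$tip.label)
  children <- split(edge[, 2], edge[, 1])
  align_node <- function(node) {
    if (node <= ntip) {
      lab <- guide$tip.label[node]
      r <- seqs$seq[[match(lab, seqs$id)]]
      names(r) <- lab
      return(r)
    }
    kids <- children[[as.character(node)]]
    acc <- NULL
    for (k in kids) {
      sub <- align_node(k)
      acc <- if (is.null(acc)) sub else {
        merged <- merge_two(acc, sub, scheme)
        names(merged) <- c(names(acc), names(sub))
        merged
      }
    }
    acc
  }
  root <- ntip + 1L
  rows <- align_node(root)
  rows <- rows[match(seqs$id, names(rows))]
  msa(seqs$id, unname(rows))
}
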