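PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                      "M","N","P","Q","R","S","T","V","W","Y","X")
NUCLEOTIDE_ALPHABET <- c("A","C","G","T","N")

alphabet_chars <- function(alphabet) {
  switch(alphabet,
         protein    = PROTEIN_ALPHABET,
         nucleotide = NUCLEOTIDE_ALPHABET,
         stop("unknown alphabet: ", alphabet))
}

#' Construct a sequence set
#'
#' A `seq_set` is an ordered, id-indexed collection of protein or nucleotide
#' sequences -- the container passed between every stage of the screening
#' pipeline. Residues are stored as uppercase strings over the 20-residue
#' protein alphabet plus `X`, or over `ACGTN` for nucleotides.
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param seq character vector of residue strings (same length as `id`).
#' @param desc optional character vector of free-text descriptions.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return An object of class `seq_set`.
#' @examples
#' s <- seq_set(c("a", "b"), c("MKV", "MKL"))
#' length(s)
#' @export
seq_set <- function(id, seq, desc = NULL, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (is.null(desc)) desc <- rep("", length(id))
  desc <- as.character(desc)
  if (length(id) != length(seq) || length(id) != length(desc))
    stop("id, seq and desc must have equal length")
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(grepl("[[:space:]]", id)))
    stop("sequence ids must not contain whitespace")
  if (length(seq) && any(!nzchar(seq)))
    stop("empty residue string for id: ", paste(id[!nzchar(seq)], collapse = ", "))
  ok <- alphabet_chars(alphabet)
  for (i in seq_along(seq)) {
    ch <- unique(strsplit(seq[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(ch, ok)
    if (length(bad))
      stop("record '", id[[i]], "': illegal ", alphabet, " character(s): ",
           paste(bad, collapse = ""))
  }
  structure(list(id = id, desc = desc, seq = seq, alphabet = alphabet),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
`[.seq_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  seq_set(x$id[i], x$seq[i], x$desc[i], x$alphabet)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> ", length(x), " ", x$alphabet, " sequence(s)\n", sep = "")
  n <- min(length(x), 6L)
  if (n) {
    w <- nchar(x$seq[seq_len(n)])
    for (i in seq_len(n))
      cat(sprintf("  %-20s %6d %s\n", x$id[i], w[i],
                  substr(x$seq[i], 1, 40)))
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Look up one sequence by id
#'
#' @param x a `seq_set`.
#' @param id a single sequence id.
#' @return The residue string, or an error when the id is absent.
#' @export
get_seq <- function(x, id) {
  stopifnot(inherits(x, "seq_set"))
  i <- match(id, x$id)
  if (is.na(i)) stop("no sequence with id '", id, "'")
  x$seq[[i]]
}

#' Read a FASTA file
#'
#' Records are uppercased on input and, for protein files, a single trailing
#' `*` stop character is stripped. Characters outside the declared alphabet
#' raise a parse error naming the offending record.
#'
#' @param path path to a (multi-record) FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A [seq_set] preserving record order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(seq_set(character(), character(), alphabet = alphabet))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path,
                                          "': ", conditionMessage(e)))
  hdr <- names(ss)
  id <- sub("[[:space:]].*$", "", hdr)
  desc <- ifelse(grepl("[[:space:]]", hdr),
                 sub("^[^[:space:]]+[[:space:]]+", "", hdr), "")
  seqs <- toupper(as.character(ss))
  if (alphabet == "protein") seqs <- sub("\\*$", "", seqs)
  names(seqs) <- NULL
  seq_set(id, seqs, desc, alphabet)
}

#' Write a FASTA file
#'
#' Round-trips exactly with [read_fasta]: ids, descriptions and residues are
#' preserved.
#'
#' @param x a [seq_set].
#' @param path output path.
#' @param width line-wrap width in residues (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "seq_set"), width >= 1)
  if (!length(x)) { file.create(path); return(invisible(path)) }
  ss <- Biostrings::BStringSet(x$seq)
  names(ss) <- ifelse(nzchar(x$desc), paste(x$id, x$desc), x$id)
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Remove exact-duplicate sequences
#'
#' The screening stage of the pipeline retains a single representative per
#' distinct residue string ("only one of identical sequences"): the
#' first-occurring record wins, so the result is deterministic and
#' order-stable. Near-duplicates are retained.
#'
#' @param x a [seq_set].
#' @return A list with elements `seqs` (the deduplicated [seq_set]) and
#'   `duplicates` (named character vector mapping each removed id to the id
#'   of its retained representative).
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "seq_set"))
  first <- !duplicated(x$seq)
  rep_id <- x$id[first][match(x$seq, x$seq[first])]
  dup <- stats::setNames(rep_id[!first], x$id[!first])
  list(seqs = x[which(first)], duplicates = dup)
}
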