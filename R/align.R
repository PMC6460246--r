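#' Scoring scheme for protein alignment
#'
#' Substitution matrix plus affine gap penalties. The default is the BLASTp
#' convention: BLOSUM62 with gap open 11 and gap extension 1, so a gap of
#' length L costs `11 + L`.
#'
#' @param matrix substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM30"`, `"PAM70"`, `"PAM250"`) or a symmetric numeric
#'   matrix with residue dimnames.
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend gap extension penalty (positive, `<= gap_open`).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    m <- get(matrix, envir = e)
    name <- matrix
  } else {
    m <- matrix
    name <- "custom"
  }
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend > 0))
    stop("require gap_open >= gap_extend > 0")
  structure(list(name = name, submat = m,
                 alphabet = paste(rownames(m), collapse = ""),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$name, ", gap open ", x$gap_open,
      ", extend ", x$gap_extend, "\n", sep = "")
  invisible(x)
}

new_pairwise_alignment <- function(raw, query, subject, type,
                                   identity_denominator = "columns") {
  cols <- nchar(raw$aligned_a)
  if (cols > 0) {
    qa <- strsplit(raw$aligned_a, "")[[1]]
    sa <- strsplit(raw$aligned_b, "")[[1]]
    ident <- sum(qa == sa & qa != "-")
    denom <- if (identity_denominator == "columns") cols
             else sum(qa != "-" & sa != "-")
    identity <- if (denom > 0) 100 * ident / denom else 0
  } else {
    identity <- 0
  }
  qlen <- nchar(query)
  cover <- if (type == "global" || is.na(raw$a_start)) {
    if (type == "global") 100 else 0
  } else 100 * (raw$a_end - raw$a_start + 1) / qlen
  structure(list(type = type, score = raw$score,
                 aligned_query = raw$aligned_a, aligned_subject = raw$aligned_b,
                 query_start = raw$a_start, query_end = raw$a_end,
                 subject_start = raw$b_start, subject_end = raw$b_end,
                 identity_percent = identity, query_cover_percent = cover,
                 alignment_length = cols,
                 no_hit = (type == "local" && cols == 0)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$type, ", score ", format(x$score),
      ", identity ", sprintf("%.1f%%", x$identity_percent),
      ", cover ", sprintf("%.1f%%", x$query_cover_percent), "\n", sep = "")
  if (x$no_hit) cat("  (no hit)\n")
  invisible(x)
}

align_input <- function(x) {
  if (inherits(x, "seq_set")) {
    if (length(x) != 1) stop("expected a single sequence")
    x$seq[[1]]
  } else toupper(as.character(x))
}

#' Global pairwise alignment (Needleman--Wunsch, affine gaps)
#'
#' Optimal global alignment score under affine gap penalties, with a fixed
#' traceback tie-break (match preferred over a gap in the subject, over a gap
#' in the query), so the reported alignment is deterministic.
#'
#' @param a,b protein residue strings (query and subject).
#' @param scheme a [scoring_scheme].
#' @param identity_denominator `"columns"` (BLAST convention, gaps count in
#'   the denominator; default) or `"ungapped"` (gapless column pairs only).
#' @return A `pairwise_alignment` with percent identity over the chosen
#'   denominator.
#' @export
global_align <- function(a, b, scheme = scoring_scheme(),
                         identity_denominator = c("columns", "ungapped")) {
  identity_denominator <- match.arg(identity_denominator)
  a <- align_input(a); b <- align_input(b)
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  raw <- cpp_pairwise_align(a, b, scheme$submat, scheme$alphabet,
                            scheme$gap_open, scheme$gap_extend, FALSE)
  new_pairwise_alignment(raw, a, b, "global", identity_denominator)
}

#' Local pairwise alignment (Smith--Waterman, affine gaps)
#'
#' Emulates a BLASTp-style comparison: percent identity is computed over all
#' alignment columns (gaps included), and query cover is the fraction of the
#' query spanned by the reported local alignment. A pair with no
#' positive-scoring alignment is reported as a no-hit.
#'
#' @inheritParams global_align
#' @return A `pairwise_alignment`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(),
                        identity_denominator = c("columns", "ungapped")) {
  identity_denominator <- match.arg(identity_denominator)
  a <- align_input(a); b <- align_input(b)
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  raw <- cpp_pairwise_align(a, b, scheme$submat, scheme$alphabet,
                            scheme$gap_open, scheme$gap_extend, TRUE)
  new_pairwise_alignment(raw, a, b, "local", identity_denominator)
}

#' Screen a database for homologs of query sequences
#'
#' For each query, local alignments against every database sequence are
#' computed and the up-to-`top_n` highest-identity subjects with identity
#' strictly greater than `min_identity` are returned, sorted by identity
#' (descending) then subject id (ascending). Self-hits (same id) are
#' excluded. The result is invariant to database input order.
#'
#' @param queries,db protein [seq_set]s.
#' @param min_identity identity threshold, percent; strict `>` (default 40).
#' @param top_n maximum hits per query (default 100).
#' @param min_cover optional query-cover floor, percent; `NULL` (default)
#'   disables it.
#' @param scheme a [scoring_scheme].
#' @return Data frame with columns `query`, `subject`, `identity_percent`,
#'   `query_cover_percent`, `alignment_length`.
#' @export
screen_homologs <- function(queries, db, min_identity = 40, top_n = 100,
                            min_cover = NULL, scheme = scoring_scheme()) {
  stopifnot(inherits(queries, "seq_set"), inherits(db, "seq_set"))
  out <- list()
  for (qi in seq_along(queries$id)) {
    q <- queries$seq[[qi]]; qid <- queries$id[[qi]]
    rows <- lapply(seq_along(db$id), function(si) {
      if (db$id[[si]] == qid) return(NULL)
      al <- local_align(q, db$seq[[si]], scheme)
      if (al$no_hit) return(NULL)
      data.frame(query = qid, subject = db$id[[si]],
                 identity_percent = al$identity_percent,
                 query_cover_percent = al$query_cover_percent,
                 alignment_length = al$alignment_length,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) next
    keep <- tab$identity_percent > min_identity
    if (!is.null(min_cover)) keep <- keep & tab$query_cover_percent >= min_cover
    tab <- tab[keep, , drop = FALSE]
    tab <- tab[order(-tab$identity_percent, tab$subject), , drop = FALSE]
    out[[qid]] <- utils::head(tab, top_n)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(query = character(), subject = character(),
                      identity_percent = numeric(),
                      query_cover_percent = numeric(),
                      alignment_length = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write a homolog hit table
#'
#' Tab-separated with fixed column order: query, subject, identity, cover,
#' length.
#'
#' @param hits data frame from [screen_homologs].
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
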