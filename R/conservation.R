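#' Column-wise conservation profile of an alignment
#'
#' For every alignment column: residue counts, the dominant residue and its
#' conservation (dominant count over *all* rows, so 100% means literally
#' universal presence), the runner-up residue, the gap fraction, and the
#' 1-based position of the column in a designated ungapped reference row
#' (absent where the reference is gapped).
#'
#' @param x an [msa].
#' @param reference_id id of the reference row used for coordinate mapping.
#' @param denominator `"all"` (default; gapped rows count in the
#'   denominator) or `"nongap"`.
#' @return An object of class `conservation_profile` with a per-column table
#'   and the raw residue-count matrix.
#' @export
build_profile <- function(x, reference_id, denominator = c("all", "nongap")) {
  stopifnot(inherits(x, "msa"))
  denominator <- match.arg(denominator)
  ri <- match(reference_id, x$id)
  if (is.na(ri)) stop("unknown reference id '", reference_id, "'")
  m <- msa_matrix(x)
  aas <- PROTEIN_ALPHABET
  counts <- vapply(seq_len(ncol(m)), function(j)
    vapply(aas, function(a) sum(m[, j] == a), integer(1)), integer(length(aas)))
  rownames(counts) <- aas
  gap_count <- colSums(m == "-")
  denom <- if (denominator == "all") rep(x$n_rows, ncol(m)) else x$n_rows - gap_count
  top2 <- apply(counts, 2, function(cc) {
    o <- order(-cc, names(cc))  # ties broken alphabetically
    c(o[1], o[2])
  })
  dominant <- aas[top2[1, ]]
  dom_count <- counts[cbind(top2[1, ], seq_len(ncol(m)))]
  runner_up <- aas[top2[2, ]]
  run_count <- counts[cbind(top2[2, ], seq_len(ncol(m)))]
  runner_up[run_count == 0] <- NA
  ref_chars <- m[ri, ]
  ref_position <- ifelse(ref_chars != "-", cumsum(ref_chars != "-"), NA_integer_)
  tab <- data.frame(
    column = seq_len(ncol(m)),
    ref_position = as.integer(ref_position),
    dominant = dominant,
    conservation = dom_count / pmax(denom, 1),
    runner_up = runner_up,
    runner_up_fraction = run_count / pmax(denom, 1),
    gap_fraction = gap_count / x$n_rows,
    stringsAsFactors = FALSE)
  structure(list(reference = reference_id, n_rows = x$n_rows,
                 denominator = denominator, table = tab, counts = counts),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> reference '", x$reference, "', ",
      nrow(x$table), " columns, ", x$n_rows, " rows\n", sep = "")
  invisible(x)
}

#' Per-column information content (logo stack height)
#'
#' `log2(20)` minus the Shannon entropy of the residue frequency
#' distribution; gaps are excluded from the distribution and frequencies
#' renormalized (the standard sequence-logo convention; no small-sample
#' correction is applied).
#'
#' @param profile a [build_profile] result.
#' @return Numeric vector of bits, one per column.
#' @export
information_content <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  apply(profile$counts, 2, function(cc) {
    tot <- sum(cc)
    if (tot == 0) stop("all-gap column has no information content")
    p <- cc[cc > 0] / tot
    log2(20) + sum(p * log2(p))
  })
}

#' Extract signature regions from a conservation profile
#'
#' A signature region is a maximal run of columns that begins and ends at
#' columns with conservation at least `tau`, contains at least
#' `min_conserved` such columns, and has no interior stretch of more than
#' `max_wildcard_run` consecutive sub-threshold columns. Sub-threshold
#' interior columns become wildcard (`X`) positions; columns whose gap
#' fraction reaches `optional_gap_min` become optional (`(X,0)`) positions.
#' Conserved positions record the dominant residue and its conservation as
#' the weight; when the runner-up fraction reaches 0.25 a two-residue
#' allowed set is recorded.
#'
#' @param profile a [build_profile] result.
#' @param tau conservation threshold in `[0,1]` (default 0.47, the weakest
#'   conserved position published for the family).
#' @param max_wildcard_run maximal interior run of sub-threshold columns
#'   (default 3).
#' @param optional_gap_min gap fraction from which a position counts as
#'   optional (default 0.5).
#' @param min_conserved minimal number of conserved columns per region
#'   (default 4).
#' @return A list of [signature_motif] objects (possibly empty), anchored in
#'   reference coordinates.
#' @export
extract_signature_regions <- function(profile, tau = 0.47,
                                      max_wildcard_run = 3,
                                      optional_gap_min = 0.5,
                                      min_conserved = 4) {
  stopifnot(inherits(profile, "conservation_profile"))
  tab <- profile$table
  if (!nrow(tab)) return(list())
  cons_idx <- which(tab$conservation >= tau)
  if (!length(cons_idx)) return(list())
  breaks <- which(diff(cons_idx) > max_wildcard_run + 1)
  grp <- cumsum(c(1, seq_along(cons_idx)[-1] %in% (breaks + 1)))
  motifs <- list()
  for (g in unique(grp)) {
    idx <- cons_idx[grp == g]
    if (length(idx) < min_conserved) next
    cols <- idx[1]:idx[length(idx)]
    sub <- tab[cols, , drop = FALSE]
    conserved <- sub$conservation >= tau
    kind <- ifelse(conserved, "fixed",
                   ifelse(sub$gap_fraction >= optional_gap_min,
                          "optional", "wildcard"))
    allowed <- ifelse(conserved,
                      ifelse(!is.na(sub$runner_up) &
                               sub$runner_up_fraction >= 0.25,
                             paste0(sub$dominant, sub$runner_up),
                             sub$dominant),
                      "")
    weight <- ifelse(conserved, sub$conservation, 0)
    ref_pos <- sub$ref_position
    if (anyNA(ref_pos)) ref_pos <- sub$column  # reference gapped: fall back
    name <- paste0("region_", length(motifs) + 1)
    motifs[[name]] <- signature_motif(
      name, data.frame(ref_pos = ref_pos, kind = kind, allowed = allowed,
                       weight = weight, stringsAsFactors = FALSE))
  }
  motifs
}

#' Export a logo table
#'
#' Tab-separated matrix, one row per alignment column: column index,
#' reference position, per-residue frequencies over all rows (so that the
#' frequencies plus the gap fraction sum to 1), gap fraction, and
#' gap-excluded information content in bits.
#'
#' @param profile a [build_profile] result.
#' @param path output path.
#' @export
export_logo_table <- function(profile, path) {
  stopifnot(inherits(profile, "conservation_profile"))
  freq <- t(profile$counts) / profile$n_rows
  out <- data.frame(column = profile$table$column,
                    ref_position = profile$table$ref_position,
                    round(freq, 6),
                    gap_fraction = round(profile$table$gap_fraction, 6),
                    information_bits = round(information_content(profile), 6),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
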