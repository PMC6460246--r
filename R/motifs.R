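#' Construct a signature motif
#'
#' An anchored run of positions in reference (PB2SF) coordinates. Each
#' position is `fixed` (a 1--2 residue allowed set with a conservation
#' weight), `wildcard` (`X`: unconstrained, always occupied) or `optional`
#' (`(X,0)`: absent in part of the family). The first and last positions
#' must be fixed and `ref_pos` must be strictly increasing.
#'
#' @param name motif label (the five built-ins are `A`--`E`).
#' @param positions data frame with columns `ref_pos` (integer), `kind`,
#'   `allowed` (string of allowed residues, `""` or `"."` for none) and
#'   `weight` in `[0,1]`.
#' @return An object of class `signature_motif`.
#' @export
signature_motif <- function(name, positions) {
  p <- positions
  p$allowed[p$allowed == "."] <- ""
  p$ref_pos <- as.integer(p$ref_pos)
  p$weight <- as.numeric(p$weight)
  if (!all(p$kind %in% c("fixed", "wildcard", "optional")))
    stop("motif '", name, "': unknown position kind")
  if (any(diff(p$ref_pos) <= 0))
    stop("motif '", name, "': ref_pos must be strictly increasing")
  if (any(p$weight < 0 | p$weight > 1))
    stop("motif '", name, "': weights must lie in [0,1]")
  fixed <- p$kind == "fixed"
  if (!fixed[1] || !fixed[nrow(p)])
    stop("motif '", name, "': first and last positions must be fixed")
  if (any(fixed & (!nzchar(p$allowed) | p$weight <= 0)))
    stop("motif '", name, "': fixed positions need residues and weight > 0")
  if (any(!fixed & (nzchar(p$allowed) | p$weight != 0)))
    stop("motif '", name, "': wildcard/optional positions carry no residues")
  if (any(nchar(p$allowed) > 2))
    stop("motif '", name, "': allowed sets hold at most two residues")
  structure(list(name = name, positions = p, anchor = p$ref_pos[1]),
            class = "signature_motif")
}

#' @export
print.signature_motif <- function(x, ...) {
  p <- x$positions
  lab <- ifelse(p$kind == "fixed",
                paste0(p$allowed, p$ref_pos,
                       "(", sprintf("%.0f%%", 100 * p$weight), ")"),
                ifelse(p$kind == "optional", paste0("(X,0)", p$ref_pos),
                       paste0("X", p$ref_pos)))
  cat("<signature_motif> ", x$name, " [", x$anchor, "-",
      p$ref_pos[nrow(p)], "]: ", paste(lab, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Read a motif definition file
#'
#' Tab-separated, one position per line (`motif`, `ref_pos`, `kind`,
#' `allowed`, `weight`), `#` comments allowed. Validation errors are raised
#' for weights outside `[0,1]` or non-increasing positions.
#'
#' @param path motif file.
#' @return Named list of [signature_motif] objects, in file order.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = c("character", "integer", "character",
                                          "character", "numeric"))
  out <- list()
  for (nm in unique(tab$motif))
    out[[nm]] <- signature_motif(nm, tab[tab$motif == nm,
                                         c("ref_pos", "kind", "allowed", "weight")])
  out
}

#' Write a motif definition file
#'
#' Inverse of [read_motifs]; write-then-read is the identity.
#'
#' @param motifs list of [signature_motif] objects.
#' @param path output path.
#' @export
write_motifs <- function(motifs, path) {
  rows <- do.call(rbind, lapply(motifs, function(m) {
    p <- m$positions
    data.frame(motif = m$name, ref_pos = p$ref_pos, kind = p$kind,
               allowed = ifelse(nzchar(p$allowed), p$allowed, "."),
               weight = p$weight, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The five built-in PB2SF-anchored signature motifs
#'
#' The published signature motifs of the bacterial
#' Delta-4,5-hexuronate-2-O-sulfatase family (regions A--E, anchored at
#' PB2SF positions 44, 86, 194, 301 and 417), with per-position conservation
#' weights, wildcard and optional positions. The transcription lives in a
#' single data file (`extdata/pb2sf_motifs.tsv`) so it can be corrected
#' without code changes.
#'
#' @return Named list of five [signature_motif] objects (`A`--`E`).
#' @export
builtin_pb2sf_motifs <- function() {
  read_motifs(system.file("extdata", "pb2sf_motifs.tsv", package = "sulfsig",
                          mustWork = TRUE))
}

#' Catalytic-residue annotation of the PB2SF reference
#'
#' The experimentally probed catalytic positions: the FGly-precursor C92
#' (C or S accepted, per the family core motif Cys/Ser-X-Pro-X-Arg) and the
#' six residues whose substitution abolishes or cripples activity.
#'
#' @return Data frame with columns `position`, `expected`, `note`.
#' @export
pb2sf_catalytic_sites <- function() {
  data.frame(
    position = c(52L, 92L, 113L, 141L, 143L, 205L, 310L),
    expected = c("D", "CS", "N", "K", "H", "H", "H"),
    note = c("essential (inactive when substituted)",
             "FGly precursor (core motif C/S-X-P-X-R)",
             "minor role", "basic pocket", "basic pocket",
             "imidazole essential", "essential (inactive when substituted)"),
    stringsAsFactors = FALSE)
}

#' Consensus string of one motif
#'
#' Fixed positions contribute their first allowed residue; wildcard and
#' (included) optional positions contribute `fill`.
#'
#' @param motif a [signature_motif].
#' @param fill residue used at unconstrained positions.
#' @param include_optional include optional positions in the string?
#' @return A residue string spanning the motif.
#' @export
motif_consensus <- function(motif, fill = "A", include_optional = TRUE) {
  p <- motif$positions
  keep <- p$kind != "optional" | include_optional
  ch <- ifelse(p$kind == "fixed", substr(p$allowed, 1, 1), fill)
  paste(ch[keep], collapse = "")
}

#' Positive-control scaffold built from motif consensi
#'
#' Lays each motif's consensus at its reference anchor inside a `fill`
#' background, reproducing the reference inter-motif spacing; used as a
#' positive control for the scanner.
#'
#' @param motifs list of [signature_motif]s (default: the five built-ins).
#' @param fill background residue.
#' @param length total length (default: last motif position).
#' @return A protein residue string.
#' @export
consensus_scaffold <- function(motifs = builtin_pb2sf_motifs(), fill = "A",
                               length = NULL) {
  last <- max(vapply(motifs, function(m) max(m$positions$ref_pos), integer(1)))
  if (is.null(length)) length <- last
  if (length < last) stop("scaffold shorter than the last motif position")
  ch <- rep(fill, length)
  for (m in motifs) {
    p <- m$positions
    fixed <- p$kind == "fixed"
    ch[p$ref_pos[fixed]] <- substr(p$allowed[fixed], 1, 1)
  }
  paste(ch, collapse = "")
}
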