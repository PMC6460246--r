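# Average (not monoisotopic) residue masses, Da; water added once per chain.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# Bjellqvist pKa set (ExPASy convention).
PK_SIDE  <- c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
              R = 12.00, Y = 10.00)
PK_NTERM <- c(A = 7.59, E = 7.70, M = 7.00, P = 8.36, S = 6.93,
              T = 6.82, V = 7.44)
PK_NTERM_DEFAULT <- 7.50
PK_CTERM <- c(D = 4.55, E = 4.75)
PK_CTERM_DEFAULT <- 3.55

char_counts <- function(s, letters) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  vapply(letters, function(a) sum(ch == a), integer(1))
}

#' GC content of a nucleotide sequence
#'
#' Computed as `100 * (G + C) / (A + C + G + T)`; `N` characters are excluded
#' from both numerator and denominator. Reported to one decimal place in
#' the tabular property report.
#'
#' @param seq a nucleotide residue string (or single-sequence `seq_set`).
#' @return GC content as a percentage in `[0, 100]`.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq) {
  s <- as_residues(seq, "nucleotide")
  n <- char_counts(s, c("A", "C", "G", "T"))
  tot <- sum(n)
  if (tot == 0) stop("GC content undefined: no countable (ACGT) bases")
  100 * (n[["G"]] + n[["C"]]) / tot
}

as_residues <- function(seq, alphabet) {
  if (inherits(seq, "seq_set")) {
    if (length(seq) != 1) stop("expected a single sequence")
    if (seq$alphabet != alphabet) stop("expected a ", alphabet, " sequence")
    return(seq$seq[[1]])
  }
  s <- toupper(as.character(seq))
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]),
                 alphabet_chars(alphabet))
  if (length(bad)) stop("illegal ", alphabet, " character(s): ",
                        paste(bad, collapse = ""))
  s
}

#' Translate a bacterial ORF
#'
#' Uses the bacterial/archaeal genetic code (translation table 11). A trailing
#' stop codon is removed; an internal stop codon or a length not divisible by
#' three is a validation error.
#'
#' @param seq nucleotide residue string (the ORF, 5' to 3').
#' @return The translated protein residue string.
#' @examples
#' translate_orf("ATGGGTTAA")  # "MG"
#' @export
translate_orf <- function(seq) {
  s <- as_residues(seq, "nucleotide")
  n <- nchar(s)
  if (n %% 3 != 0) stop("ORF length ", n, " not divisible by 3")
  code <- Biostrings::getGeneticCode("11")
  codons <- substring(s, seq(1, n, by = 3), seq(3, n, by = 3))
  aa <- unname(code[codons])
  if (anyNA(aa)) aa[is.na(aa)] <- "X"  # codons containing N
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

#' Average molecular weight of a protein
#'
#' Sum of average isotopic residue masses plus one water (18.0153 Da),
#' matching the common web-server convention. Sequences containing `X`
#' have undefined mass and raise an error.
#'
#' @param seq protein residue string.
#' @return Molecular weight in daltons.
#' @examples
#' molecular_weight("G")  # 75.07
#' @export
molecular_weight <- function(seq) {
  s <- as_residues(seq, "protein")
  if (grepl("X", s, fixed = TRUE))
    stop("molecular weight undefined for sequences containing X")
  cnt <- char_counts(s, names(RESIDUE_MASS))
  sum(cnt * RESIDUE_MASS) + WATER_MASS
}

net_charge_at <- function(counts, nterm_aa, cterm_aa, ph) {
  # basic groups: N-terminus, K, R, H side chains
  pos <- 0
  pk_n <- if (nterm_aa %in% names(PK_NTERM)) PK_NTERM[[nterm_aa]] else PK_NTERM_DEFAULT
  pos <- pos + 1 / (1 + 10^(ph - pk_n))
  for (aa in c("K", "R", "H"))
    pos <- pos + counts[[aa]] / (1 + 10^(ph - PK_SIDE[[aa]]))
  # acidic groups: C-terminus, D, E, C, Y side chains
  pk_c <- if (cterm_aa %in% names(PK_CTERM)) PK_CTERM[[cterm_aa]] else PK_CTERM_DEFAULT
  neg <- 1 / (1 + 10^(pk_c - ph))
  for (aa in c("D", "E", "C", "Y"))
    neg <- neg + counts[[aa]] / (1 + 10^(PK_SIDE[[aa]] - ph))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Henderson--Hasselbalch net charge over the termini and the D, E, C, Y, H,
#' K, R side chains with the Bjellqvist pKa set; the pI is located by
#' bisection on pH 0--14 to a tolerance of 0.001 pH units, so the net charge
#' at the returned pI is within 0.01 elementary charge of zero.
#'
#' @param seq protein residue string.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq) {
  s <- as_residues(seq, "protein")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  counts <- as.list(char_counts(s, c("D", "E", "C", "Y", "H", "K", "R")))
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (net_charge_at(counts, ch[1], ch[length(ch)], mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' ORF-level property report
#'
#' For each nucleotide ORF: length in bases, GC percentage, translated
#' protein length, average molecular weight and theoretical pI.
#'
#' @param orfs a nucleotide [seq_set].
#' @return A data frame with columns `id`, `length_nt`, `gc_percent`
#'   (one decimal), `protein_length`, `molecular_weight`, `isoelectric_point`.
#' @export
orf_properties <- function(orfs) {
  stopifnot(inherits(orfs, "seq_set"), orfs$alphabet == "nucleotide")
  rows <- lapply(seq_along(orfs$id), function(i) {
    nt <- orfs$seq[[i]]
    prot <- translate_orf(nt)
    data.frame(id = orfs$id[[i]],
               length_nt = nchar(nt),
               gc_percent = round(gc_content(nt), 1),
               protein_length = nchar(prot),
               molecular_weight = molecular_weight(prot),
               isoelectric_point = round(isoelectric_point(prot), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
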