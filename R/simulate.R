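#' Specify a planted motif
#'
#' @param motif a [signature_motif] to plant.
#' @param offset 0-based insertion offset of the motif's first position in
#'   the ancestor (default: anchor - 1, i.e. reference coordinates).
#' @param conservation per-fixed-position conservation targets in `(0, 1]`
#'   (default: the motif's own weights).
#' @param presence probability that an optional position is present in a
#'   family member (default 0.5).
#' @return An object of class `planted_motif_spec`.
#' @export
planted_motif_spec <- function(motif, offset = motif$anchor - 1L,
                               conservation = NULL, presence = 0.5) {
  stopifnot(inherits(motif, "signature_motif"))
  fixed <- motif$positions$kind == "fixed"
  if (is.null(conservation)) conservation <- motif$positions$weight[fixed]
  if (length(conservation) != sum(fixed))
    stop("one conservation target per fixed position required")
  if (any(conservation <= 0 | conservation > 1))
    stop("conservation targets must lie in (0, 1]")
  if (presence < 0 || presence > 1) stop("presence must lie in [0, 1]")
  structure(list(motif = motif, offset = as.integer(offset),
                 conservation = conservation, presence = presence),
            class = "planted_motif_spec")
}

#' Specify a synthetic protein family
#'
#' The generator emulates the statistical structure behind a conserved
#' protein family: a random ancestor with motifs planted at fixed offsets,
#' from which each family member is drawn as an independent mutant (a star
#' phylogeny, so per-column conservation has exact binomial expectations).
#'
#' @param label family label.
#' @param n number of sequences (>= 2).
#' @param length ancestor length in residues (default 510, a typical
#'   bacterial sulfatase).
#' @param background_sub per-position substitution probability outside
#'   constrained motif positions (default 0.8, i.e. background columns are
#'   weakly conserved at ~0.2).
#' @param background_indel per-position deletion probability outside motifs
#'   (default 0).
#' @param motifs list of [planted_motif_spec]s (offsets must not overlap).
#' @param positive is this family a true (motif-carrying) family? Defaults
#'   to `length(motifs) > 0`.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(label, n, length = 510L, background_sub = 0.8,
                        background_indel = 0, motifs = list(),
                        positive = length(motifs) > 0, seed) {
  if (missing(seed)) stop("family_spec requires a seed")
  if (n < 2) stop("n must be >= 2")
  if (background_sub < 0 || background_sub >= 1 ||
      background_indel < 0 || background_indel >= 1)
    stop("background probabilities must lie in [0, 1)")
  spans <- lapply(motifs, function(ms)
    ms$offset + seq_len(nrow(ms$motif$positions)))
  if (length(spans) > 1) {
    all_pos <- unlist(spans)
    if (anyDuplicated(all_pos)) stop("planted motifs overlap")
  }
  if (length(spans) && max(unlist(spans)) > length)
    stop("planted motif extends past the ancestor length")
  structure(list(label = label, n = as.integer(n), length = as.integer(length),
                 background_sub = background_sub,
                 background_indel = background_indel,
                 motifs = motifs, positive = positive,
                 seed = as.integer(seed)),
            class = "family_spec")
}

random_ancestor <- function(length) {
  paste(sample(aa20(), length, replace = TRUE), collapse = "")
}

mutate_chars <- function(ch, prob) {
  hit <- stats::runif(length(ch)) < prob
  if (any(hit)) {
    aas <- aa20()
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(aas, a), 1), "", USE.NAMES = FALSE)
  }
  ch
}

# per-ancestor-position annotation: kind, consensus target, conservation
ancestor_layout <- function(spec, anc_chars) {
  L <- spec$length
  kind <- rep("background", L)
  target <- anc_chars
  cons <- rep(NA_real_, L)
  motif_of <- rep(NA_character_, L)
  for (ms in spec$motifs) {
    p <- ms$motif$positions
    pos <- ms$offset + seq_len(nrow(p))
    kind[pos] <- p$kind
    motif_of[pos] <- ms$motif$name
    fixed <- p$kind == "fixed"
    target[pos[fixed]] <- substr(p$allowed[fixed], 1, 1)
    cons[pos[fixed]] <- ms$conservation
  }
  list(kind = kind, target = target, cons = cons, motif_of = motif_of)
}

#' Generate a synthetic protein family with planted motifs
#'
#' A random uniform-residue ancestor is drawn and the planted motifs'
#' consensus residues written in at their offsets. Each family member is an
#' independent mutant of the ancestor: at motif fixed positions the
#' consensus is kept with probability equal to the conservation target,
#' otherwise substituted uniformly among the 19 alternatives; background
#' (and wildcard) positions are substituted with the background probability;
#' optional positions are deleted with probability `1 - presence`; background
#' positions are deleted with the background indel probability. Output is
#' bit-identical for a fixed seed.
#'
#' @param spec a [family_spec].
#' @param ancestor optional pre-built ancestor string (used by
#'   [generate_dataset] to control inter-family divergence).
#' @return A list: `seqs` (unaligned [seq_set]); `alignment` (the true [msa],
#'   gaps at deleted positions; columns absent from every member are dropped
#'   and attr `"ancestor_columns"` maps alignment columns to ancestor
#'   positions); `truth` (a `truth_table`: per-sequence labels,
#'   per-(sequence, motif) realized coordinates and residues, per-position
#'   realized conservation, all in ancestor coordinates); `ancestor` (the
#'   consensus string); `layout` (per-ancestor-position kind, consensus and
#'   expected consensus frequency); `rows_full` (internal, pre-drop rows).
#' @export
generate_family <- function(spec, ancestor = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  anc <- if (is.null(ancestor)) random_ancestor(spec$length) else ancestor
  if (nchar(anc) != spec$length) stop("ancestor length mismatch")
  anc_chars <- strsplit(anc, "", fixed = TRUE)[[1]]
  lay <- ancestor_layout(spec, anc_chars)
  consensus <- lay$target
  aas <- aa20()
  ids <- sprintf("%s_%03d", spec$label, seq_len(spec$n))
  rows <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    ch <- consensus
    for (j in seq_len(spec$length)) {
      k <- lay$kind[j]
      if (k == "fixed") {
        if (stats::runif(1) >= lay$cons[j])
          ch[j] <- sample(setdiff(aas, consensus[j]), 1)
      } else {
        if (stats::runif(1) < spec$background_sub)
          ch[j] <- sample(setdiff(aas, consensus[j]), 1)
        if (k == "optional") {
          pres <- spec$motifs[[match(lay$motif_of[j],
                                     vapply(spec$motifs, function(m)
                                       m$motif$name, ""))]]$presence
          if (stats::runif(1) >= pres) ch[j] <- "-"
        } else if (spec$background_indel > 0 && k == "background" &&
                   stats::runif(1) < spec$background_indel) {
          ch[j] <- "-"
        }
      }
    }
    rows[[i]] <- ch
  }
  m0 <- do.call(rbind, rows)
  rownames(m0) <- ids
  seqs <- seq_set(ids, apply(m0, 1, function(r)
    paste(r[r != "-"], collapse = "")),
    rep(paste0("family=", spec$label), spec$n))
  truth <- build_truth(spec, m0, ids, seqs)
  # optional positions absent from every member leave no alignment column;
  # attr "ancestor_columns" maps alignment columns back to ancestor positions
  allgap <- colSums(m0 != "-") == 0
  alignment <- msa(ids, apply(m0[, !allgap, drop = FALSE], 1, paste,
                              collapse = ""))
  attr(alignment, "ancestor_columns") <- which(!allgap)
  presence_of <- function(j) {
    nm <- lay$motif_of[j]
    spec$motifs[[match(nm, vapply(spec$motifs, function(m)
      m$motif$name, ""))]]$presence
  }
  layout <- data.frame(
    position = seq_len(spec$length),  # ancestor coordinates
    kind = lay$kind,
    motif = lay$motif_of,
    consensus = consensus,
    # probability that a family member carries the consensus residue
    target = vapply(seq_len(spec$length), function(j)
      switch(lay$kind[j],
             fixed = lay$cons[j],
             optional = presence_of(j) * (1 - spec$background_sub),
             wildcard = 1 - spec$background_sub,
             (1 - spec$background_sub) *
               (1 - spec$background_indel)), numeric(1)),
    stringsAsFactors = FALSE)
  list(seqs = seqs, alignment = alignment, truth = truth,
       ancestor = paste(consensus, collapse = ""), layout = layout,
       rows_full = apply(m0, 1, paste, collapse = ""))
}

build_truth <- function(spec, m, ids, seqs) {
  seq_tab <- data.frame(id = ids, family = spec$label,
                        positive = spec$positive, stringsAsFactors = FALSE)
  inst <- list(); cons <- list()
  for (ms in spec$motifs) {
    p <- ms$motif$positions
    cols <- ms$offset + seq_len(nrow(p))
    fixed_cols <- cols[p$kind == "fixed"]
    # realized conservation per fixed position (consensus residue frequency)
    consensus <- substr(p$allowed[p$kind == "fixed"], 1, 1)
    realized <- vapply(seq_along(fixed_cols), function(k)
      mean(m[, fixed_cols[k]] == consensus[k]), numeric(1))
    cons[[ms$motif$name]] <- data.frame(
      motif = ms$motif$name, ancestor_position = fixed_cols,
      target = ms$conservation, realized = realized,
      stringsAsFactors = FALSE)
    # realized (unaligned) span per sequence
    for (i in seq_along(ids)) {
      row <- m[i, ]
      ungapped <- cumsum(row != "-")
      present <- cols[row[cols] != "-"]
      if (!length(present)) next
      start <- ungapped[present[1]]; end <- ungapped[present[length(present)]]
      inst[[length(inst) + 1]] <- data.frame(
        id = ids[i], motif = ms$motif$name,
        start = start, end = end,
        residues = substr(seqs$seq[[i]], start, end),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(sequences = seq_tab,
                 instances = if (length(inst)) do.call(rbind, inst) else
                   data.frame(id = character(), motif = character(),
                              start = integer(), end = integer(),
                              residues = character(), stringsAsFactors = FALSE),
                 conservation = if (length(cons)) do.call(rbind, cons) else NULL),
            class = "truth_table")
}

#' Generate a multi-family dataset
#'
#' Families descend from independent ancestors derived from one base
#' ancestor: each family ancestor substitutes base positions with
#' probability `divergence / 2`, so the expected pairwise ancestor
#' p-distance is approximately `divergence` (families therefore share a
#' common coordinate system and the combined true alignment is column-wise
#' consistent). Motifs are then planted per family and members drawn as in
#' [generate_family].
#'
#' @param family_specs list of [family_spec]s with distinct labels.
#' @param divergence expected pairwise ancestor distance, substitutions per
#'   site (default 0.5).
#' @param seed integer seed for the base ancestor and family ancestors.
#' @return A list: `seqs` (combined [seq_set]), `alignment` (combined true
#'   [msa]), `truth` (combined `truth_table`).
#' @export
generate_dataset <- function(family_specs, divergence = 0.5, seed) {
  if (missing(seed)) stop("generate_dataset requires a seed")
  labels <- vapply(family_specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("family labels must be distinct")
  lens <- vapply(family_specs, `[[`, integer(1), "length")
  if (length(unique(lens)) != 1)
    stop("families in one dataset must share the ancestor length")
  set.seed(as.integer(seed))
  base <- strsplit(random_ancestor(lens[1]), "")[[1]]
  ancestors <- lapply(family_specs, function(fs)
    paste(mutate_chars(base, divergence / 2), collapse = ""))
  fams <- mapply(function(fs, anc) generate_family(fs, ancestor = anc),
                 family_specs, ancestors, SIMPLIFY = FALSE)
  seqs <- do.call(function(...) {
    parts <- list(...)
    seq_set(unlist(lapply(parts, function(p) p$id)),
            unlist(lapply(parts, function(p) p$seq)),
            unlist(lapply(parts, function(p) p$desc)))
  }, lapply(fams, `[[`, "seqs"))
  ids_all <- unlist(lapply(fams, function(f) f$alignment$id))
  rows_all <- unlist(lapply(fams, `[[`, "rows_full"))
  mm <- msa_matrix_chr(rows_all)
  allgap <- colSums(mm != "-") == 0
  alignment <- msa(ids_all, apply(mm[, !allgap, drop = FALSE], 1, paste,
                                  collapse = ""))
  attr(alignment, "ancestor_columns") <- which(!allgap)
  truth <- structure(list(
    sequences = do.call(rbind, lapply(fams, function(f) f$truth$sequences)),
    instances = do.call(rbind, lapply(fams, function(f) f$truth$instances)),
    conservation = do.call(rbind, lapply(fams, function(f)
      f$truth$conservation))),
    class = "truth_table")
  list(seqs = seqs, alignment = alignment, truth = truth)
}

#' Write a truth table
#'
#' Two tab-separated sections: one row per sequence (id, family, positive)
#' and one row per planted motif instance (id, motif, start, end, residues),
#' each introduced by a `#` header line. Round-trips with [read_truth].
#'
#' @param truth a `truth_table`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# sequences\tid\tfamily\tpositive", con)
  with(truth$sequences, writeLines(paste("seq", id, family, positive,
                                         sep = "\t"), con))
  writeLines("# instances\tid\tmotif\tstart\tend\tresidues", con)
  if (nrow(truth$instances))
    with(truth$instances, writeLines(paste("inst", id, motif, start, end,
                                           residues, sep = "\t"), con))
  invisible(path)
}

#' Read a truth table written by [write_truth]
#' @param path input path.
#' @return A `truth_table` (without the conservation section, which is
#'   recomputable from the alignment).
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  seqs <- Filter(function(t) t[1] == "seq", toks)
  inst <- Filter(function(t) t[1] == "inst", toks)
  structure(list(
    sequences = data.frame(id = vapply(seqs, `[[`, "", 2),
                           family = vapply(seqs, `[[`, "", 3),
                           positive = as.logical(vapply(seqs, `[[`, "", 4)),
                           stringsAsFactors = FALSE),
    instances = data.frame(id = vapply(inst, `[[`, "", 2),
                           motif = vapply(inst, `[[`, "", 3),
                           start = as.integer(vapply(inst, `[[`, "", 4)),
                           end = as.integer(vapply(inst, `[[`, "", 5)),
                           residues = vapply(inst, `[[`, "", 6),
                           stringsAsFactors = FALSE),
    conservation = NULL), class = "truth_table")
}
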