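expand_masks <- function(n) {
  # all inclusion masks over n optional positions, fewest inclusions first
  if (n == 0) return(list(logical(0)))
  g <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  g <- g[order(rowSums(g)), , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) as.logical(g[i, ]))
}

scan_one_motif <- function(chars, motif, pass_threshold) {
  p <- motif$positions
  L <- length(chars)
  opt <- which(p$kind == "optional")
  fixed <- which(p$kind == "fixed")
  wsum <- sum(p$weight[fixed])
  allowed <- strsplit(p$allowed[fixed], "", fixed = TRUE)
  best <- NULL
  for (mask in expand_masks(length(opt))) {
    included <- rep(TRUE, nrow(p))
    included[opt[!mask]] <- FALSE
    span <- sum(included)
    if (L < span) next
    off <- cumsum(included) - 1L  # relative offset of each included position
    starts <- seq_len(L - span + 1L)
    weighted <- numeric(length(starts))
    nmatch <- integer(length(starts))
    for (k in seq_along(fixed)) {
      j <- fixed[k]
      ok <- chars[starts + off[j]] %in% allowed[[k]]
      weighted <- weighted + p$weight[j] * ok
      nmatch <- nmatch + ok
    }
    norm <- weighted / wsum
    ibest <- which.max(norm)  # smallest start among ties
    cand <- list(start = starts[ibest], span = span,
                 n_optional_included = sum(mask),
                 matched_count = nmatch[ibest],
                 weighted_score = weighted[ibest],
                 normalized_score = norm[ibest],
                 offsets = stats::setNames(off, p$ref_pos),
                 included = included)
    if (is.null(best) ||
        cand$normalized_score > best$normalized_score + 1e-12 ||
        (abs(cand$normalized_score - best$normalized_score) <= 1e-12 &&
         (cand$start < best$start ||
          (cand$start == best$start &&
           cand$n_optional_included < best$n_optional_included))))
      best <- cand
  }
  if (is.null(best))
    return(list(row = data.frame(motif = motif$name, start = NA_integer_,
                                 span = NA_integer_, n_optional_included = NA_integer_,
                                 matched_count = NA_integer_,
                                 weighted_score = NA_real_,
                                 normalized_score = NA_real_,
                                 passes = FALSE, stringsAsFactors = FALSE),
                detail = NULL))
  list(row = data.frame(motif = motif$name, start = best$start,
                        span = best$span,
                        n_optional_included = best$n_optional_included,
                        matched_count = best$matched_count,
                        weighted_score = best$weighted_score,
                        normalized_score = best$normalized_score,
                        passes = best$normalized_score >= pass_threshold,
                        stringsAsFactors = FALSE),
       detail = best)
}

#' Scan a candidate sequence against signature motifs
#'
#' Every start offset and every optional-position inclusion mask is
#' evaluated; matching is ungapped within a motif except at the declared
#' optional positions, and insertions between motifs are unconstrained. For
#' each motif the highest normalized score is reported (ties broken by
#' smallest start, then fewest optional inclusions). A motif passes when its
#' normalized score -- weighted fraction of matching fixed positions --
#' reaches `pass_threshold`. A candidate shorter than a motif's minimal span
#' yields an unmatchable record for that motif.
#'
#' @param candidate protein residue string (or single-sequence `seq_set`).
#' @param motifs list of [signature_motif]s (default: the five built-ins).
#' @param pass_threshold normalized-score threshold in `[0,1]` (default 0.7).
#' @return Data frame, one row per motif: `motif`, `start`, `span`,
#'   `n_optional_included`, `matched_count`, `weighted_score`,
#'   `normalized_score`, `passes`; per-motif match details (offset maps) are
#'   attached as attribute `"details"`.
#' @export
scan_sequence <- function(candidate, motifs = builtin_pb2sf_motifs(),
                          pass_threshold = 0.7) {
  s <- align_input(candidate)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  res <- lapply(motifs, scan_one_motif, chars = chars,
                pass_threshold = pass_threshold)
  tab <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(tab) <- NULL
  details <- lapply(res, `[[`, "detail")
  names(details) <- vapply(motifs, `[[`, "", "name")
  attr(tab, "details") <- details
  tab
}

core_motif_present <- function(chars, motifB, detail) {
  # C/S-X-P-X-R at reference positions 92..96 inside the motif-B match
  if (is.null(detail)) return(FALSE)
  need <- c(`92` = "CS", `94` = "P", `96` = "R")
  pos <- detail$start + detail$offsets[names(need)]
  if (anyNA(pos) || any(pos > length(chars))) return(FALSE)
  all(mapply(function(p, aa) chars[p] %in% strsplit(aa, "")[[1]],
             pos, need))
}

#' Map reference coordinates onto a candidate sequence
#'
#' Built from the global-alignment traceback: a reference position maps to a
#' candidate position iff both are non-gap in the same alignment column.
#'
#' @param candidate,reference protein residue strings.
#' @param scheme a [scoring_scheme].
#' @return Integer vector of length `nchar(reference)`; `NA` where the
#'   reference position has no candidate counterpart.
#' @export
map_to_reference <- function(candidate, reference, scheme = scoring_scheme()) {
  cand <- align_input(candidate); ref <- align_input(reference)
  al <- global_align(ref, cand, scheme)
  rc <- strsplit(al$aligned_query, "")[[1]]
  cc <- strsplit(al$aligned_subject, "")[[1]]
  rpos <- cumsum(rc != "-")
  cpos <- cumsum(cc != "-")
  map <- rep(NA_integer_, nchar(ref))
  both <- rc != "-" & cc != "-"
  map[rpos[both]] <- cpos[both]
  map
}

#' Check catalytic residues of a candidate against the reference annotation
#'
#' Each annotated reference position is mapped onto the candidate via global
#' alignment and the candidate residue is compared with the expected one;
#' position 92 accepts C or S (the family core motif allows both).
#'
#' @param candidate,reference protein residue strings.
#' @param annotation data frame as returned by [pb2sf_catalytic_sites()].
#' @param scheme a [scoring_scheme].
#' @return Data frame: `position`, `expected`, `candidate_position`,
#'   `residue`, `status` (`match`, `mismatch` or `absent`).
#' @export
check_catalytic_residues <- function(candidate, reference,
                                     annotation = pb2sf_catalytic_sites(),
                                     scheme = scoring_scheme()) {
  cand <- align_input(candidate)
  map <- map_to_reference(cand, reference, scheme)
  chars <- strsplit(cand, "", fixed = TRUE)[[1]]
  res <- annotation
  res$candidate_position <- map[res$position]
  res$residue <- ifelse(is.na(res$candidate_position), NA,
                        chars[res$candidate_position])
  res$status <- ifelse(is.na(res$residue), "absent",
                       ifelse(mapply(function(r, e)
                         r %in% strsplit(e, "")[[1]],
                         res$residue, res$expected),
                         "match", "mismatch"))
  res
}

#' Classify a candidate as a predicted family member
#'
#' The verdict is a conservative conjunction of the two published lines of
#' evidence: the universal core motif C/S-X-P-X-R must be present inside the
#' motif-B match, AND at least `quorum` of the motifs must pass the
#' normalized-score threshold. Catalytic residues are reported as evidence
#' when a reference sequence is supplied, but do not enter the verdict.
#'
#' @param candidate protein residue string (or single-sequence `seq_set`).
#' @param motifs list of [signature_motif]s.
#' @param reference optional reference protein for catalytic-residue mapping.
#' @param annotation catalytic annotation (see [pb2sf_catalytic_sites()]).
#' @param pass_threshold per-motif normalized-score threshold (default 0.7).
#' @param quorum motifs that must pass (default 4 of 5).
#' @param id candidate identifier used in reports.
#' @return An object of class `classification_report`.
#' @export
classify_candidate <- function(candidate, motifs = builtin_pb2sf_motifs(),
                               reference = NULL,
                               annotation = pb2sf_catalytic_sites(),
                               pass_threshold = 0.7, quorum = 4, id = NULL) {
  s <- align_input(candidate)
  if (is.null(id) && inherits(candidate, "seq_set")) id <- candidate$id[[1]]
  if (is.null(id)) id <- "candidate"
  matches <- scan_sequence(s, motifs, pass_threshold)
  details <- attr(matches, "details")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  core <- if ("B" %in% names(details))
    core_motif_present(chars, motifs[["B"]], details[["B"]]) else FALSE
  n_passing <- sum(matches$passes, na.rm = TRUE)
  catalytic <- if (!is.null(reference))
    check_catalytic_residues(s, reference, annotation) else NULL
  verdict <- if (core && n_passing >= quorum) "predicted 2-O-sulfatase"
             else "not predicted"
  structure(list(id = id, matches = matches, core_motif = core,
                 n_passing = n_passing, quorum = quorum,
                 pass_threshold = pass_threshold,
                 catalytic = catalytic, verdict = verdict),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> ", x$id, ": ", x$verdict, "\n", sep = "")
  cat("  core motif C/S-X-P-X-R: ", if (x$core_motif) "present" else "absent",
      "; motifs passing: ", x$n_passing, "/", nrow(x$matches),
      " (threshold ", x$pass_threshold, ", quorum ", x$quorum, ")\n", sep = "")
  m <- x$matches
  for (i in seq_len(nrow(m)))
    cat(sprintf("  motif %-2s start %-5s score %s\n", m$motif[i],
                ifelse(is.na(m$start[i]), "-", m$start[i]),
                ifelse(is.na(m$normalized_score[i]), "unmatchable",
                       sprintf("%.3f%s", m$normalized_score[i],
                               ifelse(m$passes[i], " (pass)", "")))))
  if (!is.null(x$catalytic)) {
    bad <- x$catalytic$status != "match"
    cat("  catalytic residues: ", sum(!bad), "/", nrow(x$catalytic),
        " match\n", sep = "")
  }
  invisible(x)
}
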