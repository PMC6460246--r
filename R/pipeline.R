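#' Pipeline configuration
#'
#' Collects the procedure constants of the screening workflow: identity
#' threshold (strictly greater than 40% by default), hits per query (100),
#' per-motif pass threshold (0.7), motif quorum (4 of 5), conservation
#' threshold tau (0.47), bootstrap replicates (1000) and the mandatory seed
#' feeding every stochastic stage.
#'
#' @param min_identity percent identity threshold for homolog screening.
#' @param top_n maximum hits per query.
#' @param min_cover optional query-cover floor (percent), `NULL` = off.
#' @param pass_threshold per-motif normalized-score threshold.
#' @param quorum motifs required to pass.
#' @param tau conservation threshold for signature-region extraction.
#' @param bootstrap bootstrap replicates for the tree stage.
#' @param seed integer seed (mandatory).
#' @param clade_stage run the phylogeny/clade-membership stage?
#' @param gap_open,gap_extend,matrix scoring parameters (BLASTp defaults).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_identity = 40, top_n = 100, min_cover = NULL,
                            pass_threshold = 0.7, quorum = 4, tau = 0.47,
                            bootstrap = 1000, seed, clade_stage = TRUE,
                            gap_open = 11, gap_extend = 1,
                            matrix = "BLOSUM62") {
  if (missing(seed)) stop("pipeline_config requires a seed")
  stopifnot(min_identity >= 0, min_identity <= 100, top_n >= 1,
            pass_threshold >= 0, pass_threshold <= 1, quorum >= 1,
            tau > 0, tau <= 1, bootstrap >= 1)
  structure(list(min_identity = min_identity, top_n = top_n,
                 min_cover = min_cover, pass_threshold = pass_threshold,
                 quorum = quorum, tau = tau, bootstrap = as.integer(bootstrap),
                 seed = as.integer(seed), clade_stage = isTRUE(clade_stage),
                 gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_scheme <- function(config)
  scoring_scheme(config$matrix, config$gap_open, config$gap_extend)

as_seq_set <- function(x, alphabet = "protein") {
  if (inherits(x, "seq_set")) x else read_fasta(x, alphabet)
}

#' Motif-only screening of candidate sequences
#'
#' The fast path: each candidate is classified against the signature motifs
#' with no alignment or tree stage.
#'
#' @param candidates a protein [seq_set] or FASTA path.
#' @param motifs list of [signature_motif]s (default: built-ins).
#' @param config a [pipeline_config].
#' @return A list with `reports` (one `classification_report` per candidate)
#'   and `summary` (a data frame: id, core motif, motifs passing, verdict).
#' @export
run_scan <- function(candidates, motifs = builtin_pb2sf_motifs(),
                     config = pipeline_config(seed = 1)) {
  cands <- as_seq_set(candidates)
  reports <- lapply(seq_along(cands$id), function(i)
    classify_candidate(cands$seq[[i]], motifs,
                       pass_threshold = config$pass_threshold,
                       quorum = config$quorum, id = cands$id[[i]]))
  summary <- data.frame(
    id = cands$id,
    core_motif = vapply(reports, `[[`, logical(1), "core_motif"),
    n_passing = vapply(reports, `[[`, integer(1), "n_passing"),
    verdict = vapply(reports, `[[`, "", "verdict"),
    stringsAsFactors = FALSE)
  list(reports = reports, summary = summary)
}

#' Run the full prediction workflow
#'
#' Stages, in order: homolog screening of the candidate database against the
#' reference family members; removal of redundant identical candidates;
#' progressive multiple alignment of references, screened candidates and
#' outgroups (or a user-supplied alignment); conservation profiling;
#' neighbor-joining tree with bootstrap supports and outgroup-rooted
#' clade-membership tests; motif classification of each screened candidate.
#' The final call is `predicted` iff the motif verdict is positive AND (the
#' clade stage is disabled OR the candidate falls inside the family clade).
#'
#' @param candidates protein [seq_set] or FASTA path (the database screened).
#' @param references protein [seq_set] or FASTA path; at least 2 known
#'   family members (screening queries and clade anchors).
#' @param outgroups protein [seq_set] or FASTA path of outgroup sequences.
#' @param config a [pipeline_config].
#' @param motifs list of [signature_motif]s.
#' @param alignment optional pre-computed [msa] covering references,
#'   candidates and outgroups (skips the progressive aligner).
#' @param run_dir optional directory; when given, every intermediate
#'   artifact is written there via [write_report].
#' @return An object of class `prediction_report`.
#' @export
run_prediction <- function(candidates, references, outgroups, config,
                           motifs = builtin_pb2sf_motifs(),
                           alignment = NULL, run_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cands <- as_seq_set(candidates)
  refs <- as_seq_set(references)
  outs <- as_seq_set(outgroups)
  if (length(refs) < 2) stop("need at least 2 reference family members")
  scheme <- config_scheme(config)

  hits <- screen_homologs(refs, cands, config$min_identity, config$top_n,
                          config$min_cover, scheme)
  screened_ids <- sort(unique(hits$subject))
  dd <- deduplicate(cands[screened_ids])
  kept <- dd$seqs

  all_ids <- c(refs$id, kept$id, outs$id)
  pool <- seq_set(all_ids, c(refs$seq, kept$seq, outs$seq),
                  c(refs$desc, kept$desc, outs$desc))
  if (is.null(alignment)) {
    alignment <- if (length(pool) >= 2) progressive_msa(pool, scheme) else NULL
  }
  profile <- if (!is.null(alignment))
    build_profile(alignment, refs$id[[1]]) else NULL

  tree <- NULL; clade <- stats::setNames(rep(NA_character_, length(kept)), kept$id)
  if (config$clade_stage && !is.null(alignment) && alignment$n_rows >= 3) {
    tree <- bootstrap_support(alignment, config$bootstrap, config$seed)
    # attachment rule: the few known references rarely span the whole family
    # clade, and the supplied outgroups stand for every non-family branch
    seen <- character()
    withCallingHandlers(
      for (id in kept$id)
        clade[[id]] <- clade_membership(tree, refs$id, outs$id, id,
                                        rule = "attachment"),
      warning = function(w) {
        if (conditionMessage(w) %in% seen) invokeRestart("muffleWarning")
        seen <<- c(seen, conditionMessage(w))
      })
  }

  reports <- lapply(seq_along(kept$id), function(i)
    classify_candidate(kept$seq[[i]], motifs, reference = refs$seq[[1]],
                       pass_threshold = config$pass_threshold,
                       quorum = config$quorum, id = kept$id[[i]]))
  motif_verdict <- vapply(reports, `[[`, "", "verdict")
  final <- ifelse(motif_verdict == "predicted 2-O-sulfatase" &
                    (!config$clade_stage | clade[kept$id] == "inside"),
                  "predicted", "not predicted")

  best_hit <- function(id) {
    h <- hits[hits$subject == id, , drop = FALSE]
    h[which.max(h$identity_percent), , drop = FALSE]
  }
  calls <- do.call(rbind, lapply(seq_along(kept$id), function(i) {
    id <- kept$id[[i]]; bh <- best_hit(id)
    data.frame(id = id,
               best_query = bh$query, best_identity = bh$identity_percent,
               core_motif = reports[[i]]$core_motif,
               n_passing = reports[[i]]$n_passing,
               motif_verdict = motif_verdict[i],
               clade = unname(clade[[id]]),
               final_call = final[i], stringsAsFactors = FALSE)
  }))
  unscreened <- setdiff(cands$id, screened_ids)
  if (length(unscreened))
    calls <- rbind(calls, data.frame(
      id = unscreened, best_query = NA, best_identity = NA,
      core_motif = NA, n_passing = NA, motif_verdict = "not screened",
      clade = NA, final_call = "not predicted", stringsAsFactors = FALSE))
  calls <- calls[order(match(calls$id, cands$id)), , drop = FALSE]
  rownames(calls) <- NULL

  report <- structure(list(calls = calls, hits = hits,
                           duplicates = dd$duplicates,
                           alignment = alignment, profile = profile,
                           tree = tree, reports = reports,
                           config = config), class = "prediction_report")
  if (!is.null(run_dir)) write_report(report, run_dir)
  report
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> ", nrow(x$calls), " candidate(s), ",
      sum(x$calls$final_call == "predicted"), " predicted\n", sep = "")
  print(x$calls[, c("id", "best_query", "best_identity", "n_passing",
                    "clade", "final_call")])
  invisible(x)
}

#' Write a prediction report and all intermediates
#'
#' The run directory is the audit trail of the workflow: hit table,
#' duplicate map, alignment, logo table, Newick tree, machine-readable call
#' table, a human-readable summary and the configuration echo (with the seed
#' recorded verbatim).
#'
#' @param report a `prediction_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "prediction_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  p <- function(f) file.path(dir, f)
  write_hit_table(report$hits, p("hits.tsv")); files <- c(files, "hits.tsv")
  utils::write.table(
    data.frame(removed = names(report$duplicates),
               representative = unname(report$duplicates)),
    p("duplicates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "duplicates.tsv")
  if (!is.null(report$alignment)) {
    write_msa(report$alignment, p("alignment.fasta"))
    files <- c(files, "alignment.fasta")
  }
  if (!is.null(report$profile)) {
    export_logo_table(report$profile, p("logo_table.tsv"))
    files <- c(files, "logo_table.tsv")
  }
  if (!is.null(report$tree)) {
    to_newick(report$tree, p("tree.nwk")); files <- c(files, "tree.nwk")
  }
  utils::write.table(report$calls, p("calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, "calls.tsv")
  cfg <- report$config
  yaml::write_yaml(cfg[setdiff(names(cfg), "min_cover")], p("config.yaml"))
  files <- c(files, "config.yaml")
  con <- file(p("summary.txt"), "w")
  writeLines(c("prediction run summary",
               paste0("seed: ", cfg$seed),
               paste0("candidates called: ", nrow(report$calls)),
               paste0("predicted: ",
                      sum(report$calls$final_call == "predicted")),
               "files:", paste0("  ", sort(c(files, "summary.txt")))), con)
  close(con)
  invisible(file.path(dir, c(files, "summary.txt")))
}
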