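test_that("the five built-in motifs carry the published anchors and weights", {
  m <- builtin_pb2sf_motifs()
  expect_identical(names(m), c("A", "B", "C", "D", "E"))
  a <- m$A$positions
  expect_equal(nrow(a), 9)
  expect_identical(a$allowed[1], "P"); expect_equal(a$ref_pos[1], 44)
  expect_equal(a$weight[1], 0.70)
  expect_identical(a$allowed[9], "D"); expect_equal(a$ref_pos[9], 52)
  expect_equal(a$weight[9], 1.00)
  b <- m$B$positions
  expect_identical(b$allowed[b$ref_pos == 92], "CS")
  d <- m$D$positions
  expect_identical(d$allowed[d$ref_pos == 310], "H")
  expect_equal(d$weight[d$ref_pos == 310], 1.00)
  expect_equal(vapply(m, function(x) x$anchor, numeric(1)),
               c(A = 44, B = 86, C = 194, D = 301, E = 417))
  spans <- vapply(m, function(x) range(x$positions$ref_pos)[2], numeric(1))
  expect_equal(unname(spans), c(52, 102, 208, 315, 446))
})

test_that("motif files round-trip and reject invalid definitions", {
  m <- builtin_pb2sf_motifs()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motifs(m, f)
  m2 <- read_motifs(f)
  expect_equal(lapply(m, `[[`, "positions"), lapply(m2, `[[`, "positions"))

  bad <- data.frame(motif = "Z", ref_pos = c(1, 2), kind = "fixed",
                    allowed = "A", weight = c(0.5, 1.2))
  writeLines(c(paste(names(bad), collapse = "\t"),
               apply(bad, 1, paste, collapse = "\t")), f)
  expect_error(read_motifs(f), "\\[0,1\\]")
  bad$weight <- 0.5; bad$ref_pos <- c(2, 2)
  writeLines(c(paste(names(bad), collapse = "\t"),
               apply(bad, 1, paste, collapse = "\t")), f)
  expect_error(read_motifs(f), "increasing")
  expect_error(signature_motif("w", data.frame(
    ref_pos = 1:2, kind = c("wildcard", "fixed"),
    allowed = c("", "A"), weight = c(0, 1))), "first and last")
})

test_that("the consensus scaffold scores 1.0 on every motif and is classified", {
  sc <- consensus_scaffold()
  res <- scan_sequence(sc)
  expect_equal(res$normalized_score, rep(1, 5))
  expect_equal(res$start, c(44, 86, 194, 301, 417))
  expect_true(all(res$passes))
  expect_true(all(res$matched_count <= vapply(builtin_pb2sf_motifs(),
    function(m) sum(m$positions$kind == "fixed"), numeric(1))))
  rep <- classify_candidate(sc)
  expect_identical(rep$verdict, "predicted 2-O-sulfatase")
  expect_true(rep$core_motif)
})

test_that("a single substitution at D52 lowers motif A by exactly its weight share", {
  sc <- strsplit(consensus_scaffold(), "")[[1]]
  sc[52] <- "A"
  res <- scan_sequence(paste(sc, collapse = ""))
  wsum <- 0.70 + 0.99 + 0.74 + 0.57 + 0.95 + 0.63 + 1.00  # published weights
  expect_equal(res$normalized_score[res$motif == "A"], 1 - 1.00 / wsum,
               tolerance = 1e-9)
  expect_equal(res$normalized_score[res$motif != "A"], rep(1, 4))
})

test_that("scanner score decreases monotonically with introduced mismatches", {
  m <- builtin_pb2sf_motifs()
  sc <- consensus_scaffold()
  fixed_pos <- m$C$positions$ref_pos[m$C$positions$kind == "fixed"]
  prev <- 1
  ch <- strsplit(sc, "")[[1]]
  for (k in seq_along(fixed_pos)) {
    ch[fixed_pos[k]] <- "W"
    s <- scan_sequence(paste(ch, collapse = ""), m["C"])
    expect_lte(s$normalized_score, prev + 1e-12)
    prev <- s$normalized_score
  }
  expect_gte(prev, 0)
})

test_that("scanner scores do not depend on residues outside the window", {
  m <- builtin_pb2sf_motifs()["A"]
  core <- motif_consensus(m$A, fill = "G")
  set.seed(30)
  base <- scan_sequence(paste0(strrep("W", 20), core, strrep("W", 20)), m)
  for (i in 1:5) {
    flank1 <- random_protein(sample(10:40, 1))
    flank2 <- random_protein(sample(10:40, 1))
    s <- scan_sequence(paste0(flank1, core, flank2), m)
    expect_equal(s$normalized_score, base$normalized_score)
  }
})

test_that("scanner equals brute-force enumeration over windows and masks", {
  set.seed(31)
  small <- signature_motif("s", data.frame(
    ref_pos = 1:6,
    kind = c("fixed", "wildcard", "optional", "fixed", "optional", "fixed"),
    allowed = c("D", "", "", "KR", "", "G"),
    weight = c(0.9, 0, 0, 0.6, 0, 1)))
  for (i in 1:25) {
    cand <- random_protein(sample(6:60, 1))
    got <- scan_sequence(cand, list(s = small))$normalized_score
    want <- brute_scan_best(strsplit(cand, "")[[1]], small)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("short candidates are reported unmatchable, not errors", {
  res <- scan_sequence("MKVILD")
  expect_true(all(is.na(res$normalized_score)))
  expect_false(any(res$passes))
})

test_that("reference coordinate mapping follows the alignment", {
  ref <- make_reference()
  expect_identical(map_to_reference(ref, ref), seq_len(nchar(ref)))
  # one residue inserted before position 52 shifts the map by one
  ins <- paste0(substr(ref, 1, 40), "W", substr(ref, 41, nchar(ref)))
  map <- map_to_reference(ins, ref)
  expect_identical(map[52], 53L)
  expect_identical(map[39], 39L)
  # deleting position 52 leaves it unmapped
  del <- paste0(substr(ref, 1, 51), substr(ref, 53, nchar(ref)))
  map2 <- map_to_reference(del, ref)
  expect_true(is.na(map2[52]))
  expect_identical(map2[51], 51L)
  expect_identical(map2[53], 52L)
})

test_that("catalytic-residue checks accept C/S at 92 and flag substitutions", {
  ref <- make_reference()
  self <- check_catalytic_residues(ref, ref)
  expect_true(all(self$status == "match"))
  ch <- strsplit(ref, "")[[1]]; ch[52] <- "A"
  mut <- check_catalytic_residues(paste(ch, collapse = ""), ref)
  expect_identical(mut$status[mut$position == 52], "mismatch")
  expect_identical(mut$residue[mut$position == 52], "A")
  expect_true(all(mut$status[mut$position != 52] == "match"))
  ch <- strsplit(ref, "")[[1]]; ch[92] <- "S"
  ser <- check_catalytic_residues(paste(ch, collapse = ""), ref)
  expect_identical(ser$status[ser$position == 92], "match")
})

test_that("classification requires the core motif and the motif quorum", {
  sc <- consensus_scaffold()
  # shuffling destroys positional structure
  set.seed(32)
  shuf <- paste(sample(strsplit(sc, "")[[1]]), collapse = "")
  expect_identical(classify_candidate(shuf)$verdict, "not predicted")
  # ablating the core C/S-X-P-X-R (P94 and R96 to A) vetoes the verdict even
  # though other motifs are intact
  ch <- strsplit(sc, "")[[1]]
  ch[c(92, 94, 96)] <- "A"
  abl <- classify_candidate(paste(ch, collapse = ""))
  expect_false(abl$core_motif)
  expect_identical(abl$verdict, "not predicted")
  # verdict equivalence with the documented rule
  expect_identical(abl$verdict == "predicted 2-O-sulfatase",
                   abl$core_motif && abl$n_passing >= abl$quorum)
})

test_that("classification is stable under arbitrary flanking sequence", {
  set.seed(33)
  sc <- consensus_scaffold()
  for (i in 1:3) {
    flanked <- paste0(random_protein(sample(5:50, 1)), sc,
                      random_protein(sample(5:50, 1)))
    expect_identical(classify_candidate(flanked)$verdict,
                     "predicted 2-O-sulfatase")
  }
})
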