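test_that("global alignment matches identity and simple derived cases", {
  al <- global_align("MKVILD", "MKVILD")
  expect_equal(al$identity_percent, 100)
  expect_false(grepl("-", al$aligned_query, fixed = TRUE))
  al2 <- global_align("MKV", "MKL")
  expect_equal(al2$identity_percent, 100 * 2 / 3, tolerance = 1e-9)
  expect_error(global_align("", "MKV"), "empty")
  # the identity denominator is configurable: gapped columns can be excluded
  al3 <- global_align("MKVILD", "MKVIWPLD", scoring_scheme(gap_open = 2))
  al4 <- global_align("MKVILD", "MKVIWPLD", scoring_scheme(gap_open = 2),
                      identity_denominator = "ungapped")
  expect_gte(al4$identity_percent, al3$identity_percent)
})

test_that("alignment scores are symmetric and self-local is full-cover", {
  set.seed(12)
  for (i in 1:6) {
    a <- random_protein(25); b <- random_protein(30)
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
    expect_gte(local_align(a, b)$score, 0)
  }
  al <- local_align("MKVILDQRST", "MKVILDQRST")
  expect_equal(al$identity_percent, 100)
  expect_equal(al$query_cover_percent, 100)
})

test_that("disjoint-composition sequences yield a no-hit local alignment", {
  al <- local_align(strrep("K", 12), strrep("D", 12))
  expect_true(al$no_hit)
  expect_equal(al$score, 0)
  expect_equal(al$identity_percent, 0)
  expect_equal(al$query_cover_percent, 0)
})

test_that("DP scores equal brute-force enumeration over all alignments", {
  # exhaustive over all pairs up to length 3 on a 4-letter alphabet,
  # then a seeded random sample of longer pairs (lengths 4-6)
  ab <- c("A", "C", "D", "E")
  sub <- blosum_sub(ab)
  sch_tight <- scoring_scheme(gap_open = 2, gap_extend = 1)   # gap-friendly
  sch_blast <- scoring_scheme()                                # BLASTp default
  strings <- unlist(lapply(1:3, function(L)
    apply(expand.grid(rep(list(ab), L)), 1, paste, collapse = "")))
  set.seed(13)
  pairs <- cbind(sample(strings, 60, TRUE), sample(strings, 60, TRUE))
  long <- t(replicate(60, c(random_protein(sample(4:6, 1), ab),
                            random_protein(sample(4:6, 1), ab))))
  for (sch in list(sch_tight, sch_blast)) {
    for (r in seq_len(nrow(pairs))) {
      expect_equal(global_align(pairs[r, 1], pairs[r, 2], sch)$score,
                   brute_global(pairs[r, 1], pairs[r, 2], sub,
                                sch$gap_open, sch$gap_extend))
    }
    for (r in seq_len(nrow(long))) {
      expect_equal(global_align(long[r, 1], long[r, 2], sch)$score,
                   brute_global(long[r, 1], long[r, 2], sub,
                                sch$gap_open, sch$gap_extend))
    }
  }
  # local: smaller sample (the enumeration is over all substring pairs)
  for (r in 1:15) {
    expect_equal(local_align(long[r, 1], long[r, 2], sch_tight)$score,
                 brute_local(long[r, 1], long[r, 2], sub, 2, 1))
  }
})

test_that("scores agree with an independent aligner implementation", {
  set.seed(19)
  for (i in 1:8) {
    a <- random_protein(sample(20:40, 1)); b <- random_protein(sample(20:40, 1))
    ba <- function(type) Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = type))
    expect_equal(global_align(a, b)$score, ba("global"))
    expect_equal(local_align(a, b)$score, ba("local"))
  }
})

test_that("traceback is deterministic across repeated calls", {
  set.seed(14)
  a <- random_protein(40); b <- random_protein(40)
  al1 <- global_align(a, b); al2 <- global_align(a, b)
  expect_identical(al1$aligned_query, al2$aligned_query)
  expect_identical(al1$aligned_subject, al2$aligned_subject)
})

test_that("homolog screening applies a strict threshold and fixed ordering", {
  # subject engineered to an exact full-span 40.0% identity local alignment:
  # 8 matching W, 12 A/S columns (A-S scores +1, keeping the span intact)
  q <- paste0(strrep("W", 8), strrep("A", 12))
  s40 <- paste0(strrep("W", 8), strrep("S", 12))
  al <- local_align(q, s40)
  expect_equal(al$identity_percent, 40)
  db <- seq_set(c("hit40", "self", "copy"), c(s40, q, q))
  hits <- screen_homologs(seq_set("self", q), db, min_identity = 40)
  expect_false("hit40" %in% hits$subject)     # strictly greater than 40
  expect_false("self" %in% hits$subject)      # self-hit excluded
  expect_equal(hits$identity_percent[hits$subject == "copy"], 100)
  hits2 <- screen_homologs(seq_set("self", q), db, min_identity = 39.9)
  expect_true("hit40" %in% hits2$subject)
})

test_that("screening recovers the generator-known truth set and ignores db order", {
  set.seed(15)
  q <- random_protein(120)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(a) sample(setdiff(AAS, a), 1), "")
    paste(ch, collapse = "")
  }
  # identities ~90/75/55 (above threshold) and ~15 (far below)
  db_seqs <- c(mutate_at(q, 12), mutate_at(q, 30), mutate_at(q, 54),
               mutate_at(q, 102))
  db <- seq_set(paste0("s", 1:4), db_seqs)
  hits <- screen_homologs(seq_set("q", q), db, min_identity = 40)
  expect_setequal(hits$subject, c("s1", "s2", "s3"))
  expect_equal(hits$subject[1], "s1")         # sorted by identity descending
  # permuting the database leaves the result unchanged
  perm <- db[c(3, 1, 4, 2)]
  hits_p <- screen_homologs(seq_set("q", q), perm, min_identity = 40)
  expect_identical(hits, hits_p)
  # top_n truncates
  hits1 <- screen_homologs(seq_set("q", q), db, min_identity = 40, top_n = 1)
  expect_identical(hits1$subject, "s1")
})

test_that("progressive alignment reduces to pairwise and preserves inputs", {
  s2 <- seq_set(c("a", "b"), c("MKVILDQ", "MKVLDQ"))
  al2 <- progressive_msa(s2)
  pw <- global_align(s2$seq[[1]], s2$seq[[2]])
  expect_identical(al2$aligned, c(pw$aligned_query, pw$aligned_subject))
  expect_error(progressive_msa(seq_set("a", "MKV")), "at least 2")

  idseqs <- seq_set(paste0("s", 1:5), rep("MKVILDQRST", 5))
  ali <- progressive_msa(idseqs)
  expect_false(any(grepl("-", ali$aligned, fixed = TRUE)))

  set.seed(16)
  rnd <- seq_set(paste0("r", 1:5),
                 replicate(5, random_protein(sample(30:40, 1))))
  alr <- progressive_msa(rnd)
  expect_identical(gsub("-", "", alr$aligned, fixed = TRUE), rnd$seq)
  expect_identical(alr$id, rnd$id)
})

test_that("progressive alignment co-columns planted motif residues", {
  g <- make_family(n = 6, background_sub = 0.05, seed = 17)
  al <- progressive_msa(g$seqs)
  mm <- msa_matrix(al)
  ta <- msa_matrix(g$alignment)
  cons <- g$truth$conservation
  tot <- 0; shared <- 0
  for (r in seq_len(nrow(cons))) {
    ap <- cons$ancestor_position[r]
    cols <- vapply(seq_len(nrow(ta)), function(i) {
      if (ta[i, ap] == "-") return(NA_integer_)
      p <- sum(ta[i, 1:ap] != "-")
      which(cumsum(mm[i, ] != "-") == p & mm[i, ] != "-")[1]
    }, integer(1))
    cols <- cols[!is.na(cols)]
    tot <- tot + length(cols)
    shared <- shared + max(table(cols))
  }
  expect_gte(shared / tot, 0.95)
})
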