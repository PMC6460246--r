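mk_msa <- function(cols, ids = NULL) {
  # cols: list of character vectors (one per column, same length)
  rows <- apply(do.call(cbind, cols), 1, paste, collapse = "")
  msa(if (is.null(ids)) paste0("r", seq_along(rows)) else ids, rows)
}

test_that("column profiles count residues, gaps and reference coordinates", {
  x <- mk_msa(list(rep("D", 10),
                   c(rep("D", 7), rep("E", 3)),
                   c(rep("D", 5), rep("-", 5))))
  p <- build_profile(x, "r1")
  expect_equal(p$table$conservation, c(1, 0.7, 0.5))
  expect_equal(p$table$dominant, c("D", "D", "D"))
  expect_equal(p$table$runner_up[2], "E")
  expect_equal(p$table$runner_up_fraction[2], 0.3)
  expect_equal(p$table$gap_fraction, c(0, 0, 0.5))
  expect_equal(p$table$ref_position, 1:3)
  expect_error(build_profile(x, "nope"), "unknown reference")

  # reference gap -> absent ref coordinate, strictly increasing elsewhere
  y <- msa(c("a", "b"), c("M-V", "MKV"))
  py <- build_profile(y, "a")
  expect_identical(py$table$ref_position, c(1L, NA, 2L))
})

test_that("information content matches the logo definition", {
  one <- mk_msa(list(rep("W", 5)))
  expect_equal(information_content(build_profile(one, "r1")), log2(20),
               tolerance = 1e-9)
  half <- mk_msa(list(c(rep("D", 5), rep("E", 5))))
  expect_equal(information_content(build_profile(half, "r1")), log2(20) - 1,
               tolerance = 1e-9)
  unif <- mk_msa(list(AAS))
  expect_equal(information_content(build_profile(unif, "r1")), 0,
               tolerance = 1e-9)
  # gaps are excluded from the distribution: D over half the rows with the
  # rest gapped is still a single-residue column
  gappy <- msa(c("a", "b"), c("DM", "-M"))
  expect_equal(information_content(build_profile(gappy, "a"))[1], log2(20))
  # maximal iff conservation (gap-excluded) is 1
  mixed <- mk_msa(list(c("D", "E"), c("D", "D")))
  ic <- information_content(build_profile(mixed, "r1"))
  expect_lt(ic[1], log2(20))
  expect_equal(ic[2], log2(20))
})

test_that("signature extraction finds fully conserved blocks and nothing in noise", {
  set.seed(20)
  n <- 12
  noise_col <- function() sample(AAS, n, TRUE)
  block <- strsplit("PNILDIQTD", "")[[1]]
  cols <- c(replicate(10, noise_col(), simplify = FALSE),
            lapply(block, rep, n),
            replicate(10, noise_col(), simplify = FALSE))
  x <- mk_msa(cols)
  regs <- extract_signature_regions(build_profile(x, "r1"), tau = 0.9)
  expect_length(regs, 1)
  p <- regs[[1]]$positions
  expect_equal(nrow(p), 9)
  expect_true(all(p$kind == "fixed"))
  expect_equal(p$weight, rep(1, 9))
  expect_equal(p$ref_pos, 11:19)

  # all columns below tau -> empty
  y <- mk_msa(replicate(30, noise_col(), simplify = FALSE))
  expect_length(extract_signature_regions(build_profile(y, "r1"), tau = 0.9), 0)
})

test_that("extraction is invariant to row order and motifs end on fixed positions", {
  g <- make_family(n = 30, background_sub = 0.8, seed = 22)
  prof <- build_profile(g$alignment, g$alignment$id[1])
  regs <- extract_signature_regions(prof)
  perm <- sample(g$alignment$n_rows)
  shuffled <- msa(g$alignment$id[perm], g$alignment$aligned[perm])
  prof2 <- build_profile(shuffled, g$alignment$id[1])
  regs2 <- extract_signature_regions(prof2)
  expect_equal(lapply(unname(regs), `[[`, "positions"),
               lapply(unname(regs2), `[[`, "positions"))
  for (r in regs) {
    p <- r$positions
    expect_identical(p$kind[1], "fixed")
    expect_identical(p$kind[nrow(p)], "fixed")
  }
})

test_that("extraction reproduces the published region-A profile exactly", {
  # build an alignment whose column statistics equal the published region-A
  # conservation series (0.70, 0.99, 0.74, 0.57, sub-tau, 0.95, sub-tau,
  # 0.63, 1.00) anchored at reference position 44
  n <- 100
  lead_col <- function(k) c(rep(AAS[k %% 20 + 1], 25), sample(AAS, 75, TRUE))
  make_col <- function(res, frac) {
    # conserved residue in `frac` rows; remainder spread so no runner-up
    # reaches it
    k <- round(frac * n)
    c(rep(res, k), rep(setdiff(AAS, res), length.out = n - k))
  }
  set.seed(23)
  a_res <- strsplit("PNILDIQTD", "")[[1]]
  a_frac <- c(0.70, 0.99, 0.74, 0.57, 0.30, 0.95, 0.30, 0.63, 1.00)
  cols <- c(lapply(1:43, lead_col),
            lapply(seq_along(a_res), function(i) make_col(a_res[i], a_frac[i])))
  x <- mk_msa(cols)
  prof <- build_profile(x, "r1")
  regs <- extract_signature_regions(prof, tau = 0.47)
  expect_length(regs, 1)
  p <- regs[[1]]$positions
  expect_equal(p$ref_pos, 44:52)
  expect_identical(p$kind, c("fixed", "fixed", "fixed", "fixed", "wildcard",
                             "fixed", "wildcard", "fixed", "fixed"))
  expect_equal(p$weight[p$kind == "fixed"],
               c(0.70, 0.99, 0.74, 0.57, 0.95, 0.63, 1.00), tolerance = 1e-9)
  expect_identical(p$allowed[p$kind == "fixed"],
                   c("P", "N", "I", "L", "I", "T", "D"))
  expect_equal(regs[[1]]$anchor, 44)
})

test_that("two-residue allowed sets appear when the runner-up reaches 0.25", {
  n <- 20
  cols <- list(rep("Y", n), c(rep("C", 12), rep("S", 6), rep("A", 2)),
               rep("P", n), rep("R", n))
  x <- mk_msa(cols)
  regs <- extract_signature_regions(build_profile(x, "r1"), tau = 0.5)
  expect_identical(regs[[1]]$positions$allowed[2], "CS")
})

test_that("gap-heavy sub-threshold columns become optional positions", {
  n <- 20
  set.seed(24)
  cols <- list(rep("Y", n), rep("K", n), rep("G", n), rep("W", n),
               c(rep("-", 12), sample(AAS, 8, TRUE)),  # 60% gapped
               rep("E", n), rep("L", n), rep("D", n), rep("N", n))
  x <- msa(paste0("r", 1:n), apply(do.call(cbind, cols), 1, function(r)
    paste(r, collapse = "")))
  regs <- extract_signature_regions(build_profile(x, "r1"), tau = 0.5)
  expect_identical(regs[[1]]$positions$kind[5], "optional")
})

test_that("logo table round-trips and rows are complete distributions", {
  g <- make_family(n = 15, seed = 25)
  prof <- build_profile(g$alignment, g$alignment$id[1])
  f <- withr::local_tempfile(fileext = ".tsv")
  export_logo_table(prof, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(tab), g$alignment$n_columns)
  freq_cols <- intersect(names(tab), c(AAS, "X"))
  sums <- rowSums(tab[freq_cols]) + tab$gap_fraction
  expect_true(all(abs(sums - 1) < 1e-4))   # written at 6 decimals
  expect_equal(tab[[AAS[1]]],
               round(prof$counts[AAS[1], ] / prof$n_rows, 6), tolerance = 1e-9)
})
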