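# Independent brute-force alignment oracles: plain enumeration over all
# pairwise alignments (no dynamic programming), affine gap cost
# open + L * ext, gap-over-gap columns disallowed.

brute_global <- function(a, b, submat, gap_open, gap_ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  go <- gap_open + gap_ext
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb)
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (i <= la)
      best <- max(best, -(if (prev == "X") gap_ext else go) + rec(i + 1, j, "X"))
    if (j <= lb)
      best <- max(best, -(if (prev == "Y") gap_ext else go) + rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "M")
}

brute_local <- function(a, b, submat, gap_open, gap_ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(ca)) for (i2 in i1:length(ca))
    for (j1 in seq_along(cb)) for (j2 in j1:length(cb)) {
      s <- brute_global(substr(a, i1, i2), substr(b, j1, j2),
                        submat, gap_open, gap_ext)
      if (s > best) best <- s
    }
  best
}

# brute-force motif scan: every window and optional-inclusion mask, scored
# by direct per-character comparison
brute_scan_best <- function(chars, motif) {
  p <- motif$positions
  opt <- which(p$kind == "optional")
  fixed <- which(p$kind == "fixed")
  wsum <- sum(p$weight[fixed])
  best <- -Inf
  masks <- if (length(opt)) expand.grid(rep(list(c(TRUE, FALSE)), length(opt)))
           else data.frame(row.names = 1)
  for (mi in seq_len(max(nrow(masks), 1))) {
    inc <- rep(TRUE, nrow(p))
    if (length(opt)) inc[opt] <- as.logical(masks[mi, ])
    span <- sum(inc)
    if (span > length(chars)) next
    for (start in 1:(length(chars) - span + 1)) {
      w <- 0; off <- 0
      for (k in seq_len(nrow(p))) {
        if (!inc[k]) next
        if (p$kind[k] == "fixed" &&
            chars[start + off] %in% strsplit(p$allowed[k], "")[[1]])
          w <- w + p$weight[k]
        off <- off + 1
      }
      best <- max(best, w / wsum)
    }
  }
  best
}

random_protein <- function(n, alphabet = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
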