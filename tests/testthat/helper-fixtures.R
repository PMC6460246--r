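# shared fixtures, built in code

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# a reference protein carrying the motif consensus at the published anchors
# plus the expected residues at all annotated catalytic positions
make_reference <- function(length = 510) {
  s <- consensus_scaffold(length = length)
  ch <- strsplit(s, "")[[1]]
  ann <- pb2sf_catalytic_sites()
  ch[ann$position] <- substr(ann$expected, 1, 1)
  paste(ch, collapse = "")
}

# small positive family carrying all five built-in motifs
make_family <- function(n = 8, background_sub = 0.05, seed = 11, label = "pos") {
  m <- builtin_pb2sf_motifs()
  generate_family(family_spec(label, n = n, length = 510,
                              background_sub = background_sub,
                              motifs = lapply(m, planted_motif_spec),
                              seed = seed))
}

# three-family dataset: one true family plus two motif-free outgroup-like
# families, mirroring the 2-O / 4-O / 6-O structure
make_three_family_dataset <- function(n = 10, seed = 21,
                                      background_sub = 0.05,
                                      divergence = 0.5) {
  m <- builtin_pb2sf_motifs()
  specs <- list(
    family_spec("twoO", n = n, length = 510, background_sub = background_sub,
                motifs = lapply(m, planted_motif_spec), seed = seed + 1),
    family_spec("fourO", n = n, length = 510, background_sub = background_sub,
                positive = FALSE, seed = seed + 2),
    family_spec("sixO", n = n, length = 510, background_sub = background_sub,
                positive = FALSE, seed = seed + 3))
  generate_dataset(specs, divergence = divergence, seed = seed)
}

blosum_sub <- function(alphabet = c("A", "C", "D", "E")) {
  s <- scoring_scheme()$submat
  s[alphabet, alphabet]
}
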