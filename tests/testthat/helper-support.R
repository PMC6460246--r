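# bootstrap support of the edge splitting `tips` from the rest of the tree
split_support <- function(tr, tips) {
  ntip <- length(tr$tip.label)
  support <- attr(tr, "support")
  for (node in (ntip + 2):(ntip + tr$Nnode)) {
    cl <- ape::extract.clade(tr, node)$tip.label
    if (setequal(cl, tips) || setequal(cl, setdiff(tr$tip.label, tips)))
      return(support[node - ntip])
  }
  NA_real_
}
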