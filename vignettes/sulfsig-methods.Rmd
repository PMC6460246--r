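---
title: "Signature-motif screening for bacterial 2-O-sulfatases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-motif screening for bacterial 2-O-sulfatases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfsig)
```

## The problem

Bacterial glycosaminoglycan (GAG) sulfatases hydrolyse sulfate esters from
chondroitin/dermatan sulfate and heparin/heparan sulfate. The
Δ⁴,⁵hexuronate-2-*O*-sulfatases (SulfAtlas family S1_9) remove the
2-*O*-sulfate from the unsaturated hexuronate left at the non-reducing end of
lyase-digested GAG oligosaccharides. Generic sulfatase signatures (the
universal core motif Cys/Ser-X-Pro-X-Arg around the FGly catalytic residue)
identify a sequence as *a* sulfatase but not *which* sulfatase, and public
annotations of GAG sulfatase specificity are unreliable. The family, however,
carries five short family-specific conserved regions — anchored at positions
44, 86, 194, 301 and 417 of the reference enzyme PB2SF — that surround the
catalytic centre in the folded protein. `sulfsig` turns those regions into an
operational screen: given candidate protein sequences it scores each against
the five signature motifs, checks the core motif and the catalytic residue
set, and (optionally) tests whether the candidate clusters with the family in
a neighbor-joining tree rooted on non-family sulfatases.

## The motif model

A signature motif is an anchored run of positions. Each position is one of

* **fixed** — a 1–2 residue allowed set with a conservation weight
  $w \in (0,1]$ (the fraction of family sequences carrying the residue),
* **wildcard** (`X`) — always occupied, unconstrained,
* **optional** (`(X,0)`) — absent in part of the family.

A candidate window matched against a motif under an optional-position
inclusion mask receives the weighted score
$S = \sum_{j \in \text{fixed}} w_j\,[x_{p_j} \in A_j]$ and the normalized
score $S/\sum_j w_j \in [0,1]$, which equals 1 iff every fixed position
matches. Scanning evaluates **every** start offset and **every** inclusion
mask and keeps the best normalized score (ties: smallest start, then fewest
optional inclusions — fixed so results are bit-stable). Matching is ungapped
inside a motif except at the declared optional positions; spacing between
motifs is unconstrained, because inter-motif distances vary across the
family while the motifs themselves are short contiguous blocks.

The five built-in motifs are transcribed in a single data file
(`extdata/pb2sf_motifs.tsv`) so the encoding can be corrected without code
changes. Two transcription decisions are recorded there: position 92 (the
FGly precursor, published as C/S with no percentage) carries allowed set
{C, S} with weight 1.00, since the core motif is universal in the family;
and the motif-E index published out of order after G440 is encoded as 441 in
order of appearance rather than silently renumbered.

### The verdict rule

The source analysis presents two lines of evidence — the universal core
motif and the five family-specific regions — but no explicit decision rule.
`classify_candidate` therefore uses a conservative conjunction:

> predicted ⇔ the core C/S-X-P-X-R is present inside the motif-B match
> **and** at least 4 of the 5 motifs reach a normalized score of 0.7.

Both the threshold (0.7) and the quorum (4/5) are configurable. The
catalytic positions outside the motifs (N113, K141, H143) are reported as
evidence via reference mapping but do not enter the verdict, as their
conservation is already partly captured by the motifs and the mutagenesis
evidence ranks them as auxiliary.

## Conservation profiling and motif extraction

For an aligned family, each column yields residue counts, the dominant
residue, and a conservation value whose denominator is **all rows including
gapped ones** — so 100% means literally universal presence, matching the
claim that catalytic positions are invariant (a gap-excluded mode is
available). Logo stack heights use the standard sequence-logo statistic,
$\log_2 20 - H$ with gap-excluded renormalized frequencies and no
small-sample correction; the two statistics are reported separately.

`extract_signature_regions` turns a profile into motifs: a region is a
maximal run beginning and ending at columns with conservation ≥ τ,
containing at least `min_conserved` = 4 such columns, with no interior gap
of more than `max_wildcard_run` = 3 consecutive sub-τ columns. Sub-τ
interior columns become wildcards; columns with gap fraction ≥ 0.5 become
optional, which is our operational reading of the `(X,0)` notation (a
position absent in roughly half the family); runner-up residues at ≥ 0.25
give two-residue allowed sets (this is what reproduces the published C/S92).
The default τ = 0.47 is taken from the weakest published conserved position
(F433, 47%); all four knobs are parameters, not constants.

A consequence worth knowing: published weights near 50% sit *at* the
threshold. In simulations at n = 200, the realized conservation of S98
(published 50%) falls below τ in a sizeable minority of families; the
97–100 linker then exceeds the wildcard-run limit and the two-position
T101–G102 tail of region B detaches. Re-extraction of all five motifs
intact is therefore an ~80% event per simulated family, not a certainty —
the bundled acceptance test fixes a seed, and the acceptance script reports
the recovered count for whatever seed is supplied.

## Alignment machinery

Pairwise alignment is affine-gap dynamic programming (Needleman–Wunsch and
Smith–Waterman; a gap of length $L$ costs $\text{open} + L\cdot\text{ext}$),
compiled in C++, with BLOSUM62 / open 11 / extend 1 defaults — the BLASTp
convention, since the emulated search is a BLASTp screen. Percent identity
uses all alignment columns in the denominator (the BLAST convention; the
source does not state one), and query cover is the fraction of the query
spanned by the local alignment. Homolog screening keeps, per query, the up
to 100 highest-identity subjects **strictly** above 40% identity, the
published rule's literal reading; an optional query-cover floor is off by
default since
covers are reported but no threshold is stated. Traceback tie-breaks
(match, then gap-in-subject, then gap-in-query) are fixed for
reproducibility. Test oracles: exhaustive enumeration of all alignments for
short pairs (up to length 3 exhaustively, lengths 4–6 by seeded sampling —
the full cross of length-≤6 pairs over a 4-letter alphabet is ~10⁷ pairs
and adds nothing), plus `Biostrings::pairwiseAlignment` as an independent
implementation.

The progressive aligner is intentionally simple: guide tree by neighbor
joining on p-distances from pairwise global alignments, then leaf-to-root
profile–profile global alignment with sum-of-pairs (expected substitution)
scores; no iterative refinement. Externally computed alignments (aligned
FASTA or Clustal) are accepted at every downstream stage for parity with
workflows that use a dedicated aligner.

## Phylogeny

Distances are p-distances with pairwise deletion (the tree figure's scale
bar is in substitutions per site and no model is named; a correction would
be a config option, not a default). Neighbor joining is the Saitou–Nei
agglomeration with the standard Q criterion, with two conventions fixed for
reproducibility: ties in Q break by the lexicographically smallest label
pair, and negative branch lengths clamp to 0 without redistribution.
Bootstrap resamples alignment columns with replacement, rebuilds the NJ
tree, and counts unrooted bipartitions (via `ape::prop.clades`); replicates
in which some pair shares no sampled columns contribute no bipartitions.
All randomness flows from one seed.

Because the synthetic generator draws family members as *independent*
mutants of an ancestor (a star phylogeny — see below), within-family
internal edges have near-zero length and their bootstrap supports are
intrinsically unstable; only the long family-separating edges are
decisively supported. The convergence test therefore tracks the
family-splitting edge, which is the biologically meaningful one.

**Clade membership.** After rooting on the outgroup attachment edge, the
default rule calls a candidate *inside* when it descends from the MRCA of
the supplied family members. With only two or three known references this
rule misfires whenever a genuine family member attaches basally to the
references' MRCA — which happens regularly on star-generated families.
`run_prediction` therefore uses the *attachment* rule: inside iff the
smallest clade containing the references **and** the candidate contains no
outgroup leaf. This matches how the published tree was read (the 4-O and
6-O families jointly as outgroup) and presumes the outgroup set represents
every non-family branch — supply outgroups accordingly.

## ORF-level properties

GC content is $100(G+C)/(A+C+G+T)$ with N excluded from both sides,
reported to one decimal. Translation uses the bacterial/archaeal code
(table 11). Molecular weight is the sum of average (not monoisotopic)
residue masses plus one water, matching the web-server convention behind
the published ~56.8 kDa. The isoelectric point solves for zero net
Henderson–Hasselbalch charge over the termini and D/E/C/Y/H/K/R side chains
with the Bjellqvist pKa set, by bisection on pH 0–14 to 0.001; an
independent implementation of the same convention (`seqinr::computePI`)
agrees to ~0.01 pH units in tests. Whether the published mass was computed on
the full ORF translation or the mature chain is not stated; we assume the
full ORF.

## The synthetic generator

`generate_family` draws a uniform-residue ancestor, writes the motif
consensus residues in at their anchors, and then draws each family member
independently: fixed positions keep the consensus with probability equal to
the conservation target (else substitute uniformly among the 19
alternatives — so the realized conservation is exactly binomial with the
target as its mean), background positions substitute with probability
`background_sub`, and optional positions are deleted with probability
1 − presence. The star-phylogeny choice is deliberate: conservation
percentages are column-wise statistics, and independence gives exact
binomial expectations for the recovery tests. Its cost is the unrealistic
within-family topology noted above; `generate_dataset` adds the
between-family structure (independent ancestors mutated from a common base
at `divergence/2` per site, so families share a column coordinate system)
used by the phylogeny tests.

Default conditions, chosen once: ancestor length 510 (the reference enzyme
is 510 residues); `background_sub = 0.8` for profiling scenarios, putting
background columns at ~0.2 conservation — comfortably below τ, as in a
deeply divergent family; optional-position presence 0.5, the natural
reading of "(X,0)"; and `background_sub = 0.05` with `divergence = 0.5` for
the three-family phylogeny scenarios, mirroring a within-family /
between-family identity contrast of roughly 90% vs 50%. Sequence sets in
the bundled tests range from 6 to 200 members — 200 where binomial
concentration is measured, small family trios elsewhere.

What passing these tests does **not** show: real families are
phylogenetically correlated (conservation estimates on real alignments are
not binomial), substitutions are not exchangeable-uniform, and indels occur
outside optional positions. The generator validates the machinery, not the
biology; the published-value spot checks against public accession records
(see the acceptance tests) are the bridge to real data and require the
records to be supplied locally, as this package ships no third-party
sequence data.

## Degenerate inputs and numerical conventions

Empty sequences are errors in alignment; a local alignment with no
positive-scoring cell is reported as a no-hit rather than an empty
alignment. All-gap alignment columns are invalid in `msa`; the generator
drops columns deleted in every member and records the column-to-ancestor
map. A candidate shorter than a motif's minimal span yields an
"unmatchable" record, not an error. Duplicate removal is exact full-string
equality after uppercasing, first occurrence wins. Bisection tolerance for
pI is 0.001 pH; logo tables are written at 6 decimals; Newick branch
lengths at 6 decimals, labels with spaces single-quoted.

## Known limitations

* The scanner has no E-value model; the null calibration is empirical
  (uniform-residue sequences, <5% per-motif pass rate at threshold 0.7).
* The progressive aligner has no refinement and is not meant for more than
  a few hundred sequences; use a dedicated aligner and feed the result in.
* p-distances saturate for deep divergence; model corrections are not
  applied by default.
* The published headline counts (60 predicted family members; the
  per-query hit splits) depend on a database snapshot and are out of scope.
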