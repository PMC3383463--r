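---
title: "Reconstructing ancestral karyotypes from chromosome painting data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral karyotypes from chromosome painting data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoanc)
```

## The data model

Zoo-FISH with human whole-chromosome probes partitions a species' karyotype
into *conserved segments*, each homologous to one human chromosome (HSA
1–22, X; no Y probe data exist for these taxa). A `painting_map` records,
per chromosome pair, the ordered list of human-chromosome blocks, plus the
features painting cannot see cleanly: wholly unpainted euchromatic pairs,
unlabeled euchromatic regions on otherwise painted chromosomes,
C-band-positive heterochromatin (recorded but excluded from all counts),
and "?" marks for uncertain blocks. All quantities are per haploid
complement except the diploid number,
`2n = 2 × (painted + unpainted autosome pairs) + sex chromosomes`.

Three counting identities tie the representation together and are enforced
by tests on every map, real or simulated:

* painted chromosomes = segments − junctions;
* segments(tip) = segments(ancestor) + fissions on the root-to-tip path;
* chromosomes(tip) = chromosomes(ancestor) + fissions − fusions.

One transcription subtlety: where a chromosome carries two blocks of the
same human chromosome separated by another segment (the *B. variegatus*
16/12/22/16 chromosome), the two same-probe blocks count as two segments
and the chromosome contributes three junctions — the only reading
simultaneously consistent with that species' printed totals of 36 segments
and 2n = 54. Segment order on that chromosome is flagged unordered, since
painting does not resolve it.

## Characters and uncertainty policies

Association characters are unordered, orientation-free sets of human
chromosomes co-occurring on one chromosome, scored as occurrence counts;
triples (12/22/16, canonicalized to 12/16/22) are characters of their own
and are **not** decomposed into their contained pairs — with one documented
exception: the 7/10 character is scored by containment, so *Tamandua*'s
20/7/10 chromosome counts as 7/10-bearing, which is how that species has
always been read in the comparative literature. Fragment-count characters
are ordered non-negative integers, one per human chromosome.

"?" entries pass through one of three policies chosen per analysis and
recorded in the output: `missing` (default — presence unknowable),
`optimistic` (score the printed value), `pessimistic` (score the minimum).
Failed probes (HSA 21 in *B. variegatus*; Y everywhere) are always missing:
no policy can conjure data a probe did not produce. Count uncertainty
("8?") becomes an integer interval that the ordered-parsimony engine treats
as free within its bounds.

## Reconstruction engines

All engines share one generalized dynamic program over an integer alphabet
with step cost |i − j|: on {0,1} it is unweighted Fitch parsimony, on
counts it is ordered (Wagner) parsimony. On trees of ≤ 15 tips every most
parsimonious reconstruction is enumerated exactly (the per-node state sets
come from the up/down-cost decomposition, the assignments from optimal
backtracking); larger trees fall back to exact state sets without event
placements, with the method recorded. Missing tips constrain nothing;
polytomies are handled natively by the dynamic program. A brute-force
enumerator over all internal assignments (refusing > 12 internal nodes) is
the independent oracle: the suite checks cost equality on 500+ random
characters and exact MPR-set equality on a further sample, plus agreement
with phangorn's independent parsimony scorer.

Dollo parsimony (single origin, unlimited losses) is available per
character and places the gain on the stem of the minimal clade spanning the
present tips. It is *not* the default: the analysis rejects convergent
associations such as 2/8 and 11/19 on Fitch logic (multiple independent
gains are cheaper than an ancestral presence with many losses), which a
Dollo default would silently ancestralize.

## Outgroup tie-breaking, overrides, assertions

The ancestral Eutherian karyotype (AEK) enters the analysis as an ordinary
outgroup tip basal to Xenarthra — that is how outgroup comparison actually
polarizes these characters — and ambiguity is resolved top-down: the root
is drawn to the outgroup state, descendants keep their parent's state
wherever it remains optimal (changes are pushed tipward, i.e. DELTRAN; the
policy is named in every output, never silently chosen), and tips take
their observed values.

Two stronger mechanisms encode outgroup evidence that plain parsimony
cannot see, both confined to an explicit, provenance-carrying override
table (`xen_overrides()`):

* **resolution** (7/10): Fitch leaves the Xenarthra node genuinely
  ambiguous at cost 3. Genome comparison places a 7q/10p association in
  the opossum and the chicken, i.e. in deep outgroups; the override
  resolves the ambiguous node to *present*. The result is a stem gain with
  secondary losses in *C. hoffmanni* and *D. novemcinctus* — reported with
  a caveat flag, since in both species an unlabeled segment adjacent to
  the HSA 7 block may well be the undetected 10p material.
* **assertion** (HSA 3 and HSA 4 counts, at the Xenarthra node): strict
  ordered parsimony puts the ancestral count at {2,3} and 2 respectively,
  driven by the armadillos and the heavily rearranged *Tamandua*. The
  analysis instead asserts one block each, on the grounds that these
  fissions recur convergently across placentals and both chromosomes are
  intact in the ancestral Eutherian complement and the outgroups. An
  assertion never masquerades as parsimony: the provenance records the
  conflicting parsimony interval alongside the justification.

HSA 1, 6 and 11 need no assertion — their Wagner intervals are ambiguous
({1,2}) and the outgroup tie-break picks 1. HSA 6 is the case the data
genuinely leave open; the two-block alternative is emitted as a labeled
variant (`axk$variants`) rather than discarded.

## Assembly

Resolved states become blocks (per-HSA counts) and adjacencies (present
associations). Which sub-block joins which partner — that the 4/8 fusion
involves the first HSA 8 block, that 7a joins 10 while 7b joins 16, that
16/19 is the q-arm fusion — is read from a packaged assignment table
derived from the ancestral Eutherian block composition, never guessed. For
simulated data without packaged assignments, blocks are allocated
greedily from the free pool, which cannot merge two associations through a
shared block. Chromosomes are the connected components of the resulting
graph (igraph); any block with more than two adjacency endpoints, or an
adjacency demanding a block the counts do not provide, is a reported
conflict, not a silent repair. The X is always its own component; the Y is
metadata only.

## The simulator

`simulate_karyotypes()` evolves an assembled ancestor (default: the AEK)
along a tree by exactly the two event types the character system can
observe: whole-chromosome end-to-end fusions and single-block fissions,
drawn as Poisson processes per branch (branch lengths default to 1).
Translocations and inversions are invisible to association/count characters
and are deliberately out of scope. Defaults are fusion and fission rates of
0.1 events per unit branch length — low, matching the rare-genomic-change
premise of the method — with no probe masking; masking and unpainted-pair
probabilities emulate the failure modes seen in real experiments. Every run
is reproducible from its seed and returns a ground-truth event log and true
karyotypes at every node, so tests can verify the event algebra per
replicate, plant a fusion on a chosen stem and demand its recovery as that
clade's signature, and measure root-karyotype recovery: at rates 0.1/0.1 on
a four-tip tree with the ancestor as outgroup (50 seeded replicates), mean
adjacency F1 in the calibration run was 1.0; the test
threshold is frozen at 0.95, and a rate grid (0, 0.15, 0.6) checks that
recovery degrades monotonically as events accumulate. What passing these
tests shows is that the pipeline is faithful to its own model — fusions and
fissions on a known tree; it does not certify performance on real data
whose rearrangements include event types the model excludes.

## Problem sizes and numerical choices

The real dataset is small by design — 9 taxa, ~45 characters — and every
published quantity is recomputed at full size in seconds. Property tests
use trees of 4–12 tips (the brute-force oracle's enumeration limit) with
500 random characters for cost equality; the simulator tests use 4-tip
trees with 5–50 replicates. Ties between equal-cost states are broken
deterministically (toward the outgroup state, then the smaller state), so
identical configurations always produce byte-identical report bundles.

## Known limitations

* Characters are arm-agnostic: whether the 10 in 7/10 is 10p everywhere is
  likely but not demonstrable from painting data, and the package never
  claims segment-level homology (the 1/19 question across supraorders is
  exactly the kind of claim painting cannot settle).
* The printed source tables under-determine two karyotype structures
  (*B. tridactylus*, *E. sexcinctus*); their fixtures carry validation
  advisories rather than invented chromosomes, and three *T. tetradactyla*
  count cells are flagged where the printed association list and count
  columns cannot both be realized by one structure.
* No statistical support values are attached to signatures; with single
  characters and a fixed topology, bootstrap-style resampling would be
  theater.
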