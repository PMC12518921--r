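---
title: "Segmenting modular proteins from predicted aligned error matrices"
author: "spaedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting modular proteins from predicted aligned error matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaedr)
```

# The signal in the PAE matrix

AlphaFold-family predictors report, next to each structure model, an
L × L matrix of predicted aligned errors: `pae[i, j]` is the expected
error (in Å) in the position of residue *j* when the model is
superimposed on residue *i*. Within a compact, autonomously folded
domain the relative placement of residues is confident and the PAE is
small (a few Å); between two domains whose mutual orientation is not
fixed, it is large (tens of Å). A modular protein therefore appears in
the PAE as low-error blocks along the diagonal separated by high-error
off-diagonal regions, while linkers and disordered termini — residues
confidently placed only relative to their immediate sequence
neighbours — contribute thin low-error bands hugging the diagonal.

`spaedr` segments a chain by clustering residues on exactly this signal.
The approach assumes the input protein has *compact, mutually separate
domains*, which is the norm for phage endolysins, cellulosome components
and many other modular proteins; the limitations section below describes
where the assumption breaks.

The raw matrix is asymmetric (aligning on *i* and measuring *j* is not
the same experiment as the converse), so the first step is always the
symmetrization `(pae + paeᵀ)/2`, which makes the residue-pair error a
single quantity. `symmetrize()` is exact, idempotent and
mean-preserving; `spaedSegment()` applies it automatically when given a
raw matrix.

# The five-step procedure

**1. Hierarchical clustering.** Each residue is represented by its full
row of the symmetrized matrix — its error profile against every other
residue — and residues are grouped by agglomerative single-linkage
clustering of the Euclidean distances between profiles. The tree is cut
at the smallest height yielding at most
`maxclust = max(2, round(maxClusterFraction × L))` flat clusters (the
default fraction is 0.10). The cap is deliberately far above the 1–4
domains expected of a lysin: the slack lets loose regions shatter into
many small, often singleton clusters while each compact domain
coalesces into one long cluster, and the downstream steps then only
have to clean up the fringes.

Two numerical details matter here. First, the cut is by *height*, not
by cluster count: when merge heights tie (e.g. groups of residues with
identical profiles), every merge at the threshold height happens, so
the number of flat clusters can drop below `maxclust` — zero-distance
blocks are never split. Second, flat cluster indices are renumbered by
first residue of appearance, which makes the pipeline deterministic and
invariant to relabelling (a property the test suite checks explicitly;
the clustering itself is also verified against a brute-force
agglomerative oracle with lowest-index tie-breaking on small matrices).

**2. Identify domains.** Clusters with *strictly more than*
`minDomainCluster = 25` residues become domains; all other residues are
provisionally `non_domain`. The threshold sits just under the smallest
expected domain size (> 30 residues), leaving a buffer for residues the
preliminary clustering misplaces. The strict inequality resolves the
boundary case deliberately: a 26-residue cluster is a domain, a
25-residue cluster is not.

**3. Correct ends.** Each terminus is treated independently, N first.
The maximal terminal run of `non_domain` residues is absorbed into the
adjacent domain when it is strictly shorter than
`terminalMergeLen = 20` residues. A longer run is kept as *disordered*
only if it fails a compactness test: counting, for each residue, the
neighbours *within the region* at PAE < `lowPae` (5 Å), the region is
disordered when strictly more than `disorderFraction = 80%` of its
residues have at most `disorderNeighborMax = 5` such neighbours. A
region that passes as compact is a less densely packed, but still
ordered, extension of the neighbouring domain and is merged into it.
The residue itself and the diagonal are excluded from the neighbour
count, and the count is restricted to the region because the question
is whether the region has internal tertiary structure, not whether it
touches the domain.

**4. Correct artifacts.** Preliminary clustering occasionally labels a
few residues inside one domain's span with another cluster. Two repair
rules, iterated to a fixed point, restore contiguity: (i) a single run
of residues (non-domain or belonging to another domain) strictly
between two runs of the same domain is absorbed into that domain;
(ii) a domain whose residues still form several runs keeps only its
longest run — ties resolved toward the N-terminus — and the other runs
revert to `non_domain`. A full-sequence scan subsumes any fixed-width
sliding window, needs no window-size parameter, and guarantees the
postcondition that every domain is one contiguous stretch. Domains are
renumbered 1..n by position afterwards. Rule (ii) can, in principle,
leave a domain smaller than 25 residues; this is permitted, since the
alternative (deleting the domain) would discard real signal.

**5. Adjust linkers.** A residue genuinely inside a domain has PAE <
`lowPae` with roughly as many residues as the domain contains, whereas
a linker residue is in contact with only a handful — which is why the
support count here is taken against the *whole chain*, not the local
region. For each interior `non_domain` run flanked by two domains, a
walk from the left edge claims residues for the left domain while their
support is at least `linkerSupport = 25`, stopping at the first failure;
a second walk claims residues for the right domain from the right edge,
never passing the left walk (left priority if they meet). The surviving
middle is the linker; it may vanish entirely, leaving two directly
abutting domains — zero-length linkers are legal. Only domain growth is
implemented: whether the boundary may also move *into* a domain is left
open by the method's description, and shrinking would re-open the
contiguity questions step 4 just settled.

## Degenerate inputs and edge policies

A segmentation must always tile the chain, so degenerate inputs resolve
by policy rather than error:

* chains with fewer than 2 residues are rejected ("protein too short");
* if step 2 yields no domain at all, the whole chain becomes a single
  region — of kind `domain` when L > `minDomainCluster`, of kind
  `disordered` otherwise. A fully disordered 60-residue band matrix
  therefore comes back as one full-length region rather than an error;
* step-4 longest-run pruning can expose a *new* terminal non-domain
  run (the pruned run sat at a terminus). The pipeline re-applies the
  step-3 terminal rule in that case, and the final label-to-region
  conversion has a defensive fallback (interior leftovers between two
  domains become linkers, terminal leftovers disordered) so the tiling
  invariant can never be violated.

Coordinates are 1-based inclusive throughout, the structural-biology
convention; the JSON readers confine any 0-based bookkeeping to the I/O
layer.

# Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `maxClusterFraction` | 0.10 | — | flat-cluster cap as a fraction of L |
| `minDomainCluster` | 25 | residues | cluster size strictly above ⇒ domain |
| `terminalMergeLen` | 20 | residues | terminal runs strictly below merge blindly |
| `lowPae` | 5 | Å | contact threshold |
| `disorderNeighborMax` | 5 | residues | "poorly connected" neighbour cap |
| `disorderFraction` | 0.80 | — | poorly-connected fraction strictly above ⇒ disordered |
| `linkerSupport` | 25 | residues | chain-wide contact count claiming a residue for a domain |

The defaults are tuned for endolysin-like proteins. Lowering
`terminalMergeLen` or `disorderFraction` detects disordered termini more
sensitively; lowering `linkerSupport` lengthens predicted domains at the
expense of linkers; other protein families may need different contact
thresholds. All seven are exposed both programmatically
(`SpaedParams()`) and as CLI flags.

# Evaluation metrics

`iouScore()` matches predicted to reference domains one-to-one so as to
maximize the summed per-pair intersection-over-union of residue sets,
then divides by `max(nPred, nRef)`. The matching is an exhaustive
assignment — domain counts are small, so this is exact and cheap — and
the normalization penalizes over- and under-segmentation symmetrically
(an unmatched domain contributes 0). If neither segmentation has a
domain the score is 1; if exactly one has none, 0.

`dbdScore()` scores boundaries: the internal domain edges of each
segmentation, taken at half-integer positions between residues, with
chain termini excluded and edges shared by abutting regions counted
once. A boundary earns `max(0, 1 − d/8)` against the other set, where
*d* is the residue distance to the nearest counterpart — one point for
an exact prediction, 1/8 lost per residue of displacement. The accuracy
component averages predicted boundaries against the reference, the
sensitivity component the converse, and the reported score is their
arithmetic mean — the simplest symmetric combination capturing both
over- and under-prediction of boundaries; separate accuracy and
sensitivity views are available through `boundaryCurves()`, which
reports, for each permissibility distance 0–7 residues, the fraction of
boundaries with a counterpart within that distance. Empty-set
conventions mirror the DBD score (both empty ⇒ 1, exactly one empty ⇒
0, which keeps the curves constant and hence non-decreasing).
`aggregateReports()` averages per protein first — mean and population
SD over proteins, curves averaged per distance.

# The synthetic generator

`randomArchitecture()` samples lysin-like architectures — 1–4 domains of
40–250 residues, linkers of 3–20, each terminus disordered with
probability 0.25 at 20–60 residues — and `generatePae()` renders an
architecture as a PAE matrix: intra-domain pairs uniform(0.5, 4) Å,
pairs spanning different domains uniform(15, 30), linker/disordered
residues low only within the ±2 near-diagonal band, independent
Gaussian noise (sd 0.5 Å by default) per cell, values clipped to the
AlphaFold2 ceiling of 31.75 Å, zero diagonal. The uniform ranges put
the 5 Å contact threshold cleanly between the intra-domain and
everything-else distributions with a noise margin on both sides. The
noise is added asymmetrically on purpose, so symmetrization is a
load-bearing, testable step. Both functions are deterministic per seed
and restore the caller's RNG state.

What the generator does *not* emulate is as important for interpreting
test results: real PAE matrices have spatially correlated errors,
partial inter-domain confidence (tightly packed domains can show PAE
well below 15 Å across the interface), discontinuous domains, and
multimer cross-chain blocks. Passing the recovery experiment therefore
demonstrates that the pipeline's logic is correct on the block-plus-band
signal it is designed around — not that real proteins segment at the
same rates. The hard cases can be approximated by lowering the
inter-domain range toward 5–8 Å when constructing matrices manually.

# Validation setup

The test suite validates each step against hand-computable fixtures
(contact-graph constructions for the disorder filter, crafted support
profiles for the linker walks, a brute-force single-linkage oracle on
matrices of up to 12 residues) and runs a recovery experiment of 200
random architectures at noise sd 0.5, checking mean IoU ≥ 0.95, mean
DBD ≥ 0.85, the exact domain count in ≥ 95% of proteins and all
boundaries within 3 residues in ≥ 90%. The same experiment, at the same
problem size, is what `scripts/acceptance.R` reruns from scratch; 200
proteins of up to ~1100 residues keep the full run in the order of a
minute on one CPU while leaving the binomial sampling error on the
checked rates at about one percentage point.

# Known limitations

* **Discontinuous domains** (formed from separate sequence segments)
  are out of scope by design: step 4 actively enforces contiguity, so a
  genuinely discontinuous domain will have its shorter segments
  reassigned. A substantial minority of domains in general structure
  databases are discontinuous; for such proteins a different tool
  should be used.
* **Tightly packed domains** with confident mutual orientation produce
  low inter-domain PAE and can merge into a single predicted domain;
  the PAE simply does not separate them.
* Disordered termini are reported structurally; whether one is a signal
  peptide is not classified.
* Reference delineations without disorder annotations simply have fewer
  boundaries; the DBD accuracy component is unaffected by boundaries
  the reference does not define, but sensitivity comparisons across
  differently annotated references should be read with care.
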