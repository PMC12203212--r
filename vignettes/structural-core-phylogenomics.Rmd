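---
title: "Structural core-gene phylogenomics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural core-gene phylogenomics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the design was
genuinely open.

## The pipeline in one paragraph

Each input species is a proteome in which every protein carries two
equal-length strings: its amino-acid sequence and its 3Di string, the
20-letter structural alphabet that encodes each residue's local tertiary
geometry. Because structure diverges far more slowly than sequence, 3Di
comparison detects homology well below the amino-acid twilight zone (~30%
identity). The pipeline clusters all proteins across species on combined
structural+sequence similarity, calls a cluster a *structural core gene*
when it is single-copy in at least a threshold fraction of species, aligns
each core gene in 3Di space, maps the alignment back to amino acids,
concatenates the per-gene alignments into a partitioned supermatrix, and
infers a species tree from it.

## Scoring model and E-values

A pairwise alignment column scores

$$S = w_{3Di}\,S_{3Di}(x, y) + w_{aa}\,S_{aa}(x, y),$$

with $w_{3Di} = 2.1$, $w_{aa} = 1.4$ (the convention used for combined
3Di+amino-acid scoring), both weights configurable; each weighted matrix is
rounded to integers so raw scores stay integral. The amino-acid matrix is
BLOSUM62. The 3Di matrix shipped with the package
(`inst/extdata/mat3di_synthetic.txt`) is a synthetic flat +6/−4
match/mismatch matrix, *not* a published structural substitution matrix: it
is the exact log-odds form for the uniform-replacement 3Di process the
generator implements, and any NCBI-format matrix can be supplied instead
via `read_score_matrix()`. `X` is permitted in either alphabet and scores 0
against everything. Alignments are local (Smith–Waterman) with affine gaps
(open 10, extend 1, on the combined-score scale); coverage is the aligned
span over the full sequence length, on each side separately.

Raw scores convert to bit scores as $(\lambda S - \ln K)/\ln 2$, and
E-values as $E = m \cdot n_{db} \cdot 2^{-\text{bits}}$ with $m$ the query
length and $n_{db}$ the total residue count of the database at the round
where the alignment is evaluated. $\lambda$ and $K$ are fitted at model
construction by a method-of-moments Gumbel fit on local-alignment scores of
shuffled random sequence pairs (80 pairs of length 200), using a fixed
internal calibration stream so E-values never depend on the analysis seed;
the fit is cached per matrix/weight/gap combination. This calibration is
deliberately crude — the pipeline only consumes E-values through the
$10^{-3}$ acceptance cut, and true-pair scores sit orders of magnitude away
from the random-score regime on either side of it.

## Clustering

Candidate pairs come from a Linclust-style minimizer prefilter: each 3Di
string contributes its 21 k-mers (k = 6) with the smallest seed-mixed hash
values, and sequences sharing a selected k-mer become candidates, capped per
sequence at `max_seqs` = max(1000, 20 × number of species), ordered by
shared-k-mer count. Greedy assignment then visits sequences longest-first;
an unassigned sequence becomes a centroid and absorbs its unassigned
candidates whose alignment passes E ≤ 10⁻³ and coverage ≥ 0.8 on both
sides. Cascading repeats the same round on the representatives (2 rounds by
default — small databases saturate after two; configurable), merging member
sets when representatives co-cluster. Finally, each non-representative
member is re-aligned against all representatives and moves to the
best-bit-score representative that passes the thresholds, or becomes a
singleton if none does. Every stage preserves the partition property: each
protein sits in exactly one cluster.

`brute_force_cluster()` is the package's own oracle: all-vs-all alignment
followed by deterministic greedy set-cover. It shares the scoring model but
none of the prefilter/cascade machinery, so agreement between the two
(adjusted Rand index, tested at ≥ 0.95 on ~200-record databases) validates
the quasilinear path.

## Core-gene selection

A cluster's *single-copy coverage* is the fraction of **all** input species
with exactly one member in it; species absent from the cluster count in the
denominator. Clusters with coverage at or above the threshold (default 0.8)
are the structural core genes. The comparison is inclusive (≥): a cluster
single-copy in exactly 90% of species is selected at t = 0.9. Multi-copy
species contribute only to `any_copy_coverage`, which is reported but not
thresholded — "excessively multi-copy" is not quantified here; users can
apply their own cutoff. A proteome single-copy in fewer than a strict
majority (⌈(n+1)/2⌉) of the core genes triggers a warning, since reduced
genomes (parasites, symbionts) distort both the core set and the tree.

Two diagnostics support comparison with externally defined gene sets: a
gene maps to the cluster holding ≥ 80% of its members (ties by larger
intersection, then id), and an unmapped gene is called *fragmented* when
the representatives of the two clusters sharing most of its members align
with E < 10⁻³ but coverage < 0.8 — homologs split apart by the strict
coverage rule.

## Alignment, projection, supermatrix

Each core gene's single-copy members are aligned progressively in 3Di
space: a neighbor-joining guide tree on normalized pairwise bit-score
distances fixes the merge order, and profiles are merged by global affine
DP on column scores equal to the mean pairwise combined score between the
two profiles (gaps contribute zero). Equal-score DP paths are resolved
"high road" (diagonal over vertical over horizontal), fixed and documented
so runs are reproducible. Columns with a gap fraction ≥ 50% are then
removed (`'X'` counts as a residue, only `'-'` as gap), with an index map
recording the surviving columns. Projection maps the k-th 3Di letter of
each row to the k-th amino acid of the same protein — positional, with no
re-alignment — and therefore preserves the gap mask exactly; composing the
filter's index map keeps the operation testable against hand enumeration.
Projected alignments concatenate into a supermatrix in which species
missing a gene receive all-gap blocks, with 1-based inclusive partition
ranges written in RAxML style (`JTT+F+I+G` per gene by default, matching
common ML practice for amino-acid supermatrices).

## Trees

The built-in tree builder is distance-based, not maximum likelihood:
Poisson-corrected distances $d = -\ln(1 - p)$ on pairwise gap-free columns
(mismatch fractions ≥ 0.95 clamp to d = 3 with a warning), canonical
neighbor joining (taxa sorted for order invariance, negative branches
clamped to zero), and classical Felsenstein bootstrap (default 100
replicates at desk scale; support = % of replicate trees containing each
split). Maximum-likelihood inference is deliberately delegated:
`run_external_tree()` forwards a verbatim options string to any builder on
PATH (IQ-TREE, FastTree, RAxML-NG) and parses its newick output; the
built-in path never depends on it.

Rooting minimizes ancestor deviation: for a candidate root position, every
leaf pair (b, c) contributes $|2 d(a,b)/d(b,c) - 1|$, where a is the pair's
ancestor under that rooting, and the root minimizing the RMS over all pairs
wins. Because crossing-pair deviations are linear in the position along an
edge, the per-edge optimum is a closed-form clamped quadratic minimum; the
test suite checks it against a brute-force positional search (100 grid
points per edge, refined to convergence) on random trees, and against zero
on clocklike trees. Pairs at zero path distance contribute deviation 0.
Rooting preserves the unrooted topology and total branch length.

Tree comparison uses brute-force quartet enumeration via the four-point
condition on unit-branch-length path distances — O(n⁴), tractable at desk
scale, and simple enough to double as its own oracle. Ultrametricity is
reported as the coefficient of variation of root-to-leaf depths (0 iff
clocklike, invariant to uniform scaling) and reference congruence as the
fraction of reference-resolved quartets reproduced; both are surrogates for
metrics whose original definitions live in external codebases, and are
documented as such.

## The synthetic-data generator

`simulate_proteomes()` draws a species tree (random topology; uniform
branch lengths rescaled so the mean root-to-tip depth equals the configured
height, default 1 — non-clocklike, with every edge long enough to carry
signal) and evolves each family's independent random root AA and 3Di
sequences down it under a Jukes–Cantor-like model: substitution events
arrive at `rate × branch length` per site and replace the letter with a
uniform random other letter, giving the closed-form expected identity
$1/20 + (19/20)\,e^{-(20/19)\,r\,t}$ the tests check against. Defaults:
20 species, 50 core + 50 accessory families, lengths 120–400, loss 0.1 and
duplication 0.05 per species per family, `rate_aa` = 0.5 and `rate_3di` =
0.1 (AA identity roughly 0.4–0.6 and 3Di identity 0.8–0.9 across species
pairs). Duplicates diverge for an extra 10% of tree height. Core families
redraw their loss/duplication events until realized single-copy coverage is
≥ 0.8, so planted status is consistent with the selection rule by
construction; accessory families are present in a random ~40% of species
(the paperless choice here: a presence probability well below the core
threshold, so accessory families are genuinely non-core rather than
borderline). The twilight preset (`synth_config_twilight()`:
`rate_aa` = 1.2, `rate_3di` = 0.05) was chosen from the closed form so mean
within-family AA identity falls below 30% while 3Di identity stays above
80%.

What the generator does **not** emulate: indels (so true alignments are
positional and MSA recovery is easier than on real data), structurally
realistic 3Di strings (real 3Di letters are strongly autocorrelated along
secondary-structure elements; the flat match/mismatch matrix is matched to
this simplification), codon structure, rate heterogeneity across sites, and
horizontal transfer. Passing tests therefore demonstrate the pipeline's
internal correctness and its behavior under decoupled sequence/structure
divergence — not performance on real proteomes, where alignment quality,
paralogy structure and annotation noise are all harsher.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at 20 species × 100 families
(~1,400 proteins, ~0.4 M residues, minutes on one CPU), the
oracle-agreement check on ~200-record databases over 5 seeds, and tree
metrics on 6–8-taxon trees; these sizes were chosen so every claim is
recomputed from scratch at each run while the whole suite stays
interactive. Degenerate inputs are handled explicitly: empty member sets,
all-gap columns, saturated distances, zero-length tree paths and star
references all either error with a named subject or take a documented
defined value (deviation 0, distance clamp). Alignment tie-breaks
(high-road DP, lexicographic ids, longest-first centroids) are fixed rather
than arbitrary so that identical seeds give byte-identical artifacts — the
determinism the manifest/replay machinery relies on.

## Known limitations

The 3Di strings must be produced externally (language model, structure
lookup, or converter function); the package treats translation as a
pluggable boundary and drops proteins with no 3Di source, with a warning.
The built-in tree is NJ — adequate for the synthetic regime and for quick
looks, but ML via the delegation hook is the right choice for publication
trees. E-value calibration is approximate (see above). Quartet similarity
is O(n⁴) and intended for n ≲ 300. The greedy clusterer's candidate
generation is heuristic; its guarantees are empirical (oracle agreement),
not worst-case.
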