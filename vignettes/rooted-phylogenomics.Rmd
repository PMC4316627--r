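---
title: "Rooted phylogenomics with phyloroot: models, screens and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooted phylogenomics with phyloroot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloroot)
```

## The problem

Placing the root of a domain-level phylogeny — for instance, the root of
the Archaea between the Euryarchaeota and a second kingdom-level clade —
requires (i) protein markers that are conserved across the ingroup and a
distant outgroup, (ii) evidence that each marker's gene tree reflects the
species history rather than horizontal gene transfer (HGT) or hidden
paralogy, (iii) a concatenated supermatrix with explicit missing-data
accounting, and (iv) diagnostics for long-branch attraction (LBA), the
artifact by which fast-evolving lineages are pulled toward a remote
outgroup and hence to the base of the tree.

`phyloroot` implements this workflow end to end at desk scale, together
with a gene-family simulator that *plants* the evolutionary events the
screens must detect. Every screening rule and rooting statistic can
therefore be scored against a known truth table, which is how the package
tests itself.

## The substitution model and the simulator

Sequences evolve under a reversible amino-acid model with discrete-gamma
rate heterogeneity:

* **Exchangeabilities.** The default is the Poisson model (all
  exchangeabilities equal, equal frequencies). Its transition
  probabilities have the closed form
  $P_{ii}(t) = e^{-\mu t} + (1 - e^{-\mu t})/s$ with $\mu = s/(s-1)$,
  which lets the simulator and the pruning likelihood be checked against
  exact values. An empirical matrix (e.g. LG) can be supplied as a plain
  matrix; everything downstream is agnostic.
* **Rate heterogeneity.** Among-site rates follow a discretized gamma with
  `n_categories = 6` equal-probability categories represented by their
  conditional means (mean rate exactly 1). Six categories mirror common
  practice for deep-phylogeny inference. The default shape `alpha = 0.7`
  is a typical value for conserved single-copy proteins: strong but not
  extreme heterogeneity.
* **Scaling.** The rate matrix is normalized to one expected substitution
  per site per unit time at equilibrium, so all branch lengths are in
  substitutions/site.

The simulated world (`world_config()`) mirrors the shape of a rooted
two-kingdom analysis: two ingroup kingdoms of `n_classes_per_kingdom`
monophyletic classes, and an outgroup of `n_outgroup_phyla` phyla joined
to the ingroup by a stem edge of `stem_length` substitutions/site.
Defaults — 3 classes of 3 species per kingdom, 24 outgroup phyla with one
species each, stem 0.5, root-to-tip depths 0.75 per side — give a 42-taxon
world whose outgroup diversity matches the downstream coverage filter
(24 phyla) and whose within-class edges (0.05) are well resolved by a few
hundred aligned sites. Edge lengths are fixed fractions of the declared
depths (class stem 0.4, class ladder spacing 0.2, kingdom edge 0.25 of the
ingroup depth), so one number per side controls the overall divergence
scale.

Planted events are modeled the way the downstream screens see them:

* **HGT** replaces the recipient's sequence by the donor's re-evolved
  along a short branch (default 0.05). This is sequence replacement, not
  topology surgery, so the same family can be handed to any tree builder;
  it produces exactly the "intermixed classes" signal the monophyly screen
  targets.
* **Paralogy** adds a second copy for one species, re-evolved along twice
  the copy divergence (default 0.1 per copy). Copy leaves carry a `#n`
  suffix that taxonomy lookups resolve to the parent species.
* **Partial sequences** are contiguous truncation masks (kept fraction
  0.25–0.45 in the benchmark); **mask** and **loss** model patchy coverage
  and gene absence. There is **no indel process**: alignments are
  simulated as homologous columns, because multiple-sequence-alignment
  inference is out of scope and the length filter only reacts to the
  non-gap length.

Each benchmark family draws its events independently (Bernoulli rates
`p_hgt = 0.2`, `p_paralog = 0.1`, `p_partial = 0.1` by default) and its
per-family seed from a documented counter scheme, so any family can be
regenerated in isolation.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: alignment error, compositional heterogeneity
(an alternative contributor to LBA that rate multipliers cannot express),
gene-tree/species-tree coalescent discordance, codon-level effects, and
within-species sampling. Results on real proteomes additionally depend on
the upstream aligner and trimmer.

## Marker detection

`search_homologs()` runs full Smith–Waterman local alignment (affine gaps,
BLOSUM62 by default) of every query against every database sequence — no
heuristic seeding, which is fine at desk scale. Significance is calibrated
from the data themselves: a Gumbel distribution is fitted by maximum
likelihood to the scores of shuffled-sequence decoys, giving
$E = K\,m\,n\,e^{-\lambda s}$. This decoy calibration is correct for any
scoring scheme and is testable against the empirical score tail, unlike
fixed analytic parameters. Hits pass at `E <= 1e-5`.

Families are built **per seed query** (seed plus everything it hit), with
single-linkage merging available but off by default. Retention requires at
least 4 distinct ingroup species, and — once outgroup coverage is enforced
— at least 24 distinct outgroup phyla. Members shorter than 50% of the
family median length are removed as partial sequences; the exact cut-off
is not dictated by any published rule, so it is exposed as
`partial_fraction` and was chosen to separate the simulator's truncation
pathology (kept fraction < 0.45) from natural length variation.

## Gene-tree screening

`screen_family()` makes the traditional manual tree inspection
algorithmic. On a gene tree (by default neighbor joining on
Kimura-corrected distances; user-supplied Newick trees are accepted):

* **Class monophyly** — every ingroup class with two or more members must
  form a clean bipartition on the full tree (unrooted convention); the
  relative order of classes is deliberately ignored.
* **Inter-domain HGT** — the all-ingroup vs. all-outgroup bipartition must
  exist; if not, a greedy search (capped at 5 removals) names the leaves
  whose removal restores it. The cap keeps the search cheap; candidates
  are advisory, the verdict only uses the flag.
* **Within-outgroup HGT** — each outgroup phylum with two or more members
  must be monophyletic on the tree pruned to outgroup leaves. Deep
  inter-phylum order is *not* tested: only recent transfers violate
  within-phylum monophyly, and deep outgroup relationships are typically
  unresolvable anyway.
* **Paralogy** — flagged on copy-number evidence (some species contributes
  two or more sequences). A class split without multi-copy evidence is
  charged to HGT via the monophyly report instead.
* **Coverage and partials** — as in the detection filters.

The verdict is retain iff every enforced check passes. Decisions are
invariant to leaf order and to the arbitrary rooting of the input tree
(both properties are tested). The screen is purely topological and
deterministic — stricter than a human curator, who might forgive weakly
supported intermixing; a support-threshold gate exists but is off by
default.

On the default 500-family benchmark the screen's retain/reject decisions
are scored against the truth table; the acceptance suite requires
precision and recall of at least 0.9 for both decisions. A family's true
status is "reject" iff it carries any planted event; the partial-length
check is enforced as a reject reason there so that the scoring exercises
the detector (in a real analysis one would drop the partial member and
keep the family, which is also supported).

## Supermatrix construction

`trim_alignment()` keeps a column iff its gap fraction is at most 0.2 and
its normalized Shannon entropy (log base 20, gaps excluded) is at most the
threshold. This is a deliberate, deterministic simplification of
window-based trimmers (BMGE-style smoothing is not reproduced); real
pre-trimmed alignments can be supplied instead. `concatenate()` records
1-based inclusive partitions in input order, fills absent species with
all-gap blocks, and reports per-species missing fractions counting both
gaps and absent blocks — the convention under which genome-reduced taxa
show ">50% missing data". `mean_pairwise_identity()` computes cross-group
identity over shared non-gap columns, the statistic used to compare the
phylogenetic depth of two kingdoms.

## Tree inference

The inference engine is deliberately desk-scale and deterministic: full ML
topology search and Bayesian MCMC are external-tool territory and are not
reimplemented. Instead:

* **Distances** — p, Kimura (1983) protein correction, or ML Poisson
  distance with optional gamma correction. When the category count is
  supplied, the gamma correction inverts the exact discrete-gamma
  expectation rather than the continuous closed form; the two differ by a
  small but systematic bias (about +3% at t = 0.3 with alpha = 0.7), and
  the exact inversion makes distance calibration unbiased against the
  simulator. Saturated pairs (undefined correction) receive 1.05 times the
  largest finite distance and are flagged, keeping neighbor joining total
  while preserving honesty.
* **Neighbor joining** — standard Q-criterion NJ; negative branch-length
  estimates are clamped to zero with the deficit recorded.
* **Likelihood** — Felsenstein pruning with pattern compression, gamma
  categories averaged per site, gaps as missing data. Checked against
  brute-force summation over internal states and against an independent
  implementation; invariant to re-rooting.
* **Branch lengths** — coordinate ascent with Brent optimization per edge;
  partial likelihoods are refreshed after every accepted move, so the
  log-likelihood trace is non-decreasing by construction. Convergence:
  sweep gain below `tol` (default 1e-3 log units) or `max_sweeps`.
* **Bootstrap** — nonparametric i.i.d. column resampling (B replicates,
  seeded), support = percentage of replicates containing each original
  bipartition. This replaces rapid-bootstrap heuristics with something
  defined, seedable and testable.

## Rooting and LBA diagnostics

`root_with_outgroup()` requires outgroup monophyly and places the root at
the **midpoint** of the stem edge — no published convention dictates where
on the branch the root sits, and the midpoint is symmetric and stable for
stem-length accounting, which always reports the whole edge.
`interdomain_stem_length()` returns the length of the single edge
separating two monophyletic, exhaustive groups (the MRCA-to-MRCA path);
`stem_ratio()` compares the stems of two marker sets, the quantity used to
contrast translation-machinery markers against other conserved proteins.
`long_branch_flags()` scores each leaf's pendant edge against the median,
flagging robust z-scores above 3 — the MAD-based rule is insensitive to a
few genuinely long branches inflating the spread.

`placement_experiment()` is the LBA diagnostic: a focal taxon set is
placed with and without the outgroup, and its sister — the class-majority
label of the smaller subtree across the attachment edge — is recorded
under each condition, with bootstrap support if requested. The
"sister" definition is a deterministic proxy for verbal statements like
"branched as sister group of X".

`lba_contrast_experiment()` packages the replicated study: one class is
accelerated by a factor of 8 (all edges of its subtree *and* its stem,
since a rate shift acts along the whole lineage), the outgroup sits on a
remote stem (1.5 substitutions/site by default), and the engine is
neighbor joining on **uncorrected p-distances**. The choice of the naive
engine is the point: long-branch attraction is driven by systematic
underestimation of deep divergences, so a deliberately under-fitting
engine reproduces the artifact — basal attachment of the fast clade with
the outgroup present, correct sister without it — while gamma-aware
corrections on the same data place the clade correctly under both
conditions. A design study during development showed the contrast is
robust for the naive engine at stems 1.0–2.0, whereas Kimura-corrected
distances only begin to show attraction around stem 2.0.

## Numerical choices and degenerate inputs

* Newick dialect: branch lengths after `:`, numeric internal labels read
  as supports, no quoted labels or comments; rootedness is inferred from
  top-level arity only. Malformed input errors carry a character offset.
* Missing branch lengths parse as 0; zero-length edges serialize
  explicitly.
* Bipartitions are canonicalized to the side not containing the
  lexicographically smallest leaf, so splits compare across rootings.
* Monophyly of sets of size 0, 1, n-1 and n is vacuously true (unrooted
  convention).
* NJ joins are resolved by ape's deterministic implementation; ties in
  greedy HGT-candidate search break toward the alphabetically first leaf.
* `optimize()` tolerance for per-edge branch lengths is 1e-4; branch
  lengths are bounded by 10 substitutions/site.
* Families smaller than 2 members skip the partial filter with a warning;
  all-columns-removed trimming warns and returns a zero-width alignment.

## Problem sizes used by the test and acceptance suites

The suite exercises the package at sizes chosen to finish in minutes on
one CPU while keeping every statistical band meaningful: 500 benchmark
families of 300–600 sites on the 42-taxon default world for screening
power; 20 replicate 30-taxon, 20-marker datasets with B = 100 bootstrap
replicates for root recovery; 20,000-site alignments for stem-length
recovery (maximum-likelihood branch lengths on a 12-taxon world) and for
the 2.6x stem-ratio comparison; 20 replicates of the 24-taxon LBA
contrast; and 50,000-site pairwise alignments for distance calibration and
stationarity checks.

## Known limitations

* The screen is topological: it cannot distinguish weakly supported
  intermixing from genuine transfer, and it charges class splits without
  copy-number evidence to HGT rather than paralogy.
* The inference engine does not search topology space; on real data with
  model misspecification the NJ backbone, not branch-length refinement, is
  the accuracy bottleneck.
* Rate acceleration is the only long-branch mechanism simulated;
  compositional attraction is not modeled, so the LBA experiment speaks to
  rate-driven artifacts only.
* E-value calibration assumes the decoy score distribution is Gumbel;
  extremely gappy or low-complexity sequences may violate this.
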