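---
title: "Signature connectivity and network-propagation synergy scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature connectivity and network-propagation synergy scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbconnect)
```

herbconnect implements the computational chain used to interrogate the
transcriptional activity of herbal-medicine compounds and their
mixtures: fold-change signature extraction from replicated microarray
intensities, connectivity-map-style scoring of those signatures against
a collection of rank-ordered reference instances, and random-walk-with-
restart (RWR) propagation on a protein-interaction network that turns
disease genes and drug-target genes into comparable, statistically
calibrated effect scores. This vignette describes each model, its
assumptions and tunable parameters, the numerical choices made, and
what the synthetic-data generators do and do not emulate.

## Signature extraction

The signature stage consumes an already-normalised probes-by-samples
intensity matrix (e.g. MAS 5.0 output; normalisation and array QC are
deliberately upstream of this package, which keeps it
platform-agnostic). For each treatment the replicate columns are
collapsed to their arithmetic mean, and the per-probe fold change is
the ratio of the treated mean to the vehicle-control (DMSO) mean on
the intensity scale — not the log scale; a convenience switch
exponentiates log2 input, but the internal contract is the plain
ratio. Probes whose control mean is zero get a flagged-undefined entry
rather than a silent infinity and are excluded from signatures.

The tag sets are a hard threshold on that ratio: up tags at FC ≥ 2,
down tags at FC ≤ 0.5 by default, configurable per run but applied
uniformly across compounds within a run. Two properties follow
directly and are tested as such: tightening a threshold can only
shrink its tag set (monotonicity), and permuting probe order permutes
tag membership identically (equivariance). Probe identifiers are
opaque strings; no probe-to-gene collapsing is performed, because a
collapse rule is a chip-annotation decision this package does not
own — counts it reports are probe counts, and users comparing to
gene-level counts from other pipelines should expect small
discrepancies. Tag sets serialise in the `.grp` convention (one
identifier per line, no header), the input format of connectivity-map
queries; in the original application of this workflow a nitidine
chloride query built this way contained 752 probes (173 up, 579 down).

## Connectivity scoring

A reference instance is one treatment experiment: a full ranking of
the probe universe from most induced to most repressed, plus compound,
dose, cell-line and batch metadata. The query statistic is a weighted
Kolmogorov–Smirnov-style tag enrichment: with `t` tags in a ranking of
`n` probes and `V(j)` the position of the j-th best-ranked tag,

    a = max_j ( j/t − V(j)/n ),   b = max_j ( V(j)/n − (j−1)/t )

and the statistic is `a` if `a > b`, else `−b`. It lies in [−1, 1],
approaches +1 as the tags lead the ranking and −1 as they trail it,
and depends only on the tag positions. Ties in reference rankings are
broken by input order, which instances must therefore supply as a
total order. Tags missing from an instance's universe are dropped with
a warning by default (chip universes differ); an error mode is
available.

Per instance, `ks_up` and `ks_down` are the statistics of the up and
down tag sets. When they share a sign the evidence is discordant (both
tag sets pushed the same way) and the raw score is set to 0; otherwise
the raw score is `ks_up − ks_down`. Raw scores are then scaled across
the collection — positive raws divided by the maximum positive raw,
negative raws by the magnitude of the most negative — so connectivity
scores span [−1, 1] and the best positive instance scores exactly 1,
matching the published contract of connectivity-map result tables.
These combination and scaling rules are fixed here explicitly because
the upstream web service that popularised them does not ship as a
library; the package's own tests pin them against brute-force oracles.

By-compound ("name-level") enrichment orders all instances by
connectivity and applies the same position statistic to each
compound's instance positions. Significance is by permutation:
random k-subsets of positions, enumerated exhaustively when
C(N, k) ≤ 10⁴ and otherwise Monte-Carlo sampled (default 10⁵ draws, a
fixed configurable seed, one-sided resolution 1/n_permutations). The
reported `p_value` is the two-sided permutation p — the observed-side
tail fraction doubled and capped at 1. The doubling matters: the
signed statistic has roughly half its null mass on each side, so the
raw observed-side fraction alone would be anti-conservative by a
factor of about two under label shuffling; the doubled p satisfies
P(p ≤ α) ≤ α, which the test suite checks empirically. The raw
observed-side fraction is reported alongside as `p_one_sided` for
compatibility with result tables that list one-sided enrichment p's,
and a post-hoc filter (`filter_positive_p`) reproduces the common
reporting convention of keeping only positively enriched compounds
below a p cutoff. No cell-line restriction is applied by default;
callers wanting, say, an MCF7-only analysis subset the collection
before querying.

## Network propagation and synergy

The propagation network comes from a weighted edge list
(STRING-style; 0–999 scores are auto-rescaled to 0–1). Edges with
confidence strictly above 0.9 are kept; any declared target gene that
would lose all its edges is re-attached through its single
maximum-confidence edge ("target rescue"). After dropping self-loops
and duplicates, only the largest connected component is retained, and
the adjacency matrix of the remaining simple graph is
column-normalised into the transition operator P. Propagation is
unweighted after thresholding: confidences decide which edges exist
but do not modulate the walk, which normalises a plain adjacency
matrix.

RWR iterates `χ(t+1) = (1 − r) P χ(t) + r χ(0)` from `χ(0)` with
restart probability r = 0.3 (a well-established operating point for
interaction networks; the fixed point is smooth in r, with r → 1
pinning the walk at its seeds and r → 0 approaching the
degree-proportional stationary distribution). Because column-stochastic
P makes the map a contraction with factor 1 − r, the iteration
converges geometrically; the stopping rule is an L1 change below
10⁻¹⁰ with a 10,000-iteration cap, a tolerance far below any score
difference of interest, and the result is verified in tests against
the dense closed form `χ = r (I − (1 − r) P)⁻¹ χ(0)` and against the
fixed-point and mass-conservation identities. Seed strengths follow
the asymmetric convention: disease genes at 1, drug-target genes at
0.01, implemented literally (no normalisation of the disease vector
across its genes). Drug-target sets are differentially expressed gene
sets mapped onto network nodes; genes absent from the network are
dropped with a logged count and the reported target number is the
post-intersection count.

The effect score is the inner product `s = ⟨χ_disease, χ_drug⟩` of the
two steady states — the overlap of the disease-affected and
drug-affected subnetworks. Raw inner products are reported as-is; no
normalisation of the vectors is applied, so absolute values depend on
seed-set sizes and network scale and are only comparable within one
network and protocol. Significance is a z-score against the count-
matched null: 1000 uniform random node subsets of the same size as the
target set (sampled from the whole retained network, without degree
matching — the null constrains only the count; a degree-matched
variant would be a different, stricter null and is intentionally not
the default), with `Z = (s − s̄_r)/Δs_r` using the sample (n−1)
standard deviation so Z is exactly reproducible from the seed. Z > 3
is read, conventionally, as a significantly stronger-than-random
effect.

Two implementation routes compute the null. Because RWR is linear in
its seed vector, `⟨χ_disease, K χ0⟩ = ⟨Kᵀ χ_disease, χ0⟩` with
`K = r (I − (1 − r) P)⁻¹`: one propagation of the disease vector
through the transposed operator turns every null effect score into a
subset sum over its target nodes. This adjoint route is the default
and is exact, not an approximation; the literal route (one full RWR
per random set) is retained as `method = "direct"`, both consume
identical random subsets for a given seed, and a test asserts their
agreement to the iteration tolerance.

The synergy table scores each component's target set and the mixture
against the same disease vector under a shared protocol (one network,
one r, per-row child seeds derived deterministically from the run
seed), mixture first. The default mixture is the union of component
target sets — a modelling choice, appropriate when no separately
measured mixture expression profile exists; when one does, its DEG set
can be supplied directly and is the more faithful design. Synergy is
then operationalised as the mixture's Z exceeding every component's Z.
A component set that is empty after network intersection yields a
flagged all-NA row rather than failing the whole table.

## What the generators emulate — and what they do not

`simulate_expression` draws control intensities from a log-normal
baseline (meanlog log 100, sdlog 0.8 by default — an MAS5-like
positive scale), multiplies planted up-probes by the effect multiplier
(default 4) and divides planted down-probes by it, then applies
multiplicative log-normal noise (default sd 0.1 on the natural-log
scale) independently per replicate, two replicates per condition as in
the emulated experimental design. Multiplicative noise keeps
intensities positive and makes the noiseless case recover planted
sets exactly at the default thresholds.

`simulate_reference_collection` plants concordance labels: +1
instances place the query's up tags at positions drawn from the top
decile of the ranking and down tags in the bottom decile, −1 instances
invert this, 0 instances are uniform permutations. Decile placement
forces the planted instance to the top of the scaled score list at the
tested signature sizes.

`simulate_network` grows a preferential-attachment graph (default 500
nodes, 3 edges per new node), chosen because degree heterogeneity is
precisely the property that stresses a count-matched propagation null;
an Erdős–Rényi alternative is provided for contrast. A randomly placed
disease module (default 30 nodes) is densified with intra-module edges
to a stated density (default 0.25), component target sets are sampled
at stated overlap fractions with the module (optionally restricted to
disjoint module halves, or forced at least a minimum hop distance from
the module), and edge confidences are drawn from (0.905, 0.999) so the
default 0.9 filter keeps the planted graph intact. Every generator is
a pure function of its scenario, and planted truth is emitted as a
machine-readable manifest so tests never re-derive it.

None of these emulate raw array artefacts (background, saturation,
batch effects), correlated noise across probes, the literature-scale
heterogeneity of a real instance collection (6100 instances over many
cell lines and doses), or the ascertainment biases of curated disease
gene sets and interaction databases. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave
as designed under controlled conditions — not that any particular
real-data conclusion is reproduced. Reproducing published absolute
effect scores would additionally require the specific interaction-
database version, disease-gene snapshot and expression series used
there; the pipeline accepts such files through its readers but does
not ship them.

## Numerical and design notes

- Problem sizes used by the shipped checks: 50 random graphs of ≤ 100
  nodes for the closed-form oracle; a 500-node network with 20-node
  target sets, 1000-draw nulls and 200 repetitions for null
  self-calibration; 100 generator seeds for the disjoint-halves
  synergy recovery; 1000 random cases for the tag-statistic oracle;
  500 shuffles for p-value calibration. These sizes give
  Monte-Carlo error comfortably inside the asserted bands while
  keeping the whole suite fast.
- Empty tag set in a query: its KS statistic is defined as 0 (no
  evidence), so a signature with only one non-empty side still scores;
  a signature with both sides empty is an error.
- All-zero raw scores scale to all-zero connectivity (no division by
  zero); a null standard deviation of exactly 0 yields a flagged NA
  z-score with a warning rather than an infinite Z.
- Child seeds for per-row nulls and per-section simulations are
  derived from the run seed by a fixed affine map modulo a 31-bit
  prime, so every reported number is reproducible from the single run
  seed and no derived seed overflows R's integer range.
- Workflow reports carry a provenance header (package version, config
  hash, seed) but no timestamp, so identical configurations produce
  byte-identical reports; timestamps appear only in the stderr log.

## Known limitations

Fold-change thresholding ignores variance information (no
moderated-t); that is faithful to the emulated workflow, not a
recommendation against limma-style inference where replicate counts
allow it. The connectivity score's same-sign zero rule discards
instances with discordant evidence rather than down-weighting them.
The union mixture rule cannot capture sub-additive chemistry (one
component masking another's transcriptional effect) — only a measured
mixture profile can. Effect scores are scale-dependent; compare them
only within a protocol, and prefer the z-scores for cross-set
statements.
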