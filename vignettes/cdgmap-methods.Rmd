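---
title: "Methods and design of cdgmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of cdgmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdgmap)
```

`cdgmap` surveys genes encoding c-di-GMP-metabolizing enzymes across
closed bacterial genomes: it classifies proteins into enzyme groups from
their domain architectures, maps the genes onto a replication-anchored
circular coordinate system, and summarizes positional, numerical and
domain-composition patterns. This vignette records the models behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design decisions taken where more than one
defensible choice existed.

## Enzyme-group classification

A protein is assigned exactly one label from its set of distinct domain
hits:

* GGDEF and EAL both present → `GGDEF_EAL` (hybrid);
* only GGDEF → `GGDEF`; only EAL → `EAL`;
* an HD-superfamily hit, no GGDEF/EAL, and the sequence motif
  `H-H-E-x(5)-G-Y-P` present → `HD_GYP`;
* otherwise `NONE`.

The HD superfamily is mostly unrelated to c-di-GMP, so the motif — the
signature of the catalytically competent HD-GYP phosphodiesterase
subfamily — is what separates a true phosphodiesterase from an incidental
HD domain. Two choices here were genuinely open:

* **Motif scope.** Nothing ties the motif's position to the HD hit
  coordinates, so the default scans the whole sequence
  (`motif_scope = "whole_sequence"`); the alternative
  (`"hd_hits"`) restricts the scan to HD hit intervals ± 10 aa for users
  who want the conservative reading. With real Pfam coordinates the two
  rarely disagree; the package implements both and tests both.
* **Where the motif check is required.** A sequence is demanded only when
  the motif actually decides the class (HD hit present, no GGDEF/EAL).
  A GGDEF+HD protein classifies as `GGDEF` either way, so a missing
  sequence there is not an error.

Auxiliary domains are all distinct domain names minus GGDEF and EAL, and
minus HD only on `HD_GYP` proteins — an HD domain without the motif
riding on a GGDEF or EAL protein is auxiliary. Repeated occurrences of a
domain in one sequence count once, everywhere: in classification, in the
none/one/many categories, and in network node/edge counts. Domain
identity is the Pfam accession when present, else the name, so PAS
subfamilies (PAS_3, PAS_4, …) stay distinct. DUF-family domains are
ordinary nodes; no filtering.

## Chromosome geometry

All replicons are treated as circles with 1-based inclusive coordinates
(GenBank/GFF3 convention); wrap-around CDS (`end < start`) are normalized
to `start..end+L` at read time. The terminus is assumed diametrically
opposite the origin, `ter = ((ori − 1 + ⌊L/2⌋) mod L) + 1`, and a gene's
normalized position is

$$ v = 100 \cdot \frac{(m - ori) \bmod L}{L}, \qquad
   m = start + (end - start)/2 , $$

so *ori* sits at 0% and *ter* at 50%. The CDS **midpoint** is the
representative point: it is strand-neutral and stable for long genes
(gene start would bias long genes by half their length depending on
strand). Strand is recorded but ignored in positional analysis. The
normalized position is rotation invariant and reflects to $100 - v$ under
mirror symmetry about the ori–ter axis; both properties are enforced by
randomized tests.

### GC-skew origin estimation

When no curated ori table is supplied, the origin is estimated from
cumulative GC skew (G = +1, C = −1, A/T = 0): on most bacterial
chromosomes the leading strand is G-rich, so the cumulative curve attains
its minimum at *ori* and its maximum at *ter*. The implementation scans
window sums (default window 1 kb), takes the global minimum, then refines
to the base-level cumulative argmin within ±2 windows. A call is
*ambiguous* when the skew curve is flat, or when a competing local
minimum further than five windows from the global one comes within 5% of
the skew range — two distant candidate origins genuinely are ambiguous,
whereas noise jitter right next to the global minimum is the same
candidate and is not. Ambiguous replicons are excluded from positional
analysis (and the exclusion count reported), mirroring the practice of
keeping only chromosomes with one unambiguously identified origin. This
estimator is a deliberately simple skew-based method; users with curated
origin calls (e.g. from dedicated ori-prediction tools) should supply
them via the ori table, which takes precedence.

## Distributional statistics

**Circular KDE.** Positions live on a circle of circumference 100, so the
Gaussian KDE triples the data at offsets −100/0/+100, evaluates on a
512-point grid over one period, and renormalizes to integrate to 1.
Bandwidth defaults to Silverman's rule-of-thumb on the unwrapped sample —
adequate for the smooth, few-mode densities seen here; no further
bandwidth selection is attempted beyond a user override.

**Two-sample KS.** The comparison is computed *linearly* on the
ori-anchored scale: because every sample is anchored at the same
biologically meaningful zero, the standard KS statistic is interpretable
and matches common practice; a rotation-invariant circular alternative
(Kuiper) would discard the shared anchor, so it is not the default. The
statistic is the ECDF supremum over all sample points (tie-safe); the
asymptotic p-value evaluates the Kolmogorov survival function
$Q(t) = 2\sum_{k\ge1} (-1)^{k-1} e^{-2k^2t^2}$ at
$t = \sqrt{n_e}\,D$, $n_e = n_x n_y/(n_x+n_y)$; the exact permutation
p-value enumerates all $\binom{n_x+n_y}{n_x}$ assignments (vectorized via
signed indicator cumulative sums) and is offered up to $n_x+n_y = 16$.
Tests cross-check both against `stats::ks.test` and against full
enumeration with an independent ECDF oracle.

**Counts and ratios.** Genus means divide the summed gene counts by the
number of genomes in the genus; medians use the standard linear
interpolation at even *n* (so counts 1,2,3,4 give 2.5). Per-genome
ratios with a zero denominator are undefined and are *excluded* from
genus means rather than imputed — only computable ratios are summarized.
Note that a genus mean of per-genome ratios is a mean-of-ratios: under a
Poisson count model its expectation exceeds the ratio of mean counts
(E[1/Y] > 1/E[Y]), which matters when comparing against planted values.
The size–count relationship uses Spearman's rank correlation
(tie-corrected, t-approximation p) on the largest replicon per genome
only.

## Auxiliary-domain analytics

The Venn partition assigns every observed auxiliary domain to exactly one
of the 15 non-empty subsets of the four enzyme groups by its exact
membership pattern; the primary count is of distinct domains per region,
with a sequence-weighted count emitted alongside (the two readings of
"shared among groups" differ only in weighting, so both are reported).
Co-occurrence networks are built per enzyme group (and per order when
taxonomy is supplied): node count = number of sequences carrying the
domain, edge weight = number of sequences carrying the unordered pair.
The length-threshold analysis reports the minimum length among
auxiliary-bearing sequences of a group and the share of auxiliary-free
sequences below it — candidates for domains not yet annotated in the
databases.

## Replicon accounting

The largest replicon of a genome is its primary chromosome; any other
replicon larger than the cutoff (default 800,000 bp, configurable) is a
secondary chromosome; the rest are extrachromosomal. Ties for largest are
broken lexicographically by replicon id and flagged. Per-order summaries
report the share of genomes with c-di-GMP genes off the primary
chromosome, the share of c-di-GMP genes on secondary chromosomes, and the
distribution of genomes by number of replicons above the cutoff (a
0/1/2/>2 breakdown that always sums to 100%).

## The synthetic-data generator

`generate_dataset()` emits exactly the formats the readers consume (GFF3
with region features, nucleotide FASTA, amino-acid FASTA, TSV domain
table, taxonomy and ori tables) plus a machine-readable truth record, all
deterministic given the seed. Its models:

* **Counts.** Per-genome class counts are independent Poisson draws. The
  default profile plants means GGDEF = 4, EAL = 2, GGDEF_EAL = 2,
  HD_GYP = 1, encoding the robust 2:1 dominance of cyclase over
  phosphodiesterase genes.
* **Positions.** Wrapped-normal mixtures on [0, 100): the default profile
  plants EAL at a single mode μ = 5, σ = 6 (near *ori*) and GGDEF
  tri-modal at 25/50/75 with σ = 5 — the qualitative mid-replichore/ter
  versus ori contrast. Wrapped normals were chosen because the observed
  densities are smooth and few-moded; the family is the package's choice,
  not a claim about the data-generating process in real genomes.
* **Placement.** Gene nucleotide coordinates are the planted positions
  rotated by the replicon's planted ori; genes are spaced ≥ 50 bp apart by
  a relaxation that shifts conflicting genes forward around the circle
  (genes pushed past the linear end wrap into the leading gap, keeping
  circular positions close to the sampled ones); configurations whose
  genes cannot fit raise an error rather than silently truncating.
* **Sequences.** HD-GYP proteins carry the motif embedded in otherwise
  uniform-random amino-acid sequence; decoy HD proteins (controlled by
  `motif_rate`) are verified motif-free. Replicon FASTA, when requested,
  is uniform-random nucleotide with a GC-skew switch at the planted ori
  (leading strand G-excess = `gc_skew_strength`, default 0.1) — enough
  for the skew estimator, with no codon structure, realistic GC content,
  or phylogenetic correlation between genomes.
* **Lengths.** Auxiliary-bearing proteins are drawn at or above a
  per-class threshold (EAL 375 aa, GGDEF 275 aa by default); auxiliary-free
  proteins come from a two-component mixture with a planted short
  fraction (default 49%), so the length-threshold analysis is
  exercisable. `plant_length_threshold_group()` builds a deterministic
  fixture in which the threshold and short fraction are exact by
  construction.

Because the generator is the package's own model of the data, passing
recovery tests shows the pipeline is *internally consistent* — it
recovers what was planted, through the real file formats — not that real
genomes obey wrapped-normal mixtures or Poisson counts. Conclusions about
real data still require real annotations.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on deliberately desk-scale
data: profiles of 40–100 genomes with 0.1–4 Mb replicons, 100 kb
chromosomes for skew-recovery (20 replicates), 200 replicates for KS
power/size at n = 150 per group, and full permutation enumeration up to
16 pooled observations. These sizes give stable statistics (KS power
100%, size 3–7% across seeds) while keeping the whole suite near a
minute. Other numerical conventions: coordinates convert to 0-based
half-open only inside arithmetic and back at boundaries; KDE integrals
are verified to 1e−6; the Kolmogorov series is truncated at 100 terms
(error far below the 1e−4 agreement asserted against the reference
implementation); p-values are clamped to (0, 1].

## Known limitations

* The GC-skew estimator assumes a single replication origin and a clear
  leading/lagging compositional bias; plasmids and replicons with
  atypical skew will come back ambiguous (by design) or wrong.
* GFF3 output cannot represent origin-spanning CDS, so generated genes
  never cross the linear seam; the readers do normalize wrap-around
  features from GenBank input.
* The GenBank flat-file reader is minimal (LOCUS length, CDS locations,
  `/protein_id` qualifiers, simple `join`/`complement`); complex compound
  locations are out of scope — use GFF3+FASTA for anything unusual.
* KS on the linear ori-anchored scale is anchor-dependent by intent;
  analyses that need rotation invariance should use a circular statistic
  instead.
* Protein length from annotation is inferred as ⌊(span−3)/3⌋ when no
  protein FASTA is given; programmed frameshifts or nonstandard codons
  will be slightly off.
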