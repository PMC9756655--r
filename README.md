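# cdgmap

Comparative genomics of c-di-GMP signaling genes on bacterial chromosomes.

Bis-(3′-5′)-cyclic dimeric GMP (c-di-GMP) is a near-universal bacterial
second messenger controlling the switch between motile and sessile
lifestyles. Its level is set by diguanylate cyclases (GGDEF domain,
Pfam PF00990) and phosphodiesterases (EAL domain, PF00563, or HD-GYP, an
HD-superfamily domain, PF01966, carrying the HHExxxxxGYP motif); many
proteins are GGDEF–EAL hybrids. `cdgmap` is for microbial comparative
genomicists who want to survey these genes across closed genomes and ask
*how many* there are, *what sensory domains* ride along with them, and
*where on the circular chromosome* they sit relative to the replication
origin.

## What it computes

* **Enzyme-group classification.** Each protein is assigned exactly one of
  GGDEF, EAL, GGDEF_EAL, HD-GYP, or none, from its Pfam-style domain
  architecture. GGDEF and EAL together define the hybrid group; an HD hit
  counts as HD-GYP only when the sequence carries the motif
  `H-H-E-x(5)-G-Y-P`; repeated domains count once. All other domains on a
  classified protein are its *auxiliary* (typically sensory) domains.
* **Ori-anchored gene positions.** Each replicon is circular with the
  origin of replication *ori* at 0% and the terminus *ter* — assumed
  diametrically opposite, `ter = ((ori − 1 + ⌊L/2⌋) mod L) + 1` — at 50%.
  A gene's position is `100 · (((m − ori) mod L) / L)` with *m* the CDS
  midpoint. Ori comes from a curated table or from the built-in cumulative
  GC-skew estimator (G = +1, C = −1; the skew minimum marks *ori*);
  replicons without one unambiguous ori are excluded.
* **Distributional statistics.** Circular Gaussian KDE of positions
  (data tripled at ±one period, renormalized; Silverman bandwidth), and
  two-sample Kolmogorov–Smirnov comparisons between enzyme groups, with
  `D = sup_t |F̂_x(t) − F̂_y(t)|`, asymptotic p from the Kolmogorov
  distribution at `√(n_x n_y/(n_x+n_y)) · D`, and an exact-permutation p
  (full enumeration) for `n_x + n_y ≤ 16`.
* **Count summaries.** Per-genus mean gene counts, per-genome
  GGDEF:EAL / GGDEF:GGDEF_EAL / GGDEF:HD-GYP ratios (zero denominators
  excluded, genus means over defined ratios), per-class medians, and the
  Spearman correlation of largest-replicon size with gene count.
* **Auxiliary-domain analytics.** Venn partition of auxiliary domains over
  the four groups, none/one/more-than-one per-sequence categories,
  co-occurrence networks (edge weight = number of sequences carrying both
  domains; GraphML export), and the minimum protein length carrying
  annotated auxiliary domains with the share of shorter auxiliary-free
  sequences.
* **Replicon accounting.** Largest replicon = primary chromosome; other
  replicons > 800 kb = secondary chromosomes; the rest extrachromosomal —
  and where the c-di-GMP genes fall across them.
* **Synthetic genomes with planted truth.** A deterministic generator
  emits GFF3/FASTA/TSV inputs whose class counts, positional mixtures,
  auxiliary models, motif rates and oris are known exactly, so the whole
  pipeline is testable offline.

## Worked example

```r
library(cdgmap)

cfg <- default_paper_profile(seed = 11)   # 40 genomes, 1 order, 10 genera
ds  <- generate_dataset(cfg)
res <- run_pipeline(ds$genomes, ds$taxonomy, ds$ori_table)

res$medians
#>               class median_count
#> GGDEF         GGDEF            4
#> EAL             EAL            2
#> GGDEF_EAL GGDEF_EAL            2
#> HD_GYP       HD_GYP            1

res$ks_table[res$ks_table$class_x == "EAL" & res$ks_table$class_y == "GGDEF", ]
#>  class_x class_y d_statistic      p_value n_x n_y     method
#>      EAL   GGDEF   0.8050971 2.178289e-31  82 167 asymptotic

de <- kde_circular(res$positions$position[res$positions$class == "GGDEF"])
sort(density_modes(de, min_height_frac = 0.5))
#> [1] 25.19531 50.78125 75.00000
```

The medians say a typical synthetic genome carries 4 GGDEF-only and 2
EAL-only genes (the planted 2:1 ratio of cyclase to phosphodiesterase
genes). The KS test rejects (D = 0.81) because the generator plants EAL
genes near *ori* but GGDEF genes in a tri-modal pattern; the KDE recovers
those planted modes at ≈25%, 50% and 75% of the ori-anchored scale —
mid-replichore and at *ter*.

With real data, point `read_domain_table()`, `read_genome_annotation()`
(GFF3+FASTA or GenBank flat file), `read_taxonomy_table()` and
`read_ori_table()` at your files, or use `load_dataset()` on a directory
in the generator's layout. `inst/scripts/cdgmap` wraps the same calls as
shell subcommands (`generate`, `pipeline`).

## Scope

Phylogenetics (tree building), web retrieval of Pfam/UniProt records, and
biological interpretation are out of scope; the package consumes local
files only. See `vignettes/cdgmap-methods.Rmd` for the modelling choices,
parameter defaults, and known limitations.
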