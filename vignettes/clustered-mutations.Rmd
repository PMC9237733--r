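---
title: "Detecting and classifying clustered somatic mutations"
author: "mutclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying clustered somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutclust)
```

## The problem

Most somatic mutations accumulate quasi-independently across the genome, but
a biologically important minority arrive in clusters: doublet-base
substitutions (DBS) from a single damaging event, multi-base substitutions
(MBS), diffuse APOBEC-style hypermutation (*omikli*), longer
strand-coordinated showers (*kataegis*), and clustered indels. The classical
detector is a fixed inter-mutational distance (IMD) threshold — usually 1--2
kb — which ignores that the *expected* IMD depends on the sample's mutational
burden, its sequence-context preferences, and regional variation in mutation
rate. A fixed threshold over-calls clusters in mutation-dense genomes and
regions, and under-calls them in quiet ones.

`mutclust` instead calibrates a *sample-dependent* IMD threshold against a
simulated background tailored to the sample, then subclassifies every
clustered event.

## The background model

For a catalog of substitutions from one sample, each simulated replicate
redistributes every substitution to a uniformly drawn position that
preserves:

* the centred pentanucleotide sequence context (configurable width `k`,
  default 5);
* the genic/intergenic status of the position and, within genes, the gene
  strand (so transcriptional strand asymmetries are maintained) — when an
  annotation is supplied;
* the per-chromosome mutational burden (mutations never move across
  chromosomes).

Indels carry no context constraint and are re-placed uniformly on their
chromosome. Substitutions whose context window runs past a chromosome end
are excluded from all simulations identically. By default 100 replicates are
generated (seed-derived, reproducible); their 2.5--97.5 percentile band is
the envelope drawn in the IMD panel of the summary figure.

The context index underlying the simulator enumerates, per chromosome and
region class, every position carrying each k-mer (`build_context_index()`).
Because a mutation's own position always carries its own context, postings
are never empty in a full index; for sparsely indexed or very small genomes
a fallback ladder (drop strand class, then region class, then shrink to the
central trimer) is applied and logged, with a warning above 1% fallbacks.

## The sample-dependent threshold

Let `r(d)` be the number of real mutations whose nearest-neighbour IMD (the
minimum of the two flanking gaps) is strictly below a candidate cutoff `d`,
and `s_i(d)` the same count in simulation `i`. Two criteria define an
acceptable cutoff:

1. **Excess over background.** The fraction of sub-cutoff mutations expected
   by chance, `mean_i s_i(d) / r(d)`, is at most `max_chance` (default
   0.10): at least 90% of the mutations below the cutoff are beyond what
   the background model explains.
2. **Significance.** The add-one empirical p-value
   `p(d) = (1 + #{i : s_i(d) >= r(d)}) / (n_sims + 1)` is below `q_alpha`
   (default 0.01). With the default 100 simulations the smallest attainable
   p is 1/101 ≈ 0.0099, so the default is attainable but tight; fewer than
   100 simulations trigger a warning because the threshold then cannot be
   met.

The selected global cutoff is the **largest** `d` in `[2, cap]` satisfying
both, with `cap = 10000` bp; the acceptance indicator is searched by binary
search (verified by direct re-evaluation, with a linear-scan fallback for
pathological non-interval acceptance regions). If no candidate qualifies,
the sample is reported as having no detectable clustering and every mutation
is non-clustered.

### Multiplicity model

The candidate cutoffs are *nested* hypotheses: `r(d)` and each `s_i(d)` are
monotone in `d`, and the candidate tests form a totally ordered family. For
such families fixed-sequence (closed) testing controls the error rate at
level `q_alpha` while testing each member directly, with no
Benjamini–Hochberg penalty; a BH adjustment across thousands of nested,
near-duplicate candidates would instead make the tight default
(`min p = 1/101` vs `alpha = 0.01`) unattainable for every input, since a
single candidate above the minimum p inflates all adjusted values beyond
0.01. The package therefore treats the global stage as a fixed-sequence
family (adjusted p = raw p per candidate) and reserves BH for the regional
stage, where the windows are genuinely parallel hypotheses.

### Regional correction

Mutation rates vary regionally (replication timing, expression). In sliding
windows (default 1 Mb, 50% overlap) the fold difference
`fold = real count / max(mean simulated count, 0.5)` is computed; the 0.5
floor guards empty-window division. Windows with `fold > 1` receive a
candidate local cutoff `floor(global / fold)`, lowered further — if needed —
until the window-restricted excess criterion (≤ 10% by chance) holds and the
window's empirical p survives BH across the corrected windows; local cutoffs
are floored at 1 bp and never exceed the global cutoff. Windows with
`fold <= 1` keep the global cutoff: corrections only tighten. Raising
cutoffs in mutation-poor windows is deliberately not done — a looser local
threshold could only be justified by a *less* significant excess, and users
of quiet genomes are better served by the global value. A mutation (or a
chaining gap) covered by several overlapping windows uses the minimum
applicable local cutoff.

## Chaining and subclassification

Clustered events are maximal runs of consecutive same-chromosome,
same-class mutations in which every internal gap is below the local cutoff
at the gap's midpoint; substitutions and indels chain separately. Each event
is then labelled:

| size | gaps | label |
|------|------|-------|
| 2 | gap = 1 | DBS |
| ≥ 3 | all gaps = 1 | MBS |
| 2–3 | ≥ 1 gap > 1 | omikli |
| ≥ 4 | ≥ 1 gap > 1 | kataegis |
| any indel run | — | clustered_indel |

A run of four or more mutations whose gaps are all 1 is an MBS, not
kataegis — the kataegis definition requires at least one gap above 1.
Substitution events whose adjacent members differ in variant allele
frequency by more than 0.10 (or, preferred when available, in cancer cell
fraction by more than 0.25) are labelled `other`: mutations of one physical
event should co-occur in the same cells, so discordant allele frequencies
argue against a single clustered event. Consistency is judged on adjacent
pairs in genomic order; one inconsistent pair marks the whole event
(re-segmenting at the discordant junction would require a model of event
boundaries that the data do not support). Pairs lacking VAF/CCF pass
vacuously, and such events are flagged low-confidence in the events table.
Clustered indels are never subclassified further.

## Input handling choices

* Coordinates are 1-based inclusive throughout; BED input is converted at
  the boundary (`start + 1`), GFF-like input is taken as is.
* Multi-allelic VCF rows are split into one record per alternate allele;
  records at a duplicated chromosome+position are then resolved by keeping
  the first (the catalog keeps strictly increasing positions, which the IMD
  arithmetic requires). Gap values are therefore always ≥ 1.
* VAF is read from the per-sample `AF` FORMAT field, falling back to
  `INFO/AF` (both configurable); no standard VCF field carries VAF, so the
  source is explicit in the reader's arguments.
* Mitochondrial and non-primary contigs are treated like any chromosome
  present in the FASTA. A chromosome with a single mutation has no defined
  IMD and contributes nothing to threshold calibration or rainfall plots.

## The synthetic-fixture generator

`make_genome()` and `plant_catalog()` produce mini-genomes (uniform base
composition at a requested GC fraction) and catalogs with planted events
whose truth labels are known by construction: background substitutions are
uniform, planted events realise the rule table exactly, and a margin
(default 10 kb) keeps background away from planted spans so labels stay
unambiguous. `score_recovery()` reports per-subclass precision and recall.

What the generator emulates: burden, uniform background spacing, exact
cluster geometries, controllable VAFs. What it does not: real mutational
signatures and context biases of backgrounds, copy-number structure,
chromatin covariates, sequencing noise in VAFs. Passing the planted-recovery
tests therefore demonstrates the detector's calibration and rule logic, not
performance on real tumours.

### Detection power and background density

The excess criterion requires the real sub-cutoff count to exceed the
simulated one roughly ten-fold. This bounds detectability: with `n` planted
clustered mutations on a background of rate `λ` per bp (and total burden
`N`), a cutoff near the planted gap scale `d` needs approximately
`n ≥ 10 · N (1 − e^{−2λd})`. Concretely, 120 kataegic mutations with
50–300 bp gaps are comfortably detected over a 10-Mb genome carrying ~10–20
background mutations per Mb (derived cutoffs ≈ 0.6–1.3 kb), but at ~100
background mutations per Mb the background's own sub-300-bp pairs outnumber
the tenfold margin and no cutoff qualifies — the sample is correctly
reported as having no resolvable clustering rather than being forced
through. The planted-recovery tests accordingly use sparse backgrounds.

## Numerical and reproducibility choices

* Add-one empirical p-values keep p strictly positive; `n_sims` below 100
  cannot reach `q_alpha = 0.01` and warns.
* Strict inequalities throughout: a mutation is sub-cutoff iff IMD < cutoff;
  chain gaps must be < the local cutoff.
* Simulated positions are drawn with replacement; within-simulation
  collisions are redrawn (up to 100 rounds) to keep positions strictly
  increasing.
* Simulation `i` of an ensemble uses seed `master_seed + i`; identical
  configuration and seed give byte-identical outputs, including the VCF/TSV
  partitions and the JSON threshold sidecar.
* Plot data series are always co-written as TSV so that results are
  comparable numerically; image bytes may differ across rendering backends.

The test suite exercises the full pipeline at deliberately moderate problem
sizes — 10-Mb single-chromosome genomes, catalogs of 40–1120 mutations, 100
simulations for calibration checks and 20 for the search-vs-scan
equivalence battery — which keep every property cheap to re-verify while
matching the regime the method targets (whole-genome catalogs are larger,
but every algorithm here is linear or near-linear in mutation count).

## Limitations

* Threshold calibration uses substitutions; indels inherit the derived
  cutoffs but do not inform them.
* No indel left-alignment/normalisation, no liftover, no multi-sample
  merging; one sample per fit.
* Regional correction only tightens cutoffs.
* Recurrent ecDNA hypermutation (*kyklonas*) requires external amplicon
  calls and is out of scope; outputs are plain VCF/TSV so downstream
  signature tools can consume the partitions.
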