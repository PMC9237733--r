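# mutclust

Detection and subclassification of **clustered somatic mutations** in
single-sample catalogs.

Clustered mutations — doublet-base substitutions (DBS), multi-base
substitutions (MBS), diffuse hypermutation (*omikli*), mutation showers
(*kataegis*) and clustered indels — are imprinted by distinct mutational
processes and matter for tumour evolution, but a fixed inter-mutational
distance (IMD) cutoff cannot separate them reliably: the expected spacing of
mutations depends on each sample's burden, sequence-context preferences and
regional rate variation. `mutclust` is aimed at cancer-genomics analysts who
have per-sample somatic variant calls (VCF/MAF/text) plus a reference FASTA
and want calibrated clustered/non-clustered partitions with event labels.

## Method

For a sample with nearest-neighbour IMDs `IMD_j`, let `r(d)` count mutations
with `IMD_j < d`, and let `s_i(d)` be the same count in the *i*-th of
`n_sims` simulated catalogs (default 100) that preserve each substitution's
pentanucleotide context, genic/intergenic status, transcriptional strand
class and per-chromosome burden. The sample-dependent global cutoff is

```
d* = max { d ≤ 10 kb :  mean_i s_i(d) / r(d) ≤ 0.10        (≥90% above chance)
                        and  (1 + #{i: s_i(d) ≥ r(d)}) / (n_sims + 1) < 0.01 }
```

found by binary search over the acceptance region. In sliding 1-Mb windows
the cutoff is tightened by the real/simulated fold difference
(`floor(d*/fold)`, re-checked against the same criteria with BH correction
across windows). Runs of mutations whose gaps all fall below the applicable
local cutoff become events and are labelled by the rule table — size 2 with
gap 1 → DBS; size ≥ 3, all gaps 1 → MBS; size 2–3 with a gap > 1 → omikli;
size ≥ 4 with a gap > 1 → kataegis; adjacent VAF difference > 0.10 (CCF
> 0.25) → other; indel runs → clustered_indel.

## Worked example

A synthetic 2-Mb genome with planted events, fitted end to end:

```r
library(mutclust)

g <- make_genome(2e6, gc = 0.5, n_chroms = 2, seed = 42)
pc <- plant_catalog(g, n_background = 30, plants = list(
  plant_spec("kataegis", size = 6, gap_range = c(50, 300), vaf = 0.6, count = 4),
  plant_spec("DBS",      size = 2, gap_range = c(1, 1),    vaf = 0.5, count = 2),
  plant_spec("MBS",      size = 3, gap_range = c(1, 1),    vaf = 0.5, count = 1),
  plant_spec("omikli",   size = 3, gap_range = c(2, 200),  vaf = 0.5, count = 2),
  plant_spec("indel_cluster", size = 3, gap_range = c(10, 100), vaf = 0.5, count = 1)),
  seed = 7)

fit <- mutclust(pc$catalog, g, n_sims = 100, seed = 3)
fit
#> Clustered-mutation fit for sample 'synthetic'
#> Threshold model: global IMD cutoff 688 bp (cap 10000)
#>   chance fraction 0.100, q-value 0.009901, n_sims 100
#>   4 window(s), 0 with a reduced local cutoff
#>   40 / 70 mutation(s) clustered in 10 event(s)
#>
#>             DBS             MBS          omikli        kataegis           other
#>               2               1               2               4               0
#> clustered_indel
#>               1
```

The fitted cutoff (688 bp) is the largest IMD at which at most 10% of the
sub-cutoff mutations are explained by the simulated background (chance
fraction 0.100) with empirical p = 1/101 < 0.01. All ten planted events are
recovered with their true labels:

```r
score_recovery(pc$truth, fit$events, pc$catalog)
#>          subclass n_true n_detected tp precision recall
#> 1          omikli      6          6  6         1      1
#> 2        kataegis     24         24 24         1      1
#> 3             MBS      3          3  3         1      1
#> 4 clustered_indel      3          3  3         1      1
#> 5             DBS      4          4  4         1      1
#> 6       clustered     40         40 40         1      1
```

`write_partitions(fit, "out/")` writes `nonClustered/<sample>.vcf`, one
`clustered/<sample>_<subclass>.vcf` per label, the per-event TSV and a JSON
threshold sidecar; `plot(fit, "rainfall")` and `plot(fit, "summary")` draw
the rainfall plot and the SBS-96 / IMD-distribution panel (each figure's
data series is co-written as TSV). `run_pipeline()` performs the whole flow
from file paths, and `inst/cli/mutclust.R` wraps it for the shell.

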