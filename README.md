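# pedsqtl

Genetic dissection of **single vs. paired spikelets (PEDS)** — the key ear
trait separating teosinte (one spikelet per cupule) from maize (two) — in
advanced maize × teosinte backcross populations (BC3F2/BC4F2 developed by
recurrent selection for PEDS = 100%). The package is aimed at quantitative
geneticists who want a tested, reusable implementation of the two analysis
arms such studies combine, plus a forward simulator that makes the whole
pipeline runnable and checkable without any sequencing or field data.

**Arm 1 — QTL-seq bulked-segregant analysis.** For extreme-phenotype bulks
(e.g. 50 plants with PEDS > 90% vs 50 with PEDS = 0%), the per-SNP

    SNP-index = (alternate reads) / (all reads),     Δ(SNP-index) = high − low

is computed with the 4×/32× depth filter, averaged in 1 Mb sliding windows
advancing by 10 kb, and compared against Monte-Carlo null bands (95%/99%
quantiles of Δ under no linkage, tabulated per read depth); runs of
significant same-sign windows merge into candidate regions.

**Arm 2 — local linkage mapping.** Markers pass a 1:2:1 segregation χ²
screen, two-point recombination fractions are estimated from the 9-class F2
likelihood and converted through Kosambi's function
(cM = 25 ln((1+2r)/(1−2r))), and cube-root-transformed PEDS is scanned by
inclusive composite interval mapping: stepwise-selected background markers,
Haley–Knott regression on conditional QTL-genotype probabilities, reporting
LOD = (n/2) log₁₀(RSS₀/RSS₁), PVE, additive and dominance effects
(negative Add = teosinte allele increases PEDS), plus a two-locus scan for
additive×additive epistasis (AA).

**Simulator.** Segment-tiling genomes, Poisson/no-interference meiosis
(compiled in C++), the F2 → BC3F2 recurrent-selection scheme, a censored
polygenic liability model of PEDS calibrated so that roughly 1 plant in 16
shows PEDS > 0 (major QTL on chromosome 3, minors on 1/6/8, strong
additive×additive suppression), and pooled sequencing at ~19× Poisson depth.

## Worked example

```r
library(pedsqtl)

cfg <- sim_config(seed = 11, n_f2 = 800, n_bcf1 = 40, n_final = 3000,
                  qtl_model = peds_qtl_model("major_only"),
                  snp_spacing_bp = 2e5)
res <- run_all(cfg, "peds_run")
res$summary
#> PEDS summary [BC3F2]
#>   n = 3000  mean = 13.10%
#>   plants with PEDS>0 : total = 1: 3.2
#>       0%   (0,10]  (10,20]  (20,30]  (30,40]  (40,50]  (50,60]  (60,70]
#>     2062      148      143      130       94       88       67       57
#>  (70,80]  (80,90] (90,100]
#>       63       43      105
```

(With the single-QTL preset about a third of plants show some single
spikelets; it is the epistasis in the `"full"` preset that makes PEDS rare.)

```r
res$regions[, c("CHROM", "start", "end", "peak_delta", "level")]
#>   CHROM    start      end peak_delta level
#> 1     3        0 30400000  0.7692666  0.01
#> 2     3 30410000 34200000  0.4789702  0.05
#> 3     3 34810000 37600000  0.3999042  0.05
#> 4     3 38410000 55000000  0.6372219  0.01
res$qtl
#>   chrom pos_cM  left right      lod      pve       add       dom
#> 1     3     16 PM3.1 PM3.2 56.30869 32.89691 -1.121635 -0.904827
```

The QTL-seq arm calls candidate regions on chromosome 3 covering the planted
QTL at 12 Mb (Δ(SNP-index) peaks at 0.77, beyond the 99% null band), and the
interval scan puts a LOD-56 peak at 16 cM of the local map explaining ~33%
of the transformed-scale variance — matching the planted heritability of
0.35 — with negative additive effect (teosinte allele increases PEDS). The
run directory additionally holds every intermediate table, a manifest of
md5 sums (byte-identical across reruns with the same seed) and
`recovery.json` comparing both arms against the planted truth.

A thin command-line front end with per-stage subcommands
(`simulate`, `snp-index`, `thresholds`, `call-regions`, `build-map`,
`scan-qtl`, `scan-epi`, `summarize`, `run-all`) is installed at
`inst/scripts/pedsqtl-cli.R`.

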