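---
title: "Methods: QTL-seq and linkage mapping of single vs. paired spikelets"
author: "pedsqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL-seq and linkage mapping of single vs. paired spikelets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The trait and the populations

A teosinte ear carries one spikelet per cupule, a maize ear two. PEDS — the
percentage of cupules on an ear bearing a single spikelet — measures where a
plant falls between these extremes: 0% fully maize-like, 100% fully
teosinte-like. In advanced maize × teosinte backcross populations
(BC3F2/BC4F2, produced by recurrent selection of PEDS = 100% plants,
backcrossing to the maize parent and selfing), the PEDS distribution is
extreme: the vast majority of plants sit exactly at 0, roughly one plant in
fourteen to eighteen shows any single spikelets at all, and those that do are
spread up to 100%.

`pedsqtl` implements the two analysis arms used to dissect such a trait —
QTL-seq bulked-segregant analysis and local-map inclusive composite interval
mapping — together with a forward simulator of the whole breeding scheme so
that every stage can be exercised and validated without any sequencing or
field data.

## The forward simulator

**Genomes and meiosis.** A genome is ten chromosomes (physical lengths close
to the maize B73 assembly; genetic lengths at ~0.7 cM/Mb), each chromosome a
pair of homologs stored as founder-origin segment tilings. Meiosis draws a
Poisson number of crossovers with mean equal to the map length in Morgans, at
uniform positions — the Haldane, no-interference model. The per-chromosome
splice is implemented in C++ (as linkage simulators in this field usually
are) with a plain-R reference implementation cross-checked in the tests.
Map estimation downstream deliberately uses the Kosambi function even though
the generating process is Haldane; the mismatch mirrors actual practice,
where the mapping function is an analysis choice, not a fact about meiosis,
and the Kosambi estimator is additionally tested against Kosambi-generated
two-point data.

**Breeding scheme.** F1 = maize × teosinte; F2 by selfing; then repeated
cycles of selecting plants with PEDS exactly at the 100% threshold,
backcrossing them to the maize parent and selfing, ending in a BC3F2 (or
BC4F2) mapping population. Selection that matches no plant raises an error
rather than silently relaxing the rule — the caller can lower the threshold
in the configuration if that is intended. Defaults: F2 and intermediate
BCnF2 populations of 2000, 100 BCnF1 plants per cycle, final population
6000. The BCnF1 cohort of 100 is deliberately generous: with few F1 families
the minor QTL are easily lost by drift, and the trait architecture below is
calibrated against the scheme as actually simulated.

**Phenotype model.** PEDS is generated by a censored ("tobit-like") linear
liability: G = mu + sum(a_j x_j + d_j z_j) + sum(aa_kl x_k x_l) + e with
x = +1/0/−1 for maize-homozygote/heterozygote/teosinte-homozygote, z = 1 for
heterozygotes, e ~ N(0, sigma_e^2), and PEDS = 100 · min(1, max(0, G)). The
double censoring is the simplest mechanism that produces both the point mass
at 0 and the long right tail observed in the field. Negative `a` means the
teosinte allele increases PEDS, matching the sign convention of the
additive-effect columns in published mapping tables.

Two presets are shipped:

* `peds_qtl_model("full")` — a major QTL on chromosome 3 (a = −0.40,
  d = −0.32), minor QTL on chromosomes 1, 6 and 8 (a = −0.15, d = −0.05),
  and additive-by-additive epistasis (aa = 0.5) between the major locus and
  each minor locus, with mu = −0.70 and sigma_e = 0.30. The strong positive
  aa terms mean a teosinte allele at the major locus is *suppressed* by
  maize homozygosity at its partners — the mechanism by which a trait with a
  35%-PVE major QTL can still appear in only ~6% of plants. The intercept
  was calibrated once against full scheme simulations (n = 4000) so the
  PEDS>0 fraction lands near 1/16, inside the 1/20–1/12 band observed across
  field environments; it is not adjusted per run.
* `peds_qtl_model("major_only")` — the chromosome-3 locus alone
  (a = −0.45, d = −0.30, mu = −0.10, sigma_e = 0.50), calibrated so that the
  single-locus heritability on the cube-root scale is ≈ 0.35 and a few
  percent of plants exceed PEDS 90 (enough to build 50-plant bulks from a
  2500-plant population). Without epistatic suppression, PEDS>0 is much more
  common (~30%) — which is itself the point: the rarity of the trait in the
  real populations is an epistasis phenomenon.

**Bulks and read counts.** Bulks are drawn uniformly without replacement
among plants satisfying the phenotype rule (strict inequalities: a plant at
exactly PEDS 90 is not in a "PEDS > 90" bulk), including the overlapping
design in which several high bulks share a 25-plant core. Pooled sequencing
is simulated per SNP and bulk as depth D ~ Poisson(19) — the mean bulk depth
of the motivating experiment — and alternate count ~ Binomial(D, p(1−e) +
(1−p)e) with e = 0.001, where p is the true teosinte-allele frequency among
the bulk's chromosomes. Maize is always REF and teosinte always ALT, fixing
the orientation of the SNP-index. Diagnostic SNPs default to one per 100 kb
(~21,000 genome-wide) — a desk-scale stand-in for the millions of SNPs a
real resequencing run yields; tests use one per 200 kb–1 Mb where speed
matters.

**What the generator does not emulate.** Read alignment and variant calling
(counts are generated directly), base qualities, repeat-induced depth
artefacts beyond the Poisson depth filter, photoperiod × genotype
interaction (the day-length collapse of PEDS expression in one field
environment is not modelled), and crossover interference. Passing tests
therefore validate the statistical machinery under a clean generative model,
not robustness to alignment artefacts.

## The QTL-seq arm

SNP-index = (alternate reads)/(all reads) per bulk; positions with depth
below 4× or above 32× in a bulk are masked there (the bounds themselves
pass). delta(SNP-index) = high − low, defined only where both bulks pass.
Sliding windows of 1 Mb advancing by 10 kb are anchored at position 0 of
each chromosome, half open `[start, end)`; windows with fewer than 3 passing
SNPs report missing means (the anchoring and the sparse-window guard are
implementation choices; upstream descriptions of the method leave both
unstated).

Significance uses a Monte-Carlo null in the style of the original QTL-seq
proposal: at an unlinked locus, bulk genotypes are drawn from the null
design, allele frequencies formed, depths drawn from a Poisson truncated to
the pass band, counts binomial; 95% and 99% two-sided quantiles of
delta(SNP-index) are tabulated per depth (10,000 replicates per depth). The
null genotype distribution of a selected BC3F2 bulk is not derivable from
first principles; F2-like (1:2:1) is the default — the single largest
modelling judgement call in this package — with BC-like (1:1) selectable.
A window is significant when its mean delta lies strictly outside the band
at its mean depth (ties are non-significant); same-sign significant windows
whose intervals overlap merge into candidate regions. Grouping by sign
before merging guarantees that regions called at the 1% level are always
nested inside regions called at 5%. No multiple-testing correction is
applied beyond the simulated genome-wide bands, matching the source method.

## The linkage arm

Markers are screened for segregation distortion by a 1:2:1 chi-square in an
F2 (in the pipeline: 36 simulated F2 plants, the size actually used for
marker screening in the motivating study; alpha = 0.05, the published
"serious distortion" threshold being unquantified). The screen is *not*
reapplied to the advanced backcross genotypes, where linked markers deviate
from 1:2:1 by construction; there, only (near-)monomorphic markers are
dropped. Marker order is taken from physical coordinates — the published
local maps are colinear with the assembly, and de-novo ordering is out of
scope. Adjacent recombination fractions are estimated by maximizing the
9-class F2 two-point likelihood (the double-heterozygote class mixes the two
phases) on [0, 0.5] and converted through Kosambi's function,
cM = 25 ln((1+2r)/(1−2r)).

Phenotypes are cube-root transformed before scanning, the standard variance
stabilization for this zero-inflated trait. The single-QTL scan (ICIM-ADD
style) first selects background markers by forward–backward stepwise least
squares over (additive, dominance) covariate pairs with partial-F
probabilities p_in = 0.01 / p_out = 0.02 (deterministic; ties broken by
chromosome then position), then walks a 1 cM grid: at each position the
phenotype is adjusted by all selected markers except those flanking the
current interval and regressed on expected additive/dominance scores from
the no-interference conditional QTL-genotype probabilities (Haley–Knott
regression; cM→r conversions inside the scan use Haldane, consistent with
the no-interference three-point formulas). LOD = (n/2) log10(RSS0/RSS1);
PVE, Add, Dom come from the same fit; peaks above LOD 3 (the conventional
declaration threshold; the published QTL all exceed 3.2) are reported with
their flanking markers. The regression approximation to the full mixture
likelihood is adopted deliberately; at the heritabilities in play its bias
is negligible, and the scan-at-marker case is verified exactly against a
direct regression oracle in the tests.

The two-locus scan (ICIM-EPI style) walks a 5 cM pair grid (the granularity
of the published epistasis tables), fits main terms (a1, d1, a2, d2) plus
the four interaction terms (aa, ad, da, dd) on the background-adjusted
phenotype, and compares full vs mains-only by the same LOD formula,
retaining pairs with LOD ≥ 5 and reporting the aa coefficient as AA
(positive = the parental-allele combination increases PEDS) with the
interaction block's incremental R² as its PVE (the published PVE
decomposition for epistatic pairs is unstated; incremental R² is this
package's definition). Two same-chromosome positions inside one
flanking-marker interval are statistically one locus and are never paired;
reported pairs are thinned to local maxima separated by at least 20 cM on
both axes. Whether the published epistasis LOD compares against a
no-epistasis or a null model is unstated; full-vs-mains is this package's
documented choice. Under a pure-noise phenotype the per-pair false-positive
rate matches the 4-df chi-square tail at LOD 5 (~1.2 × 10⁻⁴); with ~780
pairs tested this leaves roughly a 7% chance per data set of at least one
false pair, which the tests check against its theoretical calibration
rather than pretending the scan is noiseless.

## Pipeline, determinism and problem sizes

`run_all()` chains simulate → summarize → bulks → SNP-index → windows →
null thresholds → regions → marker screen → map → ICIM-ADD → ICIM-EPI,
writing every artifact (TSV/CSV/BED/JSON), a structured log with
filter counts, a manifest of md5 sums, and a recovery report comparing
called regions and scan peaks against the planted truth. All randomness
derives from one mandatory seed fanned out per stage through a stable hash
of the stage name, so adding a stage does not shift the randomness of the
others, and two runs with the same configuration produce byte-identical
artifacts. Genomic tables use 1-based positions; BED output is 0-based
half-open; each file header states its convention.

Numerical choices worth knowing: depth-filter bounds are inclusive
([4, 32] passes); multi-allelic sites are not modelled (the simulator emits
biallelic diagnostic SNPs; the VCF reader rejects multi-allelic allele-depth
entries); missing genotype codes are excluded pairwise in two-point
estimation, marginalized in interval probabilities, and mean-imputed only in
the background-marker regression; the two-point likelihood search uses
`optimize()` on [0, 0.5] with tolerance 1e-8, so an estimated r of exactly
zero is represented as ~1e-6 and distances below 0.01 cM should be treated
as zero.

Validation problem sizes were chosen to keep the full suite comfortably
desk-scale while leaving no estimate noise-limited: 10,000 gametes for
meiosis oracles; 10,000 Monte-Carlo replicates per depth for threshold
curves and the type-I-error check; 100 seeded replicates of a
2500-plant BC3F2 scheme for QTL-seq planted-truth recovery; 100 replicates
of n = 650 populations (the size of the largest published mapping test) for
the single-QTL scan and 50 for the epistasis scan; the reproduction script
uses 40–60 replicates per arm. The phenotype calibrations reported above
were fixed from dedicated calibration runs before the recovery experiments
and are not tuned per seed.

## Known limitations

* The F2-like null for selected bulks is an assumption; if the truth is
  closer to BC-like, the bands are mildly conservative or anticonservative
  depending on depth.
* Interval probabilities treat the two flanking markers as the only
  information; genotyping error is not modelled anywhere.
* The epistasis scan's background adjustment excludes markers flanking
  either scanned position but does not refit the stepwise selection per
  pair.
* PVE estimates from Haley–Knott regression are biased slightly downward at
  high heritability with wide marker intervals.
* The broad "candidate genomic region" criterion sometimes used to describe
  QTL-seq curves descriptively (entire chromosome arms with elevated
  SNP-index) is noted but not formalized; only the threshold-based criterion
  is implemented, because no published rule exists for the broad version.
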