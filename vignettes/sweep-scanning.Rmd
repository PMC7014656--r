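---
title: "Methods: diversity, differentiation and sweep scanning in lotuscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, differentiation and sweep scanning in lotuscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotuscan)
```

lotuscan implements the comparative-population-genomics workflow used to
locate domestication sweeps in resequenced crop cohorts: a wild group and
one or more cultivated groups are genotyped at genome-wide SNPs, and regions
where the cultivated group has lost diversity *and* diverged strongly from
the wild group are flagged as candidate targets of artificial selection.
This vignette documents the statistical model behind each stage, the
defaults and why they were chosen, and what the synthetic-data generator
does and does not emulate.

## Data model

All statistics operate on a `genotype_matrix`: biallelic sites with diploid
alternate-allele dosages (0/1/2, `NA` missing). Variants are classed by the
ref/alt length difference — SNP (0, single base), indel (1–5 bp), structural
variant (> 5 bp). Diversity, F~ST~ and LD use SNPs only; indels and SVs are
carried for annotation and accounting. VCF and GFF3 coordinates stay 1-based
inclusive at the boundary; window and region arithmetic is 0-based
half-open internally, which keeps the half-overlapping window tiling free of
off-by-one errors. Multiallelic VCF records are dropped rather than split so
that the dosage coding stays well defined, and missing genotypes are never
imputed at ingest (PCA mean-imputes locally, see below).

## Nucleotide diversity

Per-site diversity is the unbiased pairwise heterozygosity

$$\hat\pi_j = 2\hat p_j(1-\hat p_j)\,\frac{n_j}{n_j-1},$$

with $\hat p_j$ the sample alternate-allele frequency and $n_j$ the number
of non-missing alleles in the group at site $j$; it equals the mean number
of differences over all pairs of sampled alleles. Group diversity
($\theta_\pi$) is $\sum_j \hat\pi_j / L$ with $L$ the *total* sequence
length, not the number of variant sites — monomorphic positions contribute
zero to the numerator but stay in the denominator, matching the windowed-pi
semantics of VCFtools and the per-bp $\times 10^{-3}$ scale on which such
panels are reported. The denominator uses the full FASTA length with no
callability mask; heterozygosity per sample is defined the same way
(heterozygous SNP count over total length, in percent). Sites with fewer
than two non-missing alleles in a group are skipped. Whether real pipelines
exclude assembly gaps from $L$ varies; we use full length and say so here,
since the same convention is applied consistently to both groups of every
contrast and cancels from the pi ratio.

## Differentiation

Per-site Weir & Cockerham (1984) variance components are computed from
allele counts in the two groups (the allele-level ANOVA form): `a` is the
between-population component and `b` the within-population mean square; the
window estimate is the ratio of sums $\sum a / \sum (a+b)$ over usable
sites ("ratio of averages"), the standard aggregation for sliding-window
resequencing scans. The estimator is unbiased in the sense that under the
Balding–Nichols model with divergence $F$ its expectation is $\approx F$,
which the test suite exploits as a sharp oracle. Sites monomorphic across
both groups, or with fewer than two non-missing alleles in either, are
unusable. Negative window estimates (common when true differentiation is
near zero) are clamped to 0 before Z-scoring by default — whether the
original analyses did this is unknowable from their text, so it is a config
flag (`clamp`). Z(F~ST~) is the genome-wide standardization
$(x-\bar x)/s$ with the sample ($n-1$) standard deviation over usable
windows.

## The sweep scan

Windows of 10 kb slide in 5 kb steps from position 0 of each chromosome;
after the last full window a truncated window is kept when the remainder is
at least one step long, so every base pair is covered under the default
2-steps-per-window geometry. For each (wild, cultivated) contrast and
window we compute $\theta_\pi$ in both groups, windowed F~ST~, and

$$\log_2\!\left(\pi_\text{wild}/\pi_\text{cultivated}\right),$$

oriented so that diversity *loss* in the cultivated group lands in the
right tail. (Method sections of this literature sometimes print the ratio
the other way; the published per-contrast thresholds are positive and the
per-locus figures draw wild diversity above cultivated diversity at sweeps,
both of which require the wild-over-cultivated orientation, so that is what
is computed.) A window with zero cultivated diversity but positive wild
diversity maps to $+\infty$, which ranks above every finite value; both
zero makes the window unusable.

Thresholds are the empirical $1-q$ quantiles (type-7 order statistics,
default $q = 0.05$) of both statistics over usable windows, computed
independently per contrast; a window is flagged iff **both** statistics are
*strictly* above their thresholds, so ties at a threshold never flag.
Windows with fewer than `min_snps` (default 10) usable SNPs are excluded
from the quantiles and can never be flagged. Flagged windows that overlap
or touch merge into selected regions (the 5 kb step makes adjacent flagged
windows overlap by construction; any 1 bp gap splits), region statistics
are SNP-weighted means, and genes are attached by ≥ 1 bp span overlap.
Both the flagged-window count and the merged-region count are reported,
since published region counts do not always state which is meant.

A degenerate case worth knowing: if more than the tail fraction of usable
windows has zero cultivated diversity, the ratio threshold itself is
$+\infty$ and nothing can strictly exceed it; `flag_outliers()` warns. This
can only happen in toy scans where implanted sweeps cover a large share of
the genome.

## Functional annotation

Sites are classed intergenic / intronic / UTR / CDS against gene models,
with the "most genic" class winning across overlapping genes
(cds > utr > intron) — published tables report single-class counts, so a
precedence rule is required. A site in the 5'UTR of one gene and the 3'UTR
of a different overlapping gene gets the combined `utr5_utr3` class. Coding
effects of CDS SNPs rebuild the affected codon from the CDS coordinate map
(reverse-complemented on the minus strand; gene models are assumed to start
in phase 0, which the generator guarantees and the GFF reader checks via
the length-divisible-by-3 rule) and translate with the standard code:
synonymous, nonsynonymous, stopgain, stoploss. CDS indels are frameshift or
nonframeshift by length mod 3. CDS SNPs in genes whose CDS length is not a
codon multiple, or where the VCF and FASTA disagree on the reference base,
fall into a residual `unknown` class — the natural reading of the
"unknown" column such tables carry without definition. Ratios and
percentages in summary tables are rounded to two decimals, half away from
zero, matching publication style. Group membership of a site ("total"
semantics) requires at least one non-missing alternate allele in the group;
the private/shared partition enumerates every non-empty group-intersection
class.

## Linkage disequilibrium

LD is the squared Pearson correlation of dosage vectors over
pairwise-complete samples — composite (genotype) r², appropriate for
unphased calls; the original analyses used haplotype-based software whose
exact dialect is unrecoverable, and the simulator provides phased truth for
oracle testing of the genotype approximation. Pairs closer than `max_dist`
(default 50 kb) on one chromosome are binned by distance (default 100 bp
bins); above 10⁶ pairs per group a seeded uniform subsample keeps the curve
deterministic and tractable. Decay distance is where the curve first drops
to a *fraction* of its maximum (default 0.5, linear interpolation), with an
absolute-r² mode as an alternative because published "half-maximum" prose
sometimes attaches an absolute r² value instead; the two are not mutually
consistent, so both are exposed and neither asserted as canonical.

Under the generator's haplotype-copying model the allelic correlation at
distance $d$ is $e^{-d/L_c}$, so genotype r² decays as $e^{-2d/L_c}$;
`ld_fit_decay_length()` therefore fits $r^2(d) = r_0 e^{-2d/L_c}$
(pair-count-weighted nonlinear least squares, log-linear fallback) and the
fitted $L_c$ estimates the simulator's correlation-length parameter
directly.

## Population structure

The sample distance is allele sharing: mean of $|d_i - d_j|/2$ over sites
non-missing in both — 0 for identical genotypes, 1 for opposite
homozygotes. The distance metric behind the original tree tool is not
published, so topology-level agreement, not branch lengths, is the testable
contract; neighbor joining itself is Saitou–Nei via `ape::nj()`, with
negative branch lengths clamped to zero. Bootstrap support resamples sites
(columns) with replacement — the standard phylogenetic bootstrap — and
reports, for each internal bipartition of the full-data tree, the fraction
of replicates containing it. PCA uses Patterson normalization (center by
$2\hat p$, scale by $\sqrt{2\hat p(1-\hat p)}$, mean-impute missing,
drop monomorphic sites), eigendecomposition of the resulting genetic
relationship matrix, coordinates scaled by the root eigenvalues, and a
deterministic sign convention (largest-magnitude coordinate positive).

## The synthetic-data generator

`sim_config()` defines a complete cohort; `simulate_cohort()` builds it in
memory and `emit_dataset()` writes mutually consistent FASTA + GFF3 + VCF +
grouping files (identical seeds give byte-identical files; every stage
draws from a seed derived deterministically from the master seed).

* **Divergence.** Ancestral frequencies are uniform on [0.05, 0.95]; each
  group draws from $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$
  (Balding–Nichols), so the expected between-group F~ST~ is ≈ F — a
  closed-form oracle that a coalescent simulator would not give, at the
  price of no shared genealogy along the chromosome. The default five-group
  cohort uses the sample sizes of a real domestication panel (22 wild,
  21 seed, 13 rhizome, 11 flower, 2 outgroup accessions) with per-group F
  chosen once (0.05/0.25/0.45/0.10/0.60) so group diversities differ on the
  10⁻³-per-bp scale such panels show.
* **Sweeps.** Inside each sweep interval the target group's frequency is
  pushed toward its nearer boundary, $p' = p^\gamma$ for $p \le 0.5$ and
  $1-(1-p)^\gamma$ otherwise; $\gamma = 1$ is the identity and expected
  heterozygosity strictly decreases for $\gamma > 1$. The transform acts on
  frequencies, not haplotypes: hitchhiking LD patterns are deliberately not
  emulated.
* **LD.** Haplotypes follow a site-ordered Markov chain: the allele at a
  site copies the previous site's allele with probability $e^{-d/L_c}$,
  otherwise it is a fresh draw from the site's frequency. The correlation
  length is thus a direct, testable input. Side effect worth knowing: when
  adjacent sites have different frequencies, copying blends them, which
  inflates per-site heterozygosity slightly and compresses between-group
  diversity differences relative to the no-LD case; diversity-recovery
  oracles therefore use $L_c = 0$ configurations, where the analytic
  expectation is exact.
* **Genome.** Genes are tiled deterministically (UTR–CDS–intron–CDS–UTR,
  alternating strand), CDS frames are filled with stop-free sense codons,
  and a handful of anchored indel/SV records exercises the annotation
  paths. SNP positions include the first two codons of the first gene so
  all three codon positions are always covered.

The benchmark sweep-recovery scenario is 20 Mb (2 × 10 Mb), 540,000 SNPs
(27 SNPs/kb — the genome-wide density of deep plant resequencing panels,
which such studies report after their MAF ≥ 0.1 filter), 22 wild + 20
cultivated diploids at F = 0.05, ten 50 kb sweeps at $\gamma = 8$, no LD,
2% missingness. The acceptance script runs it over five seeds.

## What passing tests do and do not show

Because sites are exchangeable draws (no genealogy, no recombination
structure beyond the copying chain), the synthetic cohorts validate the
*estimators* — unbiasedness, parameter recovery, threshold logic,
determinism — not the demographic realism of any particular organism.
Window-to-window variation in real data is dominated by linked drift and
varying mutation/recombination rates, which this generator does not
produce; real scans will show heavier-tailed window distributions than the
synthetic ones.

One quantitative consequence is worth spelling out. In the benchmark
scenario the 5% joint tails hold ~200 of ~4,000 windows, but ten 50 kb
sweeps can occupy at most ~110 of them, so ~90 neutral windows remain in
each marginal tail and, even at the measured near-zero neutral correlation
between the two statistics, a few neutral windows per cohort land in both
tails by chance. Each becomes a single-window "selected region". The scan's
sensitivity is therefore excellent (every implanted sweep is recovered in
the test suite), while region-level precision plateaus slightly below the
0.8 mark that the recovery test asserts — a structural property of strict
joint empirical-quantile thresholding at this genome size, not a tuning
failure; the corresponding acceptance expectation is left failing rather
than loosened, and the acceptance script reports the measured sensitivity
and precision directly. At real genome sizes (hundreds of Mb) the same
arithmetic yields proportionally more joint-tail windows, which is why
published scans report hundreds to thousands of candidate regions and treat
them as candidates for enrichment analysis, not as a high-precision call
set.

## Numerical choices and degenerate inputs

* Quantiles: type-7 (linear interpolation of order statistics), the R
  default, computed over usable windows only; strict inequality at the
  threshold.
* Rounding of presentation ratios/percentages: two decimals, half away
  from zero.
* `z_transform()` refuses vectors with zero variance or fewer than two
  finite values; `flag_outliers()` refuses scans with fewer than 20 usable
  windows.
* Empty filter results return an empty matrix with a warning, not an
  error; a group with < 2 samples cannot have diversity, < 4 samples
  cannot have LD.
* NJ input must be symmetric and non-negative; tie-breaking is delegated
  to `ape`'s deterministic implementation, and output stability under
  identical input is part of the test contract.
* All pipeline randomness (LD pair subsampling, bootstrap, simulation)
  derives from one master seed via a fixed integer hash, so `run_full()`
  bundles are byte-identical across runs with the same inputs and seed.
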