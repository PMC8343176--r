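---
title: "Methods: genotyping and QTL mapping for low-coverage sequenced RILs"
author: "rilqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping and QTL mapping for low-coverage sequenced RILs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilqtl)
```

# The problem

A biparental recombinant inbred line (RIL) population — here an F6 obtained
by five rounds of selfing with single-seed descent from a cross of two
inbred accessions — is sequenced at low depth. Each line's reads yield
sparse, error-prone genotype calls at segregating SNPs. The analysis task is
to turn those calls into (i) clean per-line genotypes along every
chromosome, (ii) an ultra-high-density genetic map of 100-Kb window markers,
and (iii) quantitative trait locus (QTL) detections for replicated seedling
phenotypes (hypocotyl length under dark, red, far-red and blue light),
confirmed by heterogeneous inbred family (HIF) contrasts and narrowed to
candidate genes with high-impact sequence variants.

`rilqtl` implements that full path, plus a simulator that generates
populations with known ground truth so that every stage can be validated by
parameter recovery.

# The simulator

`simulate_ril_genomes()` performs explicit iterated meiosis: per meiosis and
chromosome, crossover counts are Poisson with mean equal to the map length
in Morgans and positions are uniform on the chromosome (a Haldane process).
Two design choices keep the process analytically tractable:

* **No crossover interference and no obligate chiasma.** The Poisson model
  makes closed forms exact — residual heterozygosity $(1/2)^g$ after $g$
  selfing rounds, discordance $R = 2r/(1+2r)$ at fixation — which the test
  suite exploits. Downstream distances use the Kosambi function, which
  allows for interference; at the sub-10-cM interval scale of a dense map
  the discrepancy between the two models is far below the sampling noise of
  163 lines.
* **Segregation distortion as per-generation viability selection** at a
  single focal locus (region midpoint), with weights $1, 1-s/2, 1-s$ for
  the favoured homozygote, heterozygote, and disfavoured homozygote. Because
  single-seed descent retries seeds from the same plant until one survives,
  selection is conditioned per parent: a lineage already fixed for the
  disfavoured allele persists. This reproduces the chromosome-arm-scale
  allele-frequency cline seen in real populations (a depleted but not
  absent minor allele, with linked hitchhiking) rather than near-fixation.

The observation model mirrors low-depth sequencing: a SNP × line call is
present unless its Poisson($\lambda$ = `mean_depth`) read count is zero
(missing fraction $e^{-\lambda}$), homozygous calls flip with probability
`call_error`, and heterozygous sites are called homozygous with probability
`het_miscall` (at depth 1 a het is necessarily sampled as one allele, so the
default is 0.5). Parents are simulated as three replicate homozygous
libraries each at 10× the RIL depth.

Phenotypes are additive: replicate value $= \mu + \sum_k a_k x_k + u + e$
with $x_k = \pm 1$ by parental allele, $u \sim N(0, \sigma_L^2)$,
$e \sim N(0, \sigma_E^2)$. The default effect size is calibrated from
$R^2 = a^2 / (a^2 + \sigma_L^2 + \sigma_E^2/r)$ so that a single QTL
explains 22% of line-value variance at the study's scale
($a = 0.59$ mm for $\sigma_L = 1$, $\sigma_E = 1.5$, $r = 10$), matching the
strongest QTL size the design is meant to emulate. The "measure only the
$k$ tallest seedlings" truncation is available (`top_k_selection`) but off
by default: it biases line means upward and its effect on heritability
estimators is not modelled.

What the simulator does **not** emulate: read-level data (base qualities,
mapping artefacts), error rates that vary along the genome (e.g. around
transposable elements), epistasis, or genotype-by-environment interaction.
Passing recovery tests on simulated data therefore validates the
*algorithms*, not robustness to every artefact of real sequencing data.
Notably, real F6 populations have been observed with ~10% apparent
heterozygosity where selfing theory predicts 3.1%; the simulator follows
theory and does not attempt to reproduce that discrepancy, which likely
reflects residual call artefacts.

# Parental diagnostic SNPs

`call_parental_snps()` keeps a locus only when each parent's libraries are
unanimously homozygous (any heterozygous library call anywhere discards the
locus as potentially spurious; an all-missing parent cannot be certified and
is dropped — the conservative reading of "reliable") and the parents differ.
`filter_te_overlap()` then removes SNPs inside transposable-element
annotation, using the SNP point position only. Coordinates are 0-based
half-open internally; a VCF SNP at 1-based position $p$ is the point
$p-1$, so a BED interval $[10,20)$ covers VCF positions 11–20 (standard
bedtools semantics). The two filters commute, which the suite checks.

# Genotype inference

`infer_genotypes()` runs a three-state hidden Markov model
$\{AA, HET, BB\}$ per line and chromosome over the diagnostic SNPs.
Parameters are design choices, exposed in `hmm_params()`:

* emissions mirror the observation model: correct homozygous call with
  probability $1-\varepsilon$ (default $\varepsilon = 0.01$), heterozygous
  truth called homozygous with probability $\eta = 0.5$; a floor of
  $10^{-6}$ keeps the het observation possible under homozygous states so
  no path scores $-\infty$; missing observations emit a flat likelihood;
* transitions over a gap of $d$ bp leave the current state with probability
  $1 - e^{-\rho d}$, with $\rho$ set so the expected number of switches per
  chromosome is twice the meiotic map length in Morgans — the map-expansion
  factor of fully selfed RILs (`switch_rate_for()`); transitions *into* HET
  are down-weighted by $\kappa = 0.1$ because heterozygous tracts are rare
  at F6;
* the initial distribution puts $(1/2)^5$ on HET.

Decoding is Viterbi by default (a jointly consistent path, matching the
goal of predicting the genotype at each position); forward–backward
posterior decoding is available for QC (`genotype_posteriors()`), and its
marginals sum to one within $10^{-9}$. All scores are kept in log space, so
chromosomes of $10^5$ sites decode without underflow. Inferred states are
reported at every diagnostic SNP, i.e. unobserved sites are imputed.

After inference, `filter_population_frequency()` drops loci whose A-allele
frequency among homozygous calls falls outside $[0.40, 0.60]$
(boundary-inclusive; heterozygous calls are excluded from the tally since
they are non-informative downstream). Per-chromosome overrides support the
deliberately relaxed thresholds used for a chromosome with known
distortion.

# Binning and marker QC

`bin_genotypes()` tiles each chromosome with consecutive 100-Kb windows
anchored at position 0 (the final partial window is kept — it can still
collect enough calls). Per line and window the marker genotype is the
strict plurality among called SNP genotypes over $\{AA, BB, HET\}$ — HET can
win a window (ties give NA), and windows with fewer than 10 called SNPs are
NA. `qc_markers()` removes markers with more than 25% missing lines or
A-occurrence outside $[0.35, 0.65]$ (both retention rules
boundary-inclusive; the occurrence denominator again excludes HET).

`flag_distortion_region()` reports maximal runs of at least $k = 10$
consecutive out-of-band markers as candidate distortion intervals. Exclusion
is deliberately a separate, explicit call (`exclude_markers()`): removing a
chromosome arm is a judgement call that should follow independent
confirmation of population integrity, so the pipeline order is bin →
flag → manual exclude → QC.

# Linkage map

`pairwise_rf()` counts discordant homozygous calls per marker pair, giving
the RIL-scale discordance $\hat R$; the meiotic-scale fraction is
$\hat r = \hat R / (2(1-\hat R))$ — the inverse of $R = 2r/(1+2r)$ for
selfed RILs, verified in the suite against a generation-by-generation
two-locus recursion (`ril_discordance_recursion()`) to $10^{-10}$. Pairs
co-scored in fewer than 10 lines are unreliable and contribute no edge.

`order_markers_mst()` reimplements minimum-spanning-tree ordering in its
simplest correct form: complete graph weighted by $\hat R$, MST, the tree's
maximum-weight path as backbone, remaining markers inserted beside their
nearest backbone neighbour on the cheaper side; orientation follows
physical coordinates. Marker input order cannot change the result (vertices
are canonicalised), duplicates land adjacent, and on exhaustive small
instances the returned order costs no more than the best 1% of all
permutations. Pre-ordering screens mirror the common MST-mapping interface:
markers above 25% missingness, markers more than 5 cM from every other
marker, and linked groups smaller than 2 are left out.

Distances are Kosambi, $d = 25\ln\frac{1+2r}{1-2r}$ cM. Because genotyping
errors masquerade as double crossovers and inflate summed adjacent
distances, `correct_map_lengths()` re-estimates each interval by direct
crossover counting on per-line runs: missing spans flanked by equal
genotypes are imputed, single markers contradicting identical flanks are
smoothed away (at 100-Kb spacing a true double crossover within one window
pair is vastly less likely than a call error at F6), and each remaining
transition is attributed to the middle interval of its span. On error-free
simulations the corrected length tracks the simulated meiotic length;
injected 1% errors inflate the raw map while moving the corrected length
by less than 15%.

# Phenotype statistics

`anova_components()` fits the one-way by-line ANOVA and reports MSG, MSE,
genotypic variance $GV = (MSG - MSE)/r$, phenotypic variance $PV = MSG/r$
and broad-sense heritability $H^2 = GV/PV$ clamped to $[0,1]$; unbalanced
designs use the effective replicate number
$r_0 = (N - \sum n_i^2/N)/(g-1)$. For balanced data this is algebraically
the intraclass correlation $\sigma_g^2 / (\sigma_g^2 + \sigma_e^2/r)$.

`boxcox_transform()` maximises the Box-Cox profile log-likelihood on a
$[-2, 2]$ grid (step 0.05) with golden-section refinement inside the best
cell; the suite cross-checks the optimum against an independent
implementation. `blue_blup()` returns line means as BLUEs and REML BLUPs
from the random-intercept model (via lme4, with a method-of-moments
shrinkage fallback). Which of BLUE/BLUP feeds the scan is configurable;
BLUPs of Box-Cox-transformed values are the default scan input. For
balanced data BLUP shrinkage is a constant factor on line deviations, so
the choice does not move scan $R^2$; with unbalanced replication BLUPs
down-weight noisy lines, which is why they are the default.

Ratio traits (light/dark) are computed from per-line means, not replicate
pairs: dark-grown and light-grown seedlings are different individuals, so
no replicate pairing exists.

`lsd_groups()` performs Fisher's LSD on the pooled ANOVA MSE with
insert-and-absorb letter assignment: two groups share no letter exactly
when they differ at the chosen level.

# QTL scan

`calc_genoprob()` computes conditional genotype probabilities on a 1-cM
grid by forward–backward over the two-state $\{AA, BB\}$ chain (binned HET
calls enter as missing — the standard two-state treatment of residual
heterozygosity in a selfed RIL cross), with inter-position transition
$R(d) = 2r/(1+2r)$, $r$ from the inverse Kosambi function, and a genotyping
error allowance (default $10^{-4}$) at scored markers.

`scan_hk()` is Haley–Knott regression of the line value on $P(BB)$;
$\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$, and the additive effect is
half the fitted difference between the homozygous classes (positive =
B-parent allele increases the trait). At a fully informative position this
reduces exactly to $\mathrm{LOD} = -(n/2)\log_{10}(1-R^2)$.

`scan_cim()` adds composite interval mapping: up to 3 cofactor markers
chosen by forward selection, each excluded within 10 cM of the scanned
position, with the null model carrying the same retained cofactors. The
cofactor scheme (count, window, selection rule) follows the common default
of the standard scanning framework, since no single convention is
canonical. With zero cofactors CIM reduces exactly to the plain scan.

`permutation_threshold()` permutes the phenotype across lines and takes the
$(1-\alpha)$ type-7 quantile of genome-wide maximum LODs; $\alpha = 0.1$,
with 1000 permutations as the desk-scale default and 10000 as the
full-scale convention. The suite verifies genome-wide type-I error
calibration within a binomial confidence band. `detect_qtl()` picks peaks
above threshold, masking each peak's contiguous above-threshold run so the
shoulders of one broad peak are not double-reported, and names QTLs by
trait plus ordinal (e.g. *Rc1*). `support_interval()` is the 1.5-LOD drop
interval (declared convention; configurable). `fit_multiple_qtl()` reports
the percent variance explained from the joint model, both as drop-one
decrease in $R^2$ (the default figure) and as marginal single-term $R^2$,
since conventions differ; peaks closer than 1 cM are merged.

# HIF contrast and candidates

`classify_hif_sibs()` assigns progeny of a still-segregating line to allele
classes only when homozygous at *every* interval marker and consistent with
the expected genotype at supplied background markers — background identity
is enforced only at those markers, matching a finite genotyping-marker set
rather than whole-genome identity. `hif_effect_test()` contrasts the
classes with the pooled-ANOVA LSD machinery and flags whether the contrast
direction confirms the scan's additive-effect sign; the class mean
difference estimates $2a$.

`genes_in_interval()` uses the any-overlap rule on half-open intervals, and
`shortlist()` intersects interval genes, a curated trait-relevant gene
list, and genes carrying at least one high-impact variant (missense, splice
donor/acceptor, start lost, stop gained/lost), reporting per-category
counts. Variant-effect prediction itself is consumed as input, never
recomputed. Genetic-to-physical conversion of support intervals
(`cm_to_bp()`) linearly interpolates between flanking marker window
midpoints — a declared convention, since no standard exists.

# Numerical and testing choices

Problem sizes in the validation suite are chosen to exercise each property
at full statistical strength while keeping runs desk-sized: exhaustive
decoder checks use chromosomes of up to 8 sites (3^8 paths), genotype
recovery uses 163 lines × 2 chromosomes × 3000 SNPs at mean depth 0.5,
QTL parameter recovery uses 200 replicate simulations of 163 lines × 5
chromosomes at 2-cM marker spacing with 200 permutations each, and
heritability recovery uses 200 replicates of 163 × 10. Permutation and
simulation seeds are fixed in the suite for reproducibility; every
simulated quantity asserted carries a tolerance derived from its sampling
variance, not from a fitted run.

Known limitations: no Baum-Welch re-estimation of HMM parameters (fixed
per run); no de-novo linkage-group discovery (markers arrive
chromosome-assigned by physical position); no epistasis or multi-trait
scans; the CIM permutation threshold reuses the plain-scan null rather
than re-selecting cofactors per permutation.
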