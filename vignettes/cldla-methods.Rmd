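---
title: "Mapping a recessive disease locus with cldla: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive disease locus with cldla: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldla)
```

# The problem

A lethal autosomal recessive disorder segregates in a closed livestock breed.
Affected animals are rare and historical (diagnosed decades ago, partly
without molecular confirmation), obligate carriers are known through progeny
testing, and medium-density SNP genotypes exist for a mixed study sample of
affected, carrier and free animals. The goal is to (i) fine-map the locus by
combined linkage-disequilibrium and linkage analysis (cLDLA), (ii) delimit
the shared disease haplotype by homozygosity mapping, (iii) reduce
region-restricted sequence variants to those concordant with carrier status,
and (iv) monitor the allele in the current population. `cldla` implements
all four stages plus a gene-dropping simulator with exact
identity-by-descent (IBD) truth, so that the whole pipeline is testable
without access to any proprietary data.

# The mixed model and the scan

For each sliding window of 40 consecutive SNPs the model is

$$ \mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}\mathbf{q} + \mathbf{e},
\qquad \mathbf{q} \sim N(0, \mathbf{D}_{RM,p}\,\sigma_q^2),
\qquad \mathbf{e} \sim N(0, \mathbf{I}\,\sigma_e^2), $$

where $\mathbf{y}$ encodes the diagnostic status on a quantitative scale
(1.0 free, 2.0 progeny-confirmed carrier, 3.0 pathologically confirmed
affected, with 2.0-2.75 interpolations for clinically-confirmed-only animals
according to their pedigree evidence; `encode_phenotypes()`), $\mathbf{X}$
holds the overall mean and the retained principal components of the
genome-wide unified additive relationship (UAR) matrix, and
$\mathbf{D}_{RM,p}$ is the diplotype relationship matrix at the window
midpoint $p$. `reml_fit()` maximizes the restricted likelihood profiled over
$\gamma = \sigma_q^2/\sigma_e^2$ (boundary $\gamma = 0$ plus a log-spaced
grid on $[10^{-6}, 10^3]$, refined by Brent search to relative tolerance
$10^{-6}$); the eigendecomposition of $\mathbf{D}$ makes each likelihood
evaluation closed-form. The null model (no locus effect) is ordinary least
squares under the same likelihood-constant convention, fitted once per scan.
The test statistic is $LRT = \max(0,\, 2(\ell_{H1} - \ell_{H0}))$, which is
referred to a $\chi^2_1$ distribution; because $\sigma_q^2$ is constrained to
the boundary, the true null is a 50:50 mixture of $\chi^2_0$ and $\chi^2_1$
and the $\chi^2_1$ convention is conservative. The genome-wide significance
threshold is the Bonferroni quantile
`significance_threshold(alpha_total, n_windows)` (0.001 over 1958 tests
gives $LRT = 25.22$), and support intervals use the 2-LOD drop-off rule with
1 LOD $= 2\ln 10 \approx 4.605$ LRT units.

## Support intervals

`lod_ci()` identifies windows above the significance threshold, computes a
drop interval for every local maximum (all consecutive windows within
`drop_lod` LOD of that peak), and merges overlapping intervals around their
highest peak; exceedance regions that stay disjoint are reported as separate
peaks, each with its own interval. Computing intervals per local maximum and
merging makes the rule robust to single-window dips in a noisy profile;
interval boundaries are reported at window midpoints without interpolation.

# Locus-IBD estimation

The scan needs, at every window midpoint, the probability that two
haplotypes are IBD. Two estimators are provided behind one interface
(`locibd_matrix(method =)`):

* **`"multipoint"` (default).** Every window marker contributes
  probabilistically. With $a_i = e^{-2 T d_i}$ the probability that an IBD
  segment at the midpoint still covers marker $i$ at genetic distance $d_i$,
  a marker is identical-by-state (IBS) with probability $a_i + (1-a_i) h_i$
  under midpoint IBD and $h_i = f_i^2 + (1-f_i)^2$ (population
  homozygosity) otherwise. Treating markers as independent gives a
  likelihood ratio $R$ and posterior $\phi R / (\phi R + 1 - \phi)$, with
  prior $\phi = 1 - (1 - 1/(2N_e))^T$ (`ibd_params()`, defaults
  $N_e = 100$, $T = 10$, $\phi \approx 0.049$, typical for a closed breed).
* **`"runs"`.** A simpler closed form driven by the maximal IBS runs
  immediately left and right of the midpoint: survival $e^{-2Td}$ over the
  run span against the chance-IBS product $\prod h_i$ (`locibd_pair()`).

The run-based form is attractive for its transparency, but its value jumps
whenever a single marker flips a run, and under realistic panels the
window-to-window noise of the resulting LRT profile exceeds the 2-LOD drop,
shredding support intervals. The multipoint estimator varies smoothly as the
window slides (only distances change, plus one weakly informative edge
marker), which is what the drop-off rule requires; it is therefore the scan
default, with the run-based form retained as a reference implementation and
for sensitivity analysis.

`drm_from_locibd()` converts a haplotype-pair IBD matrix to the animal-level
diplotype relationship matrix: $D_{jk} = \tfrac12 (M_{j_1k_1} + M_{j_1k_2} +
M_{j_2k_1} + M_{j_2k_2})$ off-diagonal and $D_{jj} = 1 + M_{j_1j_2}$. These
matrices need not be positive definite; when the smallest eigenvalue falls
below $10^{-6}$ a minimal diagonal ridge is added and recorded. The mixed
model family is invariant to diagonal shifts of $\mathbf{D}$ (a shift is
absorbed by reparametrizing $\gamma$ and $\sigma_e^2$), so the repair does
not distort likelihood ratios.

# Stratification correction

The UAR matrix (`uar_matrix()`) uses centered, frequency-standardized
dosages with the usual distinct diagonal estimator; missing genotypes are
mean-imputed ($2p_i$) for this computation only. The number of principal
components entering $\mathbf{X}$ is chosen by Horn's parallel analysis
(`horn_retain()`): each SNP column is permuted across animals, the UAR
spectrum recomputed, and the leading components whose observed eigenvalue
exceeds the 95th percentile of the permuted spectrum at the same rank are
retained (a fixed count can be forced with the `n_pcs` configuration key;
a full-scale analysis of the motivating design would set 60). Two
points matter in practice:

* The UAR must be **genome-wide**. If it is built from the mapped
  chromosome alone, the retained components absorb the local family
  structure around the disease locus and distort both the scan height and
  the peak location. The pipeline therefore computes the UAR from all SNPs
  passing the first four QC filters (including other chromosomes) and scans
  only the target chromosome.
* In a closed, related population parallel analysis legitimately retains
  many components (family structure is real structure); counts of 35-45 for
  ~160 animals are expected, comparable to the 60 components such
  analyses retain at full scale.

# Homozygosity mapping and the common haplotype

`asshom_scan()` finds maximal runs of consecutive SNPs at which every case
is homozygous for one identical allele and scores a run by
$\sum_i -\log_{10}\max(f_i, \varepsilon)$, where $f_i$ is the shared
allele's control frequency and $\varepsilon = 1/(2 n_{controls} + 2)$ keeps
unseen alleles finite: longer and rarer shared homozygosity scores higher.
This scoring is this package's own concrete form of the case-control
homozygosity idea; the published procedure it follows is not reproduced
verbatim in the source literature.

Misdiagnosed cases (phenocopies) destroy such runs, so
`drop_incompatible_cases()` searches for the maximum-score window in which
at most $k$ case animals mismatch the per-SNP majority homozygous allele (a
sliding-window search; the incompatible set can only grow as a window
extends) and reports those animals with their mismatch counts and
leave-one-out score gains. Plain leave-one-out ranking is the $k = 1$
special case; for $k > 1$ it fails structurally -- excluding one phenocopy
still leaves the others breaking every run, so all leave-one-out scores
collapse together -- which is why the budgeted search is the default.

`common_haplotype()` formalizes the manual haplotype comparison: starting
from the SNP nearest an anchor (normally the LRT peak), it extends the
maximal interval over which all affected animals are homozygous for
identical alleles and every carrier keeps at least one haplotype matching
the whole interval (`exact_one = TRUE` enforces the strict obligate-carrier
configuration). Right extension precedes left extension; with the carrier
condition coupling the two sides the maximal interval is not unique in
pathological cases, and this fixed order keeps the result deterministic.

# Variant concordance and monitoring

`concordance_filter()` restricts a variant table to the mapped interval and
keeps variants at which every declared carrier is heterozygous and every
other sequenced animal is homozygous reference. Missing genotypes are not
addressed by the source method; the default `lenient` policy treats a
missing non-carrier genotype as compatible (counted and reported) and
`strict` treats it as a violation; variants with missing carrier genotypes
are excluded under both. Near-misses (up to 2 violations) are reported for
diagnostics. `allele_frequency()` and `mating_risk()` convert monitoring
genotype counts into per-stratum and pooled allele frequencies
($\,(n_{het} + 2 n_{hom}) / 2n\,$, percent, two decimals) and the
Hardy-Weinberg carrier-mating risk $(2q(1-q))^2/4$ -- the exact carrier
frequency $2q(1-q)$ is used rather than the $2q$ approximation, although
both round identically at the frequencies involved.

# The simulator

`simulate_population()` provides the testbed: founder haplotypes with
per-SNP allele frequencies from $U(0.05, 0.95)$, gene dropping with
Poisson crossovers on a uniform genetic map (Haldane, no interference,
default 1 cM/Mb), and founder-segment labels carried through every meiosis
so IBD truth is exact. The defaults emulate the motivating study design:
2000 SNPs on one ~120-Mb chromosome (50K-chip density), a study sample of
43 affected / 31 carrier / 86 free animals, a disease allele planted on a
single founder haplotype at 49,878,773 bp, three phenocopies (mutation-free
animals labelled clinically affected, with the interpolated phenotype 2.25),
1% missing genotypes, and a fraction of affected animals with genotyped
carrier parents forming in-panel trios. Two structural choices deserve
comment:

* **Transmission depth.** Six gene-dropping generations with a handful of
  forced carrier matings per generation emulate descent of the mutant
  haplotype through few prominent sires. The resulting observed
  shared-haplotype interval (the maximal run over which all affected are
  homozygous for one allele, recorded as `truth_interval`) has a median
  around 1-1.5 Mb across seeds, matching the scale of the reported shared
  haplotype; its length is dominated by the ~117 final conditioned meioses
  that any such design requires, so it is a property of the study structure
  rather than a tunable knob.
* **Rest-of-genome SNPs.** 8000 unlinked SNPs spread over the other 28
  chromosomes (scaled down from a ~52k chip for tractability) feed the
  genome-wide UAR and exercise the off-target-chromosome QC rule.
* **The variant table** "sequences" the study carriers and free animals
  plus the mutation-free founder generation. The founders stand in for a
  population-scale reference panel: they carry every ancestral haplotype,
  so background variants that merely ride on the mutant haplotype's
  ancestral background are observed in non-carriers and rejected by the
  concordance filter -- precisely the role of the large multi-breed control
  panel in the motivating design. One causal variant tracks the disease
  allele exactly; one planted variant outside the region is perfectly
  concordant with carrier status and must be excluded by the region
  restriction alone.

What the simulator does **not** model: realistic demography or effective
population size trajectories, mutation, genotyping error beyond random
missingness, sex chromosomes, or LD beyond what gene dropping from
independent founder haplotypes creates. Passing tests on simulated data
therefore demonstrate the mathematical correctness and joint behaviour of
the pipeline under a faithful IBD structure, not calibration against real
bovine LD.

The pipeline treats phasing and imputation as an upstream, external step
(the study used a hidden-Markov phasing tool with thousands of extra
animals): QC runs on the raw masked genotypes, while the scan and haplotype
stages consume fully phased, imputed haplotypes -- in simulation, the
generator's phased truth. `trio_phase()` is provided as a minimal
convenience (Mendelian transmission where a parent is informative, then
frequency-guided greedy extension over a 10-SNP window, major-allele
imputation of what remains), not as a substitute for proper phasing.

# Numerical and interface choices

* Coordinates are 1-based and intervals closed, `[start_bp, end_bp]`;
  BED exports convert to 0-based half-open and say so in a header comment.
* Window midpoints are `floor((bp[20] + bp[21]) / 2)` for a 40-SNP window;
  genetic midpoints are the arithmetic mean.
* The "frequent paternity conflict" QC criterion is operationalized as a
  Mendelian-conflict rate above 1% over checkable parent-offspring pairs
  (configurable); heterozygosity is observed, not expected; each dropped
  SNP carries the first applicable reason in the documented order.
* Problem sizes used by the bundled studies: the acceptance analyses use 20
  simulated datasets at the default scale plus one dataset with two
  phenotype permutations (~3750 window-permutations) for null calibration;
  unit tests use ~40-animal, 300-SNP populations.
* One global integer seed drives each simulation; derived sub-streams keep
  every operation bit-reproducible. `run_pipeline()` exposes the whole flow
  (simulate, qc, relmat, scan, ci, homozygosity, haplotype, variants,
  monitor) through a single declarative configuration with a JSON manifest;
  as an R-native analysis package the exported functions are the intended
  interface, and no shell entry point is installed.

# Known limitations

* The multipoint estimator assumes marker independence given IBD state;
  it underweights nothing but double-counts correlated evidence in strong
  LD, which inflates IBD posteriors for closely related pairs. This affects
  scan height more than peak location.
* The LRT profile's absolute height depends on the retained principal
  components; with phenotypes that are near-deterministic functions of
  genotype the variance ratio saturates at the grid cap for the strongest
  windows.
* `common_haplotype()` is strict by construction: a single genotyping error
  in an affected animal terminates the extension, as in any manual
  haplotype comparison; it is meant to run on curated, imputed data.
* Support-interval coverage is assessed against the planted position, not
  as a calibrated confidence level; boundary effects of the drop-off rule
  are inherited from the method.
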