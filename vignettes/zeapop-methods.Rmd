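---
title: "Methods: introgression, connectivity and selective sweeps in Helicoverpa zea"
author: "zeapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression, connectivity and selective sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeapop)
```

# Scope

`zeapop` implements the statistical core of a population-genomic analysis of
North American *Helicoverpa zea* (corn earworm), a noctuid crop pest whose
sister species *H. armigera* carries pyrethroid-resistance alleles and has
invaded the Americas. The package answers three questions on a multi-sample
SNP call set: (i) has *H. armigera* ancestry introgressed into *H. zea*
(windowed ABBA--BABA statistics), (ii) is the metapopulation connected
enough for adaptive alleles to spread freely (windowed Hudson FST and an
isolation-by-distance regression), and (iii) which loci show selective
sweeps, how strong was selection, and does that strength explain observed
allele-frequency change over calendar time (a composite-likelihood scan on
the unfolded site frequency spectrum, an $\alpha \to s$ conversion, and a
deterministic selection recursion with dominance).

Everything is exercisable without external data: synthetic generators
produce genotype datasets with exactly the statistical structure each stage
assumes.

# Detecting introgression: D and $\hat{f_d}$

For each biallelic SNP, derived-allele frequencies $p_1, p_2, p_3, p_O$ are
taken in four pools: a non-admixed recipient reference (P1), the test set
(P2), the candidate donor (P3), and an outgroup used to polarize alleles.
Sites are polarized to the outgroup *major* allele; sites where the
outgroup frequency is strictly between 0.2 and 0.8 are excluded (the
original scripts' rule is unstated, so the threshold is exposed as
`fixedFreq`). Per site,

$$\mathrm{ABBA} = (1-p_1)\,p_2\,p_3\,(1-p_O), \qquad
  \mathrm{BABA} = p_1\,(1-p_2)\,p_3\,(1-p_O),$$

and the donor terms substitute $p_D = \max(p_2, p_3)$ for both $p_2$ and
$p_3$. In windows (20 kbp, requiring $\ge 200$ SNPs by default),

$$D = \frac{\sum(\mathrm{ABBA} - \mathrm{BABA})}
           {\sum(\mathrm{ABBA} + \mathrm{BABA})}, \qquad
  \hat{f_d} = \frac{\sum(\mathrm{ABBA} - \mathrm{BABA})}
                   {\sum(\mathrm{ABBA}_D - \mathrm{BABA}_D)},$$

so $\hat{f_d}$ estimates the admixture fraction: it is 1 under complete
donor sharing and, for a window fully covered by a donor tract on one of
$2k$ sampled P2 chromosomes, about $1/2k$. When $D \le 0$ the statistic is
meaningless and is reported missing by default; `dNonPos = "zero"` fills
zeros instead, which is the convention to use when averaging over many
windows (a window with $D \le 0$ carries no evidence of introgression, and
conditioning on $D > 0$ truncates the null distribution upward).
`perIndividualFd()` computes the same quantity with a single diploid as P2
($p_2 \in \{0, \tfrac12, 1\}$), the configuration that identifies
individual admixed samples.

$\hat{f_d}$ is conservative: sampling noise inflates
$E[\max(p_2, p_3)]$ above the shared frequency, so the denominator is
biased slightly upward at donor-polymorphic sites. The homozygous-tract
expectation of 1 is reached exactly only when donor-private polymorphism is
absent; the package's tests therefore use a generator mix without
donor-private sites for the calibration checks and the full mix for
detection-power checks.

# Windowed summary statistics

Per site with derived/ALT count $i$ among $n$ non-missing chromosomes,
nucleotide diversity is the mean pairwise difference
$\pi_{site} = 2i(n-i)/(n(n-1))$; absolute divergence between populations is
$d_{site} = p_A(1-p_B) + p_B(1-p_A)$; windows sum sites and divide by a
callable length (by default the window length, configurable because real
callable fractions vary). FST uses Hudson's estimator as a ratio of sums
("ratio of averages"), with the within-population correction
$p(1-p)/(n-1)$ per side — the recommended form for window data; it can
differ from other estimators by a small constant, which matters only for
cross-study comparison of absolute values. Windows below the
informative-site minimum (200 sites per 20 kbp, 100 per 100 kbp) are
reported missing, never zero: a zero would masquerade as perfect identity.

LD decay uses composite $r^2$ (squared Pearson correlation of unphased
dosage vectors), since decay is typically measured before phasing; under
independence its expectation is the $1/(n-1)$ sampling floor, not zero.

Segment contrasts (e.g. the two chromosome-15 segments, introgressed vs
not) use Welch's unequal-variance $t$ test on per-window values.

# Connectivity and isolation by distance

Pairwise deme differentiation is the unweighted mean of non-missing 20 kbp
window FST values; geographic distance is the haversine great-circle
distance (mean Earth radius 6371.0088 km — an ellipsoidal geodesic differs
by < 0.5%, far below the biological signal). Following Rousset, linearized
differentiation $F/(1-F)$ is regressed on $\ln(\mathrm{km})$ and the
one-sided (positive) Pearson correlation is the IBD test. Natural log is
used; the base affects only the slope scale, not $r$ or $p$. Deme pairs are
not independent (each deme participates in $D-1$ pairs), so the parametric
p-value is mildly anticonservative; the package follows the parametric
convention and documents this caveat rather than switching to a Mantel
permutation.

# The sweep scan

**Polarization and background.** Alleles are polarized against outgroup
samples (ancestral = allele at consensus frequency $\ge$ 0.8); ambiguous
and ingroup-monomorphic sites are excluded with recorded reasons. The
genome-wide unfolded SFS over derived counts $1..n-1$ is the null model,
which absorbs demographic non-equilibrium; sites observed at larger $n$
than the target are projected down by the hypergeometric expectation
$q_j^{(m)} = \sum_i p_i \binom{i}{j}\binom{n-i}{m-j}/\binom{n}{m}$.

**Sweep spectrum.** Near a sweep, each of the $n$ sampled lineages escapes
by recombination with probability $p_e = 1 - e^{-\alpha d}$ at distance $d$
bp, where $\alpha = r \ln(2N_e)/s$ is the per-bp intensity. Conditional on
$e$ escapees (binomial), the $e$ escapees plus the single sweeping ancestor
are $m = e+1$ exchangeable draws from the background; the ancestor's state
(derived with probability $j/m$ given $j$ derived among $m$) is copied to
the $n - e$ dragged lineages. The mixture over $(e, j)$ is conditioned on
polymorphism. At $p_e = 0$ every outcome is monomorphic, so the
implementation takes the $p_e \to 0^+$ limit (mass at the extreme
frequency classes) by flooring $p_e$ at $10^{-12}$. Only polymorphic sites
are modelled; invariant-site classes used by some published scan tools are
a documented simplification left out.

**CLR.** On a 1 kbp grid, $\mathrm{CLR}(x) = 2(\max_\alpha \ell(\alpha) -
\ell_0)$, where $\ell$ sums log sweep-spectrum probabilities of the
observed counts at each site's distance from $x$ and $\ell_0$ uses the
background. $\alpha$ is maximized on a 41-point log grid spanning
$[10^{-8}, 10^{-1}]$ with golden-section refinement to relative tolerance
$10^{-3}$; because the grid's upper end is effectively the background
limit, CLR is non-negative (and floored at 0 against rounding). Spectra
are precomputed on 1001 escape-probability bins — the spectrum depends on
$(\alpha, d)$ only through $p_e$ — making the scan linear in sites
$\times$ positions $\times$ alpha values.

**Regions.** Outliers are the top 0.01st percentile of grid CLR values,
implemented as a count rule $k = \lfloor 10^{-4} n_{grid} \rfloor$ with
boundary ties included: on genome-scale scans this reproduces the usual
percentile thresholding, while on small scans ($k = 0$) no regions are
called — which keeps the null well-behaved, since every called region is
extended 20 kbp on both flanks after merging outliers within 20 kbp.

**Selection strength.** $\hat{s} = r \ln(2 N_e) / \hat\alpha$, with
$N_e = \theta_\pi / 4\mu$ (default $\mu = 8.4 \times 10^{-9}$, the
*Drosophila* rate; the per-generation, per-bp unit matters) and $r$ the
mean per-bp recombination rate of the chromosome, obtainable from the
population-scaled $\rho = 4 N_e c$ via `convertRates()` (Haldane's map
function $\mathrm{cM} = 50 \ln \frac{1}{1-2c}$ is provided for unit
sanity-checks). Candidate-locus enrichment uses a permutation test:
equal-length intervals placed uniformly in the scanned span build null
distributions of mean and maximum CLR, with add-one empirical p-values.

# Selection trajectories with dominance

With ancestral homozygote fitness 1, heterozygote $1 + hs$ and derived
homozygote $1 + s$, the per-generation change of the ancestral frequency
$p = 1 - q$ is

$$\Delta p = \frac{pq\,[\,p(w_{AA} - w_{Aa}) + q(w_{Aa} - w_{aa})\,]}
                  {\bar w}, \qquad
  \bar w = p^2 w_{AA} + 2pq\,w_{Aa} + q^2 w_{aa},$$

iterated $(\mathrm{year}_{end} - \mathrm{year}_0) \times
\mathrm{gens/yr}$ times from the anchor year (2–12 generations per year is
the plausible multivoltine range; the recursion starts at the anchor year,
an explicit convention since inclusive/exclusive year counting is
ambiguous at the margins). Fitting draws $s$ (and $h$, when free) uniformly
at random — $U(0,1)$ by default, configurable — and scores each candidate
as $1 - \mathrm{mean}\,|q_{obs} - q_{exp}|$ over the non-anchor
observation years (the mean, rather than the sum, keeps the score in
$[0,1]$ for any number of timepoints). The search is vectorized across
candidates, so $10^6$ iterations over ~200 generations take seconds. The
first observation anchors the trajectory to avoid assumptions about when
the allele arose.

# What the synthetic data emulate — and what they do not

The generators control exactly the statistic each analysis consumes:

* `simBackgroundGenotypes()` draws derived counts from the neutral
  $1/i$ law and assigns alleles to haplotypes uniformly — exact SFS
  control, no linkage. The CLR scan consumes only site frequencies, so
  this is the right null; it is *not* a coalescent and has no LD, so
  haplotype-based statistics would be meaningless on it.
* `spikeSweepSignal()` re-draws counts from the same escape-and-drag
  spectrum the scan fits. Scan recovery on these fixtures is therefore a
  self-consistency check of the generator/inference pair, not evidence
  about misspecified real data.
* `simStructuredDemes()` draws deme frequencies from the Balding–Nichols
  Beta around a shared ancestral frequency, with per-deme $F$ given by a
  distance map evaluated against the first deme. Independent demes with
  equal $F$ have pairwise Hudson FST $\approx F$; pairwise FST between
  demes $i, j$ is $\approx (F_i + F_j)/2$. A consequence worth knowing:
  with demes evenly spaced on a line and $F$ *linear* in position, the
  expected pair value $(F_i + F_j)/2$ is constant in pair separation, so
  no IBD signal exists to recover. The positive-control fixtures therefore
  use geometrically spaced demes, where $\ln(\mathrm{km})$ tracks the
  larger deme index. Real IBD arises from spatially autocorrelated drift,
  which this independent-deme model only caricatures.
* `simIntrogressionDataset()` uses four site classes: shared ancestral
  polymorphism (all three ingroup pools segregate around one frequency —
  the incomplete-lineage-sorting noise that makes null $D$ fluctuate
  around zero), recipient-private, donor-private, and fixed differences at
  rate `divergence`; the outgroup is fixed ancestral. Admixed P2
  individuals carry donor alleles across explicit tract intervals on 1 or
  2 haplotypes, and the truth tracts are returned verbatim for recovery
  scoring. There is no recombination structure within tracts.
* `simTrajectoryObservations()` propagates the deterministic recursion
  with optional binomial drift (off by default — the fitted model is
  deterministic) and binomial observation noise per sampled year.

Passing tests on these fixtures show the estimators compute their defining
formulas correctly and recover parameters under their own assumptions;
they do not show robustness to LD, linked selection, reference bias or
call-set artefacts in real data.

# Numerical and design choices

* Filter order in `filterVariants()`: per-genotype depth masking first,
  then site QUAL, site mean depth (computed from pre-mask depths),
  missingness, biallelic, singletons — fixed and reported because
  singleton status depends on prior masking; each removed site is counted
  under the first rule it fails, so report counts sum exactly.
* The HWE filter uses the Levene/Haldane exact conditional test (no mid-p),
  applied per species group only at sites with complete genotypes in that
  group; removal requires violation ($p < 0.01$) in $\ge 2$ groups.
* The Z-heterozygosity association filter (against sex-linked mis-mapping)
  takes the OLS slope t-test p-value per SNP and removes the smallest
  $\lceil 0.01 m \rceil$ p-values among $m$ testable SNPs, boundary ties
  included; a constant trait removes nothing, with a warning.
* `codingVariantReport()` masks whole sites below the QUAL threshold
  (13.0103 = 95% confidence); the container carries per-site QUAL, not
  per-genotype GQ. The biochemical-property partition (nonpolar /
  polar-uncharged / positive / negative / special, stop as its own class)
  is one standard choice and is configurable.
* Windows are tiled, non-overlapping, aligned to multiples of the window
  size; positions are 1-based internally and in VCF, window coordinates
  0-based half-open.
* Test and acceptance problem sizes: scans use 2,000 polymorphic sites on
  1 Mbp with 10 diploids; fd̂ fixtures 12,000–23,000 sites on 1–2 Mbp;
  deme fixtures 5,000–6,000 sites; random-search fits $10^5$ (fixed $h$)
  and $10^6$ (joint) iterations. These sizes give each check comfortable
  statistical margin while keeping a full run in minutes.

# Known limitations

* The scan models polymorphic sites only and a hard-sweep spectrum; soft
  sweeps, background selection and invariant-site information are out of
  scope, and $\hat s$ inherits the no-dominance assumption of the
  $\alpha$ approximation (a dominant sweep can make it an overestimate).
* $\hat{f_d}$ is frequency-based; it does not infer local ancestry or
  tract boundaries beyond window resolution.
* The IBD test is parametric over non-independent pairs (see above).
* Genotype-calling, phasing, imputation and recombination-map estimation
  are upstream of this package and are not reimplemented.
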