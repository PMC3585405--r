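---
title: "Methods: network condensation, eigenvalue GWAS and spectral reconstruction in eigenmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network condensation, eigenvalue GWAS and spectral reconstruction in eigenmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eigenmet` condenses a non-targeted LC-MS feature matrix into correlation-network
modules, summarizes each module as a per-sample eigenvalue, maps the genetic
control of those eigenvalues with a kinship-aware mixed linear model, and
closes the loop by regressing external phenotypes on the eigenvalues and by
reconstructing fragment spectra for features of interest. This vignette is
the package's own account of the statistical machinery: the models, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## Input model

The primary observable is a samples-by-features intensity matrix from
alternating-collision-energy acquisition: a low-energy ("MS", survey)
channel and a high-energy ("MSE", all-ion fragmentation) channel, with
feature identifiers of the form `"<mz>_<rt>"` (m/z in Da, retention time in
seconds). The package requires a *gap-filled* matrix — peak detection,
alignment and fill-in are upstream concerns — and therefore rejects missing
or negative intensities outright. Missing values are tolerated only in
genotypes, where they are mean-imputed per SNP for kinship and principal
components and excluded pairwise in per-SNP tests.

Technical replicate injections are averaged (arithmetic mean per feature)
to one row per biological line *before* any scaling, because all downstream
models operate at the accession level. The mean, rather than the median, is
used: with two or three replicates a median is either the mean or a single
arbitrary injection.

Autoscaling (per-feature centering and division by the sample standard
deviation, $n-1$ denominator) precedes network construction so that
high-abundance, dynamic metabolites do not dominate the correlation
structure. Pareto scaling (division by the square root of the SD) is
provided for PCA-style QC, where full variance equalization tends to
amplify pure-noise features.

## Unsigned weighted network and modules

For autoscaled features $i, j$ the adjacency is

$$a_{ij} = \lvert \mathrm{cor}(x_i, x_j) \rvert^{\beta}, \qquad \beta \ge 1,$$

an *unsigned* network: substrate/product pairs and other negatively
coupled chemistry should co-cluster. The soft-thresholding power $\beta$
can be fixed or chosen by the scale-free topology criterion: the smallest
candidate whose connectivity distribution fits a power law with signed
$R^2 \ge 0.8$ (binned log-log regression; a positive slope scores 0), with
a conventional fallback of 6 when no candidate fits. The selection is
deterministic — same input, same $\beta$.

Module detection uses average-linkage hierarchical clustering on the
topological overlap dissimilarity $1 - \mathrm{TOM}$, where

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
\ell_{ij} = \sum_u a_{iu} a_{uj},\; k_i = \sum_u a_{iu},$$

so that shared neighbourhoods reinforce direct edges. A static cut of the
dendrogram keeps the procedure deterministic and testable; clusters below
`min_module_size` (default 10) are left unassigned (`"grey"`). Raw
adjacency dissimilarity is available as a config switch.

**Cut height.** The default static cut is 0.99. This is deliberate and
worth explaining: after soft thresholding, unsigned TOM dissimilarities
concentrate immediately below 1. On a factor-model metabolome with
loadings 0.7–0.9, feature noise SD 0.6 and $\beta = 6$, within-module
merge heights fall around 0.86–0.97 while unrelated features merge at
$\approx 0.9995$ — a cut anywhere in the wide gap (roughly 0.97–0.999)
recovers the planted modules exactly, whereas any cut below that leaves
every node a singleton. Conventional-looking cut heights such as 0.75 are
calibrated to *unpowered* dissimilarities and are effectively a null
procedure here. Lower the cut only for nearly noise-free data.

Module labels are colour names assigned in strictly decreasing size order
(largest module = `"turquoise"`), with ties broken by the
lexicographically smallest member id. Colour labelling of network modules
is conventionally arbitrary; making it a deterministic function of the
partition is required for reproducible pipelines.

**Module eigenvalues.** Each module's per-sample eigenvalue is the first
principal component score of its autoscaled member submatrix (computed by
SVD), rescaled to unit sample variance. The PC sign is arbitrary, so it is
fixed by requiring non-negative correlation with the mean member profile:
"more of the module" is always a larger score. Unsigned GWAS inference is
sign-invariant, but a fixed convention makes regression coefficients and
cross-run comparisons meaningful. The proportion of member variance
explained is reported alongside.

**Pruning.** The connectivity-SD rule retains node pairs whose edge weight
strictly exceeds $\bar w + k \cdot \mathrm{SD}(w)$ computed over *all*
off-diagonal weights of the full network (grey nodes included), for $k$
conventionally 1, 4 or 6. "Connectivity between nodes" is interpreted as
the pairwise edge weight, not node degree — the rule thresholds an
edge-projected network — and the statistics are computed on the
$\beta$-powered weights because the same matrix defines the network (a
raw-|correlation| switch exists). Pruning is nested by construction:
the edge set at $k=6$ is a subset of $k=4$ is a subset of $k=1$. Isolated
nodes are dropped and connected components are reported, since a module
can split into several components once its weaker internal edges fall
below the threshold. Edge lists are exported as SIF plus weighted TSV for
Cytoscape-style viewers, and guilt-by-association annotation propagates
identified features' labels to co-module neighbours scored by the retained
edge weight (zero when pruning severed the pair).

## Mixed linear model GWAS

Each module eigenvalue (or any trait) is analyzed under

$$y = X\beta + u + e, \qquad u \sim N(0, \sigma_g^2 K), \quad
e \sim N(0, \sigma_e^2 I),$$

with $X$ an intercept plus population-structure covariates and $K$ the
Loiselle marker-based coancestry matrix. For biallelic dosages with
per-line allele frequency $p_{il} = d_{il}/2$,

$$f_{ij} = \frac{\sum_l (p_{il} - \bar p_l)(p_{jl} - \bar p_l)
 + \sum_l \bar p_l (1 - \bar p_l) / (n_l - 1)}
{\sum_l \bar p_l (1 - \bar p_l)},$$

where $n_l$ counts lines scored at locus $l$; the second numerator term is
the small-sample bias correction. The per-allele factor 2 cancels between
numerator and denominator. The estimator can go negative for pairs less
related than random draws; negative values are *retained* by default (a
clamp-to-zero switch exists) because they carry real information about the
covariance. Positive semi-definiteness is enforced by flooring the
eigenvalues of $K$ at $10^{-8}$, with a message when a shift was applied.

Structure covariates default to the top $q = 3$ principal components of
the mean-imputed centered dosage matrix — the standard stand-in for
ancestry membership proportions that needs no external tool — and an
externally computed membership matrix can be supplied instead. The number
of components is a judgment call; three matches the handful of recognised
subpopulation groups in typical diversity panels and is configurable.

REML estimation exploits the eigendecomposition $K = UDU^\top$: after
rotation by $U^\top$ the restricted likelihood is a one-dimensional
function of $\lambda = \sigma_g^2/\sigma_e^2$, profiled on a coarse grid
over $\log\lambda \in [-6, 6]\cdot\log 10$ and refined by golden-section
search (tolerance $10^{-8}$). Heritability is reported as
$h^2 = \lambda/(1+\lambda)$.

The scan follows the P3D shortcut: variance components are estimated once
on the null model and reused for every SNP, so each test is a generalized
least squares regression with a Wald/F test on the SNP coefficient —
equivalent to weighted OLS in the rotated basis, which is how the
implementation computes it (one QR of the covariates, then two inner
products per SNP). Per-SNP REML would change p-values marginally at
hundred-fold the cost. SNPs with minor allele frequency below the floor
(default 0.05, *inclusive* retention at exactly 0.05) or constant after
missingness are excluded before testing; SNPs with missing calls fall back
to a dense GLS on the complete lines.

Raw p-values are Benjamini–Hochberg adjusted (the step-up procedure), and
significance is flagged at two conventional levels, conservative 0.001 and
generous 0.05; the conservative set is nested in the generous one by
monotonicity of the adjustment.

## Stepwise eigentrait regression

An external phenotype is regressed on the module eigenvalues by mixed
stepwise selection on partial-F p-values. At each step every remaining
candidate is scored by the p-value of its coefficient in the model
containing the current terms plus that candidate; the smallest-p candidate
enters if its **Bonferroni-adjusted** p (raw p times the number of
candidates examined at that step) clears `p_enter`. The adjustment is the
package's selection rule, chosen because an unadjusted minimum-p entry
test admits a noise module with probability $1 - (1 - p_{enter})^m$ — about
18% already at $m = 20$ candidates and `p_enter` = 0.01 — which defeats
the point of a selection threshold when dozens of modules compete. After
every entry, backward elimination removes retained terms whose unadjusted
partial p exceeds `p_leave` (default 0.10), worst first. Ties break on
smaller p then lexicographic term id, so the path is deterministic and
column-order invariant; the raw p of every action is logged.

The fitted model is summarized in a partial (Type III) sum-of-squares
ANOVA table: per term, the increase in error SS on removing that term
alone, the F ratio against the full-model MSE, and the signed t ratio
($t^2 = F$ for these 1-DF terms). Partial rather than sequential SS makes
each row order-independent. The table closes with an `Error` row and a
corrected-total `Model` row carrying the whole-model F,

$$F = \frac{(SS_{tot} - SS_{err}) / (df_{tot} - df_{err})}{SS_{err}/df_{err}},
\qquad
R^2_{adj} = 1 - \frac{SS_{err}/df_{err}}{SS_{tot}/df_{tot}},$$

so the headline quantities are recomputable from two printed rows alone.

## Spectral reconstruction and mass arithmetic

Indiscriminant MS/MS reconstruction assumes fragments of one compound
(1) co-elute with their precursor and (2) co-vary with it across samples.
Candidates are features within a ±2 s retention-time window of the target
(the chromatographic peak width of a UPLC separation); survivors must
reach a Pearson correlation of `r_min` with the target's cross-sample
profile, default 0.5 — permissive enough for noisy fragments, strict
enough that unrelated co-eluters are rejected when a few dozen samples are
available. Peak intensity is the *median* of the retained feature across
samples (robust to single-injection spikes), renormalized so the base
peak is exactly 999 per the NIST msp convention; provenance records the
contributing feature ids, and libraries round-trip through the msp
reader/writer at 4-decimal precision.

Charge states are inferred from isotope spacing: member peaks of a cluster
are separated by $1.003355/z$ Da (the $^{13}$C–$^{12}$C mass difference),
so $z$ is the rounded reciprocal of the mean spacing, with clusters
rejected as irregular when any spacing deviates from the implied ideal by
more than $2 \times$ `tol_ppm` $\times 10^{-6} \times$ mean m/z (each
spacing involves two jittered peak positions; the default 25 ppm
tolerates realistic centroiding error while rejecting mixed clusters).

Two mass constants deserve a note. Deconvolution of multiply charged ions
uses $M = z\,(m/z - 1.00794)$ — the *hydrogen-atom* mass per charge — the
convention of common instrument-vendor software for peptide molecular
weights; small-molecule adduct arithmetic uses the proton mass 1.007276
for [M+H]$^+$. Both are configurable, but the defaults reproduce the
molecular weights practitioners see printed by their acquisition software.
Elemental formulas over C/H/N/O/S/P and peptide sequences are evaluated
against standard monoisotopic masses (residue table plus one water).
Cosine similarity between spectra matches peaks greedily by smallest m/z
difference within tolerance, each peak used at most once.

## The synthetic cohort generator

Every stage is testable offline because the generator emulates the joint
structure the pipeline assumes:

* **Genotypes** follow the Balding–Nichols model: ancestral frequencies
  uniform on (0.1, 0.9), subpopulation frequencies Beta-distributed with
  differentiation $F_{st}$ (default 0.2 over 3 subpopulations), and inbred
  lines carrying dosage 0/2 (residual heterozygosity configurable,
  default 0 to mirror an inbred panel).
* **Metabolome**: each module's latent is the sum of its QTL effects times
  dosage plus standard normal noise; member features load on the latent
  (loadings uniform in 0.7–0.9) plus Gaussian noise (SD 0.6); background
  features are pure noise. Defaults: 200 lines, 2,000 features, 8 modules
  of 10–200 features, three module-QTLs of effect 0.5 (at a common-SNP
  dosage variance of roughly 0.8, each explains on the order of 15% of its
  latent's variance). Standardized values map affinely to positive
  ion-count-like intensities (1000 + 100z, floored at 0), which preserves
  every correlation exactly.
* **Phenotype**: a weighted latent sum plus noise scaled from the realized
  genetic variance so the variance ratio hits the target $h^2$ (default
  0.5) in expectation.
* **Spectra fixture**: compounds contribute isotope clusters (given
  charge) to the low-energy channel and correlated fragments within
  ±0.5 s to the high-energy channel, with log-normal per-sample abundances
  and 5% multiplicative noise; uncorrelated decoys are planted, half of
  them co-eluting with a compound so the correlational filter is actually
  exercised. The default 60 samples keeps chance correlations above 0.5
  rare; with only ~20 samples such false positives occur at the percent
  level per decoy, which is a property of the filter, not a bug in it.

What the generator does **not** emulate: linkage disequilibrium beyond
subpopulation structure, chromatographic drift, batch effects, ionization
suppression, heteroscedastic intensity noise, and correlated missingness.
Passing tests therefore demonstrate correctness of the statistical
machinery under its stated assumptions, not robustness to every artifact
of real acquisitions.

All randomness flows from a single mandatory seed, with fixed per-stage
offsets (genotypes: seed, metabolome: seed+1, phenotype: seed+2) so each
stage is independently reproducible.

## Validation scale and numerical choices

The test suite validates module recovery (adjusted Rand index against the
planted partition) and eigenvalue fidelity on the default 200 × 2,000
cohort; mixed-model calibration on 200 null replicates of a 200-line,
500-SNP panel; heritability recovery on 50 replicates at 400 lines; exact
GLS equivalence against a dense brute-force solver at 20 lines; and
stepwise recovery over 100 replicates of 20 candidate modules at 200
samples. These sizes were chosen to make sampling noise small relative to
the tested tolerances while keeping a full run in the low minutes on a
single core.

Numerical details worth recording: sample SD uses the $n-1$ denominator
throughout; autoscaling is idempotent to $10^{-10}$; zero-variance
features are dropped with a warning rather than silently NaN-ing a
correlation; the REML profile is maximized on a 61-point grid before
local refinement, which is robust to the likelihood's occasional plateaus
at the boundary ($h^2 \to 0$); kinship eigenvalue flooring at $10^{-8}$ is
logged; and tie-breaks (module colour order, stepwise entry, cosine peak
matching) are all deterministic so that reruns are byte-identical.

## Limitations

Module counts and membership depend on $\beta$, the dissimilarity, the cut
height and the minimum module size; on real data these are not uniquely
recoverable quantities, and different defensible settings yield different
(nested or overlapping) module structures. The static cut is simple and
reproducible but less adaptive than dynamic tree-cut heuristics. The
mixed model assumes a single polygenic variance component; compression,
epistasis and multi-trait extensions are out of scope, as are spectral
library search engines — the package exports msp libraries and computes
masses, it does not rank database candidates.
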