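---
title: "Models and methods: shared genetic architecture of two case-control GWAS traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `bivargwas`,
the conventions and tunable parameters behind them, what the synthetic-data
generator does and does not emulate, and the package's known limitations.
It is the package's reference for *why* things are computed the way they
are; the README shows *how* to run them.

## 1. Setting

Two case–control GWAS of genetically correlated traits (the motivating
setting is a musical-rhythm trait and dyslexia) are observed only through
summary statistics: per-SNP z-scores or beta/SE, allele codes, allele
frequencies and sample sizes, possibly with overlapping participants.
Individual-level data are unavailable. Everything in the package operates
on these summary moments.

`sumstats` objects enforce internal consistency at construction: `z =
beta/se` and `pval` equal to the two-sided normal tail of `z` (relative
tolerance 1e-6), alleles in A/C/G/T with `a1 != a2`, unique SNP ids,
positive SEs. Harmonization between two sets aligns the second trait's
effect alleles to the first's, negating `beta`/`z` where the pair is
reversed, and drops strand-ambiguous (A/T, C/G) SNPs — the standard
munging safeguard, since their strand cannot be resolved from allele codes
alone. Positions are 1-based inclusive inside `sumstats` and converted to
0-based half-open only at BED boundaries (block partitions, locus output).

Genomic control divides `z` by `sqrt(lambda)` and inflates `se` by the
same factor, so beta/se/z/p stay mutually consistent — the correction acts
on z rather than on a separate chi-squared column precisely because
downstream fits consume beta and se. LDSC-based fits refuse GC-corrected
input by default (GC correction biases heritability downward); the
genomic-SEM factor output can be GC-corrected opt-in, mirroring common
practice of reporting a GC-corrected multivariate GWAS while feeding LDSC
uncorrected statistics. The inflation factor is `median(z^2)/qchisq(0.5,
1)`; whether a user-supplied lambda is an LDSC intercept or a median-based
ratio is recorded by the caller, since conventions differ between tools.

Effective sample size of a case–control GWAS is `4 N_cases (1 -
N_cases/N_total)`: the balanced-design equivalent N, used when a
multivariate method needs one N per study.

## 2. LD score regression

For SNP $j$ with LD score $\ell_j$ and reference SNP count $M$:

* univariate: $E[\chi^2_j] = \text{int} + N_j h^2 \ell_j / M$;
* cross-trait: $E[z_{1j} z_{2j}] = \text{cti} + \sqrt{N_{1j} N_{2j}}
  \rho_g \ell_j / M$, where the cross-trait intercept
  $\text{cti} = \rho N_s / \sqrt{N_1 N_2}$ captures correlated estimation
  error from $N_s$ overlapping samples with phenotypic correlation $\rho$.

**One fitting routine for all matrix elements.** Every element of the
genetic covariance matrix — diagonal (chi-squared on $\ell$) and
off-diagonal (z-product on $\ell$) — is estimated by the same routine:
weighted regression with weights $1/(\ell_j (e_{1j} e_{2j} +
E[y_j]^2))$ (heteroskedasticity plus LD weighting, iterated once; $e_{ij}$
are expected chi-squareds from a preliminary univariate pass), and
two-step estimation in which the intercept comes from SNPs with $|y_j| <
30$ and the slope from all SNPs with the intercept fixed. Using one code
path guarantees two exact identities that are useful guards: a duplicated
trait yields $r_g = 1$ exactly, and flipping one trait's effect direction
exactly negates $\rho_g$ and $r_g$. If no statistic falls below the
cutoff, the routine falls back to a one-step joint fit with a warning.

**Jackknife.** All standard errors and the sampling covariance $V$ of the
unique elements of $S$ come from a delete-one-block jackknife over 200
contiguous equal-count SNP blocks in genomic order, shared across all
regressions so that covariances between elements are meaningful. The
block count and the weighting scheme are conventions of the standard LDSC
tooling rather than published prescriptions; both are configurable
(`n_blocks`, minimum 20). Per-block sufficient statistics make the full
jackknife O(m + blocks). A replicate-level detail that matters: blocks
contributing no SNPs to the intercept step (e.g. a block full of planted
genome-wide-significant SNPs) still appear as empty rows in the block
sums, keeping replicates aligned.

**Ratios.** $r_g = \rho_g / \sqrt{h^2_1 h^2_2}$ is computed per jackknife
replicate, so its SE reflects the uncertainty of numerator and
denominators jointly. When $h^2_1 h^2_2 \le 0$ the ratio is reported as
`NA` with an out-of-bounds flag, never fabricated; |rg| > 1 likewise only
raises the flag.

**Liability conversion** uses the case–control ascertainment form
$h^2_{liab} = h^2_{obs} K^2(1-K)^2/(P(1-P) z^2)$ with $z =
\phi(\Phi^{-1}(1-K))$; at $K = P = 1/2$ the multiplier is exactly
$\pi/2$. Genetic covariances are scaled by the geometric mean of the two
traits' multipliers, which leaves $r_g$ invariant.

## 3. The per-SNP common-pathway model and Q_b

With $k = 2$ traits and both loadings on the shared genetic factor fixed
to 1, the SNP-free measurement model (factor variance $\sigma^2_F$ and two
residual variances against the three unique elements of $S$) is exactly
identified: $\sigma^2_F = S_{12}$, $u_i = S_{ii} - S_{12}$, zero degrees
of freedom. All misfit of the SNP-augmented model therefore lives in the
two SNP–trait covariance moments, and the CPM reduces to a one-parameter
GLS problem with a closed form (README, section "The models"). This is an
algebraic property of the constrained bivariate model, guarded in the test
suite by an independent numeric WLS minimizer on random inputs.

Conventions, in the order they matter:

* **Scale.** SNP–trait covariances and $S$ share the
  standardized-genotype scale: $\sigma^2_{SNP} = 2p(1-p)$ from a
  user-chosen frequency source (a reference panel in real analyses; either
  trait's frequency column works for matched designs), and
  $c_i = z_i \sqrt{\sigma^2_{SNP} / N_i}$, i.e. the per-allele effect on
  the standardized trait times $\sigma^2_{SNP}$. A duplicated trait makes
  $\hat b_F$ equal the univariate standardized effect (property-tested).
* **W.** The diagonal of the sampling covariance $W$ is the rescaled
  squared SE, $\sigma^2_{SNP}/N_i$; the off-diagonal is
  $\text{cti} \cdot \sigma^2_{SNP}/\sqrt{N_1 N_2}$ — the sample-overlap
  covariance of the two estimation errors.
* **Diagonal vs full W.** `run_mvgwas()` defaults to the diagonally
  weighted fit (off-diagonal dropped), exposing the full overlap-aware W
  via `overlap_w = TRUE`. Rationale: the diagonal fit is exact when
  samples do not overlap, whereas the full fit inherits the sampling noise
  of the estimated cross-trait intercept — at panel sizes of a few tens of
  thousands of SNPs that noise (SD ~0.04–0.06) perturbs the Q_b scale by
  the same order. With substantial overlap and a precisely estimated
  intercept the full-W variant is the better-calibrated choice; the two
  agree closely in well-conditioned settings (tested). Multiplying the W
  diagonal by the estimated univariate intercepts (`intercept_scale_w`) is
  similarly opt-in: it absorbs residual confounding in real data, but
  truncation-biased intercept estimates at small panel sizes would
  systematically inflate W and deflate Q_b.
* **Q_b.** The IPM gives each trait its own SNP path, fitting the two SNP
  moments exactly, so $\chi^2_{IPM} = 0$ and
  $Q_b = \chi^2_{CPM} - \chi^2_{IPM}$ carries 1 degree of freedom (one
  extra free path). $Q_b \ge 0$ always; under a shared-factor
  (pure-pleiotropy) generator it is $\chi^2_1$-distributed because the
  shared polygenic background shifts both $c$ components equally and
  cancels in the CPM contrast. With $W \propto I$, $Q_b$ equals Cochran's
  Q for two studies.
* **Factor summary statistics.** The factor GWAS reports `beta = b_F`,
  `se`, `z`, `p` and a per-SNP effective sample size
  $\sigma^2_{SNP}/se_F^2$ (equal to $N_1 + N_2$ for matched designs with
  unit intercepts), making the output a valid `sumstats` for downstream
  LDSC.

**Loci.** Genome-wide significant SNPs ($p < 5\times10^{-8}$) are merged
greedily within 250 kb per chromosome (the merge window is exposed; locus
definitions in published multivariate GWAS vary and reported locus counts
depend on the clumping rule, so counts are not treated as reproducible
targets). Locus intersection pads *both* interval sets by `pad` (±1 Mb in
the cross-method comparison) and tests half-open overlap; padding both
sides keeps the operation symmetric.

## 4. Cross-method validation statistics

**N-weighted GWAMA.** $z_{meta} = \sum_i w_i z_i / \sqrt{\sum_i w_i^2 +
\sum_{i\ne k} w_i w_k \text{CTI}_{ik}}$ with $w_i = \sqrt{h^2_i N_i}$.
The published method names its inputs (heritability vector, cross-trait
intercept matrix) without restating the weight formula, so the choice is
isolated in one function for easy substitution; with this form two
identical traits at CTI = 1 reproduce the single-study z exactly, and a
single trait is the identity.

**S_hom.** $S_{hom} = (e^\top R^{-1} T)^2 / (e^\top R^{-1} e)$ with
$T_i = \sqrt{N_i/\bar N} z_i$, $N_i$ the per-trait *median* sample size
(per-SNP Ns vary in consumer-cohort GWAS), and $R$ the correlation of
z-scores over SNPs where every trait has $|z| < 1.96$ — an estimate of the
error correlation from overlapping samples, computed after SNP
intersection. The scaling convention (recorded in the function's output)
is pinned by three requirements: a single trait reduces to $z^2$;
uncorrelated equal-N traits give the fixed-effect meta chi-squared; and
under homogeneity the statistic equals the square of the classic
$\sqrt{N}$-weighted meta-analysis z, which is what makes S_hom comparable
to the CPM factor scan. Truncation at 1.96 attenuates the estimated
correlation relative to the untruncated one (for fully overlapping samples
with $\rho = 0.4$, the doubly truncated correlation is ~0.32); this is a
property of the estimator, inherited deliberately.

## 5. Blockwise Spearman correlation

When signed effects are unavailable (e.g. multivariate test statistics),
shared signal between two GWAS is measured as the Spearman correlation of
per-block mean $-\log_{10} P$ over approximately independent LD blocks
(~1,703 genome-wide in the standard partitions), with a standard error
from resampling *blocks* with replacement (10,000 cycles). Conventions:
block files are read in BED dialect (0-based half-open) and SNP positions
converted at the boundary; a SNP on a boundary belongs to the block whose
start it equals; blocks empty in either trait are dropped pairwise before
correlation and the bootstrap universe is the used (non-empty, shared)
blocks; ties get average ranks; degenerate resamples with zero rank
variance are dropped from the SE. The statistic is invariant under
strictly increasing transforms of either input, and the bootstrap SE is
stable to <5% when doubling from 5,000 to 10,000 resamples (both tested).

## 6. Trait clustering

A panel of traits is reduced to genetically independent representatives in
four pinned steps:

1. traits with at least one $|r_g| > 0.80$ partner form the
   high-correlation subset (the threshold is two-sided — strong negative
   correlation is shared architecture too, which is also why the distance
   is $d = 1 - |r_g|$);
2. Ward-linkage hierarchical clustering on $d$;
3. the cluster count by the elbow rule, pinned as the $k$ maximizing the
   gap between consecutive merge heights — equivalently the second
   difference of the cumulative within-cluster dispersion profile versus
   $k$. Inputs with all pairwise distances equal have no preferred $k$;
   they return $k = 1$ with a degenerate-structure flag;
4. one representative per cluster: the trait with the largest absolute
   coefficient on the first eigenvector of the cluster's correlation
   submatrix (the trait most correlated with the cluster principal
   component); exact ties break to the lowest index, and singletons
   represent themselves. The eigenvector convention (rather than
   factor-score regression) is isolated in `select_representatives()`.

Representatives plus the never-clustered traits form the independent
panel. A Benjamini–Hochberg helper (`fdr_correct()`) supports the
downstream correlation screens over that panel.

## 7. The synthetic-data generator

`simulate_joint_sumstats()` draws per-SNP z-score pairs from the exact
sampling distribution implied by the LDSC model: variance
$1 + N_i h^2_i \ell_j / M$, covariance $\sqrt{N_1 N_2}\, r_g
\sqrt{h^2_1 h^2_2}\, \ell_j / M + \rho N_s / \sqrt{N_1 N_2}$, SNPs
independent given their LD scores. SEs derive from allele frequencies as
$1/\sqrt{N \cdot 2p(1-p)}$ and betas as $z \cdot se$. Planted SNPs add
mean shifts: heterogeneous SNPs directly on the z scale (e.g. +8/−8),
pleiotropic SNPs as a shared per-allele standardized effect scaled by
$\sqrt{N_i \sigma^2_{SNP}}$ so both traits receive the same effect on the
covariance scale.

Study conditions encoded in the defaults, chosen once:

* **Reference SNP count M = 1.2e6**, a genome-wide HapMap3-like panel
  size. M is a property of the genome, not of the analyzed subset, so it
  is *not* tied to `m_snps`; this keeps per-SNP chi-squared inflation at
  the levels of well-powered GWAS (mean chi-squared ~3 at N = 1e5,
  h2 = 0.25) for any panel size.
* **LD scores** ~ 1 + Gamma(shape 2) with mean 100: right-skewed with a
  long tail, minimum 1, resembling empirical LD-score distributions.
* **Allele frequencies** uniform on [0.05, 0.5], avoiding rare-variant SE
  blow-ups irrelevant to the methods.
* **Binary-trait realism** is carried by metadata (prevalences, case
  counts); liability conversion is tested analytically rather than by
  simulating threshold data.

What the generator deliberately does **not** emulate: real LD structure
(LD enters only through $\ell_j$; there are no correlated neighboring
SNPs), ancestry stratification or other confounding (univariate intercepts
are 1 by construction), MAF- or selection-dependent architecture,
per-SNP sample-size variation, and genotyping error. Consequently,
passing tests demonstrate correctness of the estimators *under the LDSC
moment model*, not robustness to model violations in real data — e.g. the
intercept's ability to absorb stratification is not exercised.

`simulate_rg_matrix()` builds block-structured correlation matrices with
planted clusters plus symmetric noise, projected to the nearest valid
correlation matrix (via `Matrix::nearPD`) when noise makes them
indefinite.

## 8. Numerical choices and degenerate inputs

* Singular or non-PSD W at a SNP is an error with a condition diagnostic,
  not a silent NA; `cti` magnitudes implying error correlation ≥ 1 are
  rejected.
* `chi2_cpm` is floored at 0 (it can go to ~−1e-16 in floating point);
  `q_b >= 0` up to 1e-8 is asserted in tests.
* Two-step regression falls back to one-step with a warning when no
  statistic lies below the cutoff.
* Block means use `rowsum` sums; results match a brute-force loop to
  floating-point associativity (1e-12 relative).
* Elbow/representative ties break deterministically (smallest k, lowest
  index) and the degenerate all-equal-distance case is flagged.
* Genomic-control lambdas below 1 warn and default to a no-op unless
  deflation is explicitly allowed.

## 9. Problem sizes used by the tests and acceptance script

The validation suite simulates panels of 20,000–50,000 SNPs (50,000 for
parameter-recovery checks, 20,000 for calibration checks that need many
replicates, 200 replicates for SE calibration, 34,060 SNPs / 1,703 blocks
/ 10,000 bootstraps for the blockwise correlation), with N ~ 1e5 and
heritabilities 0–0.4. These sizes were chosen so the full suite exercises
every pipeline end to end in well under a minute per check while leaving
Monte-Carlo noise small relative to the tolerances being asserted.
Q_b calibration and power scenarios use non-overlapping samples, which
isolates the heterogeneity statistic from cross-trait-intercept estimation
noise; overlap handling itself is validated separately through
cross-trait-intercept recovery (within 3 SE across overlap fractions 0,
0.5 and 1).

## 10. Known limitations

* **Two traits only** for the factor model: the closed form relies on the
  exactly identified bivariate measurement model with unit loadings. No
  free-loading estimation, no k > 2 factor structures, no
  sandwich-corrected SEs beyond the overlap-aware W (a documented
  simplification of the general genomic-SEM estimator that is exact for
  this constrained case).
* **Two-step truncation bias**: at strong per-SNP inflation (mean
  chi-squared well above the cutoff at high-LD SNPs), selecting
  intercept-step SNPs on the observed statistic biases the intercept
  slightly upward and the slope downward (~1 jackknife SE at the default
  study conditions). This is inherent to truncating on a noisy outcome
  and shared with standard LDSC practice.
* **Cross-trait intercept precision** scales with panel size; at desk
  scale its noise dominates the off-diagonal of W, which is why the
  diagonal fit is the Q_b default (section 3).
* No partitioned/stratified heritability, no INFO filtering, no liftover,
  no X/Y/MT handling, no LD-block derivation from genotypes (the partition
  is an input), and the genome-wide trait panel itself is not shipped.
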