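---
title: "Genomic relationships, inbreeding and variance components: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic relationships, inbreeding and variance components: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgrm)
```

## The quantitative-genetics model behind every matrix

Consider one biallelic SNP with counted-allele (A1) frequency $p$ and
$q = 1 - p$, in a population at Hardy–Weinberg equilibrium.  The classical
partition of the genotypic value into mean, breeding value and dominance
deviation fixes two per-genotype codings:

* the **additive coding** $w_\alpha = x - 2p$, where $x$ counts A1 copies
  (values $2q$, $q - p$, $-2p$);
* the **dominance coding** $w_\delta$ with values $-2q^2$, $2pq$, $-2p^2$
  for A1A1, A1A2, A2A2.

Both have zero expectation under HWE (the package asserts this exactly on
constructed panels whose genotype counts are exact multiples of $p^2$,
$2pq$, $q^2$), and unit-effect variances $2pq$ and $(2pq)^2$.  These two
facts are the whole engine: every relationship definition is a choice of
how to divide the cross-products of the coding matrices $W_\alpha$,
$W_\delta$ by SNP variances.

Effect sizes never appear: they multiply both the numerator and the
denominator of every definition and cancel, so the package carries them as
1 throughout.

### The four relationship definitions and two correlations

With $n$ individuals and $m$ SNPs:

* **Definition I** (across-SNP, expected variances):
  $A = W_\alpha W_\alpha' / \sum_i 2p_iq_i$ and
  $D = W_\delta W_\delta' / \sum_i (2p_iq_i)^2$ — the VanRaden-style
  additive matrix and its dominance analogue.
* **Definition II** (across-SNP, sample variances): the same numerators
  divided by $\sum_i w_i'w_i / n$, which equals the *average diagonal* of
  $WW'$.  This is why the sample variances use divisor $n$, not $n-1$:
  with divisor $n$ the identity
  $\operatorname{mean}(\operatorname{diag} A) = 1$ holds *exactly*, not
  approximately, and Definition II coincides with the average-diagonal
  (Hayes–Goddard-style) standardization.  A test asserts this identity to
  $10^{-12}$.
* **Definition IV** (within-SNP, expected variances):
  $A_{jk} = \tfrac1m \sum_i w_{\alpha ij} w_{\alpha ik} / 2p_iq_i$,
  analogously for dominance with $(2p_iq_i)^2$; the additive off-diagonals
  are those of the allele-frequency-weighted GRM familiar from GCTA-type
  estimators.
* **Definition V** (within-SNP, sample variances); its mean diagonal is
  again exactly 1.

Definitions I and II share a numerator and differ by one positive scalar.
Consequently their correlation forms are identical, which the package
exploits as a cross-check rather than an optimization: both paths are
computed in tests and compared at $10^{-14}$.

Genomic correlations (**III** from I/II, **VI** from IV/V) are
$\gamma_{jk} = A_{jk} / \sqrt{A_{jj} A_{kk}}$.  The diagonal is computed,
not assigned; it equals 1 up to two floating-point roundings
($\sim 10^{-16}$), and tests require $10^{-12}$.

**Definition IVb** is a diagonal only: per SNP a homozygote contributes the
reciprocal of its *own* allele's frequency ($1/p$ for A1A1, $1/q$ for
A2A2), a heterozygote 0, averaged over SNPs.  This assignment is the unique
one with unit expectation under HWE ($p^2/p + q^2/q = 1$) and is
algebraically identical to one plus the classical single-SNP inbreeding
estimator $\hat F = (x^2 - (1+2p)x + 2p^2)/(2pq)$; a test verifies the
identity term by term.  Off-diagonals of the "IVb matrix" are those of
Definition IV, so the package exposes IVb as a diagonal vector rather than
duplicating a matrix.

### A generic weighted constructor

Internally all four definitions call one constructor taking a coding
matrix, a per-SNP variance vector and a standardization scheme
(`across`/`within`).  It is deliberately not exported: arbitrary
user-supplied SNP weights are a different modeling commitment
(LD-adjusted and weighted GRMs are out of scope), and the four named
definitions are the supported surface.

## Pedigree relationships

The comparison baseline is the numerator relationship matrix from the
tabular method, $A_{jk} = \tfrac12(A_{j,s(k)} + A_{j,d(k)})$,
$A_{kk} = 1 + \tfrac12 A_{s(k),d(k)}$, with unknown parents treated as
unique unrelated non-inbred founders (contribution zero) — the standard
convention.  Dominance uses the classical no-inbreeding form
$D_{jk} = \tfrac14(A_{s_js_k}A_{d_jd_k} + A_{s_jd_k}A_{d_js_k})$ with unit
diagonal; inbreeding-corrected pedigree dominance is out of scope.
Pedigree inbreeding is parental coancestry, $F = \tfrac12 A_{s,d}$,
identical to $\operatorname{diag}(A) - 1$.

The tabular implementation is validated against an independent memoized
recursion on parent pairs (a path-counting equivalent) on random pedigrees;
the two agree exactly.

## Genomic inbreeding coefficients

Four estimator families operate on the same panel:

1. `f_from_diagonal`: $F = A_{jj} - 1$ for Definitions I/II/IV/V.
2. `f_yang`: $F = A^{IVb}_{jj} - 1$.
3. `f_parental`: $F_A = \tfrac12 A_{jk}$ over the individual's parents —
   genomic coancestry in place of pedigree coancestry.
4. `f_gamma`: $F_\gamma = \tfrac12 \gamma_{jk}$, the parental genomic
   *correlation*.  Definition III here is built from Definition II
   ingredients and Definition VI from Definition V, matching how the
   correlation forms are anchored to the sample-variance standardizations.

Individuals lacking two genotyped parents are excluded from families 3–4
rather than approximated; the pedigree contributes only parent identities,
never values.  Because Definitions I and II differ by a positive scalar,
their diagonal-based estimators are an increasing affine map of each other
and correlate exactly 1 — a useful end-to-end sanity check that the report
machinery asserts.

Report tables use SD with divisor $n - 1$ and pairwise-complete Pearson
correlations; a zero-variance estimator yields an undefined (`NA`)
correlation, never 0.

## The mixed model

GBLUP solves $y = Xb + a + d + e$, $\operatorname{Var}(a) = A\sigma^2_a$,
$\operatorname{Var}(d) = D\sigma^2_d$.  The implementation uses the
generalized-least-squares form: factorize only
$V = A\sigma^2_a + D\sigma^2_d + I\sigma^2_e$ (always positive definite
when $\sigma^2_e > 0$), then $\hat a = \sigma^2_a A V^{-1}(y - X\hat b)$.
This equals the solution of the mixed-model equations but needs no inverse
of $A$ or $D$ — which matters because a genomic relationship matrix built
with sample-frequency centering is always singular ($W_\alpha' \mathbf{1} =
0$ implies $A\mathbf{1} = 0$ for Definitions I–II), so an
inverted-relationship formulation would need a ridge and would carry that
ridge's error into the predictions.  The GLS route keeps the SNP-BLUP
equivalence below at machine precision.

**SNP-BLUP equivalence.**  With i.i.d. marker priors
$\sigma^2_{\alpha} = \sigma^2_a / \sum 2p_iq_i$ (and the dominance
analogue), the marker-level model implies
$\operatorname{Var}(W_\alpha\alpha) = \sigma^2_a A^{(I)}$ exactly, so
marker-level and individual-level fits are the same model.  The package
implements both routes and tests their agreement at $10^{-10}$ relative on
a 300-individual, 1000-SNP panel.

**Back-solving.**  SNP effects from a GBLUP fit use the
conditional-expectation back-solve
$\hat\alpha = K W'(WKW')^{-}\hat a$ with $K = I$ for Definitions I–II and
$K = \operatorname{diag}(1/\text{SNP variance})$ for IV–V — the unique
linear predictor consistent with each definition's implied prior.  A
symmetric-eigenvalue pseudo-inverse handles rank deficiency (relative
eigenvalue threshold $10^{-10}$) with a logged message; reconstruction
$W\hat\alpha = \hat a$ is exact on the fitted subspace.

**REML.**  `greml` offers EM (default) and average-information updates.
Per iteration the only $O(n^3)$ operation is one Cholesky of $V$: all trace
terms reduce to $\operatorname{tr}(PV_k) = \operatorname{tr}(V^{-1}V_k) -
\operatorname{tr}[(X'V^{-1}X)^{-1}(V^{-1}X)'V_k(V^{-1}X)]$, which are
elementwise sums once $V^{-1}$ is available.  EM is monotone in the
restricted likelihood (asserted per iteration in tests); AI steps are
guarded — any step leaving the parameter space or decreasing the
likelihood falls back to the EM update for that iteration.  Defaults:
relative tolerance $10^{-6}$, `max_iter` 1000, component floor
$10^{-8}\operatorname{var}(y)$.  EM remains the default for robustness;
the 20-replicate recovery studies in the test suite use the AI algorithm
because it reaches the same optimum (tested) in an order of magnitude
fewer $O(n^3)$ iterations.

## The simulator

`simulate_panel` chains three stages, all driven by one seed:

1. **Pedigree**: founder families by design — full-sib families, paternal
   half-sib groups (which also furnish parent-offspring and full-sib
   pairs), full-sib matings for inbred offspring ($F = 0.25$), and
   stand-alone founders.  The generated pedigree carries its relative-pair
   classes so expectations can be evaluated without re-deriving them.
2. **Gene drop**: founder genotypes Binomial$(2, p)$ per locus (HWE), with
   $p$ drawn once per SNP from U(0.05, 0.95) by default — a flat, broadly
   polymorphic spectrum typical of filtered commercial SNP arrays;
   non-founders inherit one allele per parent per locus, independently
   across loci.
3. **Phenotypes**: $y = \mu + W_\alpha\alpha + W_\delta\delta + e$ with
   effects drawn i.i.d. normal and rescaled so the *realized* variance
   shares equal the targets exactly.  Exactness comes from two
   deflections: $\delta$ is adjusted within the column space of $W_\delta$
   so the realized dominance values are uncorrelated with the realized
   breeding values (the recorded $\delta$ stays the exact truth), and the
   noise is residualized on both genetic components.  The three variance
   contributions then add with no cross terms, and
   $\operatorname{var}(y) = 1$.

What the simulator does *not* emulate: linkage and LD (loci are unlinked;
the per-SNP derivations above are marginal, so linkage would change the
sampling variance of relationship estimates but not the means that the
tests target), selection, mutation, genotyping error, and multi-generation
drift.  Passing tests therefore demonstrate correctness of the estimators
under the model's own assumptions — not robustness to LD structure or to
misspecified allele frequencies in real panels.

## Numerical and design choices

* **Missing genotypes** default to mean imputation *in the codings*
  (additive entry 0 = its column mean; dominance entry 0 = its HWE mean),
  preserving the null-mean structure the derivations assume; `drop_snp` is
  available.  The IVb diagonal averages over non-missing SNPs instead.
* **QC** removes monomorphic SNPs always (within-SNP definitions divide by
  $2pq$) and SNPs below a MAF threshold on request; it is idempotent.  A
  SNP can be polymorphic in frequency yet have a zero *sample* additive
  variance (every individual heterozygous at $p = \tfrac12$); Definitions
  II and V refuse such panels with a contract error rather than returning
  infinities.
* **Allele orientation** is irrelevant by construction: flipping A1/A2
  negates $W_\alpha$ columns and fixes $W_\delta$, leaving every
  relationship matrix unchanged (property-tested).
* **Frequencies** default to sample-computed; an external per-SNP frequency
  file can override them, since which reference population supplies $p$ is
  a modeling choice the package does not hard-code.  Whatever frequencies
  the codings use, the definitions' denominators use the same vector.
* **Matrix files** are written at full double precision (17 significant
  digits), so square and long layouts reload bit-identically.
* **Problem sizes** used by the heavier checks were chosen to bound the
  Monte-Carlo error of each expectation well inside its tolerance: 500
  full-sib pairs with 5000 SNPs for relationship-class means (±0.02
  tolerances), and 20 replicates of a 1000-individual, 2000-SNP panel for
  heritability recovery (±0.05 on means of 20).

## Known limitations

* Dominance pedigree relationships ignore inbreeding of parents (classical
  approximation); single-step blends of pedigree and genomic matrices are
  not provided.
* The REML implementation targets one trait, one record per individual,
  and up to two genetic components; multi-trait and G×E models are out of
  scope.
* No binary PLINK `.bed` reader: text dosage (`--recode A`) and plain TSV
  layouts only, in keeping with the package's text-only data policy.
* Genomic correlations require strictly positive diagonals; an individual
  with a zero diagonal (possible only on degenerate panels) is reported by
  ID rather than silently dropped.
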