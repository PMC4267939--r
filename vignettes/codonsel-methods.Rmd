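---
title: "Models and methods behind codonsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind codonsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsel)
```

`codonsel` analyses codon usage bias and weak selection on synonymous sites
from per-gene, in-frame haplotype alignments with a single outgroup. This
vignette is the package's account of the models it implements, the
numerical choices behind them, and what its synthetic-data tests do and do
not demonstrate.

## The biological setting

Most amino acids are encoded by several synonymous codons, and in
*Drosophila* and many other taxa the most-used ("major") codon of nearly
every amino acid ends in G or C, even though mutation is biased several-fold
toward A/T. Two forces are in tension: mutation pressure, which alone would
drive third codon positions AT-rich (as observed in noncoding DNA), and
weak selection — usually attributed to translational accuracy and/or
efficiency — favouring the GC-ending majors. The package quantifies both
sides: bias statistics and the Akashi accuracy test on the selection side,
directional polymorphism rates on the mutation side, and a
site-frequency-spectrum (SFS) model that estimates them jointly.

## Codon-bias statistics

**Major codons** are identified from pooled counts as the most frequent
synonymous codon per amino acid; onefold amino acids (Met, Trp) are
excluded. Ties (never observed in real data at genomic scale) break
lexicographically and are flagged. A G-test per amino acid
(`G = 2 Σ O ln(O/E)`, `E = total/k`, `0·ln0 = 0`, df `k − 1`) measures
usage heterogeneity against the equal-usage expectation — the natural null
when the question is whether synonymous codons are used unequally at all.

**ENC** follows Wright's estimator: per amino acid with `n ≥ 2` observed
codons the codon homozygosity is `F̂ = (nΣp̂² − 1)/(n − 1)`; class averages
`F̄` over the two-, three-, four- and sixfold classes combine as
`ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`, clamped to `[20, 61]`. Wright left
the treatment of missing classes open; here a missing threefold class is
imputed as the mean of `F̄₂` and `F̄₄` (Ile is a single amino acid and often
absent from short genes), while a wholly missing two-, four- or sixfold
class drops its term and rescales the result so uniform usage still maps
to 61. Sixfold amino acids (Leu, Ser, Arg) are treated as single classes of
six codons, and Ile as one class of three, matching how the counts are
actually pooled rather than splitting 6 = 2 + 4.

**Fop** is the fraction of a gene's codons that are their amino acid's
major codon, among codons of amino acids with a defined major codon.
**CAI** is the geometric mean of relative-adaptiveness weights
`w = f/max f` computed from a reference set. Because a curated
highly-expressed reference is dataset-specific, the default reference is
the pooled usage of the top decile of genes by Fop (configurable); codons
unobserved in the reference get a floor weight of 0.01 so a single rare
codon cannot zero out a gene.

**Composition randomization.** A gene's ENC can look biased purely because
of its amino-acid composition. Each of (by default) 1000 replicates
redraws every codon uniformly among its amino acid's synonymous codons —
preserving amino-acid composition, destroying preference — and the p-value
is the fraction of replicates at least as biased (ENC no larger) than
observed. Genes with `p > 0.05` are flagged: their bias is
indistinguishable from a compositional artefact. The flag direction is
configurable because the opposite reading ("flag when p < 0.05") appears in
parts of the literature; the implemented default treats the randomized
ensemble as the null for *genuine* codon preference.

## Polymorphism and polarization

Synonymous and nonsynonymous site counts use the Nei–Gojobori fractional
scheme: each codon position contributes `s/3` synonymous sites, `s` being
the number of the three single-base changes at that position that preserve
the amino acid; changes to stop codons count as nonsynonymous, and
`syn + nonsyn = 3` exactly for every codon. π_S is the mean pairwise count
of synonymous differences divided by the haplotype-averaged synonymous site
count; pairwise comparisons skip columns with `N`/`-` in either sequence.
θ_W = S/(aₙ·sites) and Tajima's D use the standard constants.

Segregating sites are polarized against the outgroup: the ancestral allele
is the outgroup base when it matches one of the two segregating alleles,
otherwise the site stays unpolarized (and is excluded from directional
rates). A synonymous polarized site is *preferred* when the derived codon
is the major codon (minor → major) and *unpreferred* for the reverse.
Nonsynonymous polymorphisms are attributed to the amino acid of the
ancestral codon when polarized, else of the majority-allele codon — a rule
the package fixes explicitly because the counts are undefined without one.
Directional rates (GC→AT vs AT→GC) are estimated from third-position
transitions, with direction-specific site denominators counted from each
haplotype's eligible third positions; their ratio estimates the
mutational-bias parameter κ when selection is absent.

## Akashi's translational-accuracy test

For each amino acid, codon occurrences are cross-classified as major/minor
× conserved/variable, where a codon column is *conserved* when the ingroup
amino acid is monomorphic and matches the outgroup, *variable* when the
ingroup amino acid is polymorphic, and excluded when monomorphic but
differing from the outgroup. Conservation is defined at the amino-acid
level — the test's original framing — with a nucleotide-level mode behind a
flag, since "site" is ambiguous in parts of the literature. ψ = ad/bc per
stratum and the Mantel–Haenszel combination
`ψ_MH = Σ(a_k d_k/n_k)/Σ(b_k c_k/n_k)` pool evidence across amino acids;
sparse strata are usually absorbed by the pooling, and an optional
Haldane–Anscombe +0.5 correction covers zero cells when a per-stratum ψ is
needed. Codons are counted per haplotype by default (sample size weights
strata); a per-column majority-codon mode is provided because either
reading of the test is defensible.

## The SFS selection model

Each synonymous site is a reversible two-allele system. With the focal
state (by convention the one whose carrier counts index the spectrum)
mutating in at scaled rate θ01 = 4Nₑμ01, out at θ10 = 4Nₑμ10, and under
selection γ = 4Nₑs (γ > 0 favours the focal state), the focal-state
frequency has Wright's stationary density
φ(x) ∝ x^(θ01−1)(1−x)^(θ10−1)e^(γx). Binomial sampling of n haplotypes
gives the closed form

p_i ∝ C(n,i) · B(i+θ01, n−i+θ10) · ₁F₁(i+θ01; n+θ01+θ10; γ),

normalised over i = 0..n, including the monomorphic classes — the model
fits mutation parameters, so the monomorphic sites are informative and no
outgroup polarization is required. The confluent hypergeometric function is
evaluated as a positive-term series in log scale (Kummer's transformation
handles γ < 0), and the closed form is verified in the test suite against
adaptive quadrature of the stationary density with singularity-absorbing
endpoint substitutions (relative error below 1e-6 across 50 random
parameter draws).

**One-step expansion.** When the population size changes by a factor g,
all scaled parameters become gθ01, gθ10, gγ, and the allele-frequency
density — starting from the pre-change equilibrium — relaxes under the
Wright–Fisher diffusion for τ time units (2Nₑ-after generations each)
before binomial sampling. Numerically the forward equation is rewritten in
self-adjoint form: with f = φ·u and φ the post-change stationary density,
φ ∂u/∂t = ∂/∂x [ (x(1−x)/2) φ ∂u/∂x ]. This form has two virtues: the
rescaled equilibrium (u ≡ const) is an *exact* fixed point of the
discretisation, and the boundary singularities of φ (exponents θ−1 ≈ −1 at
realistic mutation rates) are absorbed into integrated cell masses rather
than sampled pointwise. The domain is divided into Chebyshev-clustered
finite-volume cells (default 192 for reporting, 64–96 inside optimization
loops); cell masses and binomial sampling moments are computed by 7-point
Gauss–Legendre quadrature, with power-law substitutions in the two
boundary cells. The semi-discrete system is advanced by Crank–Nicolson
time stepping with tridiagonal Thomas solves in compiled code, on a
geometric time-step ramp (120 steps spanning four orders of magnitude)
whose first two steps are implicit Euler (Rannacher smoothing) so the
stiff transients excited at τ ~ 10⁻³ are damped rather than rung.
Time stepping in the natural cell basis was chosen deliberately over a
spectral (eigendecomposition) propagator: when the pre- and post-change
densities differ by large factors (|gγ| of order 10²), the symmetrised
eigenbasis spans hundreds of orders of magnitude and eigenvector round-off
injects order-one log-likelihood noise, which litters the surface with
spurious optimizer traps; the diagonally dominant tridiagonal solves keep
per-cell relative accuracy and leave the likelihood smooth at the 10⁻⁶
level, which multi-start maximisation requires. The solver is
validated against an independent Wright–Fisher binomial-transition-matrix
oracle with 2N = 400 and g-rescaled per-generation rates (total variation
below 5×10⁻³, including the published hard case g ≈ 24, τ = 0.003), and
against its own limits: g = 1 reduces identically to the equilibrium form,
and large τ reproduces the rescaled equilibrium. Note that the latter limit
is only numerically observable when mutation rates are O(1): at
θ ~ 0.005 the slowest mode of the diffusion (exchange of mass between the
two fixation boundaries) relaxes at rate O(θ), so τ = 10 is far from
stationarity and the limit test uses parameters where relaxation is real.

**Likelihood and fitting.** The data are multinomial over classes 0..n
(a Poisson-random-field reading differs only by a factor the data do not
identify here). L1 frees (θ01, θ10, γ, g, τ); L0 fixes g = 1 (τ drops);
NS fixes γ = 0 with the expansion retained. Positive parameters are
log-transformed, γ is unconstrained, and each Nelder–Mead start is polished
by alternating Nelder–Mead with the bounded PORT quasi-Newton routine
(`nlminb`) until neither improves — the two methods stall at different
points in the long curved valleys of the expansion likelihood, so the
alternation ratchets further than either alone (box bounds θ ∈ [1e-5, 1],
|γ| ≤ 50, g ∈ [0.02, 50], τ ∈ [1e-5, 50]). Starts are drawn log-uniform
from a seeded generator; expansion models additionally seed a start grid
from a fast equilibrium fit crossed with
(g, τ) ∈ {1.5, 4, 16} × {0.01, 0.1, 0.5} plus the best points of a short
profile over the mutational-bias ratio κ, and the winning fit is refined by
a κ-graft scan (stepped κ values grafted onto the incumbent's remaining
parameters), since κ is the direction along which competing optima arise
when they arise at all. The default of 50 random starts suits noisy real
spectra; self-consistency refits of expected spectra converge from far
fewer, and the reproduction script uses 10 plus the informed grid. Likelihood-ratio tests report 2·ΔlnL against χ² with df =
the difference in free parameters.

**Sign conventions.** γ > 0 means the focal state is favoured, and
κ = θ10/θ01 is mutation *away from* the focal state over mutation toward
it. On a spectrum indexed by major-codon counts, selection for preferred
changes appears as γ > 0 together with κ > 1 (mutational bias toward the
minor, AT-ending states); on the minor-codon spectrum both invert. These
conventions make the two spectra exact mirror images
(p_i(θ01,θ10,γ) = p_{n−i}(θ10,θ01,−γ), a property the tests assert).

**Binned fits.** `fit_binned()` partitions genes into k equal-size bins at
type-7 quantile boundaries of a covariate (Fop, recombination rate ρ),
pools one SFS per bin and fits per bin. Confidence intervals use a
site-level bootstrap (multinomial resampling of the pooled spectrum,
refitting from the bin's point estimate; 200 replicates by default) —
"iterations" of a point estimate conflate optimizer restarts and resampling
in parts of the literature, so the package reports the resampling CI and
keeps optimizer restarts a separate, documented knob.

## The synthetic-data generator

`simulate_alignments()` emulates the study design the analysis assumes: n
haplotypes across labelled arrangements (default 47 across five), genes of
a few hundred codons, and for each amino acid a two-state synonymous system
— the GC-ending codon versus its AT-ending third-position transition
partner. Per site, a focal-state frequency x is drawn from the model's
allele-frequency density (discretised on the same finite-volume grid the
solver uses), the n haplotypes are sampled binomially, and the outgroup
draws its allele from the same x before accumulating divergence (default
0.03 substitutions/site, in the range expected for a close outgroup
species) on its own lineage only — keeping conserved/variable
classification clean, as ingroup fixed differences would otherwise be
conflated with divergence. Nonsynonymous variation enters at a reduced rate
(θ ≈ 0.001) at first codon positions. Default selection parameters are the
total-dataset preferred-spectrum estimates (θ01 = 0.005, κ = 2.23,
γ = 0.788, g = 3.7, τ = 0.026). Sites are unlinked: the analysis model
assumes independent sites, so linkage (and with it Hill–Robertson
interference, the phenomenon whose *absence* of effect the statistics are
designed to measure) is deliberately not simulated. Annotations place
non-overlapping gene intervals on a 20-Mb chromosome, draw per-gene ρ from
a long-tailed log-normal (mean ≈ 0.05/bp), and label regions
proximal/inverted/distal from the first and last breakpoint intervals.

Passing tests on this generator show that the estimators recover the
parameters of the model they assume, at realistic sizes — not that real
data satisfy those assumptions. One calibration subtlety the tests made
explicit: when synonymous usage is truly 50:50 (no mutation bias, no
selection), the "major" codon estimated from the data is sampling noise,
and its winner's-curse excess concentrates in the data-rich conserved
columns, inflating the Akashi odds ratio to about 1.1 with no accuracy
selection at all; the accuracy-null calibration therefore simulates
mutation-driven (real but accuracy-independent) majors, under which
ψ_MH ≈ 1.05 at 200 genes. On real data, where majors are strongly
established, the artefact is negligible. In particular the generator has no
linkage, no gene conversion, no selection heterogeneity within a gene
class, and a single outgroup lineage with a clock-free divergence knob.

## Numerical and design notes

* Coordinates are 0-based half-open internally; GFF-style I/O is 1-based.
* Codons containing `N` or gaps are excluded from all tallies; sites with
  any ambiguous codon are excluded from the SFS (a hypergeometric
  projection to common n is the natural extension but real isochromosomal
  panels have complete calls, so exclusion is the default).
* The SFS includes monomorphic classes by default; they identify the
  mutation parameters.
* Quantile binning uses type-7 interpolation and sends boundary ties to
  the lower bin — bin membership near boundaries depends on this and it is
  therefore fixed and documented.
* QC thresholds (SNP quality ≥ 30, coverage ≥ 2, heterozygote removal,
  gene-level 0.99 coverage-quantile exclusion) are defaults of
  `qc_filter_sites()`, matching standard practice for isochromosomal
  resequencing panels.
* The parameter-recovery test draws |γ| in [0.3, 3.5]: a 5% *relative*
  recovery criterion is not meaningful as γ → 0, where the spectrum
  becomes flat in γ.
* Problem sizes in the test suite (ten to two hundred genes, 6–47
  haplotypes, 10⁴–10⁶ sites, 96-cell grids inside optimizers) were chosen
  so the full suite exercises every claim at desk scale; all sizes are
  arguments and scale up unchanged.

## Known limitations

* The expansion model supports a single size change; multi-step histories
  are out of scope.
* ψ_MH p-values (exact conditional tests) are not computed; the package
  reports the pooled odds ratio and leaves inference to resampling.
* CAI depends on the reference set; the Fop-top-decile default is a
  reasonable proxy but not a substitute for a curated highly-expressed
  gene set.
* Between-species divergence statistics (dN/dS, fixation-based tests) are
  not implemented; the outgroup serves polarization and conservation
  classification only.
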