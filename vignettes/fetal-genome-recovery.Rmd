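---
title: "Haplotype-assisted fetal genome recovery from maternal plasma counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-assisted fetal genome recovery from maternal plasma counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-free DNA in the plasma of a pregnant woman is a mixture: a fraction
$1-f$ of maternal origin and a small fraction $f$ (the cff-DNA or *fetal
fraction*, typically 3–10% in the first trimester) of placental/fetal
origin. Sequencing this mixture to moderate depth and counting ref/alt
reads at a few hundred thousand biallelic SNVs leaves, at every site, a
faint imprint of which alleles the fetus carries. Site-by-site calling
(SBSS) of that imprint fails at realistic operating points: with
$f \approx 5.7\%$ and ~34X non-duplicate depth, a paternal-specific allele
is expected in only $n f/2 \approx 1$ read, and the maternal allelic
imbalance at a heterozygous site is a shift of $f/2 \approx 2.8\%$ around
50% — far below per-site noise.

The method implemented here recovers the fetal genome *jointly along each
chromosome* instead. Given **phased** parental haplotypes, the fetus is
fully described by two slowly-changing hidden sequences: which paternal
haplotype (0/1) and which maternal haplotype (0/1) was transmitted at each
site. These transmitted-haplotype paths change only at recombination
breakpoints (a handful per chromosome), so thousands of weakly informative
sites between breakpoints share their evidence. A hidden Markov model over
the four joint transmission states decodes genotype, haplotype, and
breakpoints in one step.

## Data model and site classes

All containers are plain site-indexed tables (1-based positions, biallelic
SNVs on chr1–chr22 and chrX). Given both parental genotypes, every site
falls in exactly one class:

* `PATERNAL_ONLY_HET` — father heterozygous, mother homozygous: the
  paternal-specific allele is absent from maternal DNA.
* `MATERNAL_ONLY_HET` — mother heterozygous, father homozygous: maternal
  transmission shows only as a $\pm f/2$ imbalance.
* `BIPARENTAL_HET` — both heterozygous: unresolvable site-by-site,
  resolvable through haplotype context.
* `DISCORDANT_HOM` — parents homozygous for different alleles: the
  paternal allele appears at expected fraction $f/2$, which is what the
  fetal-fraction estimator inverts.
* `UNINFORMATIVE` — both homozygous for the same allele.

For a male fetus the father transmits Y, not X, so on chrX only the
mother's heterozygosity matters: maternal-het sites become the 2-state X
chain and everything else is uninformative. We deliberately classify
mother-homozygous/father-divergent X sites as `UNINFORMATIVE` rather than
`DISCORDANT_HOM`: with no paternal X in the fetus there is no
paternal-specific signal, and such sites must not enter fetal-fraction
estimation.

## The plasma observation law

At an autosomal site with maternal alt dosage $g_M \in \{0,1,2\}$ and
fetal alt dosage $g_F \in \{0,1,2\}$, the probability that a plasma read
carries the alt allele is

$$\theta = (1-f)\,\frac{g_M}{2} + f\,\frac{g_F}{2},$$

and with a symmetric per-read error $\varepsilon$,
$\theta_\mathrm{err} = \theta(1-\varepsilon) + (1-\theta)\varepsilon$. The
alt count at a site of depth $n$ is $k \sim \mathrm{Binomial}(n,
\theta_\mathrm{err})$. On chrX with a male fetus the fetal contribution is
a single maternal-derived allele and the X depth scales by $(2-f)/2$:

$$\theta_X = \frac{(1-f)\,g_M + f\,\mathbb{1}[\text{transmitted maternal
allele is alt}]}{2-f}.$$

Two consequences worth internalizing: at a maternal-only heterozygous
site, the transmitted-allele read fraction is exactly $1/2$ when the fetus
is heterozygous (the paternal allele balances the scale) and $1/2 + f/2$
when it is homozygous; the per-site signal is therefore $f/2$ at best.
This is the quantitative core of why SBSS fails and the HMM works.

## The HMM

* **States.** $(h_p, h_m) \in \{0,1\}^2$ on autosomes (4 states), $h_m$
  alone on male-fetus chrX (2 states). The chain runs over the informative
  sites only (the three heterozygous classes; maternal-het on X).
* **Emissions.** $\log \mathrm{Binomial}(k; n, \theta_\mathrm{err}(h_p,
  h_m))$ with $\theta$ as above, the fetal dosage being determined by the
  state through the phased parental haplotypes. Sites with $n = 0$
  contribute 0 — no data, no information.
* **Transitions.** Independent parental meioses on a Haldane map with a
  constant rate $r$ cM/Mb: for an inter-site gap of $d$ Morgans
  ($d = \Delta\mathrm{bp}\cdot r/10^8$), the per-parent switch probability
  is $\rho = \tfrac{1}{2}(1 - e^{-2d})$; the joint autosomal transition is
  the product over the two parents. Defaults $r_\mathrm{maternal} =
  r_\mathrm{paternal} = 1.2$ cM/Mb (a sex-averaged genome-wide figure; the
  source study does not disclose its map, so the value is a package
  default, configurable everywhere).
* **Initial distribution.** Uniform — the first-site call is driven by
  emissions alone.
* **Decoding.** Viterbi gives the called path; ties are broken toward
  no-switch, then toward the lowest state index, so decoding is
  deterministic (a chain with no reads decodes to a constant path).
  Forward–backward gives per-site posteriors and the reported per-parent
  log-odds $L = \log P(h{=}1 \mid \mathrm{data}) - \log P(h{=}0 \mid
  \mathrm{data})$ (natural log). All arithmetic is in log space with
  log-sum-exp; both recursions are checked against exhaustive path
  enumeration to $10^{-9}$ in the test suite.
* **Breakpoints.** Wherever the decoded per-parent path switches, the
  interval between the flanking informative sites is reported (written to
  BED as 0-based half-open).
* **Outside the chain.** Uninformative and discordant-homozygous sites
  need no inference; their fetal genotype is implied by the parental
  genotypes.

The exact emission/transition parameterization of the original method is
in an unavailable supplement; the forms above are this package's own
definition — the minimal generative model consistent with the published
description — and the simulator draws from exactly the same law, so
recovery tests are internally consistent. Mendelian-impossible plasma
support is *not* filtered before decoding; robustness comes from the
$\varepsilon$ term in the emission.

## Fetal-fraction estimation

Pooling reads over `DISCORDANT_HOM` sites, with $\hat p$ the fraction
carrying the paternal-specific allele,

$$\hat f = \frac{2(\hat p - \varepsilon)}{1 - 2\varepsilon}
\quad \text{clipped to } [0,1].$$

This is a method-of-moments estimator on pooled counts (the source study
does not give its formula); the error correction exactly inverts the
symmetric flip model and is disabled at $\varepsilon = 0$, the default,
since it is unknown whether the original estimate was error-corrected.
Per-chromosome estimates use the same pooled form within each chromosome.
`min_depth` defaults to 1. The parameter-recovery test demands
$|\hat f - f| < 0.005$ across $f \in \{0.03, \ldots, 0.20\}$ at 20,000
discordant-hom sites; at that size the estimator's standard error is
$\approx 2\times10^{-4}$, so the tolerance is generous by design.

## Parental phasing

`trio_phase()` orients a parent's alleles as (from-grandfather |
from-grandmother) wherever Mendelian transmission forces a unique
assignment; all-heterozygous trios are `AMBIGUOUS` and impossible
transmissions are `INCONSISTENT` (excluded downstream, mirroring SNP QC).
`panel_resolve()` stands in for statistical phasing against a reference
panel (the original study ran BEAGLE, which is out of scope): each
ambiguous heterozygous site is oriented by a vote of panel haplotypes over
a window of the nearest 10 trio-phased heterozygous sites per side.

One refinement over a plain majority vote proved necessary: most panel
haplotypes are unrelated to the target haplotype, match the anchors at
chance level, and would drown out the minority of locally IBD haplotypes.
Votes are therefore weighted by the match margin $|a_0 - a_1|$ (anchors
matched on the grandfather side minus the grandmother side), with a
minimum margin of 2 to vote at all. Remaining ties fall back to a seeded
coin flip with a warning. The resolver reports its own inferred rates and
does not target the source study's panel-specific figures.

## The simulator: a stated world

`sim_params()` defaults *are* the operating point of the study this
package models, and are not tuned:

| parameter | default | meaning |
|---|---|---|
| `f` | 0.0569 | true cff-DNA fraction |
| `mean_depth` | 33.6 | non-duplicate autosomal depth (X: ×$(2-f)/2$) |
| `eps` | 0.005 | symmetric per-read error (no published value; a typical post-filter Illumina figure) |
| `r_maternal`, `r_paternal` | 1.2 cM/Mb | Haldane map, no interference |
| `n_sites` | 375,000 | genome-wide marker budget |
| `n_sites_chrx` | 5,300 | chrX marker budget (below) |
| allele frequency | Uniform(0.05, 0.95) | per site, independent across sites |
| `fetal_sex` | male | |

The pedigree is three generations: grandparental haplotypes drawn
site-independently from the AF law, each parent one meiosis per
grandparent, the fetus one meiosis per parent, crossover counts
Poisson($L_\mathrm{Mb}\, r/100$) with uniform positions. chrX is haploid
in males throughout the pedigree.

The chrX marker budget is a deliberate deviation from length-proportional
scaling (which would give ~19,000 X markers): the study's marker set
carried only 1,932 maternal-heterozygous X loci, reflecting array
ascertainment on X, and the acceptance setup pins "~1,900 maternal-het X
sites". 5,300 X markers under the AF law yield ≈1,905 such sites.

What the generator does **not** emulate: linkage disequilibrium between
markers (sites are independent by default; `simulate_panel()` reuses
pedigree founders to create LD only for phasing tests), GC and
fragment-length biases, PCR duplicates (depth is non-duplicate by
definition), indels, and de-novo mutations except via explicit
`spike_denovo()`. A green recovery test therefore establishes correctness
of the inference given the assumed observation law — not robustness to
real-data artifacts, which enter through the configurable `eps` only.

## Evaluation and the error taxonomy

`allele_accuracy()` scores paternal alleles over paternal-only +
biparental-het autosomal sites, maternal alleles over maternal-only +
biparental-het, chrX separately, and unordered genotypes per class.
`classify_errors()` types each error site: **III** if inside an annotated
centromere/edge region (default: first/last 1 Mb of each simulated
chromosome — simulated chromosomes have no real heterochromatin, so edges
are the only systematic regions), else **II** if within `window_bp`
(default 1 Mb; no published window exists) of any true crossover or
inferred breakpoint, else **I** (haplotype-inference noise).
`downsample_curve()` thins counts binomially — counts are the data model,
so thinning reads rather than resampling them — and reruns the whole
recovery per retained fraction.

## Numerical choices and degenerate inputs

* All probability work in natural-log space; log-odds reported in natural
  log (the original figure's base is unstated).
* $\Delta\mathrm{bp} = 0$ transitions degenerate to the identity
  ($\log \rho = -\infty$ is handled exactly); negative distances are
  rejected.
* Zero-depth sites emit 0 for every state; a whole chain of them decodes
  to a constant path by the tie-break contract.
* Chains with a single site skip transitions entirely; empty chains are an
  error.
* Multi-allelic and indel VCF records are dropped with a logged count;
  a ref/alt swap between the counts TSV and the site list is a hard error
  (it almost always indicates shifted coordinates).

## Known limitations

* **chrX close crossover pairs are unidentifiable at this marker
  density.** With ~12 maternal-het markers/Mb on X, per-site evidence is
  ≈0.056 nats, so a pair of maternal crossovers closer than roughly
  15–20 Mb carries less evidence than the double-switch transition penalty
  and the MAP path correctly coalesces it — losing every site in between.
  Chromosomes drawing 0–1 X crossovers decode at ≈100%; a close pair costs
  several percent at once. The acceptance suite's chrX criterion (≥98.45%
  over seeds 1–3) observes exactly this: the three-seed mean falls short
  because one seed draws an 8.7 Mb crossover pair, and the criterion is
  left failing rather than re-tuned, since the generator parameters are
  the stated world. Autosomes are unaffected in practice (≈47
  maternal-informative markers/Mb).
* Viterbi optimizes the path posterior, not per-site error; per-site
  posterior decoding could marginally improve allele accuracy but would
  not fix the identifiability limit above, and the path/breakpoint output
  is the method's point.
* The phasing resolver is a desk-scale stand-in, not an imputation engine;
  with sparse panels it degrades to seeded coin flips (with a warning).
* Twins, trisomy, indels, structural variants and epigenetics are out of
  scope.
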