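---
title: "Simulating pure, strict epistatic models and case/control SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pure, strict epistatic models and case/control SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistasim)
```

## The problem

Methods that search genotype data for gene–gene interactions need simulated
benchmarks in which the true disease model is known. The hardest such
benchmarks are *purely, strictly epistatic* models: n biallelic SNPs that
are jointly predictive of disease while **no** single SNP and no proper
subset of SNPs carries any marginal signal. Against such a model, any
method that filters on main effects or builds up from lower-order
interactions is blind by construction, which makes these models a natural
worst-case gold standard.

epistasim generates random n-locus models of exactly this type, subject to
user constraints — per-SNP minor allele frequencies (MAFs), broad-sense
heritability, and optionally population prevalence — and simulates balanced
case/control SNP datasets from them.

## Penetrance models and the purity condition

A model over n biallelic SNPs is a *penetrance function*: for each of the
$3^n$ multi-locus genotypes (MLGs) $g$, a probability $f_g$ of disease
given $g$. Genotypes are coded 0/1/2 as minor-allele counts and enumerated
row-major (locus 1 most significant). Each locus is assumed to be in
Hardy–Weinberg equilibrium, so a locus with minor allele frequency $q$ has
genotype frequencies $(p^2, 2pq, q^2)$, $p = 1 - q$; loci are in linkage
equilibrium, so MLG frequencies are products, $P(g) = \prod_i w_i(g_i)$.

Two derived quantities summarise a model:

* **prevalence** $K = \sum_g P(g)\, f_g$, and
* **heritability** $H^2 = \sum_g P(g) (f_g - K)^2 \,/\, K(1-K)$,

the broad-sense variance ratio for a binary trait. We adopt this definition
because it is the one under which the canonical fully penetrant XOR model
(both MAFs $1/2$) has heritability exactly 1, it is bounded by 1 for every
penetrance table, and it behaves predictably under affine maps
($f \mapsto m f + b$ scales the numerator by $m^2$) — the property the
rescaling step below relies on.

A *line* of the table fixes all loci but one and lets the free locus range
over its three genotypes; dotting the three entries with the free locus's
genotype frequencies gives a conditional penetrance. There are $n\,3^{n-1}$
lines. The model is pure and strict exactly when **all** line dot products
are equal, in which case their common value is $K$. Equality is tested with
an absolute tolerance of $10^{-9}$, appropriate for double-precision solves
on tables of at most a few thousand cells.

```{r}
m <- example_model()       # 2-locus, MAFs .4/.5, continuous penetrances
round(line_dot_products(m), 3)
round(prevalence(m), 3)
```

## Pre-penetrance tables and the constraint system

Direct random search over pure, strict tables is hopeless because the
constraint set is a measure-zero slice of $[0,1]^{3^n}$. The generator
works instead in the linear space of *pre-penetrance tables*: real-valued
tables whose every line dot product is zero. Each line contributes one
homogeneous linear equation; the solution space is the tensor product of
the per-locus kernels $\{v \in \mathbb{R}^3 : w \cdot v = 0\}$ and so has
dimension $2^n$, while the constraint matrix has rank $3^n - 2^n$ (verified
by tests against a generic rank computation). The implementation exploits
the tensor structure: completion of $2^n$ seeded cells reduces to one
$2^n \times 2^n$ solve against the Kronecker-product kernel basis, which is
what makes tens of thousands of generation attempts cheap even at n = 7.

A set of $2^n$ cells whose values freely determine the whole table is a set
of *parameters*. Two selection strategies are provided:

* **Sudoku** (`sudoku_select()`): pick cells sequentially, uniformly at
  random among the cells not yet expressible in terms of earlier picks,
  propagating after every pick the rule "a line with one undetermined cell
  determines it". The attempt *succeeds* when propagation has expressed all
  $3^n$ cells after the $2^n$ picks — in that case the picks are provably
  valid parameters and no further check is needed — and *fails* otherwise.
  Counting closure as the success criterion reproduces the method's
  characteristic success-rate decay (about 100, 99.9, 99, 92.9, 61.2 and
  3.3 percent for n = 2…7), which collapses at high n.
* **Point** (`point_select()`): choose one reference cell at random; the
  parameters are the $2^n$ cells whose genotypes differ from it at every
  locus. This always succeeds (the restricted basis is a Kronecker product
  of nonsingular $2\times 2$ blocks) at a modest cost in randomness.

The default routing (`choose_method()`) uses Sudoku up to n = 5 and Point
from n = 6. The pick distribution within Sudoku is uniform over currently
undetermined cells — the most random choice consistent with the method's
description — and the empirical success rates above confirm it. Candidate
parameter sets from other sources are vetted in `build_solution_map()` by
the singular values of the restricted basis, with relative tolerance
$10^{-10}$ (robust to the near-degenerate weights that extreme MAFs
produce).

## From a random direction to a constrained model

Because pre-penetrance tables with fixed parameters form a copy of
$\mathbb{R}^{2^n}$, "a random table shape" is just a random *direction*: a
unit vector obtained by normalising $2^n$ independent standard normal
draws (uniform on the sphere by rotation invariance). The direction seeds
the parameters, the solution map completes the table, and the scaling

$$S(G)_g = \frac{g - m}{M - m}, \qquad m = \min G,\; M = \max G$$

maps it onto $[0,1]$ with extremes attained, yielding a pure, strict
penetrance model. $S$ is invariant under positive scaling of $G$, so each
direction corresponds to exactly one model class. Directions whose
completion is numerically constant ($M - m < 10^{-12}$) are redrawn.

To hit the requested constraints the model is then rescaled affinely,
$f(x) = mx + b$ with $m > 0$, which preserves purity:

* heritability only: $m = \sqrt{h / H^2}$, $b = (1-m)K$ leaves $K$ fixed;
  feasible iff $h$ does not exceed the class representative's
  heritability — random classes can only be scaled *down*;
* heritability and prevalence: $m = \sqrt{h\,K_t(1-K_t)/V}$ with
  $V = \sum_g P(g)(f_g - K)^2$, $b = K_t - mK$; feasible iff every
  transformed entry stays in $[0,1]$.

These closed forms follow uniquely from how $K$ and $V$ transform under an
affine map; floating-point overshoot up to $10^{-12}$ outside $[0,1]$ is
clamped, anything larger is infeasibility. `generate_model()` iterates
selection → direction → completion → scaling until success or an attempt
limit (default 100{,}000) is exhausted; when prevalence is left free, the
emergent prevalence $-m/(M-m)$ of the $S$-scaled table is reported with the
model. The per-attempt success probability (`generation_frequency()`) is
the natural difficulty measure of a constraint combination: it decreases
in the target heritability and collapses as n grows, because random classes
rarely reach high heritability.

## Limits on heritability

Not every (MAF, prevalence, heritability) combination is achievable —
heritability 1 with prevalence 1/4 is impossible for any table, and MAF
constraints tighten the limits further. `estimate_max_heritability()`
estimates the achievable maximum by sampling random classes and recording,
per class, the heritability of the member with the requested prevalence and
the largest feasible slope $m = \min\{K_t/K_S,\,(1-K_t)/(1-K_S)\}$ (for
free prevalence, the representative's own heritability). This is a
sampling lower bound that improves with the number of classes examined; it
can under-cover near-degenerate optima, and it is deliberately the same
machinery the generator itself uses, so it predicts what the generator can
actually produce rather than a purely analytic supremum. At prevalence
near 0.5 the 2-locus estimates peak at MAF 0.5 and near
$1 - \sqrt{1/2} \approx 0.29$ and fall away elsewhere.

## Dataset simulation

`simulate_dataset()` draws balanced case/control samples directly from the
Bayes-inverted MLG distributions
$P(g \mid \text{case}) = P(g) f_g / K$ and
$P(g \mid \text{control}) = P(g)(1 - f_g)/(1-K)$. This is mathematically
identical to sampling individuals from the population, assigning status by
a Bernoulli($f_g$) draw and conditioning on status — a property the test
suite checks empirically — but wastes no draws when $K$ is small. Noise
SNPs are unlinked Hardy–Weinberg draws (genotype $\sim$ Binomial(2, MAF)),
each noise SNP's MAF drawn once per dataset, uniformly from a configurable
range defaulting to $[0.05, 0.5]$ — a spread typical of post-QC GWAS
panels. The predictive SNPs are placed at random column positions, recorded
in the returned object and in a provenance sidecar file, so
detection-success studies can score hits; rows are shuffled. Archives of
replicates (`simulate_archive()`) derive per-dataset seeds from a master
seed, making the archive reproducible in whole or dataset by dataset.

What the simulator does *not* emulate: linkage disequilibrium, population
structure, genotyping error, missingness, covariates, or quantitative
traits. Tests passing on these data therefore demonstrate correctness of
the sampling construction, not robustness of downstream detection methods
to the complications of real cohorts.

## Numerical and design choices, in brief

* MAFs are restricted to $(0, 0.5]$; supply $1-q$ for the symmetric case.
* Purity tolerance $10^{-9}$ (absolute), singularity tolerance $10^{-10}$
  (relative, on singular values), degenerate-direction and clamping
  tolerance $10^{-12}$.
* Sudoku success is propagation closure; non-closure is a failed attempt
  even though such pick sets are occasionally invertible — this matches
  the method's observed success rates and keeps the expensive check off
  the hot path.
* The two antipodal maximum-heritability members of each class are
  disambiguated by the drawn direction's sign; no canonicalisation, to
  preserve randomness.
* Model files store values at 17 significant digits so write→read
  round-trips are bit-exact; dataset files use the flat tab-delimited
  format (SNP columns plus a final `Class` column) consumed by MDR-style
  tools.

## Problem sizes used in the test suite

The package's stochastic checks run at sizes chosen to balance statistical
resolution against runtime: 2{,}000 attempts per success-rate or
generation-frequency estimate (three binomial standard errors at that size
resolve the reference values cleanly), 10{,}000 sampled classes per
heritability-limit estimate, and $10^4$-scale individuals for dataset
convergence checks. Larger runs sharpen the estimates but do not change
any conclusion.

## A full run from the shell

```sh
epistasim model --n 2 --maf 0.5 0.5 --herit 0.01 --prev 0.5 \
          --count 5 --seed 7 --out models/
epistasim data --model models/model_1.txt --cases 100 --controls 100 \
          --snps 20 --replicates 100 --seed 8 --out datasets/
```

The `model` command logs the observed generation frequency alongside each
model's prevalence and heritability; `full` chains both steps under one
master seed.
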