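# epistasim

Random generation of **purely, strictly epistatic** disease models and
simulation of case/control SNP datasets from them, for benchmarking
gene–gene interaction detection methods.

## The problem

An n-locus penetrance model assigns each multi-locus genotype
g ∈ {0,1,2}ⁿ (minor-allele counts at n biallelic SNPs) a penetrance
f(g) = P(disease | g). Under Hardy–Weinberg and linkage equilibrium the
model's prevalence is K = Σ P(g) f(g) and its broad-sense heritability is

    H² = Σ_g P(g) (f(g) − K)² / (K (1 − K)).

The model is *pure* (no SNP has a main effect) and *strict* (no proper
subset of SNPs is predictive) exactly when all n·3ⁿ⁻¹ "line" dot
products — genotype frequencies of one SNP dotted with the three table
entries obtained by varying that SNP while fixing the others — are equal;
their common value is then K. Such models are the worst case for
interaction detection: nothing short of considering all n loci together
carries signal. epistasim samples them **uniformly in direction** from the
linear space of zero-margin "pre-penetrance" tables (dimension 2ⁿ inside
the 3ⁿ table cells), scales each sample onto [0,1], and rescales affinely
to hit a requested heritability and (optionally) prevalence at given MAFs.
A balanced case/control simulator then draws predictive genotypes from the
Bayes-inverted distributions P(g|case) = P(g) f(g) / K and
P(g|control) = P(g)(1 − f(g))/(1 − K), embedded among Hardy–Weinberg
noise SNPs.

## Worked example

```r
library(epistasim)
set.seed(42)

cons <- model_constraints(2, mafs = c(0.25, 0.5),
                          heritability = 0.02, prevalence = 0.3)
res <- generate_model(cons)
res
#> Model generated after 1 attempt(s)
#> Penetrance model: 2 loci, MAFs 0.25, 0.5
#>     SNP2
#> SNP1     BB     Bb     bb
#>   AA 0.3210 0.3233 0.2324
#>   Aa 0.2939 0.2848 0.3365
#>   aa 0.1481 0.1812 0.6894
#>   prevalence K = 0.3, heritability = 0.02
```

The nine penetrances are a random architecture whose row and column
weighted means all equal 0.3: each SNP alone is pure noise, yet the pair
explains 2% of the status variance, exactly as requested.

```r
ds <- simulate_dataset(res$model, n_cases = 100, n_controls = 100,
                       total_snps = 20)
ds
#> Case/control SNP dataset: 200 individuals (100 cases), 20 SNPs
#> (predictive: P1, P2)
```

The two predictive SNPs sit at random recorded columns among 18
Hardy–Weinberg noise SNPs; `write_dataset_file()` emits the flat
tab-delimited genotype/`Class` format read by MDR-style tools, and
`generation_frequency(cons, 1000)` reports the per-attempt success
probability of the constraint combination (0.739 for the one above).

From the shell, the same pipeline is

```sh
inst/cli/epistasim model --n 2 --maf 0.25 0.5 --herit 0.02 --prev 0.3 \
    --count 5 --seed 42 --out models/
inst/cli/epistasim data --model models/model_1.txt --cases 100 \
    --controls 100 --snps 20 --replicates 100 --seed 43 --out datasets/
```

Other entry points: `estimate_max_heritability()` /
`max_heritability_curve()` (empirical feasibility limits of the
heritability–prevalence–MAF space), `sudoku_select()` / `point_select()`
(the two parameter-selection strategies), `xor_model()` and
`example_model()` (reference 2-locus models), and `read_model_file()` /
`write_model_file()` for the bit-exact plain-text model format (a sample
lives in `inst/extdata/model_2locus_example.txt`).

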