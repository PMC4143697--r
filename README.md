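# fbcm — family-based Bayesian collapsing for rare-variant association

Rare variants (minor allele frequency below 1%) carry too little per-marker
information for single-SNP association tests, and population-based collapsing
tests (burden/CMC, SKAT and relatives) are vulnerable to population
stratification. `fbcm` implements a family-based Bayesian collapsing model
for quantitative traits in nuclear families that addresses both problems at
once: transmission information within families is immune to stratification,
and a hierarchical spike-and-slab model aggregates the per-variant signals of
a gene while letting the data decide which variants contribute.

## The model

For offspring *j* in family *i*, the genotypic score *G<sub>ijk</sub>*
(minor-allele count at locus *k*) is decomposed into two orthogonal parts
given the parental scores *GM<sub>ik</sub>*, *GF<sub>ik</sub>*:

- the Mendelian expectation **GE**<sub>ik</sub> = (GM<sub>ik</sub> + GF<sub>ik</sub>)/2
  (between-family component, confounded with ancestry), and
- the transmission deviation **D**<sub>ijk</sub> = G<sub>ijk</sub> − GE<sub>ik</sub>
  (within-family component, stratification-resistant).

Because an individual rarely carries minor alleles at more than two rare loci
(P(X > 2) ≈ 1.38% for X ~ Binomial(50, 0.01)), each offspring is collapsed
onto its at most two deviating loci with the smallest MAFs, indexed
r<sub>ij</sub> and s<sub>ij</sub> (0 = pseudolocus with GE = D = 0). The
phenotype model is

y<sub>ij</sub> = μ + β₁(α<sub>r</sub>·D<sub>ij,r</sub> + α<sub>s</sub>·D<sub>ij,s</sub>)
 + β₂(γ<sub>r</sub>·GE<sub>i,r</sub> + γ<sub>s</sub>·GE<sub>i,s</sub>)
 + φ<sub>i</sub> + ε<sub>ij</sub>,

with spike indicators α<sub>k</sub> ~ Bern(p<sub>k</sub>),
γ<sub>k</sub> ~ Bern(q<sub>k</sub>), p<sub>k</sub>, q<sub>k</sub> ~ Beta(1,1),
β₁, β₂ ~ N(0, σ²<sub>β</sub>), family effect φ<sub>i</sub> ~ N(0, σ²<sub>φ</sub>)
and residual ε<sub>ij</sub> ~ N(0, σ²<sub>ε</sub>). β₁ is the
within-family (association) effect; β₂ absorbs stratification-driven signal.
All full conditionals are conjugate; a Gibbs sampler written in C++ produces
full posterior draws.

Gene-level evidence is a composite-hypothesis **hybrid Bayes factor**: the
posterior versus prior odds of {|β₁| > ∈ and Σ<sub>k</sub> α<sub>k</sub> > 0},
with ∈ = 0.2·σ̂<sub>ε</sub> estimated from a null pilot fit, and the prior
odds available in closed form via the error function. Per-variant evidence is
the marginal Bayes factor of α<sub>k</sub> (prior odds 1). The decision
cutoff BF > 2 controls the type-I error below 0.005 in the packaged
simulation design.

## Worked example

Simulate the packaged family design (300 families of two sibs, 50 rare loci
at MAF 0.005, stratification effect β₂ = 0.5) with a within-family effect
β₁ = 1.5 acting through 60% of the loci, then run the full pipeline:

```r
library(fbcm)

sim  <- simulate_gene(sim_config(beta1 = 1.5, prop_causal = 0.6), seed = 42)
gene <- collapse_sim(sim)
gene
#> Collapsed gene: 50 rare loci, 300 families, 600 offspring
#> # A tibble: 600 × 10
#>    family_id family offspring      y     r     s   D_r   D_s  GE_r  GE_s
#>  5 3              3         1 -1.14     22     0   0.5     0   0.5     0
#>  ...

sigma_eps <- estimate_sigma_eps_null(
  gene, mcmc_control(iterations = 2000, chains = 1), seed = 1)
round(sigma_eps, 3)
#> [1] 1.194

fit <- fbcm_fit(gene, mcmc_control(iterations = 10000, chains = 3), seed = 2)
fit
#> Collapsed family model fit: 50 loci, 3 chain(s), 15000 kept draws
#> Posterior means: beta1 = 1.685, beta2 = 0.6902, sigma2_eps = 0.9618
#> Max R-hat (continuous parameters): 1.001

(bf <- fbcm_bf(fit, sigma_eps_hat = sigma_eps))
#> Gene Bayes factor: 57.26 (very strong)
#>   posterior odds 30000 / prior odds 523.9, epsilon = 0.2388, 15000 draws
#>   effect size (posterior mean beta1): 1.685

head(dplyr::arrange(tidy(bf), dplyr::desc(bf)), 5)
#> # A tibble: 5 × 3
#>   variant_id posterior_freq    bf
#> 1 rv008               1.000 5999.
#> 2 rv005               0.999 1428.
#> 3 rv034               0.997  336.
#> 4 rv038               0.996  239.
#> 5 rv011               0.994  161.
```

The gene BF of 57 far exceeds the cutoff of 2, and the top-ranked variants
(rv005, rv008, rv011, rv034, rv038) are all truly causal in this replicate.
The posterior mean of β₁ (the reported "effect size") is upward of the
generating 1.5; the methods vignette discusses why the unconditional
posterior mean overshoots under strong full-gene causality.

Real studies enter through standard files:

```r
study <- load_study("study.vcf", "study.ped", "phenotypes.tsv", "genes.bed")
scan  <- scan_genes(study, mcmc_control(), seed = 1)
write_results(scan, "results/")
autoplot(scan)   # Manhattan-style plot of gene Bayes factors
```

Phenotype tables may be visit-level (`individual_id`, `measurement`, `age`):
each individual's phenotype is then the natural log of the highest
measurement, with the age at that visit as a covariate. A thin command-line
front end with `simulate`, `fit`, `scan` and `power` subcommands is installed
at `inst/cli/fbcm`.

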