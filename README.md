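# admixkit

Simulation and inference tools for studying genetic admixture in human
populations, written for population geneticists who want a fully synthetic,
end-to-end testbed for the standard admixture-analysis workflow: global and
local ancestry inference, ancestry-specific masking, subcontinental
inference by haplotype painting with non-negative least squares, sex-biased
admixture statistics, population comparisons (F_ST, neighbor joining,
outgroup f3), and admixture dating from ancestry tract lengths.

Admixed genomes of the Americas are mosaics of African, European, Native
American and East Asian segments. Because the individual-level genotype
data behind published studies of such populations are typically not public,
`admixkit` pairs every estimator with a simulator that generates the data
the estimator expects — drifted founder panels, phased admixed diploid
genomes with known truth tracts, genetic maps — so every inference can be
validated against known truth.

## The quantities at the package's core

* **Ancestry fractions** `q`: per individual, the supervised likelihood
  `l(q) = sum_j [ g_j log(sum_k q_k f_kj) + (2 - g_j) log(sum_k q_k (1 - f_kj)) ]`
  is maximized over the simplex by EM, with panel allele frequencies
  `f_kj` fixed.
* **Admixture entropy**: the Shannon entropy of a population's mean
  ancestry fractions, `S = -sum_i p_i log2(p_i)` (bits); 2 bits for an
  evenly 4-way admixed population, 0 for an unadmixed one.
* **Local ancestry and masking**: windowed naive-Bayes posteriors over
  reference panels; a window is labeled only at >= 95% posterior
  certainty, and a *masked genome* keeps one ancestry's haplotype
  segments, blanking everything else.
* **Painting + NNLS**: a copying profile `b` of a masked genome over
  subcontinental reference panels is converted to ancestry proportions by
  solving `min ||Ax - b||, x >= 0`, where column `k` of `A` is the mean
  leave-one-individual-out copying profile of reference population `k`.
* **Sex-biased admixture**:
  `DeltaAdmix = F_total (F_X - F_auto) / (F_X + F_auto)` per ancestry;
  positive values indicate female-biased, negative male-biased
  contributions (the X spends 2/3 of its history in females).
* **F_ST / f3**: Hudson's ratio-of-averages F_ST and the outgroup
  f3 statistic `f3(O; A, B)` with block-jackknife errors; F_ST matrices
  feed neighbor-joining trees with site-bootstrap supports.
* **Admixture timing**: after a single admixture pulse `g` generations
  ago, ancestry tracts of a component with proportion `m` have genetic
  lengths ~ Exponential(rate `g (1 - m)` per Morgan); `g` is estimated by
  the censored-exponential MLE with a bootstrap CI.

## Worked example

Simulate four drifted founder panels, a 40-individual cohort admixed ten
generations ago at proportions (0.45, 0.20, 0.30, 0.05), then recover the
proportions and the admixture time:

```r
library(admixkit)

ps <- generate_founder_panels(K = 4, F_k = c(0.08, 0.1, 0.12, 0.1),
        n_sites = 2000, n_hap = 40, seed = 7,
        chrom_lengths_bp = setNames(rep(1e6, 8), as.character(1:8)),
        labels = c("AFR", "EUR", "NAM", "EAS"))
co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 40,
        m = c(0.45, 0.20, 0.30, 0.05), g = 10, seed = 8)

fit <- estimate_ancestry_fractions(cohort_genotypes(co),
                                   panel_frequencies(ps$panels))
summary(fit)
#> mean fractions (+- SE):
#>         AFR    EUR   NAM    EAS
#> mean 0.4503 0.1915 0.301 0.0573
#> se   0.0104 0.0089 0.010 0.0057
#> admixture entropy: 1.733 bits

tl <- collect_tract_lengths(co$tracts, ps$map, "AFR")
estimate_pulse_time(tl, proportion = 0.45, n_boot = 500, seed = 9)
#> pulse_estimate [AFR]: g_hat = 9.86 generations (95% CI 9.37-10.42)
#>   1874 tracts (1569 uncensored), raw switch rate 5.425 / Morgan
```

The cohort means recover the simulated proportions within their standard
errors, the entropy (1.733 bits) reflects a strongly 3-way admixed
population, and the tract-length estimate recovers the simulated ten
generations. `run_pipeline(demo_config(seed = 1))` chains all stages —
simulation, global/local ancestry, sex bias, painting validation,
population statistics, timing — and writes VCF/TSV/Newick/JSON outputs
with a checksummed manifest; reruns under the same seed are bit-identical.

Entropies of published populations can be computed directly from reported
mean ancestry percentages:

```r
m <- reported_ancestry_means()
p <- as.numeric(m[m$population == "Afro-Ecuadorian", -1]) / 100
round(admixture_entropy(p), 2)
#> [1] 1.48
```

## Documentation

The methods vignette (`vignettes/admixture-methods.Rmd`) describes the
models, the estimators, the numerical conventions, what the synthetic data
do and do not emulate, and the package's design decisions.
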