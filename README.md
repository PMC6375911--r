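# petrelpop

Population structure and recent demographic history of a fragmented
island seabird system — the Peruvian diving petrel (*Pelecanoides
garnotii*) of the Humboldt Current — from two marker types: a
mitochondrial cytochrome-b haplotype alignment sampled across seven
breeding colonies, and a two-island RAD-seq SNP panel. The package is the
computational core of an analysis workflow (`analysis/01_simulate.R` …
`analysis/06_calibration.R`) that exercises every step end-to-end on
synthetic coalescent data.

## What it computes

**Structure.** Haplotype summary statistics — unbiased haplotype
diversity *H*, nucleotide diversity π, mean pairwise differences *K*,
segregating sites *S*, Tajima's *D* — and hierarchical analysis of
molecular variance on squared pairwise-difference distances, decomposing
variance among island groups (σ²ₐ), among colonies within groups (σ²_b)
and within colonies (σ²_c), with

Φ_ST = (σ²ₐ+σ²_b)/σ²_tot,  Φ_SC = σ²_b/(σ²_b+σ²_c),  Φ_CT = σ²ₐ/σ²_tot,

permutation tests per level, Benjamini–Yekutieli FDR correction of the
pairwise Φ_ST matrix, and windowed Weir–Cockerham F_ST for the SNP panel.

**Demography.** The folded joint (2D) minor-allele frequency spectrum
with hypergeometric projection over missing calls and locus block
bootstrap; six two-deme demographic models (isolation,
isolation-with-migration, and post-glacial scenarios with migration
and/or size changes at a free time T₁, divergence fixed at 7,000
generations); expected spectra by branch-length accumulation over
simulated structured-coalescent genealogies; composite-likelihood
maximization (multistart ECM line searches plus Nelder–Mead polish on a
fixed genealogy stream) and AIC model comparison with bootstrap
confidence intervals.

**Calibration.** μ = rate·generation-time arithmetic (1.6 × 10⁻³
subst·site⁻¹·Myr⁻¹ × 6 yr = 9.6 × 10⁻⁹ per generation), Poisson modeling
of SNPs per RAD locus, class rates μ_S = S·μ/λ for highly polymorphic
loci, Θ/(4μ) effective sizes, Θ·M/4 migrant numbers, and the
allele-dropout one-haplotype-per-individual subsampling.

A C++ structured-coalescent engine (piecewise-constant two-or-more-deme
demographies, backward migration, deme mergers; infinite-sites SNP loci
and finite-sites Jukes–Cantor mtDNA) generates the synthetic data and the
expected spectra.

## Worked example

```r
library(petrelpop)

# seven-colony mtDNA alignment under the study conditions
aln <- simulate_study_mtdna(seed = 1)
summary_stats(aln)
#> n = 109, L = 900 sites: H = 0.678, pi = 0.00557, K = 5.009, S = 18, Tajima's D = 1.311

am <- amova(aln, n_permutations = 1000, seed = 1)
am
#> Hierarchical AMOVA (1000 permutations)
#>                               df      SSD sigma2 percent
#> among_groups                   3  54.4742 0.5226 19.3119
#> among_colonies_within_groups   3  14.8807 0.2120  7.8337
#> within_colonies              102 201.1129 1.9717 72.8544
#> Phi_ST = 0.2715 (p = 0.000999), Phi_SC = 0.0971 (p = 0.06394), Phi_CT = 0.1931 (p = 0.1748)
```

About a fifth of the molecular variance separates the four island groups
(Φ_ST = 0.27, permutation p < 0.001) while colonies within a group add
little (Φ_SC = 0.10) — the strong-philopatry regime the generator
encodes.

```r
# two-island SNP panel at the best-supported demography, folded joint SFS
gm  <- simulate_study_snp_panel(seed = 1, n_loci = 20000, scale = 10)
sfs <- folded_2dsfs(gm, "CHR", "AZR")
sfs
#> <folded_2dsfs> 22 x 20 haploid samples (23x21 cells), 2654 SNPs

# calibration arithmetic
per_generation_rate(1.6e-3, 6)   # 9.6e-09 substitutions/site/generation
scale_theta(0.00697, 3.55e-8)    # Ne = 49084.51
scale_migrants(0.00697, 2075)    # 3.615687 migrants per generation
```

The analysis drivers under `analysis/` chain these steps (simulate →
mtDNA structure → SNP structure → SFS → demographic fits → calibration)
and write their tables under `results/`.

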