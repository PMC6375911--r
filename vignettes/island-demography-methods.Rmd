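---
title: "Methods: population structure and demographic history of a two-island seabird system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and demographic history of a two-island seabird system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The Peruvian diving petrel (*Pelecanoides garnotii*), an endangered seabird
endemic to the Humboldt Current System, breeds on a handful of islands
spread over its formerly continuous range. Whether those colonies form one
panmictic population or demographically independent units decides how
census trends and conservation measures should be interpreted. The package
implements the genetic side of that question for two marker types:

* a ~900-bp mitochondrial cytochrome-b fragment sequenced in 109 birds from
  seven colonies (two on Isla Choros, one on Isla Grande de Atacama, two on
  Isla Pan de Azúcar, and two in Peru), and
* a RAD-seq SNP panel of 21 birds (11 from Choros, 10 from Pan de Azúcar)
  genotyped on tens of thousands of independent 95-bp loci.

Every computation is exercised end-to-end on synthetic data produced by the
package's own structured-coalescent generator, so the whole pipeline is
testable without the deposited reads.

# Population structure

## Distances and summary statistics

mtDNA sequences are compared by Hamming distance over jointly unambiguous
sites (pairwise deletion; a global trim to the region resolved in all
samples is available in the reader). Per colony and pooled we report the
unbiased haplotype diversity $H = \frac{n}{n-1}(1 - \sum_h p_h^2)$, mean
pairwise differences $K$, per-site nucleotide diversity $\pi = K/L$, the
number of segregating sites $S$, and Tajima's D computed from $S$ and $K$
with the standard constants. $D$ is undefined (NaN) when $S = 0$.

For SNP matrices, diversity is the sum of unbiased per-site
heterozygosities $\frac{n_i}{n_i-1} 2 p_i (1-p_i)$ over SNPs divided by the
*total* number of sequenced sites (loci × locus length), with per-site
complete-case haploid sample sizes $n_i$ (twice the called individuals);
Tajima's D uses the rounded mean $n_i$ for its constants. This mirrors how
diversity from a reduced-representation panel is scaled against the
sequenced fraction of the genome.

## AMOVA and $\Phi$-statistics

The hierarchical analysis of molecular variance partitions squared
inter-individual distances into among-group ($\sigma^2_a$),
among-colony-within-group ($\sigma^2_b$) and within-colony ($\sigma^2_c$)
components using the classical unbalanced-design expected-mean-square
coefficients, and reports
$\Phi_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_{tot}$,
$\Phi_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c)$ and
$\Phi_{CT} = \sigma^2_a/\sigma^2_{tot}$. Negative components are retained
(they are legal method output and are reported by the original analyses).
Significance uses three permutation schemes — individuals among all
colonies ($\Phi_{ST}$), individuals among colonies within their group
($\Phi_{SC}$), whole colonies among groups ($\Phi_{CT}$) — with the
tie-tolerant estimate $p = (\#\{perm \ge obs\}+1)/(B+1)$. Defaults follow
the study design: 15,000 permutations for the hierarchical AMOVA and
10,000 for pairwise $\Phi_{ST}$, both exposed as arguments.

For the haplotypic AMOVA the squared distance is taken to be the raw
pairwise-difference count (the default of Arlequin-style haplotypic AMOVA
with pairwise-difference distances). Because the source analysis does not
state whether raw or squared differences entered the decomposition, the
alternative convention is available through the `distance` argument.

The SNP AMOVA is locus-by-locus: per-locus components on complete cases
with the squared allele-count difference $(g_i-g_j)^2$ as distance —
computed through the identity $\sum_{i<j}(g_i-g_j)^2/n = \sum g^2 -
(\sum g)^2/n$ — summed over loci, with $\Phi$ statistics formed from the
summed components and one shared permutation across loci per replicate.

Pairwise mtDNA $\Phi_{ST}$ p-values are corrected with the
Benjamini–Yekutieli procedure (valid under arbitrary dependence), through
`stats::p.adjust(method = "BY")`.

Windowed $F_{ST}$ uses the Weir–Cockerham (1984) estimator, the field
default when no estimator is named: SNPs are partitioned in input order
into near-equal count blocks (RAD loci are unordered, so genomic windows
are meaningless) and the ratio-of-sums estimator is computed per window;
the mean ± sd across windows is reported.

# The structured-coalescent generator

A single continuous-time engine (in C++) drives everything stochastic:
backward-in-time lineages with per-deme coalescence rate
$\binom{k}{2}/\text{size}$ (haploid sizes; $2N$ for diploid nuclear data),
backward per-lineage migration rates, piecewise-constant epochs, and
instantaneous deme mergers. Rationale for a continuous-time (not
discrete-generation) simulator: accuracy at the low rates involved and
speed. Three front ends share it:

* **SNP panels** — one genealogy per locus, Poisson($\mu L T_{tot}$)
  mutations under infinite sites, diploids formed by random within-deme
  pairing per locus (RAD loci are treated as unlinked throughout);
  genotype codes count the globally minor allele with ties kept on the
  simulated derived allele, so downstream folding is stable.
* **mtDNA alignments** — one shared non-recombining genealogy for all
  samples and finite-sites Jukes–Cantor mutation on the 900-bp fragment,
  so recurrent mutation and haplotype reuse are possible (infinite sites
  would overstate haplotype counts on a short mitochondrial fragment).
* **expected spectra** — branch lengths accumulated into joint
  descendant-count cells (below).

Allele dropout is emulated per individual-locus: with the dropout
probability one haplotype is lost and heterozygous calls collapse to a
random homozygote (drawn per site; the within-locus identity of the lost
haplotype is not tracked, which leaves per-SNP expectations exact but
ignores within-locus correlation of multi-SNP loci — an acceptable
simplification given the one-SNP-per-locus thinning used downstream).
Locus-level missingness is superimposed the same way.

**Study conditions.** The default mtDNA design is the empirical one (seven
colonies, n = 32/11/7/27/11/12/9, four island groups). Per-colony scaled
diversity $\theta = 4\times10^{-4}$ per site with scaled migration
$2Nm = 10$ within and $0.15$ between island groups was chosen once to
match the scale of the empirical fragment — about 14 segregating sites
pooled and group-level $\Phi_{ST}$ near 0.27 — and is not revisited. The
default SNP panel simulates the best-supported demographic model (model 4
below) at its published medians, 11 + 10 diploids and 95-bp loci at
$\mu = 9.6\times10^{-9}$; at full sizes this reproduces the observed
~1.3 SNPs per polymorphic locus and a windowed $F_{ST}$ in the observed
range as predictions, not calibrations. What the generator does **not**
emulate: sequencing error, depth-dependent genotype uncertainty (hard
calls only), linked SNPs within loci beyond the shared genealogy,
selection, and recombination — so green tests support the statistical
machinery, not robustness to those artifacts. One visible consequence of
the equilibrium island model: at the migration rates that reproduce the
group-level $\Phi_{ST}$, between-group coalescence is deep, so the
pooled mitochondrial $\pi$, $K$ and Tajima's D run above their empirical
counterparts (which reflect shallow, frequency-driven differentiation
among shared haplotypes); the per-colony statistics and the variance
decomposition are the quantities the defaults were matched to.

# Folded joint site frequency spectrum

The folded 2D SFS counts SNPs by their minor-allele counts $(i, j)$ in the
two samples. Missing data are absorbed by hypergeometric projection: per
SNP and population, the observed allele count $d$ out of $c$ called
alleles contributes the expectation $P(k) = \binom{d}{k}\binom{c-d}{n-k} /
\binom{c}{n}$ at projection size $n$, and the joint cell weights are the
products across populations, accumulated as real numbers (composite
likelihood consumes real-valued spectra). SNPs with zero calls — or fewer
called alleles than the projection size — in either population are
excluded and logged. The default projection is the full haploid size for a
population without missing calls, otherwise 80% of it (rounded to even),
exposed as an argument; the deposited analysis does not state its
treatment, so the default is documented and switchable.

Folding reflects cells with pooled frequency above one half onto their
mirror; exact ties ($i+j = (n_1+n_2)/2$) are split half-weight between the
two mirror cells, with an alternative rule (assign to the
lexicographically smaller cell) behind a flag for bit-compatibility
comparisons. Folding is idempotent, the spectrum mass equals the number of
SNPs used, and the monomorphic cell is carried but excluded from
likelihoods. Bootstrap replicates resample RAD loci with replacement
(block bootstrap preserving within-locus SNPs) and rebuild each replicate
with the original projection.

# Demographic models and fitting

Six two-deme models connect Choros (deme C) and Pan de Azúcar (deme A).
Divergence is fixed at $T_0 = 7000$ generations — a conservative
post-glacial estimate — for all models except model 2, where it is free:

| model | structure | free parameters (k) |
|---|---|---|
| 1 | full isolation, stable sizes | $N_C, N_A$ (2) |
| 2 | classical isolation-with-migration | $N_C, N_A, M_{AC}, M_{CA}, T_0$ (5) |
| 3 | constant gene flow since divergence | $N_C, N_A, M_{AC}, M_{CA}$ (4) |
| 4 | migration regime change at $T_1$ | $N_{C1}, N_{A1}, M_{AC0}, M_{CA0}, T_1, M_{AC1}, M_{CA1}$ (7) |
| 5 | size change at $T_1$ | $N_{C0}, N_{A0}, N_{C1}, N_{A1}, M_{AC}, M_{CA}, T_1$ (7) |
| 6 | both change at $T_1$ | all nine (9) |

Parameter counts follow the published estimate table (model 4 lists only
one size per deme, so sizes are shared across epochs there). Migration
parameters are backward per-generation lineage-migration probabilities:
$M_{AC}$ moves a lineage currently in A into C. Epoch 1 is the recent
period $[0, T_1)$, epoch 0 the older $[T_1, T_0)$.

Two structural choices were open and are resolved as follows. A literal
"infinite divergence" for model 1 makes the conditional-on-polymorphism
spectrum improper under branch-length simulation (the root branch
accumulates unbounded mass), so model 1 uses the same fixed
$T_0 = 7000$ as models 3–6 with migration identically zero, keeping
k = 2. The estimate table lists no ancestral size, so at $T_0$ the demes
merge into deme C at its oldest-epoch size (model 2 uses its free $N_C$);
the refugial island is the natural ancestral stand-in and the choice only
affects the deepest part of the genealogy.

**Expected spectra.** For each simulated genealogy every branch adds its
length to the cell indexed by its descendant counts in the two demes; the
accumulated matrix is folded, the monomorphic cell zeroed, and the result
normalized over the polymorphic support — the standard branch-length
estimator of the conditional SFS. The composite log-likelihood is
$\ln CL = \sum_c o_c \ln e_c$ in natural log (AIC comparisons are
log-base invariant only if consistent; everything here is natural log).
Expected cells below the floor $\varepsilon = 1/(10 \times \text{total
simulated branch mass})$ are raised to $\varepsilon$ and the expectation
renormalized, so SNPs observed in cells the finite simulation left empty
stay finite; uses of the floor are logged.

**Optimization.** The likelihood is maximized on the log-parameter scale
under box constraints that double as log-uniform initialization ranges.
The search is organized as restarts with successive halving: every run
starts from a log-uniform draw and gets a short screening block of ECM
cycles — one golden-section line search per parameter, in a bracket
around the current value that shrinks over cycles, on a Monte Carlo size
that grows over cycles — after which the best quarter of runs completes
the remaining cycles. Models with a regime change additionally get one
line search per cycle along the ridge direction that rescales $T_1$ while
holding the cumulative recent migration $T_1 \times M_{*1}$ fixed, which
is the direction the folded spectrum constrains least. All evaluations of
a fit share one fixed genealogy stream (sample-average approximation), so
the optimized surface is deterministic and improvements are real rather
than noise; endpoints are rescored on a fresh stream before the best run
is chosen, and an optional Nelder–Mead polish on the same fixed stream
follows the curved ridges that one-parameter-at-a-time moves cannot. A
run stops early when the relative lnCL improvement over a cycle falls
below $2\times10^{-5}$ — on a composite likelihood of order $10^4$ SNPs
this matches the Monte Carlo noise floor; a looser relative tolerance
(e.g. $10^{-3}$) fires tens of lnCL units too early on these surfaces.
AIC $= 2k - 2\ln CL_{max}$, with $\Delta$AIC and Akaike weights in the
comparison table.

For the regime- and size-change models (4–6) a staged strategy
(`fit_model_staged`) treats $T_1$ as a profile parameter. The
constant-migration model 3 is fitted first to pin the deme sizes and the
average gene flow. An ascending log-spaced $T_1$ grid is then swept:
at each fixed $T_1$ the remaining parameters are maximized by a short
simplex search — a well-conditioned subproblem once $T_1$ is held fixed —
with each grid point warm-started from its predecessor (continuation)
and all evaluations on one fixed stream, so the profile values are
directly comparable. The two leading profile points then receive a deep
free-$T_1$ simplex polish at full Monte Carlo size (which also recovers
the likelihood a fixed-$T_1$ conditional optimum leaves on the table,
material for AIC comparisons), and the winner is chosen by a fresh
high-precision evaluation. Profiling is what makes
basin selection reliable: the near-degenerate modes along the
$T_1 \times M_{*1}$ ridge differ by only a few lnCL units, free searches
barely move $T_1$ off their starting value, and plain random multistart
rarely places a run in each basin.

**Budgets.** The published scheme — 50 runs × 80 ECM cycles × $10^5$
spectra per evaluation, 50 bootstrap replicates each refit with 50 runs —
is restored by passing those numbers (the `"paper"` budget of the
analysis driver). Desk-scale work uses 6–10 runs, 4–12 cycles and
2,000–20,000 genealogies; the acceptance studies state their sizes below.
Bootstrap refits share one fit seed across replicates (common random
numbers), so identical replicates refit identically and CI width reflects
data variation, not optimizer noise; percentile 2.5/50/97.5 summaries are
reported.

# Calibration arithmetic

The background genomic rate for water birds, $1.6\times10^{-3}$
substitutions·site⁻¹·Myr⁻¹, times a 6-year generation time gives $\mu =
9.6\times10^{-9}$ per generation — exact, linear arithmetic. SNP counts
per neutrally evolving locus are modeled as Poisson($\lambda$): $\lambda$
is the sample mean (the empirical anchor is 1.3 SNPs per polymorphic
locus) with a tail-pooled $\chi^2$ goodness-of-fit. Loci with $S$
polymorphisms evolve at the class rate $\mu_S = S\mu/\lambda$, and a
weighted average over the classes $S \in \{4,5,6\}$ calibrates the
haplotype-based inference. The per-class locus counts behind the published
weighted average ($3.55\times10^{-8}$) are unprinted; observed class
counts are used as weights when data are supplied, truncated-Poisson
masses otherwise, and the two conventions bracket the published value
(≈$3.16$–$3.69\times10^{-8}$ at $\lambda = 1.3$).

Scaling conventions are stated in the output because the source scaling is
ambiguous: diploid nuclear $\Theta = 4N_e\mu$ per site, hence $N_e =
\Theta/(4\mu)$, and with the mutation-scaled immigration rate $M = m/\mu$
the migrant number is $Nm = \Theta M / 4$. Note that
$\Theta_{CHR} = 0.00697$ with $\mu = 3.55\times10^{-8}$ gives
$N_e = 49{,}085$ under this convention, not the published ≈58,600 (the
implied factor ≈3.35 matches no standard ploidy convention); the package
implements the standard arithmetic and documents the discrepancy. The
allele-dropout correction randomly draws one haplotype per individual per
locus: homozygotes are deterministic, heterozygote draws are fair, and
allele-frequency expectations are unchanged while heterozygosity
information is halved.

# Numerical choices and degenerate inputs

* Permutation p-values use "greater or equal" counting with the +1
  correction (valid p-values under ties).
* Colonies with a single member are allowed in AMOVA but logged; empty
  groups are errors; all-identical sequences give zero components and NaN
  $\Phi$.
* Half-missing VCF calls (`./1`) are treated as missing; multi-allelic
  and indel rows are dropped with logged counts; sites with more than 25%
  missing calls are dropped by default (the panel kept sites genotyped in
  ≥75% of individuals).
* VCF coordinates are 1-based; internal SNP indices 0-based; alignment
  columns are reported 0-based half-open in logs.
* Seeds are mandatory for every stochastic operation; derived seeds stay
  below $2^{31}$; identical seeds reproduce byte-identical outputs.

# Scale of the validation studies

The test suite validates the machinery at sizes a desk machine completes
in minutes, chosen as the package's own study sizes: analytic-form checks
of the folded spectrum use $10^5$ SNPs; permutation-uniformity checks use
500 null data sets × 1,000 permutations; the model-recovery study
simulates the best-supported model at its published medians with deme
sizes divided by 10 and $10^4$ SNPs, fits with the staged procedure
(nested model-3 fit, a six-point two-pass $T_1$ profile sweep at 1,200
genealogies per evaluation, and an 800-iteration deep free-$T_1$ simplex
polish of the two leading profile points at 3,000 genealogies), and asks that the regime-change time land
in its published 95% CI in at least half of 20 replicates; model
identification (1 vs 2, 3 vs 4) asks the generating model to win by AIC
in at least 80% of 20 replicates, with both models rescored on a common
fresh stream. The recovery check is the one validation this package
does not currently pass: at these study sizes the staged fit places
$T_1$ inside the published interval in roughly a third of replicates
(see the limitation below), while the identification checks hold. The published point estimates themselves are not reproducible
at these sizes — they require the empirical spectrum and the full budget —
so recovery and identification properties stand in for them.

# Known limitations

* The composite likelihood treats SNPs as independent; its AIC ranks
  models but its curvature understates uncertainty — hence bootstrap CIs.
* The folded projected spectrum weakly identifies jointly compensating
  parameter combinations: the $T_1 \times M_{*1}$ ridge carries
  near-degenerate modes a few lnCL units apart. A simplex polish started
  at the generating parameters converges to the correct basin in every
  replicate we examined, so the information is present; but ranking the
  competing basins requires converging each candidate to its basin
  floor, which costs several times the desk-scale evaluation budget. In
  consequence the staged fit recovers $T_1$ inside its published 95% CI
  in only ~30–35% of desk-scale replicates; reliable $T_1$ recovery
  needs the full published budget (or equivalently more Monte Carlo
  compute per likelihood evaluation).
* The mtDNA generator's island model is symmetric within groups; it does
  not emulate source-sink asymmetries or founder events.
* Hard genotype calls only; genotype-likelihood workflows are out of
  scope.
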