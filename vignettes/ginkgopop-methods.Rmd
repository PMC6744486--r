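---
title: "Models and methods behind ginkgopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ginkgopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ginkgopop)
```

ginkgopop packages the population-genomic inference chain used to
reconstruct the demographic history of ginkgo (*Ginkgo biloba*): a
structured-coalescent simulator for the four-lineage
split-plus-admixture demography, the diversity and differentiation
statistics reported for the resequenced lineages, identity-by-state (IBS)
distances with the dispersal classification, structure inference (PCA,
neighbor joining, model-based ancestry), SFS composite-likelihood
demographic fitting with model comparison, and a two-pronged selection
scan. Because the underlying resequencing data are tens of terabytes of
raw reads, the package ships a synthetic-data module that emulates the
study conditions; every stage is testable without downloads.

## The demographic model

`ginkgo_model()` builds the best-fit demography: four extant lineages —
EAST, SOUTH, NORTH, SWEST — where SWEST diverged from the EAST+SOUTH
ancestor 515,780 years ago, EAST and SOUTH split 318,120 years ago, and
NORTH was founded 139,260 years ago by an instantaneous admixture pulse
of 71.55% SOUTH and 28.45% SWEST ancestry. The most recent common
ancestral population has diploid effective size $N_e = 50{,}514$;
descendant lineages were inferred in the range 24,819–32,093, so the
default descendant size is the midpoint 28,456 and each deme is
individually overridable. The size of the intermediate EAST+SOUTH
ancestor is not separately reported; we default it to the ancestral
50,514 (the pre-split epoch size) and expose it as `n_es`.

Two scaling constants convert between coalescent and calendar units: a
generation time of 20 years and a mutation rate of $0.67\times10^{-9}$
per site. Whether that rate is per year or per generation is not
unambiguous in the source material; the numerical consistency of
$4 \times 50{,}514 \times (20 \times 0.67\times 10^{-9}) \approx
2.7\times10^{-3}$ with the reported per-site diversity
($\pi \approx 2.2$–$2.4\times10^{-3}$) supports the per-year reading, so
that is the default, with `mu_is_per_generation = TRUE` switching the
interpretation.

Model invariants are enforced at construction: positive sizes and times,
pulse fractions in $[0,1]$ summing to one within $10^{-9}$, and exact
time conversion $t_{\text{gen}} = t_{\text{years}} / g$. Lineages left
without an ancestral path (e.g. a split time proposed below the time of
a deme's founding pulse) raise an error at simulation time; the fitting
machinery converts that error into a large finite penalty so bracketed
searches traverse invalid parameter regions gracefully.

## The coalescent engine

Genealogies are drawn backwards in time: within a deme of diploid size
$N$, each pair of lineages coalesces at rate $1/(2N)$ per generation; at
a split time the child deme's lineages move to the parent; at a pulse
each recipient lineage independently chooses a source with the stated
fractions. Time is continuous; simultaneous events are applied in their
(deterministic) compiled order — splits before pulses at equal times.
There is no recombination within a locus and free recombination between
loci, matching the genome-wide-SNP assumption of SFS composite
likelihood, and no migration after splits, consistent with the reported
absence of recent gene flow among the ancient lineages.

The expected joint site frequency spectrum is estimated by Monte Carlo:
every branch contributes its length to the cell indexed by its number of
descendant leaves per deme, and polymorphic cells are normalized to
sum to one. The engine is written in C++ (allocation-free inner loop,
incremental per-deme bookkeeping) because demographic fitting evaluates
the expected spectrum thousands of times; 20,000 replicates of the
80-lineage four-deme spectrum take well under a second.

Genotype matrices are simulated per locus: one genealogy, a Poisson
number of mutations at rate $\mu_{\text{gen}} \times L \times
\text{total branch length}$, infinite-sites placement at distinct
uniform positions, and diploid genotypes formed by pairing consecutive
haploid lineages within a deme. A single seeded generator drives each
run and the seed is recorded in the VCF header, making output
byte-reproducible.

What the generator does *not* emulate: sequencing error, genotype
likelihoods and depth-dependent missingness, recombination within loci,
linkage disequilibrium structure, and selection simulated
forward-in-time (the sweep injection below is a spectral caricature).
Passing tests therefore validate the statistical machinery under the
model's assumptions, not robustness to real-data artefacts.

## Diversity, differentiation, and IBS

Per-site nucleotide diversity uses the unbiased frequency form
$\pi = \tfrac{1}{L}\sum_s \tfrac{n_s}{n_s-1}\, 2 p_s (1-p_s)$, which
equals the average pairwise difference count divided by $L$; Watterson's
estimator is $\theta_W = S/(a_{n-1} L)$. Summary tables report standard
deviations across 100 kb windows. $F_{ST}$ defaults to Hudson's
estimator in ratio-of-averages form (the source names no nuclear
estimator; Weir–Cockerham is available behind `estimator = "wc"`), with
negative values reported as computed.

IBS distance between two individuals is
$\sum_s |g_i - g_j| / (2m)$ over the $m$ pairwise-complete sites — the
`1 - ibs` distance of standard genotype tooling. The dispersal
classification applies the bracket rule: distances below 0.03 mark
near-identical pairs (recent dispersal or introduction), $[0.03, 0.07)$
earlier introductions, $[0.07, 0.09]$ intermediate, and above 0.09 deep
between-lineage divergence.

For the joint SFS from genotypes, sites with any missing call in the
involved populations are excluded; genotype-likelihood-weighted allele
frequency projection (as in easySFS-style workflows) is not
re-implemented — hard-call counting is a deliberate simplification. Folding merges complementary cells, with
hinge cells (total count exactly $n/2$) keeping half of the merged mass
so totals are preserved.

## Structure inference

PCA standardizes each polymorphic site as $(g - 2p)/\sqrt{2p(1-p)}$,
mean-imputes missing entries (0 after centering), forms the relationship
matrix $XX^\top/M$, and reports eigenvalue-over-trace percent variance,
matching the variance-standardized relationship matrix convention of
PLINK's `--pca`. Neighbor joining is delegated to `ape::nj()` behind a
validating wrapper; rows are pre-sorted lexicographically so ties
resolve deterministically, and negative branch lengths (an NJ artefact)
are permitted but flagged.

Ancestry estimation maximizes the binomial likelihood
$\sum_{i,s} g_{is}\log(q_i^\top p_s) + (2-g_{is})\log(1-q_i^\top p_s)$
by EM-style block relaxation (frappe-type multiplicative updates chosen
over quasi-Newton for clarity), from seeded random starts with a
multi-restart wrapper. Component frequencies are clipped to
$[10^{-6}, 1-10^{-6}]$ to keep the likelihood finite; convergence is a
log-likelihood gain below $10^{-4}$. The log-likelihood is provably
non-decreasing per iteration and the tests assert it on every trace.
Cross-validation masks a random $1/n_{\text{folds}}$ share of
non-missing genotype *entries* per fold (the masking scheme of the
ADMIXTURE software) and scores masked entries by squared error against
the expected genotype $2\,QP$.

## Demographic fitting

The composite likelihood is multinomial over polymorphic cells,
$\ln L = \sum_c m_c \ln p_c$, with monomorphic cells masked (the SNP
convention of fastsimcoal-style inference; the observed monomorphic
count is unused). Expected spectra floor empty cells at
$1/(10\, n_{\text{sims}}\, n_{\text{cells}})$ before renormalization so
the likelihood stays finite.

Two likelihood reductions are offered. The default scores the full joint
lattice. The `pairwise_2d` mode reduces the joint spectrum to its six
two-dimensional marginals, folds each, and sums their composite
log-likelihoods — the 2D-SFS convention of the original fastsimcoal
analysis. We recommend (and use, in our own validation) the pairwise
mode for four-deme problems: the full $21^4$-cell lattice is so sparse
at desk-scale simulation counts that floor penalties on empty cells
dominate the signal, while the 2D marginals concentrate the same
information in a few hundred cells. Profile diagnostics under the
generating model show the pairwise objective peaking at the true
parameter values where the full-lattice objective drifts.

Optimization is cyclic conditional maximization: a bracketed 1-D
golden-section search per free parameter (log-space for scale
parameters), cycled until the gain is negligible — the
coordinate-conditional spirit of ECM. The Monte-Carlo objective is
stabilized by common random numbers: one simulation seed per cycle,
refreshed between cycles, and a fresh common batch to compare restart
endpoints on equal footing. The original study ran each model 100 times
with 100,000 simulations; the package defaults scale this to 3 restarts
of 20,000 simulations — full settings remain reachable through the
arguments.

Model comparison uses $\mathrm{AIC} = 2k - 2\ln\hat L$ and Akaike
weights $w_i \propto \exp(-\Delta_i/2)$; shipped templates cover the
full admixture model, a bifurcating no-admixture alternative (NORTH as a
simple SOUTH offshoot), and a single constant-size deme, enabling the
comparison workflow end to end. Confidence intervals come from
parametric bootstrap: multinomial draws of $n_{\text{sites}}$ sites from
the fitted spectrum, refit per replicate, percentile 2.5/97.5 bounds.

### Validation protocol and problem sizes

`ginkgo_parameter_recovery()` is the package's headline validation:
simulate the joint SFS for 10 diploids per lineage with 50,000
coalescent replicates under the published best-fit values, then
re-estimate one parameter with the others fixed at truth (admixture
fraction; the two split times; the pulse time; the ancestral size).
With 20,000 simulations per likelihood evaluation and two seeded
restarts, recoveries across seeds land within about 2% for the times,
one percentage point for the admixture fraction, and 5% for the
ancestral size — comfortably inside the ±5-point and ±15% envelopes the
acceptance checks assert. These problem sizes are the package's chosen
desk-scale defaults; they are also what `scripts/acceptance.R` runs.

## Selection scan

Windowed statistics use 0-based half-open 100 kb windows (a site is
assigned by `floor(pos / window_bp)`); windows under `min_snps` (default
10) are reported missing, and $Z$-transformation is computed
chromosome-set-wide over non-missing windows. A window is called
selected when differentiation is extreme *and* focal diversity depleted:
$Z_{F_{ST}} \ge 2.326$ and $Z_{H_E} \le -2.326$ by default — the 1%
normal tails; the original study's exact cutoffs live in supplementary
material, so the thresholds are configurable rather than asserted.
Window sizes of 50/100/200 kb mirror the robustness check of the
original analysis.

The CLR scan implements the SweepFinder model as used by SweeD, on
folded spectra (no outgroup polarization in scope): at grid position $x$
and intensity $\alpha$, a lineage at distance $d$ escapes the sweep with
probability $p_e = 1 - e^{-\alpha d}$; given $k \sim
\mathrm{Bin}(n, p_e)$ escapees, the site's spectrum is the genome-wide
background hypergeometrically projected to $k$ lineages with the $n-k$
non-escapees collapsed onto the swept class. The folded background is
first unfolded symmetrically (each minor-allele class split equally
between $j$ and $n-j$), the mixture is computed unfolded, then folded
and conditioned on polymorphism. $\mathrm{CLR}(x) = 2[\max_\alpha \ln
L_{\text{sweep}} - \ln L_{\text{background}}]$, floored at zero — the
large-$\alpha$ limit reproduces the background exactly, so the
statistic is non-negative by construction. $\hat\alpha$ is maximized
over 21 log-spaced grid values ($10^{-5}$–$10^{2}$ per bp): bounded,
deterministic, and adequate given the statistic's plateau behaviour.
Escape probabilities are bucketed to $1/1000$ and the per-bucket sweep
spectra cached, which bounds the whole scan at ~1000 spectrum
computations regardless of site count.

The simulator's `sweep_injection` creates a detectable signature by
redrawing the derived count of each site inside the named interval from
a completed-sweep spectrum: a site at distance $d$ from the interval
centre has per-lineage escape probability rising from `escape_frac` at
the centre toward one at the edges
($p = 1 - (1-\text{escape\_frac})\,e^{-2d/w}$ with $w$ the half-width);
escapee lineages carry counts projected from the neutral spectrum and
non-escapees all carry the swept allele. At the centre this reduces to
counts in $\{n-1, n\}$ — count $n$ is monomorphic and dropped, thinning
diversity — and the signature grades into the background at the edges.
The gradient matters: a spatially uniform injection is *undetectable in
principle* by the exponential-kernel CLR model (no single $\alpha$ can
make distant swept sites look swept while nearer neutral sites look
escaped), whereas the graded form mirrors the recombination-during-sweep
decay the detector models. This remains a spectral caricature of a hard
sweep, not a forward simulation; it exercises the detector's
localization, and the window counts or gene lists of the original study
are explicitly not reproduction targets.

## Numerical choices and limitations

* Zero-cell floors, frequency clipping, and the invalid-model penalty
  are the three guards keeping likelihoods finite; all are documented
  above with their magnitudes.
* NJ ties and simultaneous demographic events resolve by fixed
  deterministic orders (lexicographic labels; compiled event order).
* The IBS classification boundary convention is exactly
  $[0, 0.03)$, $[0.03, 0.07)$, $[0.07, 0.09]$, $(0.09, 1]$.
* Real-data effects — genotype error, missingness structure, linkage,
  reference bias — are out of the generator's scope, so recoveries here
  bound what the machinery can do under its own assumptions, not what
  any pipeline achieves on raw reads.
* PSMC-style sequential-Markov inference, chloroplast haplotype
  networks, species distribution modeling, and annotation-dependent
  enrichment analyses are outside the package's scope.
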