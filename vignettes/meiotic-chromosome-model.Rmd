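---
title: "Modelling meiotic chromosome organisation with confined worm-like chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling meiotic chromosome organisation with confined worm-like chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meioMC)
```

## The model

During early meiosis, chromosomes reorganise dramatically: centromeres that
were clustered at one nuclear pole (the Rabl configuration) release, telomeres
attach to the nuclear envelope, and the telomeres then cluster near the
spindle pole body (SPB) to form the bouquet. meioMC asks a purely physical
question about this programme: how much homologue juxtaposition do
confinement, tethering, clustering and chain stiffness produce *on their own*,
before any homology-sensing biochemistry is invoked?

Each chromosome is a discretised worm-like chain: `N` loci
$x_1, \dots, x_N$ joined by `N - 1` inextensible rods of length $b$,
confined to a sphere of radius $R$ (1000 nm; all distances are reported as
fractions of the 2 µm nuclear diameter, ND). The genomic-to-physical mapping
assumes a 30-nm fibre: contour length = bp × 0.34 nm / 40, where 0.34 nm is
the B-DNA rise and 40 the fibre compaction factor; both are exposed as
parameters of `chromosome_spec()`. At the production discretisation
(`N = 300`) the rod length is ~6.8 nm for chromosome I (240 kb) and ~43 nm
for chromosome IV (1530 kb).

The conformational energy, in units of $k_BT$ ($\beta = 1$), is

$$E = g\beta \sum_{i=1}^{N-2} (1 - \hat t_i \cdot \hat t_{i+1})
      \;+\; \sum_i V_{\mathrm{conf}}(x_i)
      \;-\; \nu \sum_{j \in \mathrm{tethered}} \hat\mu \cdot \hat x_j ,$$

with $\hat t_i$ the unit rod vectors. The three terms are:

* **Bending.** The discrete stiffness is mapped from the persistence length
  by $g\beta = \ell_p / b$, the standard small-angle discretised-WLC
  correspondence. Because this mapping is approximate at finite $b$, the
  package validates it against the exact discrete Kratky–Porod relation
  $\langle\cos\theta\rangle = \coth(g\beta) - 1/(g\beta)$ and the closed-form
  $\langle R^2 \rangle$ (`discrete_wlc_r2()`); the unconfined sampler
  reproduces both within Monte Carlo error. Two regimes are studied:
  flexible, $\ell_p = 0.2$ µm (interphase-like), and rigid,
  $\ell_p = 2.0$ µm.
* **Confinement.** Hard-core: zero inside the sphere, infeasible outside.
  The boundary itself is allowed (tethered loci live there). Infeasibility is
  represented by an exact `Inf` sentinel, never a large float, so the
  Metropolis accept/reject decision is exact.
* **Clustering.** Tethered loci (the centromere, or both telomeres) are
  constrained *exactly* onto the sphere surface and feel a von Mises–Fisher
  (vMF) potential $-\nu\, \hat\mu \cdot \hat x$ pulling them toward the SPB
  direction $\hat\mu$ (the +z axis by default). $\nu = 0$ leaves tethered
  loci uniform on the surface; $\nu = 50$ clusters them tightly. The vMF
  normalising constants are dropped: $\nu$ is constant within a run, so they
  cancel in every Metropolis ratio. Realised clustering is an emergent
  property — the chain connecting two telomeres reweights their joint
  distribution, typically concentrating them beyond what the bare vMF factor
  alone would produce.

An optional intrachromosomal excluded-volume term treats loci as 40-nm hard
spheres. Pairs within `ceiling(40 / b)` positions along the contour are
exempt, since contour neighbours necessarily sit closer than 40 nm whenever
$b < 40$ nm; a literal all-pairs rule would make every fine discretisation
infeasible. The term is off by default: for the persistence lengths studied
it has negligible influence, which can be reproduced by comparing runs with
`excluded_volume = TRUE`.

The six named conditions map onto tether mode and $\nu$ as: `no_tether`
(free chain), `rabl` (centromere tethered, $\nu = 50$), `telomeres_tethered`
($\nu = 0$), `early_bouquet` ($\nu = 5$), `loose_bouquet` ($\nu = 10$) and
`tight_bouquet` ($\nu = 50$). The loose-bouquet level follows the 5/10/50
ladder used to label the bouquet series; the intermediate level $\nu = 20$
remains available as an explicit override of `make_condition()`.

## Sampling

Conformations are drawn from the Boltzmann distribution by Metropolis MCMC
(`run_chain()`, compiled core). Every proposal is a rigid rotation of a
contiguous block of loci, so the hard constraints are maintained by
construction rather than by penalty:

* **Crankshaft** — rotate the loci strictly between two anchors about the
  axis through them. Valid under every tether mode (anchors never move); in
  centromere mode segments strictly containing the centromere are excluded.
  Segment lengths are drawn log-uniformly so both local wiggles and global
  rearrangements are proposed; the angle amplitude is scaled by
  $\sqrt{2/s}$ for segment length $s$ so acceptance stays roughly uniform
  across scales.
* **Pivot** — rotate everything beyond a pivot locus about a random axis
  through it. Only proposed for chain sides containing no tethered locus.
* **Arm rotation** — rotate one side of a pivot locus about the axis through
  the *origin* and that locus. This preserves every locus norm and every rod
  length exactly, so it moves tethered loci across the sphere surface while
  respecting both confinement and tethering. It is also what makes the
  doubly tethered chain ergodic: crankshafts fix their anchors (so the
  telomeres never move) and whole-body rotations preserve the relative
  telomere geometry, so without arm rotations the telomere–telomere angle
  could never change.
* **Rigid rotation** — rotate the whole chain about a random axis through
  the origin. Free ($\Delta E = 0$) whenever $\nu = 0$ or nothing is
  tethered, which makes orientational statistics decorrelate quickly.

The default mix is 0.70 crankshaft / 0.15 pivot / 0.15 rigid for free
chains, 0.55 / 0.30 / 0.15 with centromere tethering (pivots restricted to
centromere-free sides), and 0.70 crankshaft / 0.15 arm / 0.15 rigid with
telomere tethering. Proposal amplitudes are auto-tuned during burn-in only,
targeting 30–50% acceptance per move class, and frozen afterwards so the
post-burn-in chain is exactly stationary. Degenerate proposals (coincident
crankshaft anchors, a pivot locus at the origin) are counted as rejections.

Incremental energy differences touch only the one or two joints whose angle
changes; a dedicated consistency check confirms they agree with a full
recomputation to better than $10^{-8}\,k_BT$ over tens of thousands of random
moves. Because moves apply a fresh Rodrigues rotation to current coordinates
(rotations are never composed symbolically), rod-length drift stays below
$10^{-9}$ relative over production-length runs, which the conformance
validator (`validate_conformation()`) enforces with tolerances of $10^{-9}$
relative on rods and $10^{-6}$ nm on tether and confinement.

**Initial conformations** are grown by constrained random growth: steps are
vMF-biased along the previous rod with concentration $g\beta$ (falling back
to uniform when confinement leaves no stiff-compatible step), rejected if
they leave the sphere. A telomere-tethered chain is grown from one tethered
surface point under a reachability constraint
($|x_i| \ge R - (N - 1 - i)\,b$) that guarantees the far end can reach the
surface, and the final rod is solved exactly on the feasible circle. Any
feasible start suffices — equilibration is the burn-in's job.

**Schedules.** The production (`"paper"`) schedule is 10 million attempted
steps, 3 million discarded as burn-in, and thinning by 40 (175,000 retained
conformations). One "sample" is one attempted Metropolis step. The
workstation (`"desk"`) default keeps the 30% burn-in fraction and thin-40 but
reduces the total to 4 million steps, retaining 70,000 conformations per
chain — enough that ensemble means carry Monte Carlo standard errors of a few
thousandths of an ND, while a full condition (two chromosome copies) runs in
well under a minute on one CPU. Homologues are two independent chains with
sub-seeds derived from the run seed by fixed offsets (`seed*100 + 1, 2`), so
a whole experiment is reproducible from one integer.

## Analytics

Retained samples of two chains are paired by index: the k-th sample of each
copy is one "nucleus". Since the energy has no inter-chromosome terms,
correlation between copies arises only through the shared SPB direction —
faithful to the model. From the paired ensembles the package computes:

* **Locus distance maps** (`intra_ldm()`, `inter_ldm()`): N×N mean pairwise
  distances in ND fractions (normalisation constant 2R = 2000 nm applied at
  construction; raw nm matrices are kept alongside). Intra maps are
  symmetric with zero diagonal; homologue maps carry the allelic distances
  on the diagonal; heterologue maps are not symmetric in general. Every map
  is asserted to lie in [0, 1] — two points in the sphere are at most one
  diameter apart.
* **Allelic profiles** (`allelic_profile()`): the homologue-map diagonal,
  telomere to telomere, with the per-locus standard deviation of the allelic
  distance across nuclei. The uncertainty band is the per-locus SD across
  retained samples (not the standard error of the mean), and it is labelled
  as such.
* **Rank-score curves** (`rank_scores()`): means sorted ascending (stable
  sort) and averaged in equal consecutive bins. Inputs are constructed to
  divide evenly — 300 allelic means into 300 bins, 90,000 heterologue means
  into 300 bins of 300, 89,700 ectopic means into 299 bins of 300 — and any
  other size is an error, never a silent truncation.
* **Condition comparisons** (`compare_conditions()`): two-sided two-sample
  Kolmogorov–Smirnov and Wilcoxon rank-sum tests on mean-distance vectors
  (`stats::ks.test`, `stats::wilcox.test`; the rank-sum test uses the
  normal approximation with continuity and tie corrections at large n and
  the exact distribution below 50 observations). Distance-map means are
  strongly spatially correlated, so these p-values characterise separation
  of the distributions rather than independent-sample inference.
* **Telomere clouds** (`telomere_cloud()`): end-locus positions from evenly
  spaced retained nuclei, for the dot-on-sphere visualisations.

## Validation oracles and test problem sizes

The test-suite checks the sampler against independent routes that share no
sampling code with it: the exact discrete Kratky–Porod $\langle R^2\rangle$
and $\langle\cos\theta\rangle$ for unconfined chains (with a direct,
non-MCMC chain grower as a second, brute-force route), the closed-form vMF
mean resultant length $\coth\nu - 1/\nu$ for the direct spherical sampler, a
chi-squared comparison of a 4-locus chain's joint-angle distribution against
exact Boltzmann bin weights, and uniformity of unclustered tethered
telomeres on the sphere. A discretisation scan (`convergence_scan()`)
re-runs one condition at several N with the contour and persistence length
held fixed and confirms the production statistic has plateaued: the mean
pairwise intra-chromosome distance at N = 150 lies within 2% of N = 300.
Global spread statistics of tethered chains relax slowly, so each scan point
averages several independent chains; the statistical tests use schedules
between 0.5 and 2 million steps (10,000–35,000 retained states), sizes at
which the checked effects exceed their Monte Carlo errors several-fold.

## What the simulations do and do not represent

The ensembles emulate steady-state conformational statistics of single
chromosomes (or independent pairs) under confinement, tethering and
clustering. Passing tests therefore demonstrate correct sampling of the
stated physical model — not that the model captures every feature of real
meiotic nuclei. Deliberately outside the model: inter-chromosomal excluded
volume and whole-genome crowding, the nucleolus and other prohibited
subnuclear regions, rapid prophase movements (the sampler has no time axis),
homology-dependent pairing forces, sister chromatids, and heterogeneous
per-region compaction. Centromere genomic positions are approximate,
configurable values recorded with every run. Where figures derived from the
model are compared against published ensemble statistics, agreement within a
few hundredths of an ND is the expected scale of fidelity, limited both by
Monte Carlo error on extreme-value statistics and by the approximations
above.

Two bookkeeping notes. Retained-ensemble sizes are always reported as the
actual count `floor((n_total - n_burn_in)/thin)` rather than a nominal
figure. And the `scale_presets()` schedules are package defaults, not
physical parameters: any schedule can be passed explicitly where stronger
equilibration is wanted (stiff, long chains are the slowest-mixing cases —
for chromosome IV at $\ell_p = 2$ µm the desk and production schedules agree
within Monte Carlo error, which was checked by direct comparison).

## A worked run

```{r example}
bundle <- run_homologue_experiment("tight_bouquet", "chrI",
                                   persistence_nm = 200,
                                   scale = "desk", seed = 1)
bundle
max(bundle$allelic_profile$mean_nd)   # widest allelic separation, ND
max(ectopic_means(bundle$map))        # widest nonallelic separation, ND
plot_ldm(bundle$map)
plot_allelic_profile(bundle$allelic_profile)
```
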